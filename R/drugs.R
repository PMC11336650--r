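#' Code drug-gene interaction labels directionally
#'
#' Maps the closed label vocabulary to integer codes: -1 for
#' 'DECREASED_EXPRESSION', 'NEGATIVE_RESPONSE' and 'OPPOSITE_RESPONSE'
#' (the drug decreases the gene's activity), +1 for 'INCREASED_EXPRESSION'
#' and 'POSITIVE_RESPONSE', and 0 for 'UNDIRECTED' (no directional
#' evidence). Unknown labels are rejected with the offending rows listed.
#'
#' @param raw data frame with columns `drug_id`, `gene_id`, `label`
#'   (and optionally `atc3`).
#' @return The input with an integer `code` column appended.
#' @export
code_interactions <- function(raw) {
  stopifnot(all(c("drug_id", "gene_id", "label") %in% names(raw)))
  vocab <- c(stats::setNames(rep(-1L, 3), DRUG_LABELS$decrease),
             stats::setNames(rep(1L, 2), DRUG_LABELS$increase),
             stats::setNames(0L, DRUG_LABELS$undirected))
  unknown <- !(raw$label %in% names(vocab))
  if (any(unknown)) {
    stop("unknown interaction label(s) at row(s) ",
         paste(utils::head(which(unknown), 10), collapse = ", "), ": ",
         paste(utils::head(unique(raw$label[unknown]), 5), collapse = ", "),
         call. = FALSE)
  }
  raw$code <- unname(vocab[raw$label])
  raw
}

#' Filter drugs to those testable for enrichment
#'
#' Retains drugs interacting with at least `min_genes` distinct genes that
#' have an available association statistic.
#'
#' @param interactions coded interaction table (see
#'   [code_interactions()]).
#' @param gene_stats named numeric vector of gene-level statistics; names
#'   define gene availability.
#' @param min_genes minimum measured genes per drug (default 2).
#' @return Character vector of retained drug ids.
#' @export
filter_testable_drugs <- function(interactions, gene_stats, min_genes = 2) {
  measured <- interactions[interactions$gene_id %in% names(gene_stats), ]
  counts <- tapply(measured$gene_id, measured$drug_id,
                   function(g) length(unique(g)))
  names(counts)[!is.na(counts) & counts >= min_genes]
}

# exact two-sided permutation p-value of the signed concordance statistic:
# enumerate every assignment of the drug's code vector to ordered m-tuples
# of distinct universe genes
signed_exact_p <- function(codes, z, s_obs, es) {
  n <- length(z); m <- length(codes)
  combos <- utils::combn(n, m)
  perms <- unique_permutations(codes)
  dev_obs <- abs(s_obs - es) - 1e-12
  hits <- 0; total <- 0
  for (ci in seq_len(ncol(combos))) {
    zz <- z[combos[, ci]]
    for (pi in seq_len(nrow(perms))) {
      s <- sum(perms[pi, ] * zz)
      total <- total + 1
      if (abs(s - es) >= dev_obs) hits <- hits + 1
    }
  }
  hits / total
}

# Wilcoxon rank-sum p-value: exact for small untied samples, midranks with
# normal approximation and continuity correction when ties are present
# (identical drug-level statistics arise legitimately when two drugs share
# the same measured interactions).
ranksum_p <- function(x, y, alternative) {
  tied <- anyDuplicated(c(x, y)) > 0
  stats::wilcox.test(x, y, alternative = alternative,
                     exact = if (tied) FALSE else NULL,
                     correct = TRUE)$p.value
}

# Monte Carlo permutation p-value: resample code-to-gene assignments from
# the universe. Drawing with replacement is used when the drug covers a
# negligible fraction of the universe (collision probability ~ m^2/2N);
# otherwise true without-replacement draws.
signed_mc_p <- function(codes, z, s_obs, es, B = 4999) {
  m <- length(codes); N <- length(z)
  idx <- if (m / N <= 0.1) {
    matrix(sample.int(N, m * B, replace = TRUE), m, B)
  } else {
    vapply(seq_len(B), function(i) sample.int(N, m), integer(m))
  }
  s_null <- colSums(codes * matrix(z[idx], m, B))
  (1 + sum(abs(s_null - es) >= abs(s_obs - es) - 1e-12)) / (B + 1)
}

unique_permutations <- function(x) {
  if (length(x) == 1) return(matrix(x, 1, 1))
  out <- list()
  for (v in unique(x)) {
    rest <- x[-match(v, x)]
    sub <- unique_permutations(rest)
    out[[length(out) + 1L]] <- cbind(v, sub, deparse.level = 0)
  }
  unique(do.call(rbind, out))
}

#' Signed drug-gene concordance enrichment
#'
#' For each drug, the raw concordance S = sum over its directional
#' interactions of code * Z measures whether the drug pushes expression in
#' the disease-risk direction. S is standardized under the permutation
#' null in which the drug's codes are reassigned to genes drawn without
#' replacement from the measured gene universe; the closed-form null
#' moments are E[S] = mu_Z * sum(codes) and
#' Var[S] = sigma^2_Z * (N * sum(codes^2) - (sum codes)^2) / (N - 1) with
#' population moments over the universe. The reported z is the negated
#' standardized S, so positive z means the drug opposes the risk-direction
#' expression profile (predicted protective). Two-sided p-values come from
#' the permutation null itself: exact enumeration when the drug has at
#' most `exact_limit` directional genes and the enumeration is small,
#' Monte Carlo resampling of code-to-gene assignments otherwise (the gene
#' universe after clumping is short-tailed, so a normal approximation to a
#' few-term sum is unreliable); q is BH across drugs.
#'
#' @param gene_z named numeric vector of signed gene-level Z-scores over a
#'   clumped, approximately independent gene universe.
#' @param interactions coded interaction table.
#' @param min_genes minimum measured genes for a drug to be tested.
#' @param exact_limit maximum directional-gene count for the exact
#'   permutation p-value (default 8); exactness additionally requires the
#'   enumeration size to stay below ~1e5 assignments.
#' @return Data frame (`drug_id`, `z`, `p`, `q`, `n_genes`) with attribute
#'   `"statistic"` describing the sign convention. Drugs whose codes are
#'   all 0 are excluded with a message.
#' @export
signed_drug_enrichment <- function(gene_z, interactions, min_genes = 2,
                                   exact_limit = 8) {
  stopifnot(!is.null(names(gene_z)))
  testable <- filter_testable_drugs(interactions, gene_z, min_genes)
  z <- gene_z
  N <- length(z)
  mu <- mean(z)
  sig2 <- mean((z - mu)^2)  # population variance of the universe
  rows <- list()
  dropped <- character()
  for (d in testable) {
    di <- interactions[interactions$drug_id == d &
                         interactions$gene_id %in% names(z), ]
    di <- di[!duplicated(di$gene_id), ]
    di <- di[di$code != 0, , drop = FALSE]
    if (nrow(di) == 0) { dropped <- c(dropped, d); next }
    codes <- di$code
    zz <- unname(z[di$gene_id])
    S <- sum(codes * zz)
    es <- mu * sum(codes)
    vs <- sig2 * (N * sum(codes^2) - sum(codes)^2) / (N - 1)
    zstd <- (S - es) / sqrt(vs)
    m <- length(codes)
    n_assign <- choose(N, m) * nrow(unique_permutations(codes))
    p <- if (m <= exact_limit && n_assign <= 1e5) {
      signed_exact_p(codes, z, S, es)
    } else {
      signed_mc_p(codes, z, S, es)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      drug_id = d, z = -zstd, p = p, n_genes = m, stringsAsFactors = FALSE)
  }
  if (length(dropped)) {
    message(length(dropped), " drug(s) with no directional codes excluded from the signed test")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(drug_id = character(), z = numeric(), p = numeric(),
                      n_genes = integer(), stringsAsFactors = FALSE)
  }
  out$q <- if (nrow(out)) bh_fdr(pmin(pmax(out$p, .Machine$double.xmin), 1)) else numeric()
  attr(out, "statistic") <- "signed concordance; positive z = predicted protective"
  out[c("drug_id", "z", "p", "q", "n_genes")]
}

#' Unsigned drug enrichment by rank-sum test
#'
#' One-sided Wilcoxon rank-sum comparison of a drug's member genes'
#' association values (chi-square scale, direction ignored) against all
#' non-member genes of the universe.
#'
#' @param gene_assoc named numeric vector of unsigned gene association
#'   values (e.g. squared Z).
#' @param interactions coded interaction table (direction is ignored).
#' @param min_genes minimum measured genes per drug.
#' @return Data frame (`drug_id`, `z`, `p`, `q`, `n_genes`); z is the
#'   normal quantile of the one-sided p.
#' @export
unsigned_drug_enrichment <- function(gene_assoc, interactions,
                                     min_genes = 2) {
  stopifnot(!is.null(names(gene_assoc)))
  testable <- filter_testable_drugs(interactions, gene_assoc, min_genes)
  rows <- lapply(testable, function(d) {
    member <- unique(interactions$gene_id[interactions$drug_id == d])
    member <- intersect(member, names(gene_assoc))
    non <- setdiff(names(gene_assoc), member)
    if (length(non) == 0) {
      stop("drug ", d, " covers the entire gene universe; no comparator",
           call. = FALSE)
    }
    p <- ranksum_p(gene_assoc[member], gene_assoc[non],
                   alternative = "greater")
    data.frame(drug_id = d,
               z = stats::qnorm(pmin(pmax(p, 1e-300), 1 - 1e-16),
                                lower.tail = FALSE),
               p = p, n_genes = length(member), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(drug_id = character(), z = numeric(), p = numeric(),
                      n_genes = integer(), stringsAsFactors = FALSE)
  }
  out$q <- if (nrow(out)) bh_fdr(pmin(pmax(out$p, .Machine$double.xmin), 1)) else numeric()
  attr(out, "statistic") <- "unsigned rank-sum; z = qnorm(1 - p)"
  out[c("drug_id", "z", "p", "q", "n_genes")]
}

#' ATC level-3 drug-class enrichment
#'
#' Wilcoxon rank-sum test of each ATC class's drug-level statistics (the
#' drug z) against all other tested drugs: two-sided for signed
#' drug statistics (direction summarized by the class median z), one-sided
#' (greater) for unsigned statistics. Classes with fewer than `min_drugs`
#' tested drugs are skipped. FDR correction is applied across classes.
#' A drug mapped to several classes contributes to each unless
#' `multiple = "first"`.
#'
#' @param drug_results output of [signed_drug_enrichment()] or
#'   [unsigned_drug_enrichment()] (or an external drug-level table with
#'   columns `drug_id` and `z`).
#' @param atc_map data frame `drug_id`, `atc3`.
#' @param min_drugs minimum class size (default 5).
#' @param sided `"two"` (signed statistics) or `"one"` (unsigned).
#' @param multiple `"all"` or `"first"` ATC membership per drug.
#' @return Data frame (`atc3`, `n_drugs`, `median_z`, `direction`, `p`,
#'   `q`).
#' @export
atc_enrichment <- function(drug_results, atc_map, min_drugs = 5,
                           sided = c("two", "one"),
                           multiple = c("all", "first")) {
  sided <- match.arg(sided)
  multiple <- match.arg(multiple)
  stopifnot(all(c("drug_id", "atc3") %in% names(atc_map)),
            all(c("drug_id", "z") %in% names(drug_results)))
  if (multiple == "first") atc_map <- atc_map[!duplicated(atc_map$drug_id), ]
  stat <- stats::setNames(drug_results$z, drug_results$drug_id)
  map <- atc_map[atc_map$drug_id %in% names(stat), , drop = FALSE]
  rows <- list()
  for (cls in sort(unique(map$atc3))) {
    members <- unique(map$drug_id[map$atc3 == cls])
    if (length(members) < min_drugs) next
    others <- setdiff(names(stat), members)
    if (length(others) == 0) {
      stop("ATC class ", cls, " contains every tested drug; no comparator",
           call. = FALSE)
    }
    p <- ranksum_p(stat[members], stat[others],
                   alternative = if (sided == "one") "greater" else "two.sided")
    med <- stats::median(stat[members])
    rows[[length(rows) + 1L]] <- data.frame(
      atc3 = cls, n_drugs = length(members), median_z = med,
      direction = if (med >= 0) "protective" else "deleterious",
      p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(atc3 = character(), n_drugs = integer(),
                      median_z = numeric(), direction = character(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE))
  }
  out$q <- bh_fdr(pmin(pmax(out$p, .Machine$double.xmin), 1))
  rownames(out) <- NULL
  out
}
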