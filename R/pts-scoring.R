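#' Pairwise predicted-expression correlation within a genomic window
#'
#' Computes Pearson correlations between all feature pairs (features are
#' gene x panel predicted-expression tracks, ids `"gene|panel"`) whose
#' gene intervals lie within `window_bp` of each other. Distance is the
#' gap between the closest interval edges (overlapping intervals have gap
#' 0), so co-located features are always paired. Zero-variance features
#' are dropped with a warning.
#'
#' @param pred_expr numeric matrix, features x reference individuals, with
#'   feature ids as rownames.
#' @param annotation gene annotation (`gene_id`, `chrom`, `start`, `end`).
#' @param window_bp pairing window in base pairs (default 500 000).
#' @return A [feature_correlation()] object.
#' @export
correlation_from_predicted_expression <- function(pred_expr, annotation,
                                                  window_bp = 500000) {
  stopifnot(is.matrix(pred_expr), !is.null(rownames(pred_expr)))
  if (ncol(pred_expr) < 3) {
    stop("need at least 3 reference individuals", call. = FALSE)
  }
  sds <- apply(pred_expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance feature(s) dropped")
    pred_expr <- pred_expr[sds > 0, , drop = FALSE]
  }
  feats <- rownames(pred_expr)
  if (length(feats) == 0) {
    warning("all features constant; empty correlation")
    return(feature_correlation(
      data.frame(feature_i = character(), feature_j = character(),
                 r = numeric()), window_bp))
  }
  gene_of <- sub("\\|.*$", "", feats)
  gidx <- match(gene_of, annotation$gene_id)
  if (anyNA(gidx)) {
    stop("features not present in annotation: ",
         paste(utils::head(feats[is.na(gidx)], 5), collapse = ", "),
         call. = FALSE)
  }
  chrom <- annotation$chrom[gidx]
  start <- annotation$start[gidx]
  end <- annotation$end[gidx]

  pairs <- list(); k <- 0L
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    idx <- idx[order(start[idx])]
    for (a in seq_along(idx)) {
      i <- idx[a]
      for (b in seq_along(idx)[-seq_len(a)]) {
        j <- idx[b]
        gap <- max(0, max(start[i], start[j]) - min(end[i], end[j]))
        if (gap <= window_bp) {
          k <- k + 1L
          pairs[[k]] <- c(i, j)
        }
      }
    }
  }
  if (k == 0L) {
    return(feature_correlation(
      data.frame(feature_i = character(), feature_j = character(),
                 r = numeric()), window_bp))
  }
  ij <- do.call(rbind, pairs)
  r <- vapply(seq_len(nrow(ij)), function(row) {
    stats::cor(pred_expr[ij[row, 1], ], pred_expr[ij[row, 2], ])
  }, numeric(1))
  feature_correlation(
    data.frame(feature_i = feats[ij[, 1]], feature_j = feats[ij[, 2]],
               r = r, stringsAsFactors = FALSE), window_bp)
}

#' Greedy correlation clumping of TWAS features
#'
#' Sorts features by p-value (ties broken lexicographically by feature
#' id), takes the next unremoved feature as a lead, and removes every
#' unremoved feature whose squared correlation with the lead exceeds
#' `r2_threshold`. Correlations absent from `corr` are 0: features beyond
#' the window are independent by construction.
#'
#' @param records data frame with columns `feature` (or `gene_id` +
#'   `panel`, combined as `"gene|panel"`) and `p`; one row per feature.
#' @param corr a [feature_correlation()] object.
#' @param r2_threshold squared-correlation removal threshold (default 0.1).
#' @return Character vector of retained (lead) feature ids, in order of
#'   selection.
#' @export
clump <- function(records, corr, r2_threshold = 0.1) {
  records <- as.data.frame(records)
  if (!"feature" %in% names(records)) {
    stopifnot(all(c("gene_id", "panel") %in% names(records)))
    records$feature <- paste(records$gene_id, records$panel, sep = "|")
  }
  if (anyDuplicated(records$feature)) {
    stop("duplicated features in clump input; resolve records to one per feature first",
         call. = FALSE)
  }
  feats <- records$feature
  ord <- order(records$p, feats)
  # adjacency restricted to pairs above the threshold
  pr <- corr$pairs[corr$pairs$r^2 > r2_threshold &
                     corr$pairs$feature_i %in% feats &
                     corr$pairs$feature_j %in% feats, , drop = FALSE]
  adj <- split(c(pr$feature_j, pr$feature_i),
               c(pr$feature_i, pr$feature_j))
  removed <- stats::setNames(rep(FALSE, length(feats)), feats)
  leads <- character()
  for (f in feats[ord]) {
    if (removed[[f]]) next
    leads <- c(leads, f)
    nb <- adj[[f]]
    if (!is.null(nb)) removed[nb] <- TRUE
  }
  leads
}

#' Build a polytranscriptomic score weight set
#'
#' Filters TWAS records to a tissue stratum and (optionally) to
#' colocalised associations (PP4 > `pp4_cut`), applies the p-value
#' threshold, clumps on the predicted-expression correlation, and averages
#' Z across the surviving features that share a gene. Records are reduced
#' to one per gene x panel feature (smallest p) before clumping, since two
#' association methods share one predicted-expression feature.
#'
#' @param records TWAS record data frame (as from
#'   [simulate_twas_sumstats()]); protein-molecule records are excluded.
#' @param corr a [feature_correlation()] object.
#' @param threshold p-value inclusion threshold.
#' @param stratum `"all"`, `"blood"` or `"brain"`.
#' @param coloc_only keep only records with `pp4 > pp4_cut`.
#' @param pp4_cut colocalisation PP4 cut-off (default 0.8).
#' @param r2_threshold clumping threshold (default 0.1).
#' @param clump_mode `"pooled"` (default: one clumping pass over all
#'   panels, cross-panel correlation supplied by `corr`) or
#'   `"per-panel"` (clump within each panel, then merge).
#' @return An object of class `weight_set`: list with `weights` (named
#'   numeric, gene -> averaged Z, all finite and non-zero), `threshold`,
#'   `stratum`, `coloc_only`, `n_features_pre_clump`, `n_genes`.
#' @export
build_weight_set <- function(records, corr, threshold = 1,
                             stratum = c("all", "blood", "brain"),
                             coloc_only = FALSE, pp4_cut = 0.8,
                             r2_threshold = 0.1,
                             clump_mode = c("pooled", "per-panel")) {
  stratum <- match.arg(stratum)
  clump_mode <- match.arg(clump_mode)
  rec <- as.data.frame(records)
  if ("molecule" %in% names(rec)) rec <- rec[rec$molecule == "expression", ]
  if (stratum != "all") rec <- rec[rec$stratum == stratum, ]
  if (coloc_only) rec <- rec[!is.na(rec$pp4) & rec$pp4 > pp4_cut, ]
  rec <- rec[rec$p <= threshold, , drop = FALSE]
  empty <- function(n_pre) {
    warning("empty weight set (no records survive filtering); scores will be 0")
    structure(list(weights = stats::setNames(numeric(0), character(0)),
                   threshold = threshold, stratum = stratum,
                   coloc_only = coloc_only, n_features_pre_clump = n_pre,
                   n_genes = 0L), class = "weight_set")
  }
  if (nrow(rec) == 0) return(empty(0L))
  rec$feature <- paste(rec$gene_id, rec$panel, sep = "|")
  rec <- rec[order(rec$p, rec$feature), ]
  rec <- rec[!duplicated(rec$feature), , drop = FALSE]
  leads <- if (clump_mode == "pooled") {
    clump(rec, corr, r2_threshold)
  } else {
    unlist(lapply(split(rec, rec$panel), clump, corr = corr,
                  r2_threshold = r2_threshold), use.names = FALSE)
  }
  kept <- rec[match(leads, rec$feature), , drop = FALSE]
  w <- tapply(kept$z, kept$gene_id, mean)
  w <- stats::setNames(as.numeric(w), names(w))
  if (any(w == 0)) {
    message(sum(w == 0), " gene(s) with exactly zero averaged Z dropped")
    w <- w[w != 0]
  }
  if (length(w) == 0) return(empty(nrow(rec)))
  w <- w[order(names(w))]
  structure(list(weights = w, threshold = threshold, stratum = stratum,
                 coloc_only = coloc_only,
                 n_features_pre_clump = nrow(rec),
                 n_genes = length(w)),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("Weight set: %d genes (threshold %g, stratum %s%s; %d features pre-clump)\n",
              x$n_genes, x$threshold, x$stratum,
              if (x$coloc_only) ", colocalised only" else "",
              x$n_features_pre_clump))
  invisible(x)
}

#' Standardize an expression matrix gene-wise
#'
#' Centers and scales each gene to mean 0 and unit sample standard
#' deviation (n - 1 denominator) across all samples of the cohort (cases
#' and controls pooled). Zero-variance genes are dropped with a warning.
#'
#' @param x an `expression_cohort` or a genes x samples numeric matrix.
#' @return A standardized genes x samples matrix.
#' @export
standardize_expression <- function(x) {
  mat <- if (inherits(x, "expression_cohort")) x$expr else x
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2) stop("need at least 2 samples to standardize", call. = FALSE)
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " constant gene(s) dropped during standardization")
    keep <- sdv > 0
    mat <- mat[keep, , drop = FALSE]; mu <- mu[keep]; sdv <- sdv[keep]
  }
  (mat - mu) / sdv
}

#' Compute polytranscriptomic scores
#'
#' Each individual's score is the sum of their standardized expression
#' values over the weight-set genes, each weighted by the gene's averaged
#' TWAS Z. Weight-set genes missing from the expression matrix are
#' skipped; the realized overlap is reported as `n_genes_used`.
#'
#' @param z_expr standardized genes x samples matrix (see
#'   [standardize_expression()]).
#' @param weights a [build_weight_set()] object.
#' @return A data frame (`sample_id`, `score`) of class `pts_vector`, with
#'   attributes `n_genes_used` and `weight_set` (descriptor list).
#' @export
compute_pts <- function(z_expr, weights) {
  stopifnot(inherits(weights, "weight_set"), is.matrix(z_expr))
  overlap <- intersect(names(weights$weights), rownames(z_expr))
  if (length(overlap) == 0 && weights$n_genes > 0) {
    warning("no weight-set genes measured on this platform; all scores are 0")
  }
  score <- if (length(overlap)) {
    drop(crossprod(z_expr[overlap, , drop = FALSE],
                   weights$weights[overlap]))
  } else {
    stats::setNames(rep(0, ncol(z_expr)), colnames(z_expr))
  }
  out <- data.frame(sample_id = colnames(z_expr), score = unname(score),
                    stringsAsFactors = FALSE)
  attr(out, "n_genes_used") <- length(overlap)
  attr(out, "weight_set") <- weights[c("threshold", "stratum", "coloc_only",
                                       "n_genes")]
  class(out) <- c("pts_vector", "data.frame")
  out
}
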