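#' Collapse probe-level expression to gene level
#'
#' Averages intensities across probes for each gene (via
#' `limma::avereps`), then log2-transforms, matching the standard
#' preprocessing of two-colour/bead-array case-control series.
#'
#' @param probe_mat probes x samples numeric matrix with probe rownames;
#'   values must be positive (they are logged).
#' @param probe_map data frame `probe_id`, `gene_id`, total on the matrix
#'   rows.
#' @return Gene x sample matrix of log2 expression.
#' @export
preprocess_expression <- function(probe_mat, probe_map) {
  stopifnot(is.matrix(probe_mat), !is.null(rownames(probe_mat)))
  idx <- match(rownames(probe_mat), probe_map$probe_id)
  if (anyNA(idx)) {
    stop("probe map does not cover matrix rows: ",
         paste(utils::head(rownames(probe_mat)[is.na(idx)], 5),
               collapse = ", "), call. = FALSE)
  }
  gene_mat <- limma::avereps(probe_mat, ID = probe_map$gene_id[idx])
  bad <- which(gene_mat <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive value at gene '%s', sample %d; cannot log2",
                 rownames(gene_mat)[bad[1, 1]], bad[1, 2]), call. = FALSE)
  }
  log2(gene_mat)
}

#' Per-gene case-control correlation (observed differential expression)
#'
#' Pearson correlation between 0/1 case status and each gene's observed
#' expression; two-sided p from the t transform with n - 2 degrees of
#' freedom; BH q across genes. Constant genes are dropped with a warning.
#'
#' @param cohort an `expression_cohort`, or a list with `expr` (genes x
#'   samples) and `pheno` (`sample_id`, `case`).
#' @return Data frame `gene_id`, `platform`, `r`, `n`, `p`, `q`.
#' @export
per_gene_case_control_correlation <- function(cohort) {
  expr <- cohort$expr
  status <- cohort$pheno$case[match(colnames(expr), cohort$pheno$sample_id)]
  if (sum(status == 1) < 3 || sum(status == 0) < 3) {
    stop("need at least 3 cases and 3 controls", call. = FALSE)
  }
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped")
    expr <- expr[sds > 0, , drop = FALSE]
  }
  n <- ncol(expr)
  r <- drop(stats::cor(t(expr), status))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  data.frame(gene_id = rownames(expr),
             platform = if (!is.null(cohort$platform)) cohort$platform else NA,
             r = r, n = n, p = p, q = bh_fdr(pmin(pmax(p, .Machine$double.xmin), 1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Meta-analyse per-platform differential-expression correlations
#'
#' Combines per-platform correlations on Fisher's z scale with
#' inverse-variance weights (variance 1/(n - 3)) and back-transforms.
#' Genes measured on a single platform pass through unchanged. BH q is
#' recomputed across genes of the meta table.
#'
#' @param per_platform list of [per_gene_case_control_correlation()]
#'   tables (or one row-bound data frame with a `platform` column).
#' @param scale `"fisher-z"` (default: variance-stabilized, variance
#'   1/(n-3)) or `"raw"` (IVW directly on r with variance
#'   (1-r^2)^2/(n-1)).
#' @return Data frame `gene_id`, `platform = "meta"`, `r`, `n`,
#'   `n_platforms`, `p`, `q`.
#' @export
meta_diffexpr <- function(per_platform, scale = c("fisher-z", "raw")) {
  scale <- match.arg(scale)
  d <- if (is.data.frame(per_platform)) per_platform
       else do.call(rbind, per_platform)
  rows <- lapply(split(d, d$gene_id), function(g) {
    if (nrow(g) == 1) {
      return(data.frame(gene_id = g$gene_id, platform = "meta", r = g$r,
                        n = g$n, n_platforms = 1L, p = g$p,
                        stringsAsFactors = FALSE))
    }
    if (scale == "fisher-z") {
      zr <- atanh(pmin(pmax(g$r, -1 + 1e-12), 1 - 1e-12))
      w <- g$n - 3
      est <- sum(w * zr) / sum(w)
      se <- sqrt(1 / sum(w))
      r_meta <- tanh(est)
    } else {
      w <- (g$n - 1) / pmax(1 - g$r^2, .Machine$double.eps)^2
      est <- sum(w * g$r) / sum(w)
      se <- sqrt(1 / sum(w))
      r_meta <- est
    }
    data.frame(gene_id = g$gene_id[1], platform = "meta", r = r_meta,
               n = sum(g$n), n_platforms = nrow(g),
               p = 2 * stats::pnorm(-abs(est / se)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id), ]
  out$q <- bh_fdr(pmin(pmax(out$p, .Machine$double.xmin), 1))
  rownames(out) <- NULL
  out
}

#' Classify TWAS-inferred vs observed direction concordance
#'
#' A gene is `concordant` when its observed differential-expression
#' correlation is FDR-significant and shares the sign of its TWAS
#' direction (mean Z across panels), `discordant` when significant with
#' opposite sign, `not_significant` otherwise, and `unclassifiable` when
#' the TWAS direction is indeterminate (mean Z numerically zero).
#'
#' @param twas_z named numeric vector of per-gene TWAS direction (e.g.
#'   averaged Z, or a [build_weight_set()] object's weights).
#' @param meta [meta_diffexpr()] table.
#' @param alpha FDR threshold on the observed q (default 0.05).
#' @return Data frame `gene_id`, `twas_sign`, `observed_sign`,
#'   `observed_significant`, `call`, with attribute `"summary"` (counts).
#' @export
classify_concordance <- function(twas_z, meta, alpha = 0.05) {
  if (inherits(twas_z, "weight_set")) twas_z <- twas_z$weights
  stopifnot(!is.null(names(twas_z)))
  genes <- intersect(names(twas_z), meta$gene_id)
  m <- meta[match(genes, meta$gene_id), ]
  tz <- twas_z[genes]
  sig <- m$q <= alpha
  call <- ifelse(abs(tz) < 1e-12, "unclassifiable",
          ifelse(!sig, "not_significant",
          ifelse(sign(tz) == sign(m$r), "concordant", "discordant")))
  out <- data.frame(gene_id = genes,
                    twas_sign = ifelse(tz >= 0, "+", "-"),
                    observed_sign = ifelse(m$r >= 0, "+", "-"),
                    observed_significant = sig,
                    call = call, stringsAsFactors = FALSE)
  attr(out, "summary") <- c(n_significant = sum(sig),
                            n_concordant = sum(call == "concordant"),
                            n_discordant = sum(call == "discordant"))
  out
}
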