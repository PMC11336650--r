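#' Construct a feature-correlation object
#'
#' @param pairs data frame with columns `feature_i`, `feature_j`, `r`.
#' @param window_bp window within which pairs are stored.
#' @return An object of class `feature_correlation`.
#' @export
feature_correlation <- function(pairs, window_bp) {
  stopifnot(all(c("feature_i", "feature_j", "r") %in% names(pairs)))
  if (any(abs(pairs$r) > 1 + 1e-12)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  # store each unordered pair once, i < j lexicographically
  swap <- pairs$feature_i > pairs$feature_j
  tmp <- pairs$feature_i[swap]
  pairs$feature_i[swap] <- pairs$feature_j[swap]
  pairs$feature_j[swap] <- tmp
  pairs <- pairs[!duplicated(pairs[c("feature_i", "feature_j")]), , drop = FALSE]
  pairs <- pairs[pairs$feature_i != pairs$feature_j, , drop = FALSE]
  pairs <- pairs[order(pairs$feature_i, pairs$feature_j), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, window_bp = window_bp),
            class = "feature_correlation")
}

#' @export
print.feature_correlation <- function(x, ...) {
  cat(sprintf("Feature correlation: %d stored pairs within %g bp\n",
              nrow(x$pairs), x$window_bp))
  invisible(x)
}

#' Look up stored correlations symmetrically
#'
#' Missing pairs return 0: features beyond the window are independent by
#' construction.
#'
#' @param corr a `feature_correlation`.
#' @param fi,fj character vectors of feature ids.
#' @return Numeric vector of correlations.
#' @export
corr_lookup <- function(corr, fi, fj) {
  a <- pmin(fi, fj); b <- pmax(fi, fj)
  key <- paste(a, b, sep = "\r")
  stored <- stats::setNames(corr$pairs$r,
                            paste(corr$pairs$feature_i, corr$pairs$feature_j,
                                  sep = "\r"))
  out <- stored[key]
  out[is.na(out)] <- 0
  out[fi == fj] <- 1
  unname(out)
}

#' Simulate the predicted-expression correlation structure
#'
#' Features are gene x panel pairs (ids `"gene|panel"`). Correlation is the
#' Kronecker product of a compound-symmetry gene block (correlation
#' `within_block_r` among genes of a block) and a compound-symmetry panel
#' matrix (correlation `cross_panel_r` between panels), which guarantees
#' positive semi-definiteness of every block. Pairs farther apart than
#' `window_bp` (i.e. in different blocks) are absent.
#'
#' @param config a [sim_config()] object.
#' @param annotation output of [simulate_gene_annotation()].
#' @return A `feature_correlation` object.
#' @export
simulate_feature_correlation <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  panels <- sprintf("panel%02d", seq_len(config$n_panels))
  rg <- config$within_block_r
  rp <- config$cross_panel_r
  if (config$block_size > 1 && rg < -1 / (config$block_size - 1)) {
    stop("within_block_r breaks positive semi-definiteness", call. = FALSE)
  }
  res <- vector("list", max(annotation$block))
  for (b in seq_len(max(annotation$block))) {
    genes <- annotation$gene_id[annotation$block == b]
    feats <- as.vector(outer(genes, panels, paste, sep = "|"))
    gene_of <- rep(genes, times = length(panels))
    panel_of <- rep(panels, each = length(genes))
    n <- length(feats)
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    r_gene <- ifelse(gene_of[ij[, 1]] == gene_of[ij[, 2]], 1, rg)
    r_pan <- ifelse(panel_of[ij[, 1]] == panel_of[ij[, 2]], 1, rp)
    r <- r_gene * r_pan
    keep <- r != 0
    res[[b]] <- data.frame(feature_i = feats[ij[keep, 1]],
                           feature_j = feats[ij[keep, 2]],
                           r = r[keep], stringsAsFactors = FALSE)
  }
  feature_correlation(do.call(rbind, res), config$window_bp)
}
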