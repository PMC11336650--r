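#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Order-preserving BH step-up adjustment, as applied across all panels
#' within each association method before triage.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same order as the input.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p_values) {
  bad <- which(!is.finite(p_values) | p_values <= 0 | p_values > 1)
  if (length(bad)) {
    stop("p-values outside (0, 1] at index: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Colocalisation call from coloc posteriors
#'
#' A gene-panel association is colocalised when PP4 / (PP3 + PP4)
#' strictly exceeds 0.8: the shared-causal-variant model dominates the
#' linkage model, ignoring the no-association models which the TWAS has
#' already excluded.
#'
#' @param pp3,pp4 posterior probabilities of the linkage (distinct
#'   variants) and shared-variant models.
#' @return Logical vector; `NA` where `pp3 + pp4 == 0` (not evaluable,
#'   distinct from `FALSE`).
#' @export
coloc_colocalised <- function(pp3, pp4) {
  denom <- pp3 + pp4
  out <- pp4 / denom > 0.8
  out[!is.na(denom) & denom == 0] <- NA
  out
}

#' Colocalisation call from the HEIDI heterogeneity test
#'
#' An SMR association is treated as colocalised when the HEIDI p-value
#' strictly exceeds 0.05 (no evidence of heterogeneity, supporting a
#' single shared causal variant).
#'
#' @param heidi_p HEIDI p-values; `NA` propagates as not-evaluable.
#' @return Logical vector.
#' @export
smr_colocalised <- function(heidi_p) {
  heidi_p > 0.05
}

#' Test whether a credible set is fully contained in a gene
#'
#' @param gene one-row data frame (or list) with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param cs data frame of variant positions with columns `chrom`, `pos`.
#' @param window_bp symmetric window added to the gene body (default 0:
#'   gene body only); the boundary is inclusive.
#' @return `TRUE` iff every variant lies on the gene's chromosome within
#'   `[start - window_bp, end + window_bp]`.
#' @export
credible_set_contained <- function(gene, cs, window_bp = 0) {
  if (nrow(cs) == 0) stop("credible set must be non-empty", call. = FALSE)
  all(cs$chrom == gene$chrom &
        cs$pos >= gene$start - window_bp &
        cs$pos <= gene$end + window_bp)
}

#' Define high-confidence disease genes
#'
#' A gene is high-confidence if it meets at least one of three criteria:
#' \describe{
#'   \item{finemap}{some fine-mapping 95% credible set is fully contained
#'     in the gene body (plus `window_bp`);}
#'   \item{fusion_coloc}{some FUSION-style record is FDR-significant
#'     (q <= `fdr_alpha`) and colocalised by [coloc_colocalised()];}
#'   \item{smr_heidi}{some SMR-style record is FDR-significant and
#'     colocalised by [smr_colocalised()].}
#' }
#' FDR correction is applied within each method across all its panels
#' jointly; expression and protein records are pooled within method unless
#' `pool_molecules = FALSE`.
#'
#' @param twas data frame of TWAS/PWAS records (`gene_id`, `method`, `p`,
#'   `pp3`, `pp4`, `heidi_p`, optionally `molecule`).
#' @param credible_sets data frame (`locus_id`, `chrom`, `pos`) or `NULL`.
#' @param annotation gene annotation (`gene_id`, `chrom`, `start`, `end`)
#'   or `NULL`; genes present in `twas` but absent from the annotation are
#'   excluded from the finemap criterion only (with a message).
#' @param fdr_alpha FDR significance threshold (default 0.05).
#' @param pool_molecules pool expression and protein records within each
#'   method stream (default `TRUE`).
#' @param window_bp containment window passed to
#'   [credible_set_contained()].
#' @return Data frame with one row per gene: `gene_id`, logical columns
#'   `finemap`, `fusion_coloc`, `smr_heidi`, `criteria` (comma-separated),
#'   `high_confidence`, and the minimum q-value per method stream.
#' @export
define_high_confidence <- function(twas, credible_sets = NULL,
                                   annotation = NULL, fdr_alpha = 0.05,
                                   pool_molecules = TRUE, window_bp = 0) {
  stopifnot(all(c("gene_id", "method", "p") %in% names(twas)))
  twas <- as.data.frame(twas)
  stream <- twas$method
  if (!pool_molecules && "molecule" %in% names(twas)) {
    stream <- paste(twas$method, twas$molecule, sep = ":")
  }
  q <- rep(NA_real_, nrow(twas))
  for (s in unique(stream)) {
    idx <- stream == s
    q[idx] <- bh_fdr(twas$p[idx])
  }
  twas$q <- q

  is_fusion <- twas$method == "fusion-like"
  is_smr <- twas$method == "smr-like"
  coloc_ok <- coloc_colocalised(twas$pp3, twas$pp4)
  heidi_ok <- smr_colocalised(twas$heidi_p)
  fusion_hit <- is_fusion & twas$q <= fdr_alpha & !is.na(coloc_ok) & coloc_ok
  smr_hit <- is_smr & twas$q <= fdr_alpha & !is.na(heidi_ok) & heidi_ok

  genes <- sort(unique(twas$gene_id))
  fusion_by_gene <- tapply(fusion_hit, twas$gene_id, any)[genes]
  smr_by_gene <- tapply(smr_hit, twas$gene_id, any)[genes]
  qf <- suppressWarnings(tapply(ifelse(is_fusion, twas$q, NA_real_),
                                twas$gene_id, min, na.rm = TRUE))[genes]
  qs <- suppressWarnings(tapply(ifelse(is_smr, twas$q, NA_real_),
                                twas$gene_id, min, na.rm = TRUE))[genes]
  qf[!is.finite(qf)] <- NA; qs[!is.finite(qs)] <- NA

  finemap_genes <- character()
  if (!is.null(credible_sets) && nrow(credible_sets) > 0) {
    if (is.null(annotation)) {
      stop("credible sets supplied without gene annotation", call. = FALSE)
    }
    missing_ann <- setdiff(genes, annotation$gene_id)
    if (length(missing_ann)) {
      message(length(missing_ann),
              " gene(s) in the association table absent from the annotation;",
              " excluded from the finemap criterion")
    }
    for (locus in unique(credible_sets$locus_id)) {
      cs <- credible_sets[credible_sets$locus_id == locus, , drop = FALSE]
      cand <- annotation[annotation$chrom == cs$chrom[1] &
                           annotation$start - window_bp <= min(cs$pos) &
                           annotation$end + window_bp >= max(cs$pos), ,
                         drop = FALSE]
      for (i in seq_len(nrow(cand))) {
        if (credible_set_contained(cand[i, ], cs, window_bp)) {
          finemap_genes <- c(finemap_genes, cand$gene_id[i])
        }
      }
    }
  }

  all_genes <- sort(union(genes, finemap_genes))
  out <- data.frame(
    gene_id = all_genes,
    finemap = all_genes %in% finemap_genes,
    fusion_coloc = unname(fusion_by_gene[all_genes]) %in% TRUE,
    smr_heidi = unname(smr_by_gene[all_genes]) %in% TRUE,
    q_fusion_min = unname(qf[all_genes]),
    q_smr_min = unname(qs[all_genes]),
    stringsAsFactors = FALSE
  )
  crit <- cbind(finemap = out$finemap, fusion_coloc = out$fusion_coloc,
                smr_heidi = out$smr_heidi)
  out$criteria <- apply(crit, 1, function(x)
    paste(colnames(crit)[x], collapse = ","))
  out$high_confidence <- rowSums(crit) > 0
  rownames(out) <- NULL
  out
}
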