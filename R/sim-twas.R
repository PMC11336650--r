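#' Simulate TWAS/SMR summary statistics with known signal genes
#'
#' Emits one record per gene x panel x method (methods `"fusion-like"` and
#' `"smr-like"`). Signal genes are placed in distinct correlation blocks;
#' their true Z has |Z| drawn around `signal_z_mean` with a random sign,
#' and each record observes `true_z * s + N(0, 1)` where `s` is the gene's
#' sign kept with probability `sign_agreement_prob` (flipped otherwise).
#' Null genes draw independent standard-normal Z per record. p-values are
#' the two-sided normal tail of Z. Colocalisation posteriors PP4 are drawn
#' skewed towards 1 for signal genes (Beta(20, 2)) and towards 0 for null
#' genes (Beta(1.5, 10)); PP3 is a uniform fraction of the remaining mass.
#' HEIDI p-values are uniform for signal genes (no heterogeneity) and
#' skewed small (Beta(1, 50)) for `heidi_null_small_frac` of null genes:
#' spurious associations are predominantly linkage-driven, which is the
#' failure mode HEIDI is designed to detect.
#'
#' @param config a [sim_config()] object.
#' @param annotation output of [simulate_gene_annotation()].
#' @return A list with elements `records` (data frame of TWAS records:
#'   `gene_id`, `panel`, `stratum`, `method`, `molecule`, `z`, `p`, `pp3`,
#'   `pp4`, `heidi_p`) and `truth` (data frame `gene_id`, `is_signal`,
#'   `true_z`).
#' @export
simulate_twas_sumstats <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  n <- config$n_genes
  genes <- annotation$gene_id
  n_blocks <- max(annotation$block)

  is_signal <- rep(FALSE, n)
  true_z <- rep(0, n)
  if (config$n_signal_genes > 0) {
    sig_blocks <- sort(sample.int(n_blocks, config$n_signal_genes))
    sig_idx <- vapply(sig_blocks, function(b) {
      in_block <- which(annotation$block == b)
      in_block[sample.int(length(in_block), 1L)]
    }, integer(1))
    is_signal[sig_idx] <- TRUE
    signs <- sample(c(-1, 1), config$n_signal_genes, replace = TRUE)
    true_z[sig_idx] <- signs *
      stats::rnorm(config$n_signal_genes, config$signal_z_mean, 1)
  }

  methods <- c("fusion-like", "smr-like")
  panels <- sprintf("panel%02d", seq_len(config$n_panels))
  grid <- expand.grid(gene = seq_len(n),
                      panel = seq_len(config$n_panels),
                      method = methods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- nrow(grid)
  gi <- grid$gene
  flip <- ifelse(stats::runif(m) < config$sign_agreement_prob, 1, -1)
  z <- ifelse(is_signal[gi], true_z[gi] * flip, 0) + stats::rnorm(m)
  p <- 2 * stats::pnorm(-abs(z))
  pp4 <- ifelse(is_signal[gi],
                stats::rbeta(m, 20, 2), stats::rbeta(m, 1.5, 10))
  pp3 <- stats::runif(m) * (1 - pp4)
  heidi <- stats::runif(m)
  null_small <- !is_signal[gi] & stats::runif(m) < config$heidi_null_small_frac
  heidi[null_small] <- stats::rbeta(sum(null_small), 1, 50)

  records <- data.frame(
    gene_id = genes[gi],
    panel = panels[grid$panel],
    stratum = config$panel_strata[grid$panel],
    method = grid$method,
    molecule = "expression",
    z = z,
    p = pmax(p, .Machine$double.xmin),
    pp3 = pp3,
    pp4 = pp4,
    heidi_p = pmax(heidi, .Machine$double.xmin),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(gene_id = genes, is_signal = is_signal,
                      true_z = true_z, stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Simulate fine-mapping 95% credible sets
#'
#' Generates position lists for `n_credible_sets` loci centred on signal
#' genes (falling back to random genes in a fully null simulation). A
#' fraction `credible_contained_frac` of sets lie fully within the gene
#' body; the rest include one variant beyond the gene end, so containment
#' fails for them.
#'
#' @param config a [sim_config()] object.
#' @param annotation output of [simulate_gene_annotation()].
#' @param truth truth table from [simulate_twas_sumstats()].
#' @return A data frame with columns `locus_id`, `chrom`, `pos`, plus an
#'   attribute `"target_genes"` naming the gene each locus sits on.
#' @export
simulate_credible_sets <- function(config, annotation, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 131L)
  n_cs <- config$n_credible_sets
  if (n_cs == 0L) {
    out <- data.frame(locus_id = character(), chrom = character(),
                      pos = numeric(), stringsAsFactors = FALSE)
    attr(out, "target_genes") <- character()
    return(out)
  }
  pool <- truth$gene_id[truth$is_signal]
  if (length(pool) < n_cs) {
    pool <- c(pool, sample(setdiff(truth$gene_id, pool),
                           n_cs - length(pool)))
  }
  target <- sample(pool, n_cs)
  contained <- stats::runif(n_cs) < config$credible_contained_frac
  rows <- lapply(seq_len(n_cs), function(i) {
    g <- annotation[annotation$gene_id == target[i], ]
    k <- sample(3:8, 1L)
    pos <- sort(sample(seq(g$start, g$end), k))
    if (!contained[i]) pos[k] <- g$end + 50000
    data.frame(locus_id = sprintf("L%02d", i), chrom = g$chrom, pos = pos,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "target_genes") <- target
  attr(out, "contained") <- contained
  out
}
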