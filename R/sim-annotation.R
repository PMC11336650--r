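#' Simulate gene annotation on a block layout
#'
#' Lays `n_genes` on chromosomes 1-22 so that each correlation block of
#' `block_size` consecutive genes spans less than `window_bp` and
#' consecutive blocks on the same chromosome are separated by more than
#' `window_bp`. Coordinates are 1-based inclusive. The layout is a pure
#' function of the configuration (no randomness).
#'
#' @param config a [sim_config()] object.
#' @return A data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   and `block` (integer block index).
#' @export
simulate_gene_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  bs <- config$block_size
  n_blocks <- ceiling(n / bs)
  gene_len <- 10000
  # genes within a block spaced so the whole block spans < window_bp
  step <- max(gene_len + 1, floor(0.75 * config$window_bp / bs))
  inter_block_gap <- 2 * config$window_bp

  chrom <- integer(n); start <- numeric(n)
  block <- (seq_len(n) - 1L) %/% bs + 1L
  chrom_of_block <- ((seq_len(n_blocks) - 1L) %% 22L) + 1L
  # cursor per chromosome
  cursor <- rep(1, 22)
  block_start <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    ch <- chrom_of_block[b]
    block_start[b] <- cursor[ch]
    cursor[ch] <- cursor[ch] + (bs - 1) * step + gene_len + inter_block_gap
  }
  within <- (seq_len(n) - 1L) %% bs
  start <- block_start[block] + within * step
  chrom <- chrom_of_block[block]

  data.frame(
    gene_id = sprintf("G%04d", seq_len(n)),
    chrom = paste0("chr", chrom),
    start = as.numeric(start),
    end = as.numeric(start + gene_len - 1),
    block = block,
    stringsAsFactors = FALSE
  )
}
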