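# Small study configuration used by fast unit tests
small_config <- function(seed = 7, ...) {
  sim_config(n_genes = 120, block_size = 6, n_signal_genes = 10,
             n_panels = 2, panel_strata = c("blood", "brain"),
             n_cases = 300, n_controls = 300, n_drugs = 40,
             n_enriched_drugs = 4, genes_per_drug_mean = 10,
             seed = seed, ...)
}

# Brute-force BH step-up definition: q_(i) = min_{j >= i} p_(j) * m / j
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m), 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force greedy clump over a dense correlation matrix R (named dims)
brute_clump <- function(feats, p, R, r2_threshold = 0.1) {
  remaining <- feats[order(p, feats)]
  leads <- character()
  while (length(remaining)) {
    lead <- remaining[1]
    leads <- c(leads, lead)
    remaining <- remaining[-1]
    drop <- vapply(remaining, function(f) R[lead, f]^2 > r2_threshold,
                   logical(1))
    remaining <- remaining[!drop]
  }
  leads
}

# dense correlation -> feature_correlation storing all off-diagonal pairs
dense_to_fc <- function(R, window_bp = 1e9) {
  ij <- which(upper.tri(R), arr.ind = TRUE)
  feature_correlation(
    data.frame(feature_i = rownames(R)[ij[, 1]],
               feature_j = colnames(R)[ij[, 2]],
               r = R[ij], stringsAsFactors = FALSE),
    window_bp)
}

# all permutations of a small vector (independent of the package internals)
perms_of <- function(x) {
  if (length(x) == 1) return(matrix(x, 1))
  do.call(rbind, lapply(seq_along(x), function(i) {
    cbind(x[i], perms_of(x[-i]), deparse.level = 0)
  }))
}

# independent exact enumeration of the signed concordance p-value
brute_signed_p <- function(codes, z, s_obs) {
  es <- mean(z) * sum(codes)
  combos <- combn(length(z), length(codes))
  pp <- unique(perms_of(codes))
  s_all <- c(apply(combos, 2, function(idx) pp %*% z[idx]))
  mean(abs(s_all - es) >= abs(s_obs - es) - 1e-12)
}

# rebuild a dense correlation block from a feature_correlation object
block_matrix <- function(corr, feats) {
  n <- length(feats)
  R <- diag(n)
  dimnames(R) <- list(feats, feats)
  pr <- corr$pairs[corr$pairs$feature_i %in% feats &
                     corr$pairs$feature_j %in% feats, ]
  for (k in seq_len(nrow(pr))) {
    R[pr$feature_i[k], pr$feature_j[k]] <- pr$r[k]
    R[pr$feature_j[k], pr$feature_i[k]] <- pr$r[k]
  }
  R
}

truth_weights_of <- function(tw) {
  with(tw$truth, stats::setNames(true_z[is_signal], gene_id[is_signal]))
}
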