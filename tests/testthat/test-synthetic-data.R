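test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(prevalence_K = 0), "prevalence_K")
  expect_error(sim_config(target_liability_r2 = 1), "target_liability_r2")
  expect_error(sim_config(block_size = 10, within_block_r = -0.5),
               "semi-definiteness")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(n_signal_genes = 200, n_genes = 100),
               "n_signal_genes")
  expect_error(sim_config(panel_strata = "blood"), "panel_strata")
  # null simulations are legitimate
  expect_s3_class(sim_config(n_signal_genes = 0, n_enriched_drugs = 0,
                             target_liability_r2 = 0), "sim_config")
})

test_that("gene annotation respects the block/window geometry", {
  cfg <- small_config()
  ann <- simulate_gene_annotation(cfg)
  expect_identical(ann, simulate_gene_annotation(cfg))
  expect_false(anyDuplicated(ann$gene_id) > 0)
  expect_true(all(ann$start <= ann$end))

  # exhaustive scan: all within-block pairs closer than the window,
  # all cross-block pairs on the same chromosome farther than the window
  for (b in unique(ann$block)) {
    blk <- ann[ann$block == b, ]
    if (nrow(blk) > 1) {
      d <- max(blk$end) - min(blk$start)
      expect_lt(d, cfg$window_bp)
    }
    same_chr <- ann[ann$chrom == blk$chrom[1] & ann$block != b, ]
    if (nrow(same_chr)) {
      gaps <- pmax(same_chr$start - max(blk$end), min(blk$start) - same_chr$end)
      expect_true(all(gaps > cfg$window_bp))
    }
  }

  one <- simulate_gene_annotation(sim_config(n_genes = 1, block_size = 1,
                                             n_signal_genes = 1))
  expect_equal(nrow(one), 1L)
})

test_that("TWAS simulator matches its stated generative model", {
  cfg <- small_config()
  tw1 <- simulate_twas_sumstats(cfg, simulate_gene_annotation(cfg))
  tw2 <- simulate_twas_sumstats(cfg, simulate_gene_annotation(cfg))
  expect_identical(tw1, tw2)

  rec <- tw1$records
  # one record per gene x panel x method
  expect_equal(nrow(rec), cfg$n_genes * cfg$n_panels * 2)
  # p equals the two-sided normal tail of Z to >= 12 significant digits
  expect_equal(rec$p, 2 * pnorm(-abs(rec$z)), tolerance = 1e-12)
  # probability constraints
  expect_true(all(rec$pp3 >= 0 & rec$pp4 >= 0 & rec$pp3 + rec$pp4 <= 1))
  expect_true(all(rec$p > 0 & rec$p <= 1))
  expect_true(all(rec$heidi_p > 0 & rec$heidi_p <= 1))

  # zero signal fraction: Z is approximately standard normal at n = 5000
  cfg0 <- sim_config(n_genes = 2500, block_size = 10, n_signal_genes = 0,
                     n_panels = 1, panel_strata = "blood", seed = 11)
  tw0 <- simulate_twas_sumstats(cfg0, simulate_gene_annotation(cfg0))
  expect_equal(nrow(tw0$records), 5000L)
  ks <- ks.test(tw0$records$z, "pnorm")
  expect_gt(ks$p.value, 0.01)

  # signal genes keep a consistent sign across panels at agreement prob 1
  sig <- tw1$truth$gene_id[tw1$truth$is_signal]
  for (g in sig[1:3]) {
    zz <- rec$z[rec$gene_id == g]
    expect_true(all(sign(zz) == sign(zz[1])))
  }
})

test_that("feature correlation is symmetric, windowed and PSD by block", {
  cfg <- small_config()
  ann <- simulate_gene_annotation(cfg)
  fc <- simulate_feature_correlation(cfg, ann)

  # symmetry through the lookup: (i,j) equals (j,i)
  pr <- fc$pairs[1:20, ]
  expect_equal(corr_lookup(fc, pr$feature_i, pr$feature_j),
               corr_lookup(fc, pr$feature_j, pr$feature_i))
  expect_equal(corr_lookup(fc, pr$feature_i, pr$feature_i),
               rep(1, nrow(pr)))

  # all stored pairs are within one block (i.e. within the window)
  gene_i <- sub("\\|.*", "", fc$pairs$feature_i)
  gene_j <- sub("\\|.*", "", fc$pairs$feature_j)
  bi <- ann$block[match(gene_i, ann$gene_id)]
  bj <- ann$block[match(gene_j, ann$gene_id)]
  expect_true(all(bi == bj))

  # eigenvalues of each reconstructed block are >= -1e-8
  panels <- sprintf("panel%02d", seq_len(cfg$n_panels))
  for (b in c(1, 5, 20)) {
    genes <- ann$gene_id[ann$block == b]
    feats <- as.vector(outer(genes, panels, paste, sep = "|"))
    ev <- eigen(block_matrix(fc, feats), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }

  # within_block_r = 0: only same-gene cross-panel entries present
  cfg0 <- small_config(within_block_r = 0)
  fc0 <- simulate_feature_correlation(cfg0, simulate_gene_annotation(cfg0))
  g_i <- sub("\\|.*", "", fc0$pairs$feature_i)
  g_j <- sub("\\|.*", "", fc0$pairs$feature_j)
  expect_true(all(g_i == g_j))
  expect_true(all(fc0$pairs$r == cfg0$cross_panel_r))
})

test_that("liability population realizes the stated prevalence and variance", {
  cfg <- sim_config(seed = 5)
  ann <- simulate_gene_annotation(cfg)
  tw <- simulate_twas_sumstats(cfg, ann)
  w <- truth_weights_of(tw)
  pop <- simulate_liability_population(cfg, ann, w, n = 50000)
  # pre-ascertainment case fraction ~ K within binomial error
  K <- cfg$prevalence_K
  expect_lt(abs(mean(pop$case) - K), 4 * sqrt(K * (1 - K) / 50000))
  # the score explains target_liability_r2 of liability variance
  struct_c <- attr(simulate_expression_cohort(cfg, ann, w), "liability")$c
  expect_equal(var(struct_c * pop$score) / var(pop$liability),
               cfg$target_liability_r2, tolerance = 0.01)
})

test_that("ascertained cohorts are deterministic and match rejection sampling", {
  cfg <- small_config()
  ann <- simulate_gene_annotation(cfg)
  tw <- simulate_twas_sumstats(cfg, ann)
  w <- truth_weights_of(tw)
  c1 <- simulate_expression_cohort(cfg, ann, w)
  c2 <- simulate_expression_cohort(cfg, ann, w)
  expect_identical(c1, c2)
  expect_equal(length(c1), cfg$n_platforms)
  expect_equal(sum(c1[[1]]$pheno$case), cfg$n_cases)
  # controls carry no clinical outcomes
  expect_true(all(is.na(c1[[1]]$pheno$onset_age[c1[[1]]$pheno$case == 0])))
  # dropout: platforms miss disjoint gene sets of the configured size
  n_drop <- round(cfg$dropout_frac * cfg$n_genes)
  miss1 <- setdiff(ann$gene_id, rownames(c1[[1]]$expr))
  miss2 <- setdiff(ann$gene_id, rownames(c1[[2]]$expr))
  expect_equal(length(miss1), n_drop)
  expect_length(intersect(miss1, miss2), 0)

  # oracle: conditional ascertainment sampler vs brute-force rejection
  # sampling at a prevalence where rejection is feasible
  cfgK <- sim_config(n_genes = 40, block_size = 4, n_signal_genes = 4,
                     n_panels = 1, panel_strata = "blood",
                     n_cases = 4000, n_controls = 4000,
                     prevalence_K = 0.3, target_liability_r2 = 0.3,
                     dropout_frac = 0, seed = 21)
  annK <- simulate_gene_annotation(cfgK)
  twK <- simulate_twas_sumstats(cfgK, annK)
  wK <- truth_weights_of(twK)
  coh <- simulate_expression_cohort(cfgK, annK, wK)[[1]]
  pop <- simulate_liability_population(cfgK, annK, wK, n = 120000, seed = 99)
  # per-case-group score moments agree between the two samplers
  mc_bound <- function(a, b) {       # 4-sigma Monte Carlo bound on a mean gap
    4 * sqrt(var(a) / length(a) + var(b) / length(b))
  }
  cond_case <- coh$truth$score[coh$pheno$case == 1]
  rej_case <- pop$score[pop$case == 1]
  expect_lt(abs(mean(cond_case) - mean(rej_case)),
            mc_bound(cond_case, rej_case))
  expect_lt(abs(sd(cond_case) - sd(rej_case)),
            4 * sd(cond_case) / sqrt(length(cond_case)))
  cond_ctl <- coh$truth$score[coh$pheno$case == 0]
  rej_ctl <- pop$score[pop$case == 0]
  expect_lt(abs(mean(cond_ctl) - mean(rej_ctl)),
            mc_bound(cond_ctl, rej_ctl))
  # null target: r2 = 0 gives scores unrelated to status
  cfg0 <- small_config(target_liability_r2 = 0)
  coh0 <- simulate_expression_cohort(cfg0, simulate_gene_annotation(cfg0),
                                     truth_weights_of(
                                       simulate_twas_sumstats(
                                         cfg0, simulate_gene_annotation(cfg0))))
  r2 <- summary(lm(coh0[[1]]$pheno$case ~ coh0[[1]]$truth$score))$r.squared
  expect_lt(r2, 0.02)
})

test_that("drug database has the closed vocabulary and planted structure", {
  cfg <- small_config()
  ann <- simulate_gene_annotation(cfg)
  tw <- simulate_twas_sumstats(cfg, ann)
  d1 <- simulate_drug_database(cfg, ann, tw$truth)
  d2 <- simulate_drug_database(cfg, ann, tw$truth)
  expect_identical(d1, d2)
  vocab <- unlist(DRUG_LABELS, use.names = FALSE)
  expect_true(all(d1$interactions$label %in% vocab))
  expect_equal(length(unique(d1$interactions$drug_id)), cfg$n_drugs)
  expect_true(all(table(d1$interactions$drug_id) >= 1))

  # planted drug targets overlap signal genes beyond hypergeometric chance
  sig <- tw$truth$gene_id[tw$truth$is_signal]
  for (dr in d1$truth$enriched_drugs[1:2]) {
    g <- unique(d1$interactions$gene_id[d1$interactions$drug_id == dr])
    k <- sum(g %in% sig)
    p_hyper <- phyper(k - 1, length(sig), cfg$n_genes - length(sig),
                      length(g), lower.tail = FALSE)
    expect_lt(p_hyper, 0.01)
  }
})

test_that("credible sets are contained in their target genes as configured", {
  cfg <- small_config()
  ann <- simulate_gene_annotation(cfg)
  tw <- simulate_twas_sumstats(cfg, ann)
  cs <- simulate_credible_sets(cfg, ann, tw$truth)
  expect_identical(cs, simulate_credible_sets(cfg, ann, tw$truth))
  targets <- attr(cs, "target_genes")
  contained <- attr(cs, "contained")
  for (i in seq_along(targets)) {
    g <- ann[ann$gene_id == targets[i], ]
    sub <- cs[cs$locus_id == sprintf("L%02d", i), ]
    expect_equal(credible_set_contained(g, sub), contained[i])
  }
})
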