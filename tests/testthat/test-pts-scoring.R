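test_that("windowed predicted-expression correlation matches a dense oracle", {
  set.seed(3)
  ann <- data.frame(gene_id = sprintf("g%02d", 1:10), chrom = "chr1",
                    start = seq(1, by = 50000, length.out = 10),
                    end = seq(10000, by = 50000, length.out = 10))
  mat <- matrix(rnorm(10 * 8), 10, 8,
                dimnames = list(paste0(ann$gene_id, "|p1"), NULL))
  fc <- correlation_from_predicted_expression(mat, ann, window_bp = 1e7)
  dense <- cor(t(mat))
  for (k in seq_len(nrow(fc$pairs))) {
    expect_equal(fc$pairs$r[k],
                 dense[fc$pairs$feature_i[k], fc$pairs$feature_j[k]],
                 tolerance = 1e-12)
  }
  # every pair within the (huge) window is present
  expect_equal(nrow(fc$pairs), choose(10, 2))

  # window restriction: with a small window only near neighbours pair up
  fc2 <- correlation_from_predicted_expression(mat, ann, window_bp = 45000)
  gi <- match(sub("\\|.*", "", fc2$pairs$feature_i), ann$gene_id)
  gj <- match(sub("\\|.*", "", fc2$pairs$feature_j), ann$gene_id)
  expect_true(all(abs(gi - gj) == 1))  # 40 kb gap between adjacent genes

  # perfect anticorrelation and self-duplicate
  ann2 <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                     start = c(1, 100, 200), end = c(50, 150, 250))
  m2 <- rbind("a|p1" = c(1, 2, 3), "b|p1" = c(3, 2, 1), "c|p1" = c(1, 2, 3))
  fc3 <- correlation_from_predicted_expression(m2, ann2, window_bp = 1000)
  expect_equal(corr_lookup(fc3, "a|p1", "b|p1"), -1)
  expect_equal(corr_lookup(fc3, "a|p1", "c|p1"), 1)

  # zero-variance feature dropped with a warning
  m3 <- rbind(m2, "d" = c(5, 5, 5))
  ann3 <- rbind(ann2, data.frame(gene_id = "d", chrom = "chr1",
                                 start = 300, end = 350))
  expect_warning(correlation_from_predicted_expression(m3, ann3, 1000),
                 "zero-variance")
  expect_error(correlation_from_predicted_expression(m2[, 1:2], ann2, 1000),
               "3 reference")
})

test_that("greedy clumping follows its definition and matches brute force", {
  # worked example: A leads and removes B; C is independent and retained
  rec <- data.frame(feature = c("A", "B", "C"), p = c(1e-8, 1e-5, 1e-4))
  fc <- feature_correlation(
    data.frame(feature_i = c("A", "A"), feature_j = c("B", "C"),
               r = c(sqrt(0.5), 0)), 5e5)
  expect_equal(clump(rec, fc), c("A", "C"))

  # all r = 0: everything retained
  fc0 <- feature_correlation(
    data.frame(feature_i = character(), feature_j = character(),
               r = numeric()), 5e5)
  expect_setequal(clump(rec, fc0), c("A", "B", "C"))

  expect_error(clump(rbind(rec, rec[1, ]), fc0), "duplicated")

  # randomized instances against the independent brute-force oracle
  set.seed(9)
  for (trial in 1:300) {
    n <- sample(2:10, 1)
    feats <- sprintf("f%02d", sample(99, n))
    R <- diag(n)
    ij <- which(upper.tri(R), arr.ind = TRUE)
    vals <- ifelse(runif(nrow(ij)) < 0.5, 0, runif(nrow(ij), -1, 1))
    R[ij] <- vals; R[ij[, c(2, 1)]] <- vals
    dimnames(R) <- list(feats, feats)
    p <- signif(runif(n), 2)        # duplicate p values exercise tie-break
    rec <- data.frame(feature = feats, p = p)
    expect_identical(clump(rec, dense_to_fc(R)), brute_clump(feats, p, R))
  }
})

test_that("clumping collapses correlation blocks to their lead", {
  cfg <- small_config(within_block_r = 0.7)
  ann <- simulate_gene_annotation(cfg)
  tw <- simulate_twas_sumstats(cfg, ann)
  fc <- simulate_feature_correlation(cfg, ann)
  rec <- tw$records[tw$records$method == "fusion-like", ]
  rec$feature <- paste(rec$gene_id, rec$panel, sep = "|")
  rec <- rec[order(rec$p, rec$feature), ]
  rec <- rec[!duplicated(rec$feature), ]
  leads <- clump(rec, fc)
  # with r^2 = 0.49 within block and 0.81 cross panel, exactly one
  # feature survives per block
  lead_genes <- sub("\\|.*", "", leads)
  lead_blocks <- ann$block[match(lead_genes, ann$gene_id)]
  expect_equal(sort(unique(lead_blocks)), sort(unique(ann$block)))
  expect_equal(length(leads), length(unique(ann$block)))
})

test_that("weight sets filter, clump and average as specified", {
  fc0 <- feature_correlation(
    data.frame(feature_i = character(), feature_j = character(),
               r = numeric()), 5e5)
  rec <- data.frame(
    gene_id = c("G1", "G2", "G2"), panel = c("p1", "p1", "p2"),
    stratum = c("blood", "blood", "brain"), method = "fusion-like",
    molecule = "expression", z = c(1.5, 2, 4),
    p = c(0.2, 1e-4, 1e-5), pp3 = 0.1, pp4 = c(0.5, 0.9, 0.9),
    heidi_p = 0.5, stringsAsFactors = FALSE)

  # threshold 1, no correlation: weights are raw Z (per-gene mean)
  ws <- build_weight_set(rec, fc0, threshold = 1)
  expect_equal(ws$weights[["G1"]], 1.5)
  expect_equal(ws$weights[["G2"]], 3)      # mean of 2 and 4 across panels
  expect_equal(ws$n_genes, 2L)

  # stratum filter
  ws_blood <- build_weight_set(rec, fc0, threshold = 1, stratum = "blood")
  expect_equal(ws_blood$weights[["G2"]], 2)

  # coloc filter removes low-PP4 records entirely
  expect_warning(
    ws_c <- build_weight_set(rec[1, ], fc0, threshold = 1, coloc_only = TRUE),
    "empty")
  expect_equal(ws_c$n_genes, 0L)

  # pooled clumping removes the cross-panel duplicate (keeps min-p panel);
  # per-panel clumping retains both copies and averages
  fc_x <- feature_correlation(
    data.frame(feature_i = "G2|p1", feature_j = "G2|p2", r = 0.9), 5e5)
  ws_pool <- build_weight_set(rec, fc_x, threshold = 1)
  expect_equal(ws_pool$weights[["G2"]], 4)       # p2 record leads, p1 clumped
  ws_pp <- build_weight_set(rec, fc_x, threshold = 1, clump_mode = "per-panel")
  expect_equal(ws_pp$weights[["G2"]], 3)

  # threshold nesting: records at t1 < t2 are a subset pre-clump
  cfg <- small_config()
  ann <- simulate_gene_annotation(cfg)
  tw <- simulate_twas_sumstats(cfg, ann)
  fc <- simulate_feature_correlation(cfg, ann)
  ws1 <- build_weight_set(tw$records, fc, threshold = 1e-4)
  ws2 <- build_weight_set(tw$records, fc, threshold = 0.05)
  expect_lte(ws1$n_features_pre_clump, ws2$n_features_pre_clump)
  expect_true(all(names(ws1$weights) %in%
                    tw$records$gene_id[tw$records$p <= 1e-4]))
})

test_that("expression standardization uses the sample-sd convention", {
  m <- matrix(c(1, 3), 1, 2, dimnames = list("g1", c("s1", "s2")))
  z <- standardize_expression(m)
  expect_equal(unname(z[1, ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  m2 <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  colnames(m2) <- paste0("s", 1:3)
  expect_warning(z2 <- standardize_expression(m2), "constant")
  expect_equal(rownames(z2), "g1")
  expect_lt(max(abs(rowMeans(z2))), 1e-12)
  expect_equal(apply(z2, 1, sd), c(g1 = 1))

  expect_error(standardize_expression(m[, 1, drop = FALSE]), "2 samples")
})

test_that("PTS is the weighted sum of standardized expression", {
  z <- rbind(g1 = c(1.0, -1), g2 = c(0.5, 2))
  colnames(z) <- c("s1", "s2")
  ws <- structure(list(weights = c(g1 = 2, g2 = -1), threshold = 1,
                       stratum = "all", coloc_only = FALSE,
                       n_features_pre_clump = 2L, n_genes = 2L),
                  class = "weight_set")
  pts <- compute_pts(z, ws)
  expect_equal(pts$score[pts$sample_id == "s1"], 1.5)   # 2*1 + (-1)*0.5
  expect_equal(attr(pts, "n_genes_used"), 2L)

  # linearity: doubling weights doubles scores
  ws2 <- ws; ws2$weights <- ws$weights * 2
  expect_equal(compute_pts(z, ws2)$score, pts$score * 2)

  # gene/sample order invariance
  perm <- compute_pts(z[c(2, 1), c(2, 1)], ws)
  expect_equal(perm$score[match(pts$sample_id, perm$sample_id)], pts$score)

  # a measured gene absent from the weights changes nothing
  z3 <- rbind(z, g9 = c(5, 5))
  expect_equal(compute_pts(z3, ws)$score, pts$score)

  # missing weight genes are skipped and counted
  pts_miss <- compute_pts(z["g1", , drop = FALSE], ws)
  expect_equal(attr(pts_miss, "n_genes_used"), 1L)
  expect_equal(pts_miss$score, c(2, -2))

  # empty weight set scores 0
  ws0 <- ws; ws0$weights <- setNames(numeric(0), character(0)); ws0$n_genes <- 0L
  expect_equal(compute_pts(z, ws0)$score, c(0, 0))

  # zero overlap with a non-empty weight set warns explicitly
  zx <- rbind(gX = c(1, -1)); colnames(zx) <- c("s1", "s2")
  expect_warning(ptsx <- compute_pts(zx, ws), "no weight-set genes")
  expect_equal(ptsx$score, c(0, 0))
})
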