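test_that("interaction coding is total on the closed vocabulary", {
  raw <- data.frame(
    drug_id = "D1", gene_id = sprintf("G%d", 1:6),
    label = c("DECREASED_EXPRESSION", "NEGATIVE_RESPONSE",
              "OPPOSITE_RESPONSE", "INCREASED_EXPRESSION",
              "POSITIVE_RESPONSE", "UNDIRECTED"),
    stringsAsFactors = FALSE)
  coded <- code_interactions(raw)
  expect_equal(coded$code, c(-1L, -1L, -1L, 1L, 1L, 0L))
  # idempotent
  expect_equal(code_interactions(coded)$code, coded$code)

  bad <- raw; bad$label[2] <- "BINDS"
  expect_error(code_interactions(bad), "row\\(s\\) 2.*BINDS")
})

test_that("drug filtering requires two measured genes", {
  inter <- data.frame(
    drug_id = c("D1", "D2", "D2", "D3", "D3", "D3"),
    gene_id = c("G1", "G1", "G2", "G1", "GX", "GY"),
    label = "UNDIRECTED", stringsAsFactors = FALSE)
  stats_map <- c(G1 = 1, G2 = 2, G3 = 3)
  kept <- filter_testable_drugs(inter, stats_map)
  expect_setequal(kept, "D2")  # D1: 1 measured; D3: 1 measured of 3 listed

  # 2 measured of 5 listed is retained (boundary)
  inter2 <- data.frame(drug_id = "D4", gene_id = c("G1", "G2", "Ga", "Gb", "Gc"),
                       label = "UNDIRECTED")
  expect_equal(filter_testable_drugs(inter2, stats_map), "D4")

  # retention equals brute-force set intersection counting
  set.seed(5)
  genes <- sprintf("G%02d", 1:30)
  inter3 <- data.frame(
    drug_id = rep(sprintf("D%02d", 1:12), each = 4),
    gene_id = sample(genes, 48, replace = TRUE),
    label = "UNDIRECTED", stringsAsFactors = FALSE)
  gs <- setNames(rnorm(15), sample(genes, 15))
  brute <- names(which(vapply(split(inter3$gene_id, inter3$drug_id),
                              function(g) length(intersect(unique(g), names(gs))),
                              integer(1)) >= 2))
  expect_setequal(filter_testable_drugs(inter3, gs), brute)
})

test_that("signed concordance has the stated arithmetic and sign convention", {
  gene_z <- c(g1 = 3, g2 = -2, g3 = 0.5, g4 = -1, g5 = 2, g6 = 0.1)
  inter <- code_interactions(data.frame(
    drug_id = "D1", gene_id = c("g1", "g2"),
    label = c("INCREASED_EXPRESSION", "DECREASED_EXPRESSION")))
  res <- signed_drug_enrichment(gene_z, inter)
  # S = (+1)(3) + (-1)(-2) = 5: risk-increasing, so reported z is negative
  expect_lt(res$z, 0)
  es <- mean(gene_z) * 0   # sum of codes is 0
  vs <- mean((gene_z - mean(gene_z))^2) * (6 * 2 - 0) / 5
  expect_equal(res$z, -(5 - es) / sqrt(vs), tolerance = 1e-12)

  # exact p matches the independent enumeration oracle
  inter3 <- code_interactions(data.frame(
    drug_id = "D2", gene_id = c("g1", "g2", "g3"),
    label = c("INCREASED_EXPRESSION", "DECREASED_EXPRESSION",
              "INCREASED_EXPRESSION")))
  res3 <- signed_drug_enrichment(gene_z, inter3)
  s_obs <- 3 - (-2) + 0.5
  expect_equal(res3$p, brute_signed_p(c(1, -1, 1), gene_z, s_obs),
               tolerance = 1e-12)

  # negating every gene Z flips every drug z exactly
  both <- rbind(inter, inter3)
  set.seed(77); a <- signed_drug_enrichment(gene_z, both)
  set.seed(77); b <- signed_drug_enrichment(-gene_z, both)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)

  # all-undirected drug excluded with a message
  und <- code_interactions(data.frame(drug_id = "D9",
                                      gene_id = c("g1", "g2"),
                                      label = "UNDIRECTED"))
  expect_message(out <- signed_drug_enrichment(gene_z, und), "excluded")
  expect_equal(nrow(out), 0)
})

test_that("unsigned enrichment matches exact rank-sum behaviour", {
  # members carry the top associations: minimal one-sided p for the size
  vals <- setNames(c(10, 9, 8, 1:7), sprintf("g%02d", 1:10))
  inter <- data.frame(drug_id = "D1", gene_id = c("g01", "g02", "g03"),
                      label = "UNDIRECTED")
  res <- unsigned_drug_enrichment(vals, code_interactions(inter))
  expect_equal(res$p, 1 / choose(10, 3), tolerance = 1e-12)

  # empty non-member set is an error
  all_in <- data.frame(drug_id = "D1", gene_id = names(vals),
                       label = "UNDIRECTED")
  expect_error(unsigned_drug_enrichment(vals, code_interactions(all_in)),
               "comparator")

  # identically distributed members: p approximately uniform
  set.seed(12)
  ps <- replicate(400, {
    v <- setNames(rnorm(40)^2, sprintf("g%02d", 1:40))
    idx <- sample(40, 5)
    it <- data.frame(drug_id = "D", gene_id = names(v)[idx],
                     label = "UNDIRECTED")
    unsigned_drug_enrichment(v, code_interactions(it))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("ATC class enrichment applies size filter, sidedness and FDR", {
  dr <- data.frame(drug_id = sprintf("D%02d", 1:10),
                   z = c(10, 9, 8, 7, 6, -1, -2, -3, -4, -5),
                   stringsAsFactors = FALSE)
  amap <- data.frame(drug_id = dr$drug_id,
                     atc3 = rep(c("C08A", "N03A"), each = 5))
  res <- atc_enrichment(dr, amap, min_drugs = 5, sided = "two")
  # group holding ranks 1..5: exact two-sided Mann-Whitney p = 2/252
  expect_equal(res$p[res$atc3 == "C08A"], 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(res$direction[res$atc3 == "C08A"], "protective")
  expect_equal(res$direction[res$atc3 == "N03A"], "deleterious")

  # a class of 4 drugs is skipped
  amap4 <- amap; amap4$atc3[1] <- "X99X"
  res4 <- atc_enrichment(dr, amap4, min_drugs = 5, sided = "two")
  expect_false("X99X" %in% res4$atc3)
  expect_false("C08A" %in% res4$atc3)  # now size 4 as well

  # invariance to drug ordering
  perm <- sample(nrow(dr))
  res_p <- atc_enrichment(dr[perm, ], amap, min_drugs = 5, sided = "two")
  expect_equal(res[order(res$atc3), ], res_p[order(res_p$atc3), ],
               tolerance = 1e-12)

  # one-sided mode favours high-statistic classes only
  res1 <- atc_enrichment(dr, amap, min_drugs = 5, sided = "one")
  expect_equal(res1$p[res1$atc3 == "C08A"], 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_gt(res1$p[res1$atc3 == "N03A"], 0.99)
})
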