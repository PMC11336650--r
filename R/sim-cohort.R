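#' @keywords internal
#' Per-block structures for the liability model.
#'
#' Observed expression shares the gene-level block structure of the
#' predicted-expression correlation: compound symmetry `within_block_r`
#' within each block, independence across blocks. The true liability score
#' is s = sum_g w_g z_g over the signal genes; its variance decomposes over
#' blocks as v = sum_b v_b with v_b = w_b' Sigma_b w_b.
liability_structure <- function(config, annotation, truth_weights) {
  blocks <- split(seq_len(nrow(annotation)), annotation$block)
  r <- config$within_block_r
  out <- lapply(blocks, function(idx) {
    genes <- annotation$gene_id[idx]
    m <- length(genes)
    Sigma <- matrix(r, m, m); diag(Sigma) <- 1
    w <- unname(truth_weights[genes])
    w[is.na(w)] <- 0
    vb <- drop(crossprod(w, Sigma %*% w))
    lst <- list(genes = genes, m = m, Sigma = Sigma, w = w, vb = vb)
    if (vb > 0) {
      sw <- drop(Sigma %*% w)
      covc <- Sigma - tcrossprod(sw) / vb
      eg <- eigen(covc, symmetric = TRUE)
      vals <- pmax(eg$values, 0)
      lst$mean_coef <- sw / vb             # E[z | s_b] = mean_coef * s_b
      lst$A_cond <- eg$vectors %*% diag(sqrt(vals), m)
    } else {
      lst$A_chol <- t(chol(Sigma))
    }
    lst
  })
  v <- sum(vapply(out, `[[`, numeric(1), "vb"))
  r2 <- config$target_liability_r2
  if (r2 > 0 && v <= 0) {
    stop("target_liability_r2 > 0 requires a non-empty truth weight map",
         call. = FALSE)
  }
  c_scale <- if (v > 0) sqrt(r2 / v) else 0
  list(blocks = out, v = v, c = c_scale, r2 = r2,
       t = stats::qnorm(1 - config$prevalence_K))
}

# draw per-block scores s_b for each individual, conditional on total s
draw_block_scores <- function(struct, s) {
  sig <- which(vapply(struct$blocks, `[[`, numeric(1), "vb") > 0)
  vb <- vapply(struct$blocks[sig], `[[`, numeric(1), "vb")
  n <- length(s)
  if (length(sig) == 0L) return(NULL)
  eta <- matrix(stats::rnorm(length(sig) * n), length(sig), n) * sqrt(vb)
  zeta <- eta - outer(vb, colSums(eta) / struct$v)
  sb <- outer(vb / struct$v, s) + zeta
  rownames(sb) <- names(struct$blocks)[sig]
  sb
}

# draw the full gene x sample expression matrix given per-block scores
draw_expression_given_scores <- function(struct, sb, n) {
  mats <- lapply(seq_along(struct$blocks), function(b) {
    blk <- struct$blocks[[b]]
    if (blk$vb > 0) {
      s_b <- sb[names(struct$blocks)[b], ]
      z <- outer(blk$mean_coef, s_b) +
        blk$A_cond %*% matrix(stats::rnorm(blk$m * n), blk$m, n)
    } else {
      z <- blk$A_chol %*% matrix(stats::rnorm(blk$m * n), blk$m, n)
    }
    rownames(z) <- blk$genes
    z
  })
  do.call(rbind, mats)
}

#' Simulate ascertained case-control expression cohorts
#'
#' Generates one cohort per platform under a liability-threshold model:
#' liability L = c * s + e, where s = sum_g w_g z_g is the weighted
#' expression score over the truth map, c is chosen so that c^2 Var(s)
#' equals `target_liability_r2`, e ~ N(0, 1 - target_liability_r2), and an
#' individual is a case iff L exceeds t = qnorm(1 - prevalence_K).
#' Case-control ascertainment is performed by conditional sampling: case
#' (control) liabilities are drawn from the upper (lower) truncated normal,
#' then the score given liability, then expression given the score — the
#' phenotype model is untouched, only sampling weights change.
#'
#' Within cases, site of onset (liability model at `spinal_prevalence`),
#' age at onset, and survival depend linearly on the standardized true
#' score. Platform effects are a small global expression shift plus
#' per-gene dropout, disjoint across platforms.
#'
#' @param config a [sim_config()] object.
#' @param annotation output of [simulate_gene_annotation()].
#' @param truth_weights named numeric vector mapping signal genes to their
#'   liability weights (typically `true_z` from [simulate_twas_sumstats()]);
#'   may be empty for a null simulation.
#' @return A list of `expression_cohort` objects (one per platform), each a
#'   list with elements `platform`, `expr` (genes x samples), `pheno`
#'   (sample_id, case, sex, onset_site, onset_age, survival), and `truth`
#'   (per-sample true score and liability). The list carries attribute
#'   `"liability"` with the realized scaling (v, c, t).
#' @export
simulate_expression_cohort <- function(config, annotation, truth_weights) {
  stopifnot(inherits(config, "sim_config"))
  if (config$target_liability_r2 >= 1) {
    stop("target_liability_r2 must be < 1", call. = FALSE)
  }
  struct <- liability_structure(config, annotation, truth_weights)
  K <- config$prevalence_K
  genes <- annotation$gene_id

  set.seed(config$seed + 199L)
  n_drop <- round(config$dropout_frac * config$n_genes)
  dropped_all <- if (n_drop > 0) {
    sample(genes, n_drop * config$n_platforms)
  } else character()
  dropped_by_platform <- if (n_drop > 0) {
    split(dropped_all, rep(seq_len(config$n_platforms), each = n_drop))
  } else rep(list(character()), config$n_platforms)

  cohorts <- vector("list", config$n_platforms)
  for (pf in seq_len(config$n_platforms)) {
    set.seed(config$seed + 211L + pf)
    n_ca <- config$n_cases; n_co <- config$n_controls
    n <- n_ca + n_co
    pK <- stats::pnorm(struct$t)
    L <- c(stats::qnorm(stats::runif(n_ca, pK, 1)),    # cases: L > t
           stats::qnorm(stats::runif(n_co, 0, pK)))    # controls: L <= t
    if (struct$v > 0 && struct$r2 > 0) {
      # (s, L) bivariate normal: Cov(s, L) = c * v
      s <- struct$c * struct$v * L +
        stats::rnorm(n, 0, sqrt(struct$v * (1 - struct$r2)))
    } else if (struct$v > 0) {
      s <- stats::rnorm(n, 0, sqrt(struct$v))
    } else {
      s <- numeric(n)
    }
    sb <- draw_block_scores(struct, s)
    expr <- draw_expression_given_scores(struct, sb, n)
    shift <- (pf - (config$n_platforms + 1) / 2) * config$platform_shift
    expr <- expr + shift
    sample_id <- sprintf("P%d_S%05d", pf, seq_len(n))
    colnames(expr) <- sample_id
    expr <- expr[!(rownames(expr) %in% dropped_by_platform[[pf]]), ,
                 drop = FALSE]
    expr <- expr[match(intersect(genes, rownames(expr)), rownames(expr)), ,
                 drop = FALSE]

    case <- rep(c(1L, 0L), c(n_ca, n_co))
    sex <- stats::rbinom(n, 1L, 0.5)
    s_std <- if (struct$v > 0) s / sqrt(struct$v) else numeric(n)
    l_site <- config$onset_site_beta * s_std + stats::rnorm(n)
    thr_site <- stats::qnorm(1 - config$spinal_prevalence,
                             sd = sqrt(1 + config$onset_site_beta^2))
    onset_site <- ifelse(l_site > thr_site, "spinal", "bulbar")
    onset_age <- config$onset_age_mean + config$onset_age_beta * s_std +
      stats::rnorm(n, 0, config$onset_age_sd)
    survival <- config$survival_mean + config$survival_beta * s_std +
      stats::rnorm(n, 0, config$survival_sd)
    is_control <- case == 0L
    onset_site[is_control] <- NA
    onset_age[is_control] <- NA
    survival[is_control] <- NA

    pheno <- data.frame(sample_id = sample_id, case = case, sex = sex,
                        onset_site = onset_site, onset_age = onset_age,
                        survival = survival, stringsAsFactors = FALSE)
    cohorts[[pf]] <- structure(
      list(platform = sprintf("PLT%d", pf), expr = expr, pheno = pheno,
           truth = data.frame(sample_id = sample_id, score = s,
                              liability = L, stringsAsFactors = FALSE)),
      class = "expression_cohort")
  }
  attr(cohorts, "liability") <- list(v = struct$v, c = struct$c,
                                     t = struct$t,
                                     dropped = dropped_by_platform)
  cohorts
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("Expression cohort %s: %d genes x %d samples (%d cases / %d controls)\n",
              x$platform, nrow(x$expr), ncol(x$expr),
              sum(x$pheno$case == 1), sum(x$pheno$case == 0)))
  invisible(x)
}

#' Simulate an unascertained population under the liability model
#'
#' Draws `n` individuals through the full generative path (expression in
#' signal blocks, weighted score, liability, threshold) with no
#' case-control ascertainment. Used to verify that the realized disease
#' prevalence matches `prevalence_K` and that the score explains
#' `target_liability_r2` of liability variance.
#'
#' @param config a [sim_config()] object.
#' @param annotation output of [simulate_gene_annotation()].
#' @param truth_weights named numeric vector of liability weights.
#' @param n number of individuals.
#' @param seed optional seed (defaults to `config$seed + 301`).
#' @return Data frame with columns `score`, `liability`, `case`.
#' @export
simulate_liability_population <- function(config, annotation, truth_weights,
                                          n, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  struct <- liability_structure(config, annotation, truth_weights)
  set.seed(if (is.null(seed)) config$seed + 301L else seed)
  sig <- Filter(function(b) b$vb > 0, struct$blocks)
  s <- numeric(n)
  for (blk in sig) {
    A <- t(chol(blk$Sigma))
    z <- A %*% matrix(stats::rnorm(blk$m * n), blk$m, n)
    s <- s + drop(crossprod(z, blk$w))
  }
  e <- stats::rnorm(n, 0, sqrt(1 - struct$r2))
  L <- struct$c * s + e
  data.frame(score = s, liability = L, case = as.integer(L > struct$t))
}
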