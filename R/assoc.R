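#' Linear association of an outcome with the PTS, adjusting for sex
#'
#' Ordinary least squares of the outcome on (intercept, sex, PTS).
#' `r2_observed` is the incremental R-squared of the full model over the
#' sex-only model, the quantity later converted to the liability scale for
#' binary outcomes.
#'
#' @param outcome numeric vector (binary 0/1 or continuous).
#' @param pts numeric vector of scores, or a `pts_vector` data frame.
#' @param sex 0/1 covariate vector.
#' @param outcome_name,platform labels carried into the result.
#' @return One-row data frame: `outcome`, `platform`, `n`, `beta`, `se`,
#'   `p`, `r2_observed`, `r2_liability` (NA; filled by the caller for
#'   binary outcomes).
#' @export
fit_linear_assoc <- function(outcome, pts, sex,
                             outcome_name = "outcome", platform = NA) {
  if (inherits(pts, "pts_vector")) pts <- pts$score
  keep <- stats::complete.cases(outcome, pts, sex)
  y <- outcome[keep]; x <- pts[keep]; s <- sex[keep]
  if (length(y) < 10) stop("need at least 10 complete observations", call. = FALSE)
  if (stats::var(y) == 0) stop("degenerate column: outcome is constant", call. = FALSE)
  if (stats::var(x) == 0) stop("degenerate column: PTS is constant", call. = FALSE)
  full <- stats::lm(y ~ s + x)
  reduced <- stats::lm(y ~ s)
  co <- summary(full)$coefficients["x", ]
  r2 <- summary(full)$r.squared - summary(reduced)$r.squared
  data.frame(outcome = outcome_name, platform = platform,
             n = length(y), beta = unname(co[1]), se = unname(co[2]),
             p = unname(co[4]), r2_observed = max(r2, 0),
             r2_liability = NA_real_, stringsAsFactors = FALSE)
}

#' Convert observed-scale R-squared to the liability scale
#'
#' Ascertainment-corrected transformation of Lee et al. (2012) for
#' case-control studies: with t = qnorm(1 - K), z = dnorm(t), m = z/K,
#' C = K^2 (1-K)^2 / (z^2 P (1-P)) and
#' theta = m (P-K)/(1-K) * (m (P-K)/(1-K) - t), the liability-scale value
#' is C R2 / (1 + C theta R2). At K = P there is no ascertainment and the
#' correction reduces to the population transformation.
#'
#' @param r2_obs observed-scale R-squared in `[0, 1)`.
#' @param K population prevalence in (0, 1).
#' @param P sample case proportion in (0, 1).
#' @return Liability-scale R-squared (non-negative).
#' @export
#' @examples
#' observed_to_liability_r2(0.1, K = 0.5, P = 0.5)  # factor pi/2 ~ 1.5708
observed_to_liability_r2 <- function(r2_obs, K, P) {
  if (any(K <= 0 | K >= 1)) stop("K must lie in (0, 1)", call. = FALSE)
  if (any(P <= 0 | P >= 1)) stop("P must lie in (0, 1)", call. = FALSE)
  if (any(r2_obs < 0 | r2_obs >= 1)) stop("r2_obs must lie in [0, 1)", call. = FALSE)
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  m <- z / K
  C <- (K * (1 - K))^2 / (z^2 * P * (1 - P))
  u <- m * (P - K) / (1 - K)
  theta <- u * (u - t)
  pmax(C * r2_obs / (1 + C * theta * r2_obs), 0)
}

#' Inverse-variance-weighted meta-analysis of association results
#'
#' Combines per-platform estimates for one outcome with weights 1/se^2.
#' The meta R-squared is recomputed from the meta Z and the pooled
#' residual degrees of freedom as t^2/(t^2 + df) — a documented
#' approximation.
#'
#' @param results data frame of [fit_linear_assoc()] rows, all for the
#'   same outcome.
#' @return One-row data frame with `platform = "meta"`.
#' @export
ivw_meta <- function(results) {
  stopifnot(nrow(results) >= 1)
  if (length(unique(results$outcome)) != 1) {
    stop("all results must share one outcome", call. = FALSE)
  }
  if (any(!is.finite(results$se) | results$se <= 0)) {
    stop("standard errors must be finite and positive", call. = FALSE)
  }
  w <- 1 / results$se^2
  beta <- sum(w * results$beta) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- beta / se
  n <- sum(results$n)
  df <- n - 3  # intercept + sex + score
  data.frame(outcome = results$outcome[1], platform = "meta",
             n = n, beta = beta, se = se,
             p = 2 * stats::pnorm(-abs(z)),
             r2_observed = z^2 / (z^2 + df),
             r2_liability = NA_real_, stringsAsFactors = FALSE)
}

#' Evaluate PTS weight sets against all outcomes across platforms
#'
#' For every weight set: scores each platform's standardized expression,
#' fits the sex-adjusted linear association for case-control status (all
#' samples) and for site of onset, age at onset and survival (cases only),
#' meta-analyses platforms by inverse-variance weighting, and converts
#' observed R-squared to the liability scale for the binary outcomes
#' (case-control at `prevalence`, onset site at `onset_prevalence`; the
#' sample case proportion P is always taken from the fitted data).
#'
#' @param cohorts list of `expression_cohort` objects.
#' @param weight_sets list of [build_weight_set()] objects.
#' @param prevalence population prevalence for case-control conversion
#'   (default 1/300).
#' @param onset_prevalence assumed prevalence for spinal-vs-bulbar onset
#'   (default 0.5, an arbitrary convention aiding cross-study comparison).
#' @param standardize standardize expression within each cohort before
#'   scoring (default `TRUE`); `FALSE` scores the matrices as supplied
#'   (e.g. raw log2 values).
#' @return Data frame of class `pts_assoc` with one row per weight set x
#'   outcome x (platform | meta): weight-set descriptors plus the
#'   [fit_linear_assoc()] columns.
#' @export
evaluate_all <- function(cohorts, weight_sets, prevalence = 1 / 300,
                         onset_prevalence = 0.5, standardize = TRUE) {
  z_list <- if (standardize) {
    lapply(cohorts, standardize_expression)
  } else {
    lapply(cohorts, function(co) co$expr)
  }
  out <- list(); k <- 0L
  for (ws in weight_sets) {
    per_platform <- list()
    for (i in seq_along(cohorts)) {
      co <- cohorts[[i]]
      pts <- compute_pts(z_list[[i]], ws)
      ph <- co$pheno[match(pts$sample_id, co$pheno$sample_id), ]
      cases <- ph$case == 1
      specs <- list(
        case_control = list(y = ph$case, sub = rep(TRUE, nrow(ph)), K = prevalence),
        onset_site = list(y = as.integer(ph$onset_site == "spinal"),
                          sub = cases, K = onset_prevalence),
        onset_age = list(y = ph$onset_age, sub = cases, K = NA),
        survival = list(y = ph$survival, sub = cases, K = NA)
      )
      for (nm in names(specs)) {
        sp <- specs[[nm]]
        fit <- tryCatch(
          fit_linear_assoc(sp$y[sp$sub], pts$score[sp$sub], ph$sex[sp$sub],
                           outcome_name = nm, platform = co$platform),
          error = function(e) {
            message(sprintf("platform %s, outcome %s skipped: %s",
                            co$platform, nm, conditionMessage(e)))
            NULL
          })
        if (is.null(fit)) next
        if (!is.na(sp$K)) {
          P <- mean(sp$y[sp$sub][stats::complete.cases(
            sp$y[sp$sub], pts$score[sp$sub], ph$sex[sp$sub])])
          fit$r2_liability <- observed_to_liability_r2(fit$r2_observed, sp$K, P)
          fit$case_prop <- P
        } else {
          fit$case_prop <- NA_real_
        }
        per_platform[[length(per_platform) + 1L]] <- fit
      }
    }
    if (length(per_platform) == 0) next
    pp <- do.call(rbind, per_platform)
    metas <- lapply(unique(pp$outcome), function(nm) {
      rows <- pp[pp$outcome == nm, , drop = FALSE]
      m <- ivw_meta(rows)
      if (nm %in% c("case_control", "onset_site")) {
        K <- if (nm == "case_control") prevalence else onset_prevalence
        P <- sum(rows$case_prop * rows$n) / sum(rows$n)
        m$r2_liability <- observed_to_liability_r2(m$r2_observed, K, P)
        m$case_prop <- P
      } else {
        m$case_prop <- NA_real_
      }
      m
    })
    block <- rbind(pp, do.call(rbind, metas))
    block <- cbind(data.frame(threshold = ws$threshold, stratum = ws$stratum,
                              coloc_only = ws$coloc_only,
                              n_genes = ws$n_genes,
                              stringsAsFactors = FALSE),
                   block, row.names = NULL)
    k <- k + 1L
    out[[k]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pts_assoc", "data.frame")
  res
}

#' Best-threshold summary of a PTS association table
#'
#' For each stratum x colocalisation filter x outcome, picks the
#' meta-analysed row maximizing the liability-scale R-squared (binary
#' outcomes) or observed R-squared (continuous outcomes) over the
#' threshold grid. The maximum over thresholds is optimistic (no
#' out-of-sample correction), mirroring common risk-score reporting.
#'
#' @param x a `pts_assoc` table from [evaluate_all()].
#' @return Data frame with the selected rows.
#' @export
best_thresholds <- function(x) {
  stopifnot(inherits(x, "pts_assoc"))
  meta <- x[x$platform == "meta", , drop = FALSE]
  key <- interaction(meta$stratum, meta$coloc_only, meta$outcome, drop = TRUE)
  picked <- lapply(split(meta, key), function(d) {
    crit <- ifelse(is.na(d$r2_liability), d$r2_observed, d$r2_liability)
    d[which.max(crit), , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' @export
print.pts_assoc <- function(x, ...) {
  cat(sprintf("PTS association table: %d rows (%d weight sets, outcomes: %s)\n",
              nrow(x), length(unique(interaction(x$threshold, x$stratum,
                                                 x$coloc_only))),
              paste(unique(x$outcome), collapse = ", ")))
  cc <- x[x$platform == "meta" & x$outcome == "case_control", , drop = FALSE]
  if (nrow(cc)) {
    best <- cc[which.max(cc$r2_liability), ]
    cat(sprintf("  best case-control liability R2 = %.4f (threshold %g, stratum %s%s), p = %.3g\n",
                best$r2_liability, best$threshold, best$stratum,
                if (best$coloc_only) ", coloc" else "", best$p))
  }
  invisible(x)
}
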