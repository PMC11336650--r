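#' Simulation configuration for the synthetic study
#'
#' Bundles every tunable of the synthetic-data generators into a single
#' validated object. Defaults describe the study conditions the package is
#' calibrated against: ~1 000 genes laid out in 500 kb correlation blocks,
#' four expression panels (two blood, two brain) each contributing a
#' FUSION-style and an SMR-style record, 50 signal genes with mean |Z| of 6,
#' two array platforms with 2 000 cases and 2 000 controls each, a
#' liability-threshold disease model with population prevalence 1/300 in
#' which the true weighted-expression score explains 5 % of liability
#' variance, and a DrugTargetor-style drug table with one planted protective
#' ATC class.
#'
#' @param n_genes number of genes.
#' @param block_size genes per correlation block; blocks are independent.
#' @param within_block_r compound-symmetry correlation among genes of a
#'   block (predicted and observed expression share this structure). Must
#'   keep the block positive semi-definite, i.e. `>= -1/(block_size - 1)`.
#' @param cross_panel_r correlation between the same gene's predicted
#'   expression in two different panels (default 0.9, kept below 1 so
#'   feature-correlation blocks stay numerically positive definite).
#' @param window_bp window in base pairs within which pairwise
#'   predicted-expression correlations are considered (default 500 000).
#' @param n_panels number of expression panels.
#' @param panel_strata character vector of length `n_panels` with values
#'   `"blood"` or `"brain"`.
#' @param n_signal_genes number of true signal genes (may be 0 for a fully
#'   null simulation); each is placed in a distinct correlation block.
#' @param signal_z_mean mean |Z| of signal genes.
#' @param sign_agreement_prob probability that a signal gene's record in a
#'   given panel/method carries the gene's true sign.
#' @param n_platforms number of target expression platforms (default 2,
#'   emulating a two-array GEO series).
#' @param n_cases,n_controls ascertained sample sizes per platform.
#' @param prevalence_K population prevalence of the binary trait.
#' @param target_liability_r2 fraction of liability variance explained by
#'   the true expression score, in `[0, 1)`.
#' @param platform_shift global additive expression shift between platforms.
#' @param dropout_frac fraction of genes unmeasured on each platform
#'   (disjoint across platforms).
#' @param onset_site_beta liability-scale effect of the standardized true
#'   score on spinal (vs bulbar) onset, within cases.
#' @param spinal_prevalence marginal probability of spinal onset.
#' @param onset_age_mean,onset_age_beta,onset_age_sd age-at-onset model
#'   (years): mean, effect per SD of true score, residual SD.
#' @param survival_mean,survival_beta,survival_sd survival model: mean,
#'   effect per SD of true score, residual SD. Survival is uncensored.
#' @param survival_unit label only (default `"months"`).
#' @param n_drugs number of drugs in the simulated interaction table.
#' @param genes_per_drug_mean mean number of gene interactions per drug
#'   (2 + Poisson(mean - 2)); large by default, reflecting the broad
#'   polypharmacology of curated drug-gene databases.
#' @param n_enriched_drugs drugs planted to target signal genes with
#'   protective direction (may be 0).
#' @param enriched_genes_per_drug signal genes targeted by each planted drug.
#' @param n_atc_classes number of level-3 ATC classes; planted drugs share
#'   one class.
#' @param undirected_frac fraction of interactions without directional
#'   evidence (code 0).
#' @param heidi_null_small_frac fraction of null genes whose HEIDI p-value
#'   is skewed small (apparent heterogeneity).
#' @param n_credible_sets number of fine-mapping 95% credible sets to
#'   simulate (may be 0).
#' @param credible_contained_frac fraction of credible sets fully contained
#'   within their gene body.
#' @param seed integer master seed; every generator derives its stream from
#'   it, so identical configs reproduce identical outputs byte for byte.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 60, block_size = 6, n_signal_genes = 5,
#'                   n_cases = 100, n_controls = 100)
#' cfg
sim_config <- function(n_genes = 1000,
                       block_size = 10,
                       within_block_r = 0.6,
                       cross_panel_r = 0.9,
                       window_bp = 500000,
                       n_panels = 4,
                       panel_strata = c("blood", "blood", "brain", "brain"),
                       n_signal_genes = 50,
                       signal_z_mean = 6,
                       sign_agreement_prob = 1,
                       n_platforms = 2,
                       n_cases = 2000,
                       n_controls = 2000,
                       prevalence_K = 1 / 300,
                       target_liability_r2 = 0.05,
                       platform_shift = 0.2,
                       dropout_frac = 0.1,
                       onset_site_beta = 0.25,
                       spinal_prevalence = 0.65,
                       onset_age_mean = 56,
                       onset_age_beta = 2,
                       onset_age_sd = 10,
                       survival_mean = 36,
                       survival_beta = -6,
                       survival_sd = 18,
                       survival_unit = "months",
                       n_drugs = 200,
                       genes_per_drug_mean = 25,
                       n_enriched_drugs = 8,
                       enriched_genes_per_drug = 6,
                       n_atc_classes = 15,
                       undirected_frac = 0.15,
                       heidi_null_small_frac = 0.8,
                       n_credible_sets = 10,
                       credible_contained_frac = 0.8,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), block_size = as.integer(block_size),
    within_block_r = within_block_r, cross_panel_r = cross_panel_r,
    window_bp = as.numeric(window_bp), n_panels = as.integer(n_panels),
    panel_strata = as.character(panel_strata),
    n_signal_genes = as.integer(n_signal_genes),
    signal_z_mean = signal_z_mean,
    sign_agreement_prob = sign_agreement_prob,
    n_platforms = as.integer(n_platforms),
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    prevalence_K = prevalence_K,
    target_liability_r2 = target_liability_r2,
    platform_shift = platform_shift, dropout_frac = dropout_frac,
    onset_site_beta = onset_site_beta, spinal_prevalence = spinal_prevalence,
    onset_age_mean = onset_age_mean, onset_age_beta = onset_age_beta,
    onset_age_sd = onset_age_sd,
    survival_mean = survival_mean, survival_beta = survival_beta,
    survival_sd = survival_sd, survival_unit = as.character(survival_unit),
    n_drugs = as.integer(n_drugs),
    genes_per_drug_mean = genes_per_drug_mean,
    n_enriched_drugs = as.integer(n_enriched_drugs),
    enriched_genes_per_drug = as.integer(enriched_genes_per_drug),
    n_atc_classes = as.integer(n_atc_classes),
    undirected_frac = undirected_frac,
    heidi_null_small_frac = heidi_null_small_frac,
    n_credible_sets = as.integer(n_credible_sets),
    credible_contained_frac = credible_contained_frac,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  stopifnot_msg(cfg$prevalence_K > 0 && cfg$prevalence_K < 1,
                "prevalence_K must lie in (0, 1)")
  stopifnot_msg(cfg$target_liability_r2 >= 0 && cfg$target_liability_r2 < 1,
                "target_liability_r2 must lie in [0, 1)")
  stopifnot_msg(abs(cfg$within_block_r) < 1, "|within_block_r| must be < 1")
  if (cfg$block_size > 1) {
    stopifnot_msg(cfg$within_block_r >= -1 / (cfg$block_size - 1),
                  sprintf(paste0("within_block_r = %g breaks positive ",
                                 "semi-definiteness for block_size = %d ",
                                 "(minimum is -1/(block_size-1) = %g)"),
                          cfg$within_block_r, cfg$block_size,
                          -1 / (cfg$block_size - 1)))
  }
  stopifnot_msg(abs(cfg$cross_panel_r) < 1, "|cross_panel_r| must be < 1")
  pos_counts <- c("n_genes", "block_size", "n_panels", "n_platforms",
                  "n_cases", "n_controls", "n_drugs")
  for (nm in pos_counts) {
    stopifnot_msg(cfg[[nm]] >= 1L, sprintf("%s must be >= 1", nm))
  }
  nonneg_counts <- c("n_signal_genes", "n_enriched_drugs", "n_credible_sets")
  for (nm in nonneg_counts) {
    stopifnot_msg(cfg[[nm]] >= 0L, sprintf("%s must be >= 0", nm))
  }
  stopifnot_msg(cfg$n_signal_genes <= cfg$n_genes,
                "n_signal_genes must not exceed n_genes")
  n_blocks <- ceiling(cfg$n_genes / cfg$block_size)
  stopifnot_msg(cfg$n_signal_genes <= n_blocks,
                sprintf("n_signal_genes (%d) must not exceed the number of correlation blocks (%d); signal genes occupy distinct blocks",
                        cfg$n_signal_genes, n_blocks))
  stopifnot_msg(length(cfg$panel_strata) == cfg$n_panels,
                "panel_strata must have one label per panel")
  stopifnot_msg(all(cfg$panel_strata %in% c("blood", "brain")),
                "panel_strata labels must be 'blood' or 'brain'")
  stopifnot_msg(cfg$dropout_frac >= 0 &&
                  cfg$dropout_frac * cfg$n_platforms <= 1,
                "dropout_frac * n_platforms must be <= 1 (dropout is disjoint across platforms)")
  stopifnot_msg(cfg$sign_agreement_prob >= 0 && cfg$sign_agreement_prob <= 1,
                "sign_agreement_prob must lie in [0, 1]")
  stopifnot_msg(cfg$spinal_prevalence > 0 && cfg$spinal_prevalence < 1,
                "spinal_prevalence must lie in (0, 1)")
  stopifnot_msg(cfg$window_bp > 0, "window_bp must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  genes: %d in blocks of %d (within-block r = %.2f, window %g bp)\n",
              x$n_genes, x$block_size, x$within_block_r, x$window_bp))
  cat(sprintf("  panels: %d (%s); signal genes: %d, mean |Z| = %.1f\n",
              x$n_panels, paste(x$panel_strata, collapse = ", "),
              x$n_signal_genes, x$signal_z_mean))
  cat(sprintf("  platforms: %d x (%d cases + %d controls), K = %.4g, liability R2 = %.3f\n",
              x$n_platforms, x$n_cases, x$n_controls,
              x$prevalence_K, x$target_liability_r2))
  cat(sprintf("  drugs: %d (%d planted protective), %d ATC classes\n",
              x$n_drugs, x$n_enriched_drugs, x$n_atc_classes))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Fields mirror the arguments of [sim_config()]; omitted fields take their
#' defaults.
#'
#' @param path path to a YAML file.
#' @return A `sim_config` object.
#' @export
load_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown)) {
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, vals)
}
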