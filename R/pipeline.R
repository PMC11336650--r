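#' Write a stage output table as annotated TSV
#'
#' Tab-separated UTF-8 with `#`-prefixed metadata lines before the header,
#' interoperable with FUSION/MAGMA-adjacent tooling.
#'
#' @param df data frame.
#' @param path output path.
#' @param meta named character vector written as `# name: value` lines.
#' @export
write_stage_tsv <- function(df, path, meta = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), meta), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stage TSV, enforcing its column contract
#'
#' @param path input path.
#' @param required required column names; a missing column raises an error
#'   naming the file, the column, and the stage.
#' @param stage stage name for error messages.
#' @return Data frame.
#' @export
read_stage_tsv <- function(path, required = NULL, stage = "") {
  if (!file.exists(path)) {
    stop(sprintf("stage '%s': required input file '%s' not found",
                 stage, path), call. = FALSE)
  }
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("stage '%s': file '%s' is missing required column(s): %s",
                 stage, path, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Default p-value threshold grid
#' @export
default_threshold_grid <- function() {
  c(1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1)
}

read_expr_matrix <- function(path, stage) {
  df <- read_stage_tsv(path, required = "gene_id", stage = stage)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' Run the full analysis pipeline
#'
#' Executes simulate, triage, score, evaluate, drugs and diffexp in order,
#' writing every intermediate as annotated TSV under `out_dir` plus a JSON
#' run manifest with file digests. Stages not listed in `stages` are
#' skipped; later stages then read their inputs from `out_dir`, so
#' partial runs over precomputed (or user-supplied) inputs work.
#'
#' @param config a [sim_config()] object or the path of a YAML file.
#' @param out_dir output directory (created if needed).
#' @param seed optional integer overriding `config$seed`.
#' @param stages character subset of
#'   `c("simulate","triage","score","evaluate","drugs","diffexp")`.
#' @param threshold_grid p-value grid for weight sets.
#' @param strata tissue strata for weight sets.
#' @param coloc_filters logical vector of colocalisation-filter settings.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = NULL,
                         stages = c("simulate", "triage", "score",
                                    "evaluate", "drugs", "diffexp"),
                         threshold_grid = default_threshold_grid(),
                         strata = c("all", "blood", "brain"),
                         coloc_filters = c(FALSE, TRUE)) {
  if (is.character(config)) config <- load_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
  }
  known <- c("simulate", "triage", "score", "evaluate", "drugs", "diffexp")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)

  manifest <- list(
    tool = "ptscore", version = as.character(utils::packageVersion("ptscore")),
    seed = config$seed,
    config_hash = digest_config(config),
    stages = list()
  )
  log_stage <- function(stage, outputs, counts = NULL) {
    manifest$stages[[stage]] <<- list(
      outputs = as.list(tools::md5sum(outputs)),
      counts = counts)
    message(sprintf("[%s] wrote %d file(s)%s", stage, length(outputs),
                    if (is.null(counts)) "" else
                      paste0(" (", paste(names(counts), counts, sep = "=",
                                         collapse = ", "), ")")))
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline halted at stage '%s': %s",
                   stage, conditionMessage(e)), call. = FALSE)
    })
  }

  state <- new.env(parent = emptyenv())
  need <- function(what) {
    if (!is.null(state[[what]])) return(state[[what]])
    val <- switch(
      what,
      annotation = read_stage_tsv(pth("annotation.tsv"),
                                  c("gene_id", "chrom", "start", "end"),
                                  "load"),
      twas = read_stage_tsv(pth("twas.tsv"),
                            c("gene_id", "panel", "stratum", "method",
                              "molecule", "z", "p", "pp3", "pp4", "heidi_p"),
                            "load"),
      credible_sets = read_stage_tsv(pth("credible_sets.tsv"),
                                     c("locus_id", "chrom", "pos"), "load"),
      corr = feature_correlation(
        read_stage_tsv(pth("feature_correlation.tsv"),
                       c("feature_i", "feature_j", "r"), "load"),
        config$window_bp),
      drugs_raw = read_stage_tsv(pth("drug_interactions.tsv"),
                                 c("drug_id", "gene_id", "label", "atc3"),
                                 "load"),
      cohorts = lapply(seq_len(config$n_platforms), function(pf) {
        plt <- sprintf("PLT%d", pf)
        structure(list(
          platform = plt,
          expr = read_expr_matrix(pth(sprintf("expr_%s.tsv", plt)), "load"),
          pheno = read_stage_tsv(pth(sprintf("pheno_%s.tsv", plt)),
                                 c("sample_id", "case", "sex"), "load")),
          class = "expression_cohort")
      }),
      stop("internal: unknown state item ", what)
    )
    state[[what]] <- val
    val
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    ann <- simulate_gene_annotation(config)
    tw <- simulate_twas_sumstats(config, ann)
    cs <- simulate_credible_sets(config, ann, tw$truth)
    corr <- simulate_feature_correlation(config, ann)
    w_true <- with(tw$truth, stats::setNames(true_z[is_signal],
                                             gene_id[is_signal]))
    cohorts <- simulate_expression_cohort(config, ann, w_true)
    drugs <- simulate_drug_database(config, ann, tw$truth)

    meta <- c(tool = "ptscore", seed = as.character(config$seed))
    # MAGMA gene-location dialect: gene, chrom, start, end (1-based incl.)
    write_stage_tsv(ann[c("gene_id", "chrom", "start", "end")],
                    pth("annotation.tsv"), meta)
    write_stage_tsv(tw$records, pth("twas.tsv"), meta)
    write_stage_tsv(cs, pth("credible_sets.tsv"), meta)
    write_stage_tsv(corr$pairs, pth("feature_correlation.tsv"),
                    c(meta, window_bp = as.character(config$window_bp)))
    write_stage_tsv(drugs$interactions, pth("drug_interactions.tsv"), meta)
    files <- c("annotation.tsv", "twas.tsv", "credible_sets.tsv",
               "feature_correlation.tsv", "drug_interactions.tsv")
    lia <- attr(cohorts, "liability")
    for (co in cohorts) {
      ef <- sprintf("expr_%s.tsv", co$platform)
      pf <- sprintf("pheno_%s.tsv", co$platform)
      expr_df <- data.frame(gene_id = rownames(co$expr), co$expr,
                            check.names = FALSE, stringsAsFactors = FALSE)
      write_stage_tsv(expr_df, pth(ef), meta)
      write_stage_tsv(co$pheno, pth(pf),
                      c(meta, survival_unit = config$survival_unit))
      files <- c(files, ef, pf)
    }
    truth <- list(
      signal_genes = tw$truth$gene_id[tw$truth$is_signal],
      true_weights = as.list(w_true),
      liability_scale_c = lia$c, score_variance = lia$v,
      liability_threshold = lia$t,
      enriched_drugs = drugs$truth$enriched_drugs,
      enriched_atc_class = drugs$truth$enriched_class)
    jsonlite::write_json(truth, pth("ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, "ground_truth.json")

    state$annotation <- ann; state$twas <- tw$records
    state$truth <- tw$truth; state$credible_sets <- cs
    state$corr <- corr; state$cohorts <- cohorts
    state$drugs_raw <- drugs$interactions
    log_stage("simulate", pth(files),
              c(genes = nrow(ann), twas_records = nrow(tw$records),
                drugs = length(unique(drugs$interactions$drug_id))))
  })

  if ("triage" %in% stages) run_stage("triage", function() {
    tri <- define_high_confidence(need("twas"), need("credible_sets"),
                                  need("annotation"))
    write_stage_tsv(tri, pth("triage.tsv"),
                    c(fdr_alpha = "0.05",
                      criteria = "finemap|fusion_coloc|smr_heidi"))
    state$triage <- tri
    log_stage("triage", pth("triage.tsv"),
              c(genes = nrow(tri), high_confidence = sum(tri$high_confidence)))
  })

  weight_set_grid <- function() {
    if (!is.null(state$weight_sets)) return(state$weight_sets)
    tw <- need("twas"); corr <- need("corr")
    grid <- expand.grid(threshold = threshold_grid, stratum = strata,
                        coloc_only = coloc_filters,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ws <- lapply(seq_len(nrow(grid)), function(i) {
      suppressWarnings(build_weight_set(
        tw, corr, threshold = grid$threshold[i],
        stratum = grid$stratum[i], coloc_only = grid$coloc_only[i]))
    })
    state$weight_sets <- ws
    ws
  }

  if ("score" %in% stages) run_stage("score", function() {
    ws <- weight_set_grid()
    ws_df <- do.call(rbind, lapply(ws, function(w) {
      if (w$n_genes == 0) return(NULL)
      data.frame(gene_id = names(w$weights), weight = unname(w$weights),
                 threshold = w$threshold, stratum = w$stratum,
                 coloc_only = w$coloc_only, stringsAsFactors = FALSE)
    }))
    write_stage_tsv(ws_df, pth("weight_sets.tsv"))
    files <- "weight_sets.tsv"
    cohorts <- need("cohorts")
    pts_rows <- list()
    for (co in cohorts) {
      z <- suppressWarnings(standardize_expression(co))
      for (w in ws) {
        pts <- suppressWarnings(compute_pts(z, w))
        pts_rows[[length(pts_rows) + 1L]] <- data.frame(
          platform = co$platform, sample_id = pts$sample_id,
          score = pts$score, threshold = w$threshold, stratum = w$stratum,
          coloc_only = w$coloc_only,
          n_genes_used = attr(pts, "n_genes_used"),
          stringsAsFactors = FALSE)
      }
    }
    write_stage_tsv(do.call(rbind, pts_rows), pth("pts.tsv"))
    files <- c(files, "pts.tsv")
    log_stage("score", pth(files),
              c(weight_sets = length(ws),
                nonempty = sum(vapply(ws, `[[`, integer(1), "n_genes") > 0)))
  })

  if ("evaluate" %in% stages) run_stage("evaluate", function() {
    res <- suppressWarnings(evaluate_all(need("cohorts"), weight_set_grid()))
    write_stage_tsv(
      as.data.frame(res), pth("assoc_results.tsv"),
      c(prevalence_case_control = "1/300", prevalence_onset_site = "0.5",
        note = paste("best-threshold R2 is the maximum over the grid,",
                     "no out-of-sample correction (optimistic)")))
    best <- best_thresholds(res)
    write_stage_tsv(best, pth("assoc_best.tsv"))
    state$assoc <- res
    log_stage("evaluate", pth(c("assoc_results.tsv", "assoc_best.tsv")),
              c(rows = nrow(res)))
  })

  if ("drugs" %in% stages) run_stage("drugs", function() {
    inter <- code_interactions(need("drugs_raw"))
    ws_all <- suppressWarnings(build_weight_set(need("twas"), need("corr"),
                                                threshold = 1,
                                                stratum = "all"))
    gene_z <- ws_all$weights
    signed <- suppressMessages(signed_drug_enrichment(gene_z, inter))
    unsigned <- unsigned_drug_enrichment(gene_z^2, inter)
    atc_map <- unique(inter[c("drug_id", "atc3")])
    atc_signed <- atc_enrichment(signed, atc_map, sided = "two")
    atc_unsigned <- atc_enrichment(unsigned, atc_map, sided = "one")
    hdr <- c(sign_convention = "positive z = predicted protective",
             gene_statistic = "clumped cross-panel mean TWAS Z")
    write_stage_tsv(signed, pth("drug_signed.tsv"), hdr)
    write_stage_tsv(unsigned, pth("drug_unsigned.tsv"),
                    c(gene_statistic = "squared clumped mean TWAS Z"))
    write_stage_tsv(atc_signed, pth("atc_signed.tsv"), hdr)
    write_stage_tsv(atc_unsigned, pth("atc_unsigned.tsv"))
    state$drug_signed <- signed; state$atc_signed <- atc_signed
    log_stage("drugs", pth(c("drug_signed.tsv", "drug_unsigned.tsv",
                             "atc_signed.tsv", "atc_unsigned.tsv")),
              c(drugs_tested = nrow(signed),
                atc_classes = nrow(atc_signed)))
  })

  if ("diffexp" %in% stages) run_stage("diffexp", function() {
    cohorts <- need("cohorts")
    per <- lapply(cohorts, function(co)
      suppressWarnings(per_gene_case_control_correlation(co)))
    meta <- meta_diffexpr(per)
    tw <- need("twas")
    tri <- if (!is.null(state$triage)) state$triage else
      tryCatch(read_stage_tsv(pth("triage.tsv"), "gene_id", "diffexp"),
               error = function(e) NULL)
    mean_z <- tapply(tw$z, tw$gene_id, mean)
    twas_dir <- stats::setNames(as.numeric(mean_z), names(mean_z))
    if (!is.null(tri)) {
      twas_dir <- twas_dir[names(twas_dir) %in%
                             tri$gene_id[tri$high_confidence]]
    }
    conc <- classify_concordance(twas_dir, meta)
    for (i in seq_along(per)) {
      write_stage_tsv(per[[i]],
                      pth(sprintf("diffexp_%s.tsv", cohorts[[i]]$platform)))
    }
    write_stage_tsv(meta, pth("diffexp_meta.tsv"))
    write_stage_tsv(conc, pth("concordance.tsv"),
                    c(twas_direction = "mean Z across panels, high-confidence genes"))
    files <- c(sprintf("diffexp_%s.tsv",
                       vapply(cohorts, `[[`, character(1), "platform")),
               "diffexp_meta.tsv", "concordance.tsv")
    smry <- attr(conc, "summary")
    log_stage("diffexp", pth(files), smry)
  })

  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

digest_config <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
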