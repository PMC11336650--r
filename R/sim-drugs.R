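#' Directional interaction label vocabulary
#'
#' The closed label set for drug-gene interactions: three labels implying
#' decreased gene activity (code -1), two implying increased activity
#' (code +1), and one undirected label (code 0).
#' @export
DRUG_LABELS <- list(
  decrease = c("DECREASED_EXPRESSION", "NEGATIVE_RESPONSE",
               "OPPOSITE_RESPONSE"),
  increase = c("INCREASED_EXPRESSION", "POSITIVE_RESPONSE"),
  undirected = "UNDIRECTED"
)

#' Simulate a DrugTargetor-style drug-gene interaction table
#'
#' Every drug receives at least one gene interaction and one level-3 ATC
#' code. `n_enriched_drugs` drugs are planted as protective: they target
#' `enriched_genes_per_drug` signal genes each, with interaction direction
#' opposing the gene's risk direction (a risk-increasing gene gets a
#' decrease-activity label and vice versa), and they all share one ATC
#' class, so that class is enriched for protective drugs. Remaining drugs
#' draw genes uniformly and directions at random; a fraction
#' `undirected_frac` of interactions carry the undirected label.
#'
#' @param config a [sim_config()] object.
#' @param annotation output of [simulate_gene_annotation()].
#' @param truth truth table from [simulate_twas_sumstats()] (signal flags
#'   and true Z give the planted drugs their aligned directions).
#' @return A list with `interactions` (data frame `drug_id`, `gene_id`,
#'   `label`, `atc3`), `atc_map` (data frame `drug_id`, `atc3`), and
#'   `truth` (list with `enriched_drugs`, `enriched_class`).
#' @export
simulate_drug_database <- function(config, annotation, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 401L)
  n_drugs <- config$n_drugs
  n_enr <- config$n_enriched_drugs
  if (n_enr > n_drugs) stop("n_enriched_drugs must be <= n_drugs", call. = FALSE)
  genes <- truth$gene_id
  sig_genes <- truth$gene_id[truth$is_signal]
  sig_z <- stats::setNames(truth$true_z, truth$gene_id)
  if (n_enr > 0 && length(sig_genes) < config$enriched_genes_per_drug) {
    stop("not enough signal genes for the planted drugs", call. = FALSE)
  }

  atc_classes <- sprintf("%s%02d%s", LETTERS[1:13][
    ((seq_len(config$n_atc_classes) - 1) %% 13) + 1],
    ((seq_len(config$n_atc_classes) - 1) %/% 13) + 1,
    LETTERS[((seq_len(config$n_atc_classes) - 1) %% 26) + 1])
  enriched_class <- atc_classes[1]
  drug_id <- sprintf("DRUG%03d", seq_len(n_drugs))
  atc <- c(rep(enriched_class, n_enr),
           sample(atc_classes[-1], n_drugs - n_enr, replace = TRUE))

  pick_label <- function(code, n) {
    out <- character(n)
    dec <- code == -1; inc <- code == 1
    out[dec] <- sample(DRUG_LABELS$decrease, sum(dec), replace = TRUE)
    out[inc] <- sample(DRUG_LABELS$increase, sum(inc), replace = TRUE)
    out[code == 0] <- DRUG_LABELS$undirected
    out
  }

  rows <- vector("list", n_drugs)
  for (d in seq_len(n_drugs)) {
    if (d <= n_enr) {
      g <- sample(sig_genes, config$enriched_genes_per_drug)
      code <- -sign(sig_z[g])              # oppose the risk direction
      n_extra <- stats::rpois(1, max(config$genes_per_drug_mean - 2, 0))
      extra <- sample(setdiff(genes, g), min(n_extra, length(genes) - length(g)))
      code_extra <- ifelse(stats::runif(length(extra)) < config$undirected_frac,
                           0, sample(c(-1, 1), length(extra), replace = TRUE))
      g <- c(g, extra); code <- c(code, code_extra)
    } else {
      k <- 2 + stats::rpois(1, max(config$genes_per_drug_mean - 2, 0))
      g <- sample(genes, min(k, length(genes)))
      code <- ifelse(stats::runif(length(g)) < config$undirected_frac,
                     0, sample(c(-1, 1), length(g), replace = TRUE))
    }
    rows[[d]] <- data.frame(drug_id = drug_id[d], gene_id = g,
                            label = pick_label(code, length(g)),
                            atc3 = atc[d], stringsAsFactors = FALSE)
  }
  interactions <- do.call(rbind, rows)
  rownames(interactions) <- NULL
  list(interactions = interactions,
       atc_map = data.frame(drug_id = drug_id, atc3 = atc,
                            stringsAsFactors = FALSE),
       truth = list(enriched_drugs = drug_id[seq_len(n_enr)],
                    enriched_class = if (n_enr > 0) enriched_class else NA))
}
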