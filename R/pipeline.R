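#' Subset a count matrix to one time point
#'
#' @param cm a [count_matrix()] with time labels.
#' @param time time label to keep (e.g. `"6wk"`).
#' @return A single-factor [count_matrix()] (time label dropped).
#' @export
subset_time <- function(cm, time) {
  stopifnot(!is.null(cm$time))
  keep <- cm$time == time
  if (!any(keep)) stop("no samples at time ", time)
  count_matrix(cm$counts[, keep, drop = FALSE], cm$condition[keep])
}

#' Master-regulator inference from a contextualized network
#'
#' The inference chain shared by both conditions: upstream neighborhood of
#' the differentially expressed genes, iterative minimal-out-degree pruning
#' of the neighborhood, and candidate validation by mutual regulation plus
#' physical interaction.
#'
#' @param network a contextualized [grn()].
#' @param de_genes character vector of DE gene ids (seeds).
#' @param ppi a [ppi_set()].
#' @param depth upstream depth (default 2).
#' @param rule validation rule (see [validate_mrs()]).
#' @param min_core_size pruning guard (see [densest_core()]).
#' @return An `mr_report`.
#' @export
infer_mrs <- function(network, de_genes, ppi, depth = 2L, rule = "both",
                      min_core_size = 2L) {
  nbh <- upstream_neighborhood(network, de_genes, depth = depth)
  core <- densest_core(nbh, min_core_size = min_core_size)
  validate_mrs(core$core, nbh, ppi, rule = rule, trace = core$trace,
               seed_genes = attr(nbh, "seed_genes"))
}

#' Simulate a study and run the full master-regulator pipeline
#'
#' One end-to-end run at a single time point: simulate annotation, network
#' and counts; call differential expression (NB Wald, BH-adjusted); define
#' expressed genes per condition; contextualize the general network for the
#' requested condition; and infer validated master regulators from the
#' upstream neighborhood of the DE genes.
#'
#' @param config a [sim_config()].
#' @param time time point analyzed (default `"6wk"`).
#' @param condition condition whose expressed-TF filter builds the network
#'   (default `"mutant"`).
#' @param alpha DE significance level (BH-adjusted), default 0.05.
#' @param depth,rule,min_core_size passed to [infer_mrs()].
#' @return A list: `sim` (the simulated study), `de` (DE table), `de_genes`,
#'   `network` (contextualized), `report` (an `mr_report`).
#' @export
run_mr_pipeline <- function(config = sim_config(), time = "6wk",
                            condition = "mutant", alpha = 0.05,
                            depth = 2L, rule = "both", min_core_size = 2L) {
  sim <- simulate_study(config)
  cm <- subset_time(sim$counts$genes, time)
  de <- nb_test(cm, diff_config(alpha = alpha, use_adjusted = TRUE))
  de_genes <- de$feature_id[de$status != "ns"]
  expressed <- expressed_genes(cm, condition = condition,
                               threshold = config$expressed_threshold)
  net <- contextualize(sim$network, expressed)
  net <- annotate_network(net, de = de)
  report <- infer_mrs(net, de_genes, sim$ppi, depth = depth, rule = rule,
                      min_core_size = min_core_size)
  list(sim = sim, de = de, de_genes = de_genes, network = net, report = report)
}

#' Contrast master regulators between control and mutant networks
#'
#' Simulates one study, calls DE once, builds a condition-specific network
#' for each condition from its own expressed-gene set, infers master
#' regulators in each, and contrasts the validated sets.
#'
#' @inheritParams run_mr_pipeline
#' @return A list: `sim`, `de_genes`, `reports` (per condition) and
#'   `contrast` (from [mr_condition_contrast()]).
#' @export
run_mr_contrast <- function(config = sim_config(), time = "6wk", alpha = 0.05,
                            depth = 2L, rule = "both", min_core_size = 2L) {
  sim <- simulate_study(config)
  cm <- subset_time(sim$counts$genes, time)
  de <- nb_test(cm, diff_config(alpha = alpha, use_adjusted = TRUE))
  de_genes <- de$feature_id[de$status != "ns"]
  reports <- lapply(c(control = "control", mutant = "mutant"), function(cond) {
    expressed <- expressed_genes(cm, condition = cond,
                                 threshold = config$expressed_threshold)
    net <- contextualize(sim$network, expressed)
    infer_mrs(net, de_genes, sim$ppi, depth = depth, rule = rule,
              min_core_size = min_core_size)
  })
  list(sim = sim, de_genes = de_genes, reports = reports,
       contrast = mr_condition_contrast(reports$control, reports$mutant))
}
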