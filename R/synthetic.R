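#' Configuration for the synthetic study generator
#'
#' Defaults describe the study conditions the generator emulates: a small
#' stranded toy genome, negative-binomial counts in a 2 (genotype) x 2 (time)
#' design with three replicates per cell, planted differential expression and
#' acetylation effects that are stronger at the later time point, CRE motif
#' occurrences near a subset of TSSs, and a general regulatory network with a
#' densely inter-regulating TF core whose members physically interact.
#'
#' @param seed integer RNG seed.
#' @param n_genes total genes (TFs included).
#' @param n_tfs number of transcription-factor genes (first `n_tfs` ids).
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @param replicates_per_group replicates per (condition, time) cell.
#' @param baseline_log_mean,baseline_log_sd lognormal parameters of baseline
#'   NB means.
#' @param dispersion NB dispersion alpha (variance `mu + alpha mu^2`).
#' @param de_fraction fraction of genes with a planted genotype effect.
#' @param de_log2fc absolute planted log2 fold change (sign random per gene)
#'   at the later time point.
#' @param effect_ratio_early multiplier on planted effects at the earlier
#'   time point (effects grow with age).
#' @param time_fraction,time_log2fc fraction of genes with a planted
#'   genotype-independent time effect, and its log2 size.
#' @param acetyl_fraction fraction of promoters / planted CRE regions with a
#'   planted acetylation effect.
#' @param acetyl_effect_log2fc absolute planted acetylation log2 fold change.
#' @param core_size,core_density,core_out_fanout planted TF core: number of
#'   members, probability of each directed edge within the core, and number
#'   of peripheral targets each member regulates.
#' @param de_targets_per_core_tf planted DE genes drawn from each core
#'   member's targets (keeps the core upstream of the DE set).
#' @param n_blockers,blocker_out peripheral regulators wired only into
#'   planted DE genes; they keep the pruning from eroding the core.
#' @param periph_max_out out-degree bound for other peripheral TFs.
#' @param n_silent_tfs peripheral TFs silenced in all samples (exercises the
#'   expression filter).
#' @param mutant_only_mr silence one core TF in control samples only, so it
#'   validates as a master regulator only in the mutant network.
#' @param cre_gene_fraction fraction of genes given planted CRE motifs within
#'   3 kb of their TSS.
#' @param motif_rate background motif occurrences per kb of genome.
#' @param library_size_sd lognormal sd of per-sample library-size multipliers.
#' @param expressed_threshold mean normalized count at or above which a gene
#'   counts as expressed.
#' @param tf_min_mean floor on TF baseline means (regulatory state of
#'   non-silenced TFs is stable above the expression cutoff).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 220L, n_tfs = 20L,
                       chrom_sizes = c(chr1 = 3e6, chr2 = 3e6),
                       replicates_per_group = 3L,
                       baseline_log_mean = log(100), baseline_log_sd = 1,
                       dispersion = 0.1,
                       de_fraction = 0.1, de_log2fc = 2, effect_ratio_early = 0.5,
                       time_fraction = 0.2, time_log2fc = 1,
                       acetyl_fraction = 0.1, acetyl_effect_log2fc = 1.5,
                       core_size = 6L, core_density = 1, core_out_fanout = 20L,
                       de_targets_per_core_tf = 3L,
                       n_blockers = 3L, blocker_out = 2L, periph_max_out = 3L,
                       n_silent_tfs = 2L, mutant_only_mr = FALSE,
                       cre_gene_fraction = 0.3, motif_rate = 0.05,
                       library_size_sd = 0.2, expressed_threshold = 10,
                       tf_min_mean = 40) {
  cfg <- as.list(environment())
  stopifnot(n_genes >= 0, n_tfs >= 0, n_tfs <= n_genes, core_size <= n_tfs,
            replicates_per_group >= 2, dispersion > 0,
            de_fraction >= 0, de_fraction <= 1, core_density > 0, core_density <= 1,
            acetyl_fraction >= 0, acetyl_fraction <= 1, all(chrom_sizes > 0),
            motif_rate >= 0)
  class(cfg) <- "sim_config"
  cfg
}

sim_gene_ids <- function(config) {
  if (config$n_genes == 0) return(character())
  ntf <- config$n_tfs
  c(sprintf("TF%03d", seq_len(ntf)),
    sprintf("G%04d", seq_len(config$n_genes - ntf)))
}

#' Simulate a toy genome annotation with CRE motif occurrences
#'
#' Places non-overlapping stranded genes on the configured chromosomes and
#' plants motif occurrences uniformly within +/-2.8 kb of the TSSs of a
#' random gene subset (recorded as truth), plus Poisson background motifs
#' elsewhere.
#'
#' @param config a [sim_config()].
#' @return A list with `annotation` (a [gene_annotation()]), `motifs`
#'   (BED-style `data.frame`: `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`) and `cre_truth` (`data.frame`: `motif_id`, `gene_id`).
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed)
  ids <- sim_gene_ids(config)
  n <- length(ids)
  chroms <- names(config$chrom_sizes)
  empty_motifs <- data.frame(chrom = character(), start = integer(), end = integer(),
                             name = character(), score = numeric(), strand = character(),
                             stringsAsFactors = FALSE)
  ann <- gene_annotation(character(), character(), integer(), integer(), character())
  if (n > 0) {
    assign_chrom <- sort(rep_len(seq_along(chroms), n))
    per <- table(factor(assign_chrom, levels = seq_along(chroms)))
    rows <- list()
    idx <- 1L
    for (ci in seq_along(chroms)) {
      pos <- 5000L
      size <- config$chrom_sizes[[ci]]
      for (j in seq_len(per[ci])) {
        gap <- as.integer(runif(1, 2000, 9000))
        len <- as.integer(runif(1, 1500, 4000))
        start <- pos + gap
        end <- start + len
        if (end + 5000 > size)
          stop("genome too small to place ", n, " genes; enlarge chrom_sizes")
        rows[[idx]] <- data.frame(gene_id = ids[idx], chrom = chroms[ci],
                                  start = start, end = end,
                                  strand = sample(c("+", "-"), 1),
                                  stringsAsFactors = FALSE)
        pos <- end
        idx <- idx + 1L
      }
    }
    ann <- validate_annotation(do.call(rbind, rows))
  }
  # planted motifs near a subset of TSSs
  motifs <- list(); cre_truth <- list()
  if (n > 0 && config$cre_gene_fraction > 0) {
    cre_genes <- sort(sample(ids, max(1L, round(config$cre_gene_fraction * n))))
    tss <- tss_of(ann)
    mi <- 1L
    for (g in cre_genes) {
      for (k in seq_len(sample(1:2, 1))) {
        offset <- sample(-2800:2800, 1)
        mid <- max(unname(tss[g]) + offset, 4L)
        id <- sprintf("cre_p%04d", mi); mi <- mi + 1L
        motifs[[id]] <- data.frame(chrom = ann$chrom[ann$gene_id == g],
                                   start = mid - 4L, end = mid + 4L, name = id,
                                   score = round(runif(1, 8, 20), 3),
                                   strand = sample(c("+", "-"), 1),
                                   stringsAsFactors = FALSE)
        cre_truth[[id]] <- data.frame(motif_id = id, gene_id = g,
                                      stringsAsFactors = FALSE)
      }
    }
  }
  n_bg <- rpois(1, config$motif_rate * sum(config$chrom_sizes) / 1000)
  if (n_bg > 0) {
    bg_chrom <- sample(chroms, n_bg, replace = TRUE)
    bg_start <- vapply(bg_chrom, function(cc)
      as.integer(runif(1, 0, config$chrom_sizes[[cc]] - 10)), integer(1))
    motifs[["bg"]] <- data.frame(chrom = bg_chrom, start = bg_start,
                                 end = bg_start + 8L,
                                 name = sprintf("cre_b%04d", seq_len(n_bg)),
                                 score = round(runif(n_bg, 8, 20), 3),
                                 strand = sample(c("+", "-"), n_bg, replace = TRUE),
                                 stringsAsFactors = FALSE)
  }
  motifs <- if (length(motifs)) do.call(rbind, c(motifs, make.row.names = FALSE)) else empty_motifs
  cre_truth <- if (length(cre_truth)) do.call(rbind, c(cre_truth, make.row.names = FALSE)) else
    data.frame(motif_id = character(), gene_id = character(), stringsAsFactors = FALSE)
  list(annotation = ann, motifs = motifs, cre_truth = cre_truth)
}

#' Simulate a general regulatory network with a planted TF core
#'
#' The first `core_size` TFs form the core: directed edges between distinct
#' members are drawn with probability `core_density` (patched so every member
#' keeps at least one in- and one out-edge within the core), and every
#' unordered core pair is a planted physical interaction. Each core member
#' additionally regulates `core_out_fanout` random non-TF targets, and
#' `de_targets_per_core_tf` of those per member are planted as differentially
#' expressed (topped up with random extra genes to `de_fraction`). Peripheral
#' "blocker" TFs regulate a couple of planted DE genes each and nothing else;
#' remaining peripheral TFs regulate random non-DE targets with bounded
#' out-degree.
#'
#' @param config a [sim_config()].
#' @return A list with `network` (a [grn()]), `ppi` (a [ppi_set()]) and
#'   `truth` (planted core, DE gene table with signed effects, silenced TFs).
#' @export
simulate_grn <- function(config) {
  stopifnot(config$core_size >= 2)
  set.seed(config$seed + 1L)
  ids <- sim_gene_ids(config)
  tfs <- ids[seq_len(config$n_tfs)]
  targets_pool <- setdiff(ids, tfs)
  core <- tfs[seq_len(config$core_size)]
  edges <- list()
  # core mutual regulation
  for (a in core) for (b in core) {
    if (a != b && runif(1) <= config$core_density)
      edges[[length(edges) + 1]] <- c(a, b)
  }
  em <- do.call(rbind, edges)
  for (m in core) {  # patch connectivity of the planted core
    if (!m %in% em[, 2]) { em <- rbind(em, c(sample(setdiff(core, m), 1), m)) }
    if (!m %in% em[, 1]) { em <- rbind(em, c(m, sample(setdiff(core, m), 1))) }
  }
  edges <- lapply(seq_len(nrow(em)), function(i) em[i, ])
  # core fan-out to targets; plant DE genes among them
  de_genes <- character()
  core_targets <- list()
  for (m in core) {
    tg <- sample(targets_pool, min(config$core_out_fanout, length(targets_pool)))
    core_targets[[m]] <- tg
    for (t in tg) edges[[length(edges) + 1]] <- c(m, t)
    de_genes <- union(de_genes, sample(tg, min(config$de_targets_per_core_tf, length(tg))))
  }
  n_de <- round(config$de_fraction * config$n_genes)
  extra_pool <- setdiff(targets_pool, de_genes)
  if (length(de_genes) < n_de && length(extra_pool))
    de_genes <- union(de_genes, sample(extra_pool, min(n_de - length(de_genes),
                                                       length(extra_pool))))
  periph <- setdiff(tfs, core)
  blockers <- utils::head(periph, config$n_blockers)
  for (p in blockers) {
    tg <- sample(de_genes, min(config$blocker_out, length(de_genes)))
    for (t in tg) edges[[length(edges) + 1]] <- c(p, t)
  }
  others <- setdiff(periph, blockers)
  quiet_pool <- setdiff(targets_pool, de_genes)
  for (p in others) {
    k <- sample(seq_len(config$periph_max_out), 1)
    tg <- sample(quiet_pool, min(k, length(quiet_pool)))
    for (t in tg) edges[[length(edges) + 1]] <- c(p, t)
  }
  em <- unique(do.call(rbind, edges))
  edf <- data.frame(tf = em[, 1], target = em[, 2],
                    mode = sample(c("activation", "repression", "unknown"),
                                  nrow(em), replace = TRUE),
                    source = "simdb", stringsAsFactors = FALSE)
  net <- grn(edf)
  pairs <- t(utils::combn(core, 2))
  ppi <- ppi_set(data.frame(a = pairs[, 1], b = pairs[, 2], stringsAsFactors = FALSE))
  silent <- utils::tail(periph, config$n_silent_tfs)
  de_tab <- data.frame(gene_id = sort(de_genes),
                       log2fc = sample(c(-1, 1), length(de_genes), replace = TRUE) *
                         config$de_log2fc,
                       stringsAsFactors = FALSE)
  truth <- list(planted_core = core, de_genes = de_tab,
                planted_ppi = ppi$pairs, silent_tfs = silent,
                mutant_only_mr = if (config$mutant_only_mr) core[1] else character(),
                core_targets = core_targets)
  list(network = net, ppi = ppi, truth = truth)
}

sim_samples <- function(config) {
  reps <- config$replicates_per_group
  grid <- expand.grid(rep = seq_len(reps), time = c("4wk", "6wk"),
                      condition = c("control", "mutant"), stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_%s_%d",
                            ifelse(grid$condition == "control", "ctrl", "mut"),
                            grid$time, grid$rep)
  grid[, c("sample_id", "condition", "time")]
}

nb_counts <- function(mu, dispersion) {
  k <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
              nrow = nrow(mu), dimnames = dimnames(mu))
  storage.mode(k) <- "integer"
  k
}

#' Simulate gene, promoter and CRE-region count matrices
#'
#' Counts are NB(mu, dispersion) with lognormal baseline means, per-sample
#' lognormal library-size multipliers, and log2 means shifted by the planted
#' effects: genotype effects on DE genes (full size at 6wk, scaled by
#' `effect_ratio_early` at 4wk), genotype-independent time effects on a
#' random gene subset, and acetylation effects on planted promoter / CRE
#' features in the mutant. TF baselines are floored at `tf_min_mean` except
#' planted silent TFs (near-zero in all samples) and, when `mutant_only_mr`
#' is set, the first core TF (near-zero in control samples only).
#'
#' @param config a [sim_config()].
#' @param grn_truth `truth` element of [simulate_grn()].
#' @param motifs motif table from [simulate_annotation()] (CRE features are
#'   its planted occurrences; `NULL` for none).
#' @return A list with `genes`, `promoters`, `cre` ([count_matrix()] objects;
#'   `cre` is `NULL` without motifs) and `truth` (planted promoter / CRE
#'   effect tables and the time-effect gene set).
#' @export
simulate_counts <- function(config, grn_truth, motifs = NULL) {
  set.seed(config$seed + 2L)
  ids <- sim_gene_ids(config)
  tfs <- ids[seq_len(config$n_tfs)]
  samples <- sim_samples(config)
  ns <- nrow(samples)
  mutant <- samples$condition == "mutant"
  late <- samples$time == "6wk"

  base <- exp(rnorm(length(ids), config$baseline_log_mean, config$baseline_log_sd))
  names(base) <- ids
  base[tfs] <- pmax(base[tfs], config$tf_min_mean)
  base[grn_truth$silent_tfs] <- 0.5

  lfc <- setNames(rep(0, length(ids)), ids)
  lfc[grn_truth$de_genes$gene_id] <- grn_truth$de_genes$log2fc
  tgenes <- sample(ids, round(config$time_fraction * length(ids)))
  tshift <- setNames(rep(0, length(ids)), ids)
  tshift[tgenes] <- config$time_log2fc

  log2mu <- matrix(log2(base), length(ids), ns, dimnames = list(ids, samples$sample_id))
  eff <- outer(lfc, ifelse(mutant, 1, 0)) *
    matrix(ifelse(late, 1, config$effect_ratio_early), length(ids), ns, byrow = TRUE)
  log2mu <- log2mu + eff + outer(tshift, ifelse(late, 1, 0))
  if (config$mutant_only_mr && length(grn_truth$planted_core)) {
    m1 <- grn_truth$planted_core[1]
    log2mu[m1, !mutant] <- log2(0.5)
  }
  lib <- exp(rnorm(ns, 0, config$library_size_sd))
  mu <- sweep(2^log2mu, 2, lib, `*`)
  genes_cm <- count_matrix(nb_counts(mu, config$dispersion),
                           samples$condition, samples$time)

  # promoter acetylation counts, one feature per gene
  pr_base <- exp(rnorm(length(ids), config$baseline_log_mean, config$baseline_log_sd))
  n_acetyl <- round(config$acetyl_fraction * length(ids))
  prom_de <- if (n_acetyl > 0) sample(ids, n_acetyl) else character()
  pr_lfc <- setNames(rep(0, length(ids)), ids)
  pr_lfc[prom_de] <- sample(c(-1, 1), length(prom_de), replace = TRUE) *
    config$acetyl_effect_log2fc
  pr_log2mu <- matrix(log2(pr_base), length(ids), ns,
                      dimnames = list(ids, samples$sample_id)) +
    outer(pr_lfc, ifelse(mutant, 1, 0)) *
    matrix(ifelse(late, 1, config$effect_ratio_early), length(ids), ns, byrow = TRUE)
  pr_lib <- exp(rnorm(ns, 0, config$library_size_sd))
  prom_cm <- count_matrix(nb_counts(sweep(2^pr_log2mu, 2, pr_lib, `*`), config$dispersion),
                          samples$condition, samples$time)

  # CRE-region acetylation counts, one feature per motif occurrence
  cre_cm <- NULL
  cre_de_tab <- data.frame(feature_id = character(), log2fc = numeric(),
                           stringsAsFactors = FALSE)
  if (!is.null(motifs) && nrow(motifs) > 0) {
    mid <- motifs$name
    cr_base <- exp(rnorm(length(mid), config$baseline_log_mean, config$baseline_log_sd))
    planted <- grep("^cre_p", mid, value = TRUE)
    n_cre_de <- round(config$acetyl_fraction * length(mid))
    cre_de <- if (length(planted) && n_cre_de > 0)
      sample(planted, min(n_cre_de, length(planted))) else character()
    cr_lfc <- setNames(rep(0, length(mid)), mid)
    cr_lfc[cre_de] <- sample(c(-1, 1), length(cre_de), replace = TRUE) *
      config$acetyl_effect_log2fc
    cr_log2mu <- matrix(log2(cr_base), length(mid), ns,
                        dimnames = list(mid, samples$sample_id)) +
      outer(unname(cr_lfc), ifelse(mutant, 1, 0)) *
      matrix(ifelse(late, 1, config$effect_ratio_early), length(mid), ns, byrow = TRUE)
    cr_lib <- exp(rnorm(ns, 0, config$library_size_sd))
    cre_cm <- count_matrix(nb_counts(sweep(2^cr_log2mu, 2, cr_lib, `*`), config$dispersion),
                           samples$condition, samples$time)
    cre_de_tab <- data.frame(feature_id = cre_de,
                             log2fc = unname(cr_lfc[cre_de]),
                             stringsAsFactors = FALSE)
  }
  truth <- list(diff_acetyl_promoters = data.frame(feature_id = prom_de,
                                                   log2fc = unname(pr_lfc[prom_de]),
                                                   stringsAsFactors = FALSE),
                diff_acetyl_cres = cre_de_tab,
                time_effect_genes = sort(tgenes))
  list(genes = genes_cm, promoters = prom_cm, cre = cre_cm, truth = truth)
}

#' Simulate a complete synthetic study in memory
#'
#' Runs [simulate_annotation()], [simulate_grn()] and [simulate_counts()]
#' under the configured seed and assembles the combined ground truth.
#'
#' @param config a [sim_config()].
#' @return A list: `annotation`, `motifs`, `network`, `ppi`, `counts`
#'   (list of [count_matrix()]), `truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  anno <- simulate_annotation(config)
  g <- simulate_grn(config)
  cts <- simulate_counts(config, g$truth, anno$motifs)
  truth <- c(g$truth, cts$truth, list(cre_gene_map = anno$cre_truth))
  list(annotation = anno$annotation, motifs = anno$motifs,
       network = g$network, ppi = g$ppi,
       counts = list(genes = cts$genes, promoters = cts$promoters, cre = cts$cre),
       truth = truth)
}

#' Write a complete synthetic study to a directory
#'
#' Emits `genes.gtf`, `motifs.bed`, `counts_genes.tsv`, `counts_promoters.tsv`,
#' `counts_cre.tsv`, `samples.tsv`, `grn.tsv`, `ppi.tsv` and `truth.json`.
#' Outputs are byte-identical across runs with the same configuration.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return The [simulate_study()] object, invisibly.
#' @export
write_synthetic_study <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_study(config)
  p <- function(f) file.path(outdir, f)
  if (nrow(sim$annotation)) {
    gr <- GenomicRanges::GRanges(sim$annotation$chrom,
                                 IRanges::IRanges(sim$annotation$start + 1L,
                                                  sim$annotation$end),
                                 strand = sim$annotation$strand)
    mcols(gr)$source <- "regucircuit"
    mcols(gr)$type <- "gene"
    mcols(gr)$gene_id <- sim$annotation$gene_id
    rtracklayer::export(gr, p("genes.gtf"), format = "gtf")
  } else writeLines(character(), p("genes.gtf"))
  write_bed(sim$motifs, p("motifs.bed"))
  write_counts(sim$counts$genes, p("counts_genes.tsv"), p("samples.tsv"))
  write_counts(sim$counts$promoters, p("counts_promoters.tsv"))
  if (!is.null(sim$counts$cre)) write_counts(sim$counts$cre, p("counts_cre.tsv"))
  write_grn(sim$network, p("grn.tsv"))
  write.table(sim$ppi$pairs, p("ppi.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(sim)
}
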