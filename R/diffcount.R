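#' Construct a count matrix with sample annotations
#'
#' Container for integer feature-by-sample counts with per-sample condition
#' labels (`control`/`mutant`) and optional time labels (e.g. `4wk`/`6wk`)
#' for the genotype-by-time design.
#'
#' @param counts integer matrix, features x samples, with rownames
#'   (feature ids) and colnames (sample ids).
#' @param condition character/factor of length `ncol(counts)`.
#' @param time optional character/factor of length `ncol(counts)`.
#' @return A list of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition, time = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have feature ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  if (length(condition) != ncol(counts)) stop("one condition label per sample required")
  condition <- as.character(condition)
  if (!all(condition %in% c("control", "mutant")))
    stop("condition labels must be 'control' or 'mutant'")
  if (!is.null(time)) {
    if (length(time) != ncol(counts)) stop("one time label per sample required")
    time <- as.character(time)
  }
  structure(list(counts = counts, condition = condition, time = time),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts), "samples\n")
  cat("  condition:", paste(sprintf("%s=%d", names(table(x$condition)), table(x$condition)),
                            collapse = ", "), "\n")
  if (!is.null(x$time))
    cat("  time:", paste(sprintf("%s=%d", names(table(x$time)), table(x$time)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Configuration for differential count tests
#'
#' @param alpha significance threshold in (0, 1); default 0.05.
#' @param use_adjusted call significance on Benjamini-Hochberg adjusted
#'   p-values (`TRUE`, the expression default) or on raw p-values (`FALSE`,
#'   the acetylation default, "p-value < 0.05").
#' @param min_dispersion hard lower floor for dispersion estimates.
#' @param common_floor additionally floor each feature's dispersion at the
#'   across-feature median of raw moment estimates. Small designs (3 vs 3)
#'   need this for a calibrated Wald test; see the methods vignette.
#' @param interaction include a genotype:time interaction in the two-factor
#'   design (default `FALSE`: additive genotype + time).
#' @return A list of class `diff_config`.
#' @export
diff_config <- function(alpha = 0.05, use_adjusted = TRUE, min_dispersion = 1e-8,
                        common_floor = TRUE, interaction = FALSE) {
  stopifnot(alpha > 0, alpha < 1, min_dispersion > 0)
  structure(list(alpha = alpha, use_adjusted = use_adjusted,
                 min_dispersion = min_dispersion, common_floor = common_floor,
                 interaction = interaction),
            class = "diff_config")
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants for sequencing depth: for each sample,
#' the median over features of the ratio of its count to the feature's
#' geometric mean across samples, computed over features with all-positive
#' counts.
#'
#' @param cm a [count_matrix()] or a plain counts matrix.
#' @return Positive numeric vector named by sample id.
#' @export
size_factors <- function(cm) {
  k <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  logk <- log(k)
  loggeo <- rowMeans(logk)
  ok <- is.finite(loggeo)
  if (!any(ok))
    stop("no feature has positive counts in every sample; ",
         "size factors need at least one all-positive feature ",
         "(consider filtering or a pseudo-reference)")
  ratios <- exp(sweep(logk[ok, , drop = FALSE], 1, loggeo[ok], `-`))
  sf <- apply(ratios, 2, median)
  if (any(sf <= 0)) stop("nonpositive size factor estimated")
  sf
}

# residual-based moment estimate of NB dispersion, pooled within groups
raw_dispersion_mom <- function(counts, sf, group) {
  q <- sweep(counts, 2, sf, `/`)
  group <- as.factor(group)
  gidx <- as.integer(group)
  ng <- nlevels(group)
  n <- ncol(counts)
  if (n - ng <= 0) stop("dispersion estimation needs replicates within groups")
  means <- vapply(seq_len(ng), function(g) rowMeans(q[, gidx == g, drop = FALSE]),
                  numeric(nrow(counts)))
  fitted <- means[, gidx, drop = FALSE]
  s2 <- rowSums((q - fitted)^2) / (n - ng)
  mbar <- rowMeans(fitted)
  xim <- mean(1 / sf)
  (s2 - xim * mbar) / mbar^2
}

#' Per-feature NB dispersion (method of moments)
#'
#' Moment estimator on normalized counts pooled within groups:
#' `alpha = (s2 - mean(1/sf) * mu) / mu^2`, floored at `min_dispersion`.
#' Features with zero mean get the floor.
#'
#' @param cm a [count_matrix()].
#' @param sf size factors from [size_factors()].
#' @param group grouping factor (defaults to condition, or condition:time
#'   when time labels are present).
#' @param min_dispersion lower floor (default 1e-8).
#' @return Nonnegative numeric vector named by feature id.
#' @export
estimate_dispersion <- function(cm, sf = size_factors(cm), group = NULL,
                                min_dispersion = 1e-8) {
  if (is.null(group))
    group <- if (is.null(cm$time)) cm$condition else paste(cm$condition, cm$time)
  raw <- raw_dispersion_mom(cm$counts, sf, group)
  d <- pmax(raw, min_dispersion)
  d[!is.finite(d)] <- min_dispersion
  setNames(d, rownames(cm$counts))
}

# Wald test of the mutant-vs-control coefficient in a per-feature NB GLM
# (log link, size factors as offsets, dispersion fixed at its estimate).
nb_wald_fit <- function(y, X, coef_idx, offset, dispersion) {
  fam <- MASS::negative.binomial(theta = 1 / dispersion, link = "log")
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = fam, offset = offset,
                                    control = stats::glm.control(maxit = 50))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged && anyNA(fit$coefficients))
    return(c(est = NA_real_, z = NA_real_))
  p <- fit$rank
  if (p < ncol(X) || anyNA(fit$coefficients)) return(c(est = NA_real_, z = NA_real_))
  # (X' W X)^-1 from the final IRLS decomposition, dispersion fixed at 1
  covmat <- tryCatch(chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]),
                     error = function(e) NULL)
  if (is.null(covmat)) return(c(est = NA_real_, z = NA_real_))
  se <- sqrt(diag(covmat))[coef_idx]
  est <- fit$coefficients[coef_idx]
  c(est = unname(est), z = unname(est / se))
}

diff_result_table <- function(feature_id, base_mean, log2fc, p, config) {
  p_adj <- rep(1, length(p))
  tested <- !is.na(p)
  p_adj[tested] <- p.adjust(p[tested], method = "BH")
  p_out <- ifelse(tested, p, 1)
  crit <- if (config$use_adjusted) p_adj else p_out
  status <- rep("ns", length(p))
  status[tested & crit < config$alpha & log2fc > 0] <- "up"
  status[tested & crit < config$alpha & log2fc < 0] <- "down"
  data.frame(feature_id = feature_id, base_mean = base_mean, log2fc = log2fc,
             p_value = p_out, p_adjusted = pmax(p_adj, p_out), status = status,
             stringsAsFactors = FALSE)
}

nb_test_engine <- function(cm, config, design, group) {
  k <- cm$counts
  n_cond <- table(cm$condition)
  if (length(n_cond) < 2 || any(n_cond < 2))
    stop("need at least 2 replicates in each condition")
  sf <- size_factors(cm)
  raw <- raw_dispersion_mom(k, sf, group)
  disp <- pmax(raw, config$min_dispersion)
  disp[!is.finite(disp)] <- config$min_dispersion
  if (config$common_floor) {
    common <- median(raw[is.finite(raw)])
    if (is.finite(common) && common > config$min_dispersion) disp <- pmax(disp, common)
  }
  q <- sweep(k, 2, sf, `/`)
  base_mean <- rowMeans(q)
  m_ctl <- rowMeans(q[, cm$condition == "control", drop = FALSE])
  m_mut <- rowMeans(q[, cm$condition == "mutant", drop = FALSE])
  design_df <- data.frame(condition = factor(cm$condition, levels = c("control", "mutant")))
  if (!is.null(cm$time)) design_df$time <- factor(cm$time)
  X <- stats::model.matrix(design, design_df)
  coef_idx <- match("conditionmutant", colnames(X))
  offset <- log(sf)
  nonzero <- rowSums(k) > 0
  est <- z <- rep(NA_real_, nrow(k))
  for (i in which(nonzero)) {
    r <- nb_wald_fit(k[i, ], X, coef_idx, offset, disp[i])
    est[i] <- r["est"]; z[i] <- r["z"]
  }
  p <- 2 * pnorm(-abs(z))
  log2fc <- est / log(2)
  # pseudo-count fallback for reporting when a group mean is zero or the fit failed
  fallback <- nonzero & (!is.finite(log2fc) | pmin(m_ctl, m_mut) == 0)
  log2fc[fallback] <- log2((m_mut[fallback] + 0.5) / (m_ctl[fallback] + 0.5))
  log2fc[!nonzero] <- 0
  diff_result_table(rownames(k), base_mean, log2fc, p, config)
}

#' Negative-binomial Wald test, single-factor design
#'
#' Per-feature NB GLM (log link) of counts on condition with median-of-ratios
#' size factors as offsets; Wald test of the mutant-vs-control coefficient;
#' Benjamini-Hochberg adjustment across tested features. Features with
#' all-zero counts are excluded from testing and reported `ns` with p = 1.
#'
#' @param cm a [count_matrix()].
#' @param config a [diff_config()].
#' @return `data.frame` with columns `feature_id`, `base_mean`, `log2fc`
#'   (log2 mutant/control), `p_value`, `p_adjusted`, `status`
#'   (`up`/`down`/`ns`).
#' @export
nb_test <- function(cm, config = diff_config()) {
  nb_test_engine(cm, config, ~condition, group = cm$condition)
}

#' Negative-binomial Wald test, two-factor (genotype x time) design
#'
#' NB GLM with additive genotype + time design (optionally with interaction);
#' Wald test of the genotype (mutant-vs-control) coefficient. Dispersions are
#' pooled within (condition, time) cells.
#'
#' @inheritParams nb_test
#' @return As [nb_test()].
#' @export
nb_test_two_factor <- function(cm, config = diff_config()) {
  if (is.null(cm$time)) stop("two-factor design requires time labels")
  cells <- table(cm$condition, cm$time)
  if (any(cells < 2))
    stop("two-factor design requires >= 2 replicates per (condition, time) cell")
  f <- if (isTRUE(config$interaction)) ~ condition * time else ~ condition + time
  nb_test_engine(cm, config, f, group = paste(cm$condition, cm$time))
}

#' Read a count table with its sample sheet
#'
#' Count table: TSV with feature ids in the first column and one column per
#' sample. Sample sheet: TSV with columns `sample_id`, `condition` and
#' optionally `time`.
#'
#' @param counts_path,samples_path file paths.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, samples_path) {
  tab <- read.table(counts_path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  k <- as.matrix(tab[, -1, drop = FALSE])
  rownames(k) <- tab[[1]]
  sheet <- read.table(samples_path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(colnames(k) %in% sheet$sample_id))
    stop("sample sheet missing samples: ",
         paste(setdiff(colnames(k), sheet$sample_id), collapse = ", "))
  sheet <- sheet[match(colnames(k), sheet$sample_id), ]
  count_matrix(k, sheet$condition, if ("time" %in% names(sheet)) sheet$time else NULL)
}

#' Write a count matrix and its sample sheet
#'
#' @param cm a [count_matrix()].
#' @param counts_path,samples_path output file paths.
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(cm, counts_path, samples_path = NULL) {
  tab <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samples_path)) {
    sheet <- data.frame(sample_id = colnames(cm$counts), condition = cm$condition,
                        stringsAsFactors = FALSE)
    if (!is.null(cm$time)) sheet$time <- cm$time
    write.table(sheet, samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(counts_path)
}
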