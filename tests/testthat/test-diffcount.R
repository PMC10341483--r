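make_cm <- function(k, cond, time = NULL) {
  if (is.null(dimnames(k)))
    dimnames(k) <- list(paste0("f", seq_len(nrow(k))), paste0("s", seq_len(ncol(k))))
  count_matrix(k, cond, time)
}

test_that("size factors: symmetry, exact scaling, and the literal definition", {
  k <- matrix(rep(c(5L, 10L, 50L), 3), 3, 3,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:3)))
  expect_equal(unname(size_factors(k)), c(1, 1, 1))

  # sample2 = 2 x sample1: geometric-mean reference gives (1/sqrt2, sqrt2)
  k2 <- cbind(a = c(10L, 20L, 30L, 40L), b = c(20L, 40L, 60L, 80L))
  rownames(k2) <- paste0("f", 1:4)
  expect_equal(unname(size_factors(k2)), c(1 / sqrt(2), sqrt(2)))

  set.seed(21)
  k3 <- matrix(rnbinom(200, mu = 50, size = 5), 50, 4,
               dimnames = list(paste0("f", 1:50), paste0("s", 1:4)))
  expect_equal(unname(size_factors(k3)), unname(oracle_size_factors(k3)),
               tolerance = 1e-12)

  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2, 2,
                                   dimnames = list(c("f1", "f2"), c("a", "b")))),
               "all-positive|positive counts")
})

test_that("count_matrix validates its invariants", {
  k <- matrix(1:4, 2, 2, dimnames = list(c("f1", "f2"), c("a", "b")))
  expect_error(count_matrix(k, c("control", "case")), "condition")
  expect_error(count_matrix(k - 3L, c("control", "mutant")), "nonnegative")
  expect_error(count_matrix(k, "control"), "one condition label per sample")
})

test_that("dispersion estimates floor under Poisson data and recover NB alpha", {
  set.seed(5)
  k <- matrix(rpois(2000 * 6, 100), 2000, 6)
  cm <- make_cm(k, rep(c("control", "mutant"), each = 3))
  d <- estimate_dispersion(cm)
  expect_gte(mean(d <= 1e-8), 0.5)  # at least half floored when truth is 0

  k2 <- matrix(rnbinom(2000 * 40, mu = 100, size = 5), 2000, 40)
  cm2 <- make_cm(k2, rep(c("control", "mutant"), each = 20))
  d2 <- estimate_dispersion(cm2)
  expect_gt(median(d2), 0.1)
  expect_lt(median(d2), 0.3)

  # constant feature after normalization sits at the floor
  k3 <- matrix(7L, 5, 4)
  cm3 <- make_cm(k3, rep(c("control", "mutant"), each = 2))
  expect_true(all(estimate_dispersion(cm3) == 1e-8))
})

test_that("nb_test handles degenerate features and enforces replication", {
  set.seed(8)
  # constant rows keep all size factors at exactly 1
  k <- matrix(rep(sample(10:200, 40), 6), 40, 6)
  k[1, ] <- 25L           # identical counts in every sample
  k[2, ] <- 0L            # all-zero feature
  cm <- make_cm(k, rep(c("control", "mutant"), each = 3))
  expect_equal(unname(size_factors(cm)), rep(1, 6))
  res <- nb_test(cm)
  expect_equal(res$log2fc[1], 0, tolerance = 1e-9)
  expect_equal(res$status[1], "ns")
  expect_equal(res$p_value[2], 1)
  expect_equal(res$status[2], "ns")
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_error(nb_test(make_cm(k[, c(1, 4)], c("control", "mutant"))),
               "2 replicates")
})

test_that("status calls are consistent with threshold, sign and adjustment mode", {
  set.seed(9)
  k <- matrix(rnbinom(300 * 6, mu = 80, size = 10), 300, 6)
  k[1:20, 4:6] <- matrix(rnbinom(20 * 3, mu = 80 * 8, size = 10), 20, 3)
  cm <- make_cm(k, rep(c("control", "mutant"), each = 3))
  res <- nb_test(cm, diff_config(alpha = 0.05, use_adjusted = TRUE))
  sig <- res$p_adjusted < 0.05
  expect_true(all(res$status[sig & res$log2fc > 0] == "up"))
  expect_true(all(res$status[sig & res$log2fc < 0] == "down"))
  expect_true(all(res$status[!sig] == "ns"))
  expect_gt(sum(res$status[1:20] == "up"), 15)  # planted 8-fold increases

  raw <- nb_test(cm, diff_config(alpha = 0.05, use_adjusted = FALSE))
  expect_true(all(raw$status[raw$p_value < 0.05 & raw$log2fc > 0] == "up"))
  expect_gte(sum(raw$status != "ns"), sum(res$status != "ns"))
})

test_that("BH adjustment is monotone in p-value rank", {
  set.seed(10)
  k <- matrix(rnbinom(200 * 6, mu = 50, size = 8), 200, 6)
  res <- nb_test(make_cm(k, rep(c("control", "mutant"), each = 3)))
  o <- order(res$p_value)
  expect_true(all(diff(res$p_adjusted[o]) >= -1e-12))
})

test_that("swapping condition labels flips log2fc and preserves p-values", {
  set.seed(12)
  k <- matrix(rnbinom(150 * 6, mu = 70, size = 6), 150, 6)
  k[1:10, 4:6] <- matrix(rnbinom(30, mu = 280, size = 6), 10, 3)
  cond <- rep(c("control", "mutant"), each = 3)
  a <- nb_test(make_cm(k, cond))
  b <- nb_test(make_cm(k, rev(cond)))
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-9)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
})

test_that("integer rescaling of one sample rescales its factor, not the fold changes", {
  set.seed(14)
  k <- matrix(rnbinom(300 * 6, mu = 90, size = 8) + 1L, 300, 6)
  cm <- make_cm(k, rep(c("control", "mutant"), each = 3))
  k2 <- k; k2[, 3] <- 4L * k2[, 3]
  cm2 <- make_cm(k2, cm$condition)
  sf1 <- size_factors(cm); sf2 <- size_factors(cm2)
  # geometric-mean reference: factor of the scaled sample rises by c relative
  # to every other sample's factor
  rel1 <- sf1[3] / sf1[-3]; rel2 <- sf2[3] / sf2[-3]
  expect_equal(unname(rel2 / rel1), rep(4, 5), tolerance = 1e-9)
  # normalized counts all scale by the same c^(1/n) constant
  expect_equal(sweep(k2, 2, sf2, `/`) / sweep(k, 2, sf1, `/`),
               matrix(4^(1 / 6), 300, 6), tolerance = 1e-9, ignore_attr = TRUE)
  # normalization absorbs depth: fold changes robust to the rescaling
  r1 <- nb_test(cm); r2 <- nb_test(cm2)
  expect_equal(r1$log2fc, r2$log2fc, tolerance = 0.05)
  expect_gt(cor(r1$log2fc, r2$log2fc), 0.999)
  expect_equal(mean(abs(r1$log2fc - r2$log2fc)), 0, tolerance = 0.01)
})

test_that("two-factor design tests genotype with a time covariate", {
  set.seed(15)
  nfeat <- 300
  cond <- rep(c("control", "mutant"), each = 6)
  tm <- rep(rep(c("4wk", "6wk"), each = 3), 2)
  mu <- matrix(100, nfeat, 12)
  mu[, tm == "6wk"] <- mu[, tm == "6wk"] * 2        # time effect everywhere
  mu[1:30, cond == "mutant"] <- mu[1:30, cond == "mutant"] * 4
  k <- matrix(rnbinom(nfeat * 12, mu = mu, size = 10), nfeat, 12)
  cm <- make_cm(k, cond, tm)
  res <- nb_test_two_factor(cm)
  expect_gt(sum(res$status[1:30] != "ns"), 24)
  expect_lt(mean(res$status[31:nfeat] != "ns"), 0.1)

  k0 <- matrix(0L, 3, 12); k0[2:3, ] <- matrix(rnbinom(24, mu = 50, size = 10), 2, 12)
  r0 <- nb_test_two_factor(make_cm(k0, cond, tm))
  expect_equal(r0$status[1], "ns")
  expect_equal(r0$p_value[1], 1)

  expect_error(nb_test_two_factor(make_cm(k[, 1:9], cond[1:9], tm[1:9])),
               "cell")
  expect_error(nb_test_two_factor(make_cm(k[, 1:6], cond[1:6])), "time labels")
})

test_that("count tables round-trip through TSV with their sample sheet", {
  set.seed(16)
  k <- matrix(rnbinom(60, mu = 30, size = 5), 10, 6)
  cm <- make_cm(k, rep(c("control", "mutant"), each = 3),
                rep(c("4wk", "6wk", "4wk"), 2))
  cp <- tempfile(fileext = ".tsv"); sp <- tempfile(fileext = ".tsv")
  write_counts(cm, cp, sp)
  back <- read_counts(cp, sp)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$condition, cm$condition)
  expect_equal(back$time, cm$time)
})

test_that("fold-change and p-value agree with an established NB pipeline", {
  skip_if_not_installed("DESeq2")
  set.seed(17)
  nfeat <- 200
  mu <- matrix(100, nfeat, 6)
  mu[1:20, 4:6] <- 400
  k <- matrix(rnbinom(nfeat * 6, mu = mu, size = 1 / 0.05), nfeat, 6,
              dimnames = list(paste0("f", 1:nfeat), paste0("s", 1:6)))
  cond <- rep(c("control", "mutant"), each = 3)
  mine <- nb_test(make_cm(k, cond))
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(k, data.frame(condition = factor(cond)),
                                          ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- as.data.frame(DESeq2::results(dds))
  })
  expect_equal(unname(size_factors(k)), unname(DESeq2::sizeFactors(dds)),
               tolerance = 1e-6)
  ok <- is.finite(ref$log2FoldChange) & is.finite(mine$log2fc)
  expect_gt(cor(mine$log2fc[ok], ref$log2FoldChange[ok]), 0.95)
  expect_gt(cor(-log10(mine$p_value + 1e-12), -log10(ref$pvalue + 1e-12),
                use = "complete.obs", method = "spearman"), 0.8)
  expect_gt(sum(mine$status[1:20] == "up"), 15)
})
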