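# Every statistic is checked against an independent brute-force evaluation of
# its defining formula, written out locally in this file.

brute_cmc_radicand <- function(w) {
  M <- nrow(w); Tn <- ncol(w)
  num <- 0
  for (t in seq_len(Tn)) {
    yb <- mean(w[, t])
    for (m in seq_len(M)) num <- num + (w[m, t] - yb)^2
  }
  num <- num / (Tn * (M - 1))
  den <- 0; g <- mean(w)
  for (t in seq_len(Tn)) for (m in seq_len(M)) den <- den + (w[m, t] - g)^2
  den <- den / (M * Tn - 1)
  1 - num / den
}

brute_icc2k <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  msr <- k * sum((rowMeans(m) - g)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - g)^2) / (k - 1)
  mse <- (sum((m - g)^2) - k * sum((rowMeans(m) - g)^2) -
            n * sum((colMeans(m) - g)^2)) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (msc - mse) / n)
}

test_that("rmse_waveform matches its definition", {
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  expect_equal(rmse_waveform(a, b), 0)
  expect_equal(rmse_waveform(a, a + 3), 3)
  set.seed(1)
  x <- rnorm(101); y <- rnorm(101)
  expect_equal(rmse_waveform(x, y), sqrt(mean((x - y)^2)))
  expect_error(rmse_waveform(1:3, 1:4), "length")
})

test_that("cmc matches brute-force evaluation on random matrices", {
  set.seed(2)
  for (i in 1:100) {
    M <- sample(2:6, 1); Tn <- sample(4:9, 1)
    w <- matrix(rnorm(M * Tn, 10, 4), M, Tn) +
      outer(rep(1, M), 5 * sin(seq_len(Tn)))
    r <- cmc(w)
    rad <- brute_cmc_radicand(w)
    expect_equal(r$radicand, rad, tolerance = 1e-9)
    if (rad >= 0) expect_equal(r$value, sqrt(rad), tolerance = 1e-9)
    else expect_identical(r$label, "<0.001")
  }
})

test_that("cmc edge behavior: identical, constant-offset, degenerate", {
  w <- rbind(sin(1:10), sin(1:10))
  expect_equal(cmc(w)$value, 1)
  # two constant waveforms at different offsets: negative radicand -> sentinel
  s <- cmc(rbind(rep(0, 8), rep(10, 8)))
  expect_identical(s$label, "<0.001")
  expect_lt(s$radicand, 0)
  # all-identical values: defined as 1 with degeneracy flag
  dgn <- cmc(matrix(5, 3, 6))
  expect_equal(dgn$value, 1)
  expect_true(dgn$degenerate)
  # invariance to a common constant; one-waveform offset lowers it
  set.seed(3)
  w2 <- matrix(rnorm(30), 3, 10) + outer(rep(1, 3), sin(1:10) * 3)
  expect_equal(cmc(w2 + 7)$radicand, cmc(w2)$radicand, tolerance = 1e-9)
  w3 <- w2; w3[1, ] <- w3[1, ] + 5
  expect_lt(cmc(w3)$radicand, cmc(w2)$radicand)
})

test_that("CMC interpretation bands follow the stated cut points", {
  expect_equal(classify_cmc(0.97), "excellent")
  expect_equal(classify_cmc(0.86), "very good")
  expect_equal(classify_cmc(0.80), "good")
  expect_equal(classify_cmc(0.70), "moderate")
  expect_equal(classify_cmc(0.59), "poor")
  expect_equal(classify_cmc("<0.001"), "poor")
})

test_that("gated_correlation picks Pearson or Spearman by Shapiro-Wilk", {
  set.seed(4)
  x <- rnorm(30)
  lin <- gated_correlation(x, 2 * x + 1)
  expect_equal(lin$method, "pearson")
  expect_equal(lin$coefficient, 1, tolerance = 1e-12)
  # heavily skewed monotone pair -> Spearman, rho = 1
  xs <- exp(rnorm(30, 0, 1.5))^3
  mono <- gated_correlation(xs, log(xs) + xs^0.3)
  expect_equal(mono$method, "spearman")
  expect_equal(mono$coefficient, 1)
  # Gaussian pairs match the textbook Pearson formula
  y <- 0.6 * x + rnorm(30, 0, 0.5)
  g <- gated_correlation(x, y)
  expect_equal(g$method, "pearson")
  expect_equal(g$coefficient,
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
               tolerance = 1e-12)
  expect_error(gated_correlation(rep(1, 10), rnorm(10)), "constant")
  expect_error(gated_correlation(1:3, 1:3), "n >= 4")
})

test_that("bland_altman matches mean +- 1.96 sample SD of differences", {
  x <- c(1, 2, 3, 4)
  expect_equal(unlist(bland_altman(x, x)),
               c(mean_diff = 0, loa_lower = 0, loa_upper = 0))
  ba <- bland_altman(x, x - 5)
  expect_equal(unlist(ba), c(mean_diff = 5, loa_lower = 5, loa_upper = 5))
  set.seed(5)
  d <- rnorm(500, 2, 3)
  ba2 <- bland_altman(d, rep(0, 500))
  expect_equal(ba2$mean_diff, mean(d))
  expect_equal(ba2$loa_upper, mean(d) + 1.96 * sd(d))
  expect_lt(abs(ba2$loa_upper - (2 + 1.96 * 3)), 0.5)   # Monte-Carlo band
  expect_error(bland_altman(1, 1), "n >= 2")
})

test_that("icc_2k matches brute-force ANOVA and frozen external oracle", {
  set.seed(6)
  for (i in 1:100) {
    n <- sample(3:8, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k), n, k) + rnorm(n, 0, 2)
    expect_equal(icc_2k(m)$icc, brute_icc2k(m), tolerance = 1e-9)
  }
  # frozen values computed with an independent implementation
  # (pingouin.intraclass_corr, ICC2k / "A,k") on these exact matrices
  m2 <- matrix(c(0.46, -1.56, 1.13, 3.41, -0.93, 0.05, 4.19, 3.53, 3.97,
                 4.72, 7.32, 7.17, 8.1, 9.69, 8.7, 8.71, 10.55, 8.56),
               6, 3, byrow = TRUE)
  r2 <- icc_2k(m2)
  expect_equal(r2$icc, 0.959697, tolerance = 1e-6)
  expect_equal(round(r2$ci_lower, 2), 0.83)
  expect_equal(round(r2$ci_upper, 2), 0.99)
  m3 <- matrix(c(17.2, 18.1, 12.3, 11.8, 9.4, 10.6, 15.1, 16.3, 11.2, 9.9,
                 14, 13.1, 10.5, 11.9, 16.8, 15.2), 8, 2, byrow = TRUE)
  r3 <- icc_2k(m3)
  expect_equal(r3$icc, 0.957272, tolerance = 1e-6)
  expect_equal(round(r3$ci_lower, 2), 0.78)
  # parallel columns (zero error variance): hand-computed mean squares
  m1 <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 4, 2, byrow = TRUE)
  expect_equal(icc_2k(m1)$icc, (40 / 3) / (40 / 3 + 2 / 4), tolerance = 1e-12)
  # identical columns, non-constant rows -> 1
  mi <- cbind(c(1, 5, 9, 2), c(1, 5, 9, 2))
  expect_equal(icc_2k(mi)$icc, 1)
  # independent columns, large n -> near zero
  set.seed(7)
  mz <- matrix(rnorm(400), 200, 2)
  expect_lt(abs(icc_2k(mz)$icc), 0.15)
  expect_error(icc_2k(matrix(1:4, 2, 2)), "n >= 3")
  expect_error(icc_2k(matrix(c(1, NA, 2, 3, 4, 5), 3, 2)), "missing")
})

test_that("sem follows SD * sqrt(1 - ICC), including negative ICC", {
  expect_equal(sem(10, 0.75), 5)
  expect_equal(sem(8, 0.64), 4.8)
  expect_equal(sem(4, 1), 0)
  expect_gt(sem(10, -0.23), 10)
  expect_error(sem(10, 1.2), "<= 1")
  expect_error(sem(-1, 0.5), ">= 0")
})

test_that("ICC interpretation bands follow the stated cut points", {
  expect_equal(classify_icc(0.93), "excellent")
  expect_equal(classify_icc(0.45), "modest")
  expect_equal(classify_icc(-0.23), "poor")
  expect_equal(classify_icc(0.39), "poor")
})

test_that("mean difference never exceeds the RMSE (bias-variance)", {
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(101, 5, 3); y <- rnorm(101, 3, 2)
    expect_lte(bland_altman(x, y)$mean_diff^2, rmse_waveform(x, y)^2 + 1e-12)
  }
})

test_that("validity_report on self-comparison is perfect", {
  cycles <- random_cycles(6, seed = 9)
  g <- build_gait_tensor(cycles, system = "G2")
  rep <- validity_report(g_kinect = g, g_reference = g)
  expect_true(all(rep$waveform$rmse_mean == 0))
  expect_true(all(rep$waveform$cmc_mean == 1))
  expect_true(all(rep$waveform$band == "excellent"))
  expect_true(all(abs(rep$discrete$mean_diff) < 1e-12))
})

test_that("reliability_report: identical days are perfectly reliable", {
  g <- build_gait_tensor(random_cycles(8, seed = 10))
  rep <- reliability_report(g, g)
  expect_true(all(rep$discrete$icc == 1))
  expect_true(all(rep$discrete$sem == 0))
  expect_true(all(rep$waveform$cmc_mean == 1))
})

test_that("reliability degrades monotonically with between-day noise", {
  base <- build_gait_tensor(random_cycles(10, seed = 12))
  sems <- sapply(c(0.5, 2, 8), function(s) {
    set.seed(99)
    d2 <- base
    d2$values <- d2$values + array(rnorm(length(d2$values), 0, s),
                                   dim(d2$values))
    mean(reliability_report(base, d2)$discrete$sem)
  })
  expect_true(all(diff(sems) > 0))
})

test_that("shuffling subjects destroys reliability", {
  g1 <- build_gait_tensor(random_cycles(12, seed = 13))
  g2 <- g1
  g2$values <- g2$values + array(rnorm(length(g2$values), 0, 0.5),
                                 dim(g2$values))
  icc_paired <- mean(reliability_report(g1, g2)$discrete$icc)
  set.seed(14)
  g2s <- g2; g2s$values <- g2$values[sample(12), , ]
  icc_shuf <- mean(reliability_report(g1, g2s)$discrete$icc)
  expect_gt(icc_paired, 0.9)
  expect_lt(abs(icc_shuf), 0.5)
})
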