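# WHAM estimator, re-weighting, and the two error estimators.

test_that("a single unbiased window degenerates to -kT log(histogram)", {
  set.seed(5)
  z <- rnorm(2e4, 0, 0.5)
  w <- umbrella_window(0, 0, samples = data.frame(z = z))
  g <- wham(list(w), bin_width = 0.1, anchor = "min")
  h <- table(cut(z, attr(g, "breaks")))
  ref <- -log(as.numeric(h) / sum(h))
  ref <- ref - min(ref[is.finite(ref)])
  fin <- is.finite(g$G_kT)
  expect_equal(g$G_kT[fin], ref[fin], tolerance = 1e-9)
})

test_that("WHAM recovers a harmonic potential from biased windows", {
  kappa <- 5
  ws <- harmonic_windows(kappa, seq(-1, 1, by = 0.2), k_bias = 500,
                         n_per_window = 3e3, seed = 6)
  g <- wham(ws, anchor = "min")
  central <- abs(g$z) <= 0.9
  expect_lt(pmf_rmsd(g$G_kT[central], 0.5 * kappa * g$z[central]^2), 0.1)
  # kcal column consistent with the kT column
  expect_equal(g$G_kcal, g$G_kT * kT_kcalmol(310), tolerance = 1e-12)
})

test_that("a flat potential yields a flat PMF within its estimated error", {
  ws <- flat_windows(seq(-1, 1, by = 0.25), k_bias = 250,
                     n_per_window = 4e3, seed = 7)
  g <- split_half_pmf_error(ws, anchor = "min")
  central <- abs(g$z) <= 0.9 & is.finite(g$G_kT)
  dev <- abs(g$G_kT[central] - mean(g$G_kT[central]))
  # a single split-half difference per bin is ~100% noisy; pooling the
  # per-bin errors (RMS) calibrates the profile's error scale
  err_scale <- sqrt(mean(g$error_kT[central]^2, na.rm = TRUE))
  expect_true(all(dev < 3 * pmax(err_scale, 0.02)))
  expect_lt(diff(range(g$G_kT[central])), 0.3)
})

test_that("window constants agree with direct likelihood minimisation", {
  # 2-window toy problem: compare the self-consistent constants with a
  # brute-force optimisation of the WHAM log-likelihood in f2 (f1 = 0)
  ws <- harmonic_windows(3, c(-0.3, 0.3), k_bias = 300,
                         n_per_window = 5e3, seed = 8)
  g <- wham(ws, bin_width = 0.05, tol = 1e-10, anchor = "min")
  breaks <- attr(g, "breaks")
  kT_kJ <- kT_kJmol(310)
  zc <- g$z
  H <- vapply(ws, function(w)
    as.numeric(table(cut(w$samples$z, breaks))), numeric(length(zc)))
  N <- colSums(H)
  # bin-averaged bias Boltzmann factors, evaluated independently
  s <- sqrt(300 / kT_kJ)
  bf <- function(z0) sqrt(2 * pi) / s *
    diff(pnorm(s * (breaks - z0))) / diff(breaks)
  b1 <- bf(-0.3); b2 <- bf(0.3)
  h <- rowSums(H)
  occ <- h > 0
  nll <- function(f2) {
    sum(h[occ] * log(N[1] * b1[occ] + N[2] * exp(f2) * b2[occ])) -
      N[2] * f2
  }
  opt <- optimize(nll, c(-20, 20), tol = 1e-12)
  expect_equal(attr(g, "f")[2], opt$minimum, tolerance = 1e-6)
})

test_that("non-overlapping windows are reported as a gap", {
  w1 <- umbrella_window(-1, 500, samples = data.frame(z = rnorm(500, -1, 0.02)))
  w2 <- umbrella_window(1, 500, samples = data.frame(z = rnorm(500, 1, 0.02)))
  expect_error(wham(list(w1, w2)), "do not overlap")
})

test_that("re-weighting reduces to plain averages when unbiased", {
  set.seed(9)
  d <- data.frame(z = rnorm(5e3, 0, 0.6), obs = rnorm(5e3, 2, 1))
  w <- umbrella_window(0, 0, samples = d)
  prof <- reweight_observable(list(w), "obs", bin_width = 0.2,
                              anchor = "min")
  breaks <- attr(wham(list(w), bin_width = 0.2, anchor = "min"), "breaks")
  bin <- cut(d$z, breaks, labels = FALSE)
  plain <- tapply(d$obs, bin, mean)
  got <- prof$mean[as.integer(names(plain))]
  expect_equal(unname(got), unname(as.numeric(plain)), tolerance = 1e-12)

  # a constant observable re-weights to a constant, exactly
  d$const <- 1.5
  w <- umbrella_window(0, 0, samples = d)
  prof <- reweight_observable(list(w), "const", bin_width = 0.2,
                              anchor = "min")
  expect_equal(prof$mean[prof$n > 0], rep(1.5, sum(prof$n > 0)),
               tolerance = 1e-12)
  # empty bins stay missing
  expect_true(all(is.na(prof$mean[prof$n == 0])))
})

test_that("profiles from windows with different k agree within errors", {
  kappa <- 4
  obsify <- function(ws) lapply(ws, function(w) {
    w$samples$obs <- hh_fraction(7, 6.5 + w$samples$z) +
      rnorm(nrow(w$samples), 0, 0.05)
    w
  })
  wsA <- obsify(harmonic_windows(kappa, seq(-0.8, 0.8, 0.2), 400, 3e3,
                                 seed = 11))
  wsB <- obsify(harmonic_windows(kappa, seq(-0.8, 0.8, 0.2), 800, 3e3,
                                 seed = 12))
  breaks <- seq(-1.6, 1.6, by = 0.1)
  pA <- reweight_observable(wsA, "obs",
                            pmf = wham(wsA, bin_width = 0.1,
                                       anchor = "min", breaks = breaks))
  pB <- reweight_observable(wsB, "obs",
                            pmf = wham(wsB, bin_width = 0.1,
                                       anchor = "min", breaks = breaks))
  common <- which(pA$n > 100 & pB$n > 100 & abs(pA$z) < 0.8)
  zdiff <- abs(pA$mean[common] - pB$mean[common]) /
    sqrt(pA$sem[common]^2 + pB$sem[common]^2)
  expect_lt(max(zdiff), 5)
})

test_that("split-half error vanishes for duplicated halves", {
  set.seed(13)
  half <- data.frame(z = rnorm(2e3, 0, 0.3))
  dup <- rbind(half, half)
  w <- umbrella_window(0, 0, samples = dup)
  g <- split_half_pmf_error(list(w), bin_width = 0.1, anchor = "min")
  expect_true(all(g$error_kT[!is.na(g$error_kT)] < 1e-12))
})

test_that("autocorrelation-block SEM is calibrated on known processes", {
  # i.i.d. Gaussian: within 20% of sigma/sqrt(n)
  set.seed(14)
  x <- rnorm(1e4)
  est <- autocorr_block_error(x)
  expect_equal(est$sem, 1 / sqrt(1e4), tolerance = 0.2)

  # AR(1), phi = 0.9: compare with the analytic SEM of the mean
  phi <- 0.9
  analytic <- sqrt((1 + phi) / (1 - phi)) / sqrt(1e4)
  ratios <- vapply(1:5, function(s) {
    set.seed(100 + s)
    y <- as.numeric(arima.sim(list(ar = phi), 1e4, sd = sqrt(1 - phi^2)))
    autocorr_block_error(y)$sem / analytic
  }, 0)
  expect_true(all(ratios > 1 / 1.5 & ratios < 1.5))

  # constant series
  est <- autocorr_block_error(rep(2, 100))
  expect_equal(est$sem, 0)
  expect_equal(est$block_length, 1L)
  expect_error(autocorr_block_error(1:5), "at least 10")
})
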