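# Fixture systems: calibration compounds, channel scans and the
# two-segment transport scan.

test_that("bulk compound shifts follow the screened-Coulomb prediction", {
  # no neighbours: apparent pKa equals the intrinsic pK
  plain <- make_bulk_compound(6)
  expect_equal(bulk_shift_prediction(plain), 0)
  occ <- unname(enumerate_exact(plain$sites, pH = 6)$occupancy)
  expect_equal(occ, 0.5, tolerance = 1e-12)

  # one fixed -1 e neighbour at 0.4 nm: positive shift equal to the
  # screened coupling in pK units (exact-enumeration titration oracle)
  sys <- make_bulk_compound(6, data.frame(q = -1, distance = 0.4))
  shift_pred <- screened_coulomb_kT(0.4) / log(10)
  expect_equal(bulk_shift_prediction(sys), shift_pred, tolerance = 1e-12)
  ph <- seq(3, 10, by = 0.5)
  occ <- vapply(ph, function(p)
    unname(enumerate_exact(sys$sites, pH = p,
                           fixed_charges = sys$fixed_charges)$occupancy), 0)
  fit <- hill_fit(ph, occ)
  expect_equal(fit$pk_half, 6 + shift_pred, tolerance = 1e-4)
  expect_equal(fit$hill_n, 1, tolerance = 1e-4)

  # triphosphate mimic shifts much more than the diphosphate mimic
  expect_gt(bulk_shift_prediction(make_atp_mimic()),
            2 * bulk_shift_prediction(make_adp_mimic()))
})

test_that("zero-field channel scan gives flat PMF and bulk protonation", {
  cfg <- small_channel_config(field = channel_field())
  res <- suppressWarnings(run_channel_scan(cfg, seed = 17))
  g <- res$pmf
  central <- abs(g$z) <= 1.8 & is.finite(g$G_kT)
  # flat within the pooled split-half error scale over the covered region
  dev <- abs(g$G_kT[central] - mean(g$G_kT[central]))
  err_scale <- sqrt(mean(g$error_kT[central]^2, na.rm = TRUE))
  expect_true(all(dev < 3 * pmax(err_scale, 0.05)))
  expect_lt(diff(range(g$G_kT[central])), 1)
  p <- res$protonation
  ok <- p$n > 300 & p$sem > 0
  bulk <- hh_fraction(cfg$pH, 6.5)
  expect_true(all(abs(p$mean[ok] - bulk) < pmax(4 * p$sem[ok], 0.02)))
})

test_that("channel scan finds the well minimum and the desolvation bump", {
  cfg <- small_channel_config()  # well at -1, desolvation bump at +1
  res <- suppressWarnings(run_channel_scan(cfg, seed = 18))
  g <- res$pmf
  fin <- is.finite(g$G_kT)
  expect_lt(abs(g$z[fin][which.min(g$G_kT[fin])] - (-1)), 0.3)
  # PMF within a few tenths of kT of the analytic 1D truth
  truth <- channel_pmf_truth(cfg, g$z, anchor = "min")
  expect_lt(pmf_rmsd(g$G_kT[fin & abs(g$z) < 1.9],
                     truth[fin & abs(g$z) < 1.9]), 0.35)
  # protonation maximum at the desolvation peak; the peak is a plateau
  # spanning several bins, so locate it to within ~a window spacing
  p <- res$protonation
  ok <- p$n > 300
  expect_lt(abs(p$z[ok][which.max(p$mean[ok])] - 1), 0.25)
  # minimum overlap between adjacent windows is healthy
  expect_gt(min(res$overlap$overlap), 0.05)
})

test_that("two-segment scans anchor independently and share the junction", {
  sch <- window_schedule(range = c(-1, 1), interior = c(-1, 1),
                         interior_spacing = 0.2, interior_k = 300)
  # identical fields: the two PMFs must agree at the junction
  f <- channel_field(cation_depth = 1, cation_width = 0.5)
  cfg <- make_two_segment_scan(fieldA = f, fieldB = f, transition_z = 0.2,
                               windows = sch, steps_per_window = 2e4)
  cfg$system$friction <- 2
  res <- suppressWarnings(run_two_segment_scan(cfg, seed = 19))
  expect_lt(abs(res$junction_gap_kT), 0.4)
  ca <- vapply(res$segments$stateA, `[[`, 0, "center")
  cb <- vapply(res$segments$stateB, `[[`, 0, "center")
  expect_true(0.2 %in% ca && 0.2 %in% cb)
  expect_equal(length(ca) + length(cb), 11 + 1)

  # a deeper well in state B opens a gap of the analytic size
  fb <- channel_field(cation_depth = 2.5, cation_width = 0.5)
  cfg2 <- make_two_segment_scan(fieldA = f, fieldB = fb,
                                transition_z = 0.2, windows = sch,
                                steps_per_window = 2e4)
  cfg2$system$friction <- 2
  res2 <- suppressWarnings(run_two_segment_scan(cfg2, seed = 20))
  # analytic per-segment truths, each anchored to its own windows
  tr <- function(field, zq, ws) {
    cfgx <- cfg2; cfgx$field <- field
    z <- seq(min(ws), max(ws), by = 0.05)
    g <- channel_pmf_truth(cfgx, z, anchor = "min")
    g[which.min(abs(z - zq))] - min(g)
  }
  gapA <- tr(f, 0.2, ca); gapB <- tr(fb, 0.2, cb)
  expect_equal(res2$junction_gap_kT, gapB - gapA, tolerance = 0.8)
})

test_that("fixtures are seed-deterministic end to end", {
  cfg <- small_channel_config(windows = window_schedule(
    range = c(-0.4, 0.4), interior = c(-0.4, 0.4), interior_spacing = 0.2),
    steps_per_window = 5e3)
  r1 <- suppressWarnings(run_channel_scan(cfg, seed = 21))
  r2 <- suppressWarnings(run_channel_scan(cfg, seed = 21))
  expect_identical(r1$pmf$G_kT, r2$pmf$G_kT)
  expect_identical(r1$protonation$mean, r2$protonation$mean)
})

test_that("random system generator is reproducible and in bounds", {
  s1 <- random_site_system(seed = 1)
  s2 <- random_site_system(seed = 1)
  expect_identical(vapply(s1$sites, `[[`, 0, "pk_int"),
                   vapply(s2$sites, `[[`, 0, "pk_int"))
  expect_identical(s1$pH, s2$pH)
  for (i in 1:20) {
    s <- random_site_system(seed = 300 + i)
    expect_lte(length(s$sites), 4)
    expect_true(all(vapply(s$sites, function(x) x$n_tautomers, 1L) <= 3))
    expect_true(s$pH >= 5 && s$pH <= 8)
  }
})
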