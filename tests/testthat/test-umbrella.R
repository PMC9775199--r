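# Window placement, steered starting configurations, overlap diagnostics
# and two-segment bookkeeping.

test_that("window placement is deterministic with the declared layout", {
  # 11 evenly spaced windows over [-1, 1]
  ws <- place_windows(window_schedule(range = c(-1, 1), interior = c(-1, 1),
                                      interior_spacing = 0.2))
  expect_length(ws, 11)
  expect_equal(vapply(ws, `[[`, 0, "center"), seq(-1, 1, by = 0.2))

  # degenerate range: one window
  expect_length(place_windows(window_schedule(range = c(0.5, 0.5))), 1)

  # default layout: dense stiff interior, sparse softer exterior
  ws <- place_windows(window_schedule())
  centers <- vapply(ws, `[[`, 0, "center")
  k <- vapply(ws, `[[`, 0, "k")
  expect_length(ws, 41 + 20)
  expect_true(all(k[abs(centers) <= 2] == 1000))
  expect_true(all(k[abs(centers) > 2] == 500))
  expect_false(is.unsorted(centers))

  # idempotent / deterministic
  ws2 <- place_windows(window_schedule())
  expect_identical(vapply(ws2, `[[`, 0, "center"), centers)
  expect_identical(vapply(ws2, `[[`, 0, "k"), k)
})

test_that("steering tracks the moving restraint and extracts snapshots", {
  sys <- model_system(list(titratable_site("A", 7)), box = c(-3, 3))

  # zero rate: equilibrate at the start position
  eq <- steer(sys, 7, start_z = -1, end_z = -1, rate = 0, k = 1000,
              seed = 3, equil_steps = 5e3)
  expect_equal(mean(eq$trajectory$z), -1, tolerance = 0.02)
  expect_error(steer(sys, 7, -1, 1, rate = 0), "rate must be nonzero")

  # stiff spring, slow pull: lag far below the restraint's thermal width
  centers <- seq(-1, 1, by = 0.25)
  out <- steer(sys, 7, -1, 1, rate = 2, k = 1000,
               snapshot_centers = centers, seed = 5)
  tr <- out$trajectory
  lag <- mean(tr$restraint_center - tr$z)
  sigma <- sqrt(kT_kJmol(310) / 1000)  # nm
  expect_lt(abs(lag), sigma)
  # snapshots lie within half a spacing of the requested centers
  expect_true(all(abs(out$snapshots$z - out$snapshots$center) < 0.125 + 3 * sigma))
  expect_error(steer(sys, 7, -1, 1, rate = 2, snapshot_centers = 2,
                     seed = 1),
               "outside traversed range")
})

test_that("stored bias energies equal the harmonic form exactly", {
  sys <- model_system(list(titratable_site("A", 7)), box = c(-3, 3))
  ws <- place_windows(window_schedule(range = c(-0.4, 0.4),
                                      interior = c(-0.4, 0.4),
                                      interior_spacing = 0.2))
  ws <- sample_windows(sys, ws, pH = 7,
                       cphmd_schedule(total_steps = 2e3), seed = 8)
  for (w in ws) {
    recomputed <- 0.5 * w$k * (w$samples$z - w$center)^2
    expect_equal(w$samples$bias, recomputed, tolerance = 1e-10)
  }
})

test_that("histogram-intersection overlap matches hand-computed values", {
  set.seed(10)
  same <- data.frame(z = rnorm(2e4))
  w1 <- umbrella_window(0, 100, samples = same)
  w2 <- umbrella_window(0.01, 100, samples = same)
  ov <- overlap_diagnostics(list(w1, w2))
  expect_equal(ov$overlap, 1)

  far <- umbrella_window(50, 100, samples = data.frame(z = rnorm(2e4, 50)))
  expect_equal(overlap_diagnostics(list(w1, far))$overlap, 0)
  expect_true(overlap_diagnostics(list(w1, far))$flag)

  # two unit-variance Gaussians 1 sigma apart: numeric-integral oracle
  oracle <- integrate(function(x) pmin(dnorm(x), dnorm(x, 1)),
                      -8, 9)$value
  g1 <- umbrella_window(0, 100, samples = data.frame(z = rnorm(4e4)))
  g2 <- umbrella_window(1, 100, samples = data.frame(z = rnorm(4e4, 1)))
  ov <- overlap_diagnostics(list(g1, g2), bin_width = 0.1)
  expect_equal(ov$overlap, oracle, tolerance = 0.02)

  expect_error(overlap_diagnostics(list(w1)), "at least 2 windows")
  expect_error(overlap_diagnostics(list(w1, umbrella_window(1, 10))),
               "must carry samples")
})

test_that("segment splitting shares the junction window", {
  ws <- place_windows(window_schedule(range = c(-1, 1), interior = c(-1, 1),
                                      interior_spacing = 0.2))
  seg <- split_segments(ws, transition_z = 0.2)
  ca <- vapply(seg$stateA, `[[`, 0, "center")
  cb <- vapply(seg$stateB, `[[`, 0, "center")
  expect_true(all(ca <= 0.2 + 1e-9))
  expect_true(all(cb >= 0.2 - 1e-9))
  # the junction window belongs to both groups
  expect_true(0.2 %in% ca && 0.2 %in% cb)
  expect_equal(length(ca) + length(cb), length(ws) + 1L)
  expect_true(all(vapply(seg$stateB, `[[`, "", "segment") == "stateB"))

  # transition beyond the covered range: a single non-empty group
  seg2 <- split_segments(ws, transition_z = 5)
  expect_length(seg2$stateA, length(ws))
  expect_length(seg2$stateB, 0)
})
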