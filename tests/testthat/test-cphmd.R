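# Constant-pH dynamics engine: diffusion, equipartition, Boltzmann
# consistency of the joint (coordinate, protonation) distribution, and
# the pKmod calibration arithmetic.

test_that("a flat potential gives free diffusion with the configured D", {
  sys <- model_system(list(titratable_site("A", 50)), friction = 2,
                      box = c(-200, 200))
  sch <- cphmd_schedule(total_steps = 1e5, protonation_period = 10)
  tr <- run_cphmd(sys, pH = 7, sch, seed = 4)
  dz <- diff(tr$z)
  dt_rec <- diff(tr$time[1:2])
  D <- 1 / sys$friction
  # increment variance over one record interval: 2 D dt
  expect_equal(var(dz), 2 * D * dt_rec, tolerance = 0.05)
  expect_equal(mean(dz), 0, tolerance = 0.01)
})

test_that("harmonic confinement satisfies equipartition; occupancy 0.5 at pH = pK", {
  k_spring <- 10  # kT/nm^2
  sys <- model_system(list(titratable_site("A", 7)),
                      potential = function(z) 0.5 * k_spring * z^2,
                      box = c(-4, 4))
  tr <- run_cphmd(sys, pH = 7, cphmd_schedule(total_steps = 2e5), seed = 2)
  d <- retained_rows(tr)
  expect_equal(var(d$z), 1 / k_spring, tolerance = 0.1)
  expect_equal(mean(d$s_A > 0), 0.5, tolerance = 0.03)
})

test_that("joint (z, protonation) distribution is Boltzmann for a static field", {
  field <- channel_field(desolv_height = 1.5, desolv_center = 0,
                         desolv_width = 0.5)
  k_spring <- 2
  sys <- model_system(list(titratable_site("A", 7)),
                      potential = function(z) 0.5 * k_spring * z^2,
                      field = field, friction = 1, box = c(-6, 6))
  tr <- run_cphmd(sys, pH = 7, cphmd_schedule(total_steps = 4e5), seed = 9)
  d <- retained_rows(tr)

  # independent oracle: quadrature over a discretised grid of the joint
  # Boltzmann weights (deprotonated carries the field energy)
  z <- seq(-6, 6, by = 0.01)
  u <- 0.5 * k_spring * z^2
  w_dep <- exp(-(u + field_energy_kT(-1, z, field)))
  w_pro <- exp(-u) * 10^(-(7 - 7))
  pz <- w_dep + w_pro
  occ_true <- sum(w_pro) / sum(pz)
  mean_true <- sum(z * pz) / sum(pz)
  var_true <- sum(z^2 * pz) / sum(pz) - mean_true^2

  expect_equal(mean(d$s_A > 0), occ_true, tolerance = 0.05)
  expect_equal(mean(d$z), mean_true, tolerance = 0.05)
  expect_equal(var(d$z), var_true, tolerance = 0.1)
})

test_that("trajectories are seed-deterministic and flag divergence", {
  sys <- model_system(list(titratable_site("A", 7)), box = c(-3, 3))
  sch <- cphmd_schedule(total_steps = 5e3)
  t1 <- run_cphmd(sys, 7, sch, seed = 31)
  t2 <- run_cphmd(sys, 7, sch, seed = 31)
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  # flat potential in a tiny box: the walker must leave and be reported
  tiny <- model_system(list(titratable_site("A", 7)), box = c(-0.05, 0.05))
  expect_error(run_cphmd(tiny, 7, cphmd_schedule(total_steps = 1e5),
                         seed = 1),
               "diverged beyond the simulation box at step")
})

test_that("pKmod calibration arithmetic and neutralisation pre-run", {
  expect_equal(calibrate_pkmod(6.5, 5.97), 0.53, tolerance = 1e-12)
  expect_equal(calibrate_pkmod(4.2, 0), 4.2)
  # algebraic round trip with pka_shift
  expect_equal(calibrate_pkmod(6.3, pka_shift(6.3, 4.78)), 4.78,
               tolerance = 1e-12)

  # three strong acids at pH 7 carry charge ~ -3: three cations needed
  sites <- lapply(1:3, function(i)
    titratable_site(paste0("A", i), pk_int = 3, position = i))
  sys <- model_system(sites, potential = function(z) 0.5 * 10 * z^2,
                      box = c(-3, 3))
  ions <- neutralize_system(sys, pH = 7,
                            cphmd_schedule(total_steps = 5e3), seed = 5)
  expect_equal(ions$count, 3L)
  expect_equal(ions$ion_charge, 1L)
  expect_lte(abs(ions$mean_charge + ions$count * ions$ion_charge), 0.5)
})

test_that("titration of an uncoupled site follows Henderson-Hasselbalch", {
  sys <- make_bulk_compound(pk_int = 6)
  curves <- run_titration(sys, seq(4, 8, by = 0.5),
                          cphmd_schedule(total_steps = 1e4), seed = 21)
  cv <- curves$sub
  expect_false(cv$degenerate)
  expect_equal(cv$fit$pk_half, 6, tolerance = 0.1)
  expect_equal(cv$fit$hill_n, 1, tolerance = 0.15)
  expect_true(all(abs(cv$occupancy - hh_fraction(cv$pH, 6)) < 0.06))
})
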