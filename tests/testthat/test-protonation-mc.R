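# Metropolis protonation sampling against closed forms and the
# exact-enumeration oracle.

test_that("microstate energies obey symmetry, additivity and coupling", {
  a <- titratable_site("A", pk_int = 6)
  b <- titratable_site("B", pk_int = 7.5)

  # at pH = pK the protonated and deprotonated forms are isoenergetic
  expect_equal(microstate_energy(0L, list(a), pH = 6),
               microstate_energy(1L, list(a), pH = 6))

  # two uncoupled sites: energies add
  for (sa in 0:1) for (sb in 0:1) {
    expect_equal(microstate_energy(c(sa, sb), list(a, b), pH = 7),
                 microstate_energy(sa, list(a), pH = 7) +
                   microstate_energy(sb, list(b), pH = 7))
  }

  # a 2 pK coupling between the doubly deprotonated states suppresses
  # that microstate's Boltzmann weight by exactly 10^-2 at pH = pK
  aa <- list(titratable_site("A", 7), titratable_site("B", 7))
  cm <- coupling_matrix(aa)
  m <- matrix(0, 2, 2); m[1, 1] <- 2  # state 0 x state 0
  cm <- set_coupling(cm, 1, 2, m)
  w_dd <- exp(-microstate_energy(c(0L, 0L), aa, cm, pH = 7))
  w_pp <- exp(-microstate_energy(c(1L, 1L), aa, cm, pH = 7))
  expect_equal(w_dd / w_pp, 1e-2, tolerance = 1e-12)

  # shifting all pk_int and the pH together leaves energies unchanged
  shift <- 2.3
  a2 <- titratable_site("A", 6 + shift)
  expect_equal(microstate_energy(1L, list(a), pH = 5.1),
               microstate_energy(1L, list(a2), pH = 5.1 + shift))

  expect_error(microstate_energy(2L, list(a), pH = 7), "invalid state")
  expect_error(mc_sample(list(), settings = mc_settings(n_cycles = 10)),
               "empty site list")
})

test_that("exact enumeration reproduces Henderson-Hasselbalch", {
  s <- list(titratable_site("A", pk_int = 6))
  expect_equal(unname(enumerate_exact(s, pH = 6.5)$occupancy),
               1 / (1 + 10^0.5), tolerance = 1e-12)

  # tautomer degeneracy must not change the site-level titration
  s3 <- list(titratable_site("A", pk_int = 6, n_tautomers = 3))
  expect_equal(unname(enumerate_exact(s3, pH = 6.5)$occupancy),
               1 / (1 + 10^0.5), tolerance = 1e-12)

  # uncoupled pair: product distribution of the single-site results
  pair <- list(titratable_site("A", 5.5), titratable_site("B", 8))
  res <- enumerate_exact(pair, pH = 7)
  expect_equal(unname(res$occupancy),
               hh_fraction(7, c(5.5, 8)), tolerance = 1e-12)

  big <- list(titratable_site("A", 7, n_tautomers = 3))
  expect_error(enumerate_exact(big, pH = 7, max_states = 2),
               "state space too large")
})

test_that("MC occupancies converge to exact enumeration", {
  n_sys <- 12
  for (i in seq_len(n_sys)) {
    sys <- random_site_system(seed = 4000 + i)
    ex <- enumerate_exact(sys$sites, sys$couplings, sys$pH)
    mc <- mc_sample(sys$sites, sys$couplings,
                    mc_settings(n_cycles = 3e4, pH = sys$pH,
                                seed = 5000 + i))
    dev <- abs(mc$occupancy - ex$occupancy)
    # 4-sigma bound per site keeps the property test deterministic-ish
    bound <- 4 * pmax(mc$sem, 1e-3)
    expect_true(all(dev < bound),
                info = sprintf("system %d: max dev %.4f, bound %.4f",
                               i, max(dev), min(bound)))
  }
})

test_that("pair moves trigger only above the coupling threshold", {
  sites <- list(titratable_site("A", 7), titratable_site("B", 7))
  strong <- charge_coupling(coupling_matrix(sites), sites, 1, 2, 3)
  weak <- charge_coupling(coupling_matrix(sites), sites, 1, 2, 1)
  exact2 <- charge_coupling(coupling_matrix(sites), sites, 1, 2, 2)

  expect_equal(nrow(eligible_pairs(strong, 2)), 1L)
  expect_equal(nrow(eligible_pairs(weak, 2)), 0L)
  # ties at exactly the threshold are excluded (strict inequality)
  expect_equal(nrow(eligible_pairs(exact2, 2)), 0L)

  st <- mc_settings(n_cycles = 500, pH = 7, seed = 1)
  expect_gt(mc_sample(sites, strong, st)$pair_attempts, 0)
  expect_equal(mc_sample(sites, weak, st)$pair_attempts, 0)
})

test_that("sampler is seed-deterministic and satisfies detailed balance", {
  sys <- random_site_system(seed = 99)
  st <- mc_settings(n_cycles = 2e4, pH = sys$pH, seed = 123)
  r1 <- mc_sample(sys$sites, sys$couplings, st)
  r2 <- mc_sample(sys$sites, sys$couplings, st)
  expect_identical(r1$states, r2$states)

  # empirical transition-count asymmetry between microstate pairs should
  # be consistent with zero for a reversible chain at equilibrium
  sites <- list(titratable_site("A", 7), titratable_site("B", 7.3))
  cm <- charge_coupling(coupling_matrix(sites), sites, 1, 2, 1.5)
  r <- mc_sample(sites, cm, mc_settings(n_cycles = 5e4, pH = 7, seed = 7))
  code <- r$states[, 1] * 2L + r$states[, 2]
  from <- code[-length(code)]; to <- code[-1]
  for (x in 0:3) for (y in 0:3) {
    if (x >= y) next
    nxy <- sum(from == x & to == y)
    nyx <- sum(from == y & to == x)
    if (nxy + nyx < 20) next
    zscore <- (nxy - nyx) / sqrt(nxy + nyx)
    expect_lt(abs(zscore), 5)
  }
})

test_that("single-site acid occupancy strictly decreases with pH", {
  s <- list(titratable_site("A", pk_int = 6.5))
  occ <- vapply(seq(3, 10, by = 0.5),
                function(p) unname(enumerate_exact(s, pH = p)$occupancy), 0)
  expect_true(all(diff(occ) < 0))
})

test_that("microstate ensembles round-trip through their table format", {
  sys <- random_site_system(seed = 11)
  r <- mc_sample(sys$sites, sys$couplings,
                 mc_settings(n_cycles = 200, pH = sys$pH, seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ensemble(r, path)
  expect_identical(read_ensemble(path), r$states)
})
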