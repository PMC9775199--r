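# Shared fixtures built in code.

# Exact sampler for a harmonically biased harmonic potential: the biased
# density is Gaussian, so windows can be filled with independent draws.
# Used as the sampling-free route when testing WHAM itself.
harmonic_windows <- function(kappa, centers, k_bias, n_per_window,
                             temperature = 310, seed = 1) {
  set.seed(seed)
  kT_kJ <- kT_kJmol(temperature)
  kb <- k_bias / kT_kJ
  lapply(centers, function(z0) {
    v <- 1 / (kappa + kb)
    m <- kb * z0 * v
    umbrella_window(z0, k_bias,
                    samples = data.frame(z = rnorm(n_per_window, m,
                                                   sqrt(v))))
  })
}

# Flat-potential windows (kappa = 0): biased density N(z0, kT/k).
flat_windows <- function(centers, k_bias, n_per_window,
                         temperature = 310, seed = 1) {
  harmonic_windows(0, centers, k_bias, n_per_window, temperature, seed)
}

# A small channel fixture that runs in a couple of seconds. The softer
# force constant keeps adjacent 0.2 nm windows well overlapped.
small_channel_config <- function(windows = window_schedule(
                                   range = c(-2, 2), interior = c(-2, 2),
                                   interior_spacing = 0.2,
                                   interior_k = 300),
                                 steps_per_window = 2e4, ...) {
  cfg <- make_channel_scan(windows = windows,
                           steps_per_window = steps_per_window, ...)
  # soft windows decorrelate slowly at the production friction; a lighter
  # medium keeps the reduced fixture's samples nearly independent
  cfg$system$friction <- 2
  cfg
}

# Anchor two profiles to their common mean over finite bins and return
# the RMS difference (standard PMF comparison up to an additive constant).
pmf_rmsd <- function(G, truth) {
  fin <- is.finite(G) & is.finite(truth)
  d <- G[fin] - truth[fin]
  d <- d - mean(d)
  sqrt(mean(d^2))
}
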