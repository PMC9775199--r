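# Reproducible fixture systems: a bulk calibration compound, a channel
# scan (cationic well + desolvation bump), a two-segment transport scan,
# and a random small-system generator for oracle comparisons.

#' Bulk calibration compound
#'
#' A single titratable site in bulk water with optional fixed, always
#' charged neighbours co-moving with it (the analogue of the non-titrating
#' phosphate units of a nucleotide), which generate a controllable pKa
#' shift through screened-Coulomb coupling. The site is weakly confined by
#' a harmonic potential; with zero field the confinement does not affect
#' protonation.
#'
#' @param pk_int Reference pK of the titrating site (pK units).
#' @param neighbor_charges Optional data frame with columns `q` (e) and
#'   `distance` (nm from the site).
#' @param kind Site kind (default `"acid"`).
#' @param confinement Harmonic confinement strength in kT/nm^2.
#' @return A [model_system()] with one site `"sub"`.
#' @examples
#' # ~1.5 pK engineered shift from two close anionic neighbours:
#' sys <- make_bulk_compound(0, data.frame(q = c(-1, -1),
#'                                         distance = c(0.28, 0.30)))
#' @export
make_bulk_compound <- function(pk_int = 0, neighbor_charges = NULL,
                               kind = "acid", confinement = 10) {
  model_system(
    sites = list(titratable_site("sub", pk_int = pk_int, kind = kind)),
    potential = function(z) 0.5 * confinement * z^2,
    field = channel_field(),
    fixed_charges = neighbor_charges,
    box = c(-3, 3))
}

#' Predicted pKa shift of a bulk compound
#'
#' Closed-form shift generated by the fixed neighbours of a
#' [make_bulk_compound()] system: the summed screened-Coulomb interaction
#' between the neighbours and the site's charged form, in pK units
#' (positive for anionic neighbours of an acid).
#'
#' @param system A [model_system()] from [make_bulk_compound()].
#' @return Predicted shift in pK units.
#' @export
bulk_shift_prediction <- function(system) {
  fc <- system$fixed_charges
  if (is.null(fc) || !nrow(fc)) return(0)
  s <- system$sites[[1]]
  q_charged <- if (s$kind == "acid") -1 else 1
  u <- sum(screened_coulomb_kT(abs(fc$distance - s$position),
                               qi = q_charged, qj = fc$q,
                               ionic_strength = system$ionic_strength,
                               temperature = system$temperature))
  # a destabilised charged form shifts the pK toward the protonated side
  if (s$kind == "acid") u / log(10) else -u / log(10)
}

#' Mimics of a tri- and di-phosphate substrate
#'
#' Convenience constructors for the calibration situation of the two
#' nucleotide substrates: the titrating terminal phosphate with either two
#' (`make_atp_mimic`) or one (`make_adp_mimic`) always-charged phosphate
#' neighbours. The stronger neighbour coupling of the triphosphate gives a
#' much larger pKa shift.
#'
#' @param pk_int Reference pK of the terminal phosphate.
#' @return A [model_system()].
#' @export
make_atp_mimic <- function(pk_int = 0) {
  make_bulk_compound(pk_int,
                     data.frame(q = c(-1, -1), distance = c(0.17, 0.34)))
}

#' @rdname make_atp_mimic
#' @export
make_adp_mimic <- function(pk_int = 0) {
  make_bulk_compound(pk_int, data.frame(q = -1, distance = 0.34))
}

#' Channel-scan experiment configuration
#'
#' Bundles everything needed to scan a titratable substrate through a
#' model channel: the system (single acid site, flat external potential,
#' the given channel field), the umbrella schedule, the per-window
#' constant-pH schedule and the analysis settings. Running it end to end
#' with [run_channel_scan()] yields a PMF with a minimum near the cationic
#' well and a protonation bump at the desolvation peak.
#'
#' The default field places a 2 pK cationic well at -1 nm and a 2 pK
#' desolvation penalty at +1 nm (both 0.6 nm wide), on a -4..+4 nm scan.
#'
#' @param field A [channel_field()].
#' @param substrate_pk Bulk pKa of the substrate site (default 6.5).
#' @param windows A [window_schedule()].
#' @param pH Solution pH (default 7).
#' @param steps_per_window Langevin steps per umbrella window.
#' @param bin_width Analysis bin width in nm.
#' @return A list of class `channel_scan_config`.
#' @export
make_channel_scan <- function(field = channel_field(cation_depth = 2,
                                                    cation_center = -1,
                                                    cation_width = 0.6,
                                                    desolv_height = 2,
                                                    desolv_center = 1,
                                                    desolv_width = 0.6),
                              substrate_pk = 6.5,
                              windows = window_schedule(),
                              pH = 7, steps_per_window = 4e4,
                              bin_width = 0.05) {
  system <- model_system(
    sites = list(titratable_site("sub", pk_int = substrate_pk)),
    potential = function(z) 0 * z,
    field = field,
    box = windows$range + c(-1, 1))
  structure(list(system = system, field = field, windows = windows,
                 pH = pH,
                 schedule = cphmd_schedule(total_steps = steps_per_window),
                 bin_width = bin_width),
            class = "channel_scan_config")
}

#' Run a channel scan end to end
#'
#' Places the umbrella windows, samples each with constant-pH dynamics,
#' and runs the full analysis: WHAM PMF with split-half errors, window
#' overlap diagnostics, and the re-weighted protonation profile of the
#' substrate site.
#'
#' @param config A [make_channel_scan()] configuration.
#' @param seed Integer seed (drives all window trajectories).
#' @return A list with `windows` (sampled), `pmf`, `protonation`,
#'   `overlap` and `config`.
#' @export
run_channel_scan <- function(config, seed = 1) {
  stopifnot(inherits(config, "channel_scan_config"))
  ws <- place_windows(config$windows)
  ws <- sample_windows(config$system, ws, config$pH, config$schedule,
                       seed = seed)
  pmf <- split_half_pmf_error(ws, bin_width = config$bin_width,
                              temperature = config$system$temperature)
  prot <- reweight_observable(ws, protonation_observable("sub"), pmf = pmf)
  ov <- overlap_diagnostics(ws, bin_width = config$bin_width)
  list(windows = ws, pmf = pmf, protonation = prot, overlap = ov,
       config = config)
}

#' Analytic references for a channel scan
#'
#' `channel_pk_profile()` gives the effective pK of the substrate site
#' along the coordinate; `channel_protonation_truth()` the corresponding
#' Henderson-Hasselbalch protonation profile in the quasi-static limit;
#' `channel_pmf_truth()` the exact 1D free-energy profile of the titrating
#' substrate, `-ln(exp(-U_charged(z)) + 10^-(pH - pk_int))` plus the
#' external potential, anchored like the WHAM profile.
#'
#' @param config A [make_channel_scan()] configuration.
#' @param z Coordinates in nm.
#' @param anchor,bulk_z Anchor convention (as in [wham()]).
#' @return Numeric vector along `z` (pK units, fraction, or kT).
#' @export
channel_pk_profile <- function(config, z) {
  effective_pk(config$system$sites[[1]], z, config$field)
}

#' @rdname channel_pk_profile
#' @export
channel_protonation_truth <- function(config, z) {
  hh_fraction(config$pH, channel_pk_profile(config, z))
}

#' @rdname channel_pk_profile
#' @export
channel_pmf_truth <- function(config, z, anchor = "bulk", bulk_z = 3.5) {
  s <- config$system$sites[[1]]
  q <- if (s$kind == "acid") -1 else 1
  u_charged <- field_energy_kT(q, z, config$field)
  G <- -log(exp(-u_charged) + 10^(-(config$pH - s$pk_int))) +
    config$system$potential(z)
  anchor_profile(G, z, anchor, bulk_z)
}

#' Two-segment transport-scan configuration
#'
#' Models a transport process interrupted by a conformational transition:
#' windows up to `transition_z` sample the channel field of state A,
#' windows beyond it the field of state B, and the junction window is
#' shared by both segments. The analysis computes two independently
#' anchored PMFs (each starting from its own water phase), with a declared
#' discontinuity at the transition.
#'
#' @param fieldA,fieldB [channel_field()] objects for the two
#'   conformational states.
#' @param transition_z Transition position in nm (default +0.2).
#' @inheritParams make_channel_scan
#' @return A list of class `two_segment_config`.
#' @export
make_two_segment_scan <- function(fieldA = channel_field(cation_depth = 2,
                                                         cation_center = -1,
                                                         cation_width = 0.6),
                                  fieldB = channel_field(cation_depth = 3,
                                                         cation_center = 1,
                                                         cation_width = 0.6),
                                  transition_z = 0.2,
                                  substrate_pk = 6.5,
                                  windows = window_schedule(),
                                  pH = 7, steps_per_window = 4e4,
                                  bin_width = 0.05) {
  base <- make_channel_scan(field = fieldA, substrate_pk = substrate_pk,
                            windows = windows, pH = pH,
                            steps_per_window = steps_per_window,
                            bin_width = bin_width)
  structure(c(unclass(base),
              list(fieldA = fieldA, fieldB = fieldB,
                   transition_z = transition_z)),
            class = "two_segment_config")
}

#' Run a two-segment scan end to end
#'
#' @param config A [make_two_segment_scan()] configuration.
#' @param seed Integer seed.
#' @return A list with `segments` (sampled window lists), `pmfA`, `pmfB`
#'   (independently anchored), `junction_gap_kT` (PMF difference at the
#'   transition window) and `config`.
#' @export
run_two_segment_scan <- function(config, seed = 1) {
  stopifnot(inherits(config, "two_segment_config"))
  ws <- place_windows(config$windows)
  seg <- split_segments(ws, config$transition_z)
  fields <- list(stateA = config$fieldA, stateB = config$fieldB)
  seg$stateA <- sample_windows(config$system, seg$stateA, config$pH,
                               config$schedule, seed = seed,
                               fields = fields)
  seg$stateB <- sample_windows(config$system, seg$stateB, config$pH,
                               config$schedule, seed = seed + 10000L,
                               fields = fields)
  pmfA <- wham(seg$stateA, bin_width = config$bin_width)
  pmfB <- wham(seg$stateB, bin_width = config$bin_width)
  gap <- junction_gap(pmfA, pmfB, config$transition_z)
  list(segments = seg, pmfA = pmfA, pmfB = pmfB,
       junction_gap_kT = gap, config = config)
}

junction_gap <- function(pmfA, pmfB, transition_z) {
  ia <- which.min(abs(pmfA$z - transition_z))
  ib <- which.min(abs(pmfB$z - transition_z))
  pmfB$G_kT[ib] - pmfA$G_kT[ia]
}

#' Random small titratable systems
#'
#' Draws a random system of up to `max_sites` coupled sites with up to
#' `max_tautomers` tautomers each — intrinsic pKs U(4, 9), pH U(5, 8),
#' random acid/base kinds, and random charge-product couplings of
#' magnitude U(0, `max_coupling`) pK units per pair (so a fraction of
#' pairs crosses the 2 pK pair-move threshold). Used to compare the
#' Metropolis sampler against exact enumeration.
#'
#' @param seed Optional seed.
#' @param max_sites,max_tautomers,max_coupling Generator bounds.
#' @return A list with `sites`, `couplings` and `pH`.
#' @export
random_site_system <- function(seed = NULL, max_sites = 4,
                               max_tautomers = 3, max_coupling = 4) {
  if (!is.null(seed)) set.seed(seed)
  n <- sample(2:max_sites, 1)
  sites <- lapply(seq_len(n), function(i)
    titratable_site(paste0("S", i),
                    pk_int = runif(1, 4, 9),
                    kind = sample(c("acid", "base"), 1),
                    n_tautomers = sample.int(max_tautomers, 1),
                    position = i * 0.5))
  cm <- coupling_matrix(sites)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    w <- runif(1, 0, max_coupling)
    cm <- charge_coupling(cm, sites, i, j, w)
  }
  list(sites = sites, couplings = cm, pH = runif(1, 5, 8))
}
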