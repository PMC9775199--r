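# Stochastic-titration constant-pH dynamics: overdamped Langevin steps on
# the reaction coordinate alternating with Metropolis protonation updates.

POTENTIAL_GRID_N <- 2001L

grid_potential <- function(system) {
  zg <- seq(system$box[1], system$box[2], length.out = POTENTIAL_GRID_N)
  Ug <- system$potential(zg)
  if (!all(is.finite(Ug)))
    stop("external potential must be finite over the simulated box",
         call. = FALSE)
  list(z = zg, U = as.numeric(Ug))
}

field_params <- function(field) {
  as.numeric(c(field$cation_depth, field$cation_center, field$cation_width,
               field$desolv_height, field$desolv_center, field$desolv_width))
}

#' Run a constant-pH dynamics trajectory
#'
#' Propagates the reaction coordinate with Euler-Maruyama overdamped
#' Langevin dynamics under the external potential, the charge-state
#' dependent channel field, and an optional harmonic bias, resampling the
#' protonation state every `schedule$protonation_period` steps at the
#' instantaneous conformation. One sample row is recorded per protonation
#' update.
#'
#' @param system A [model_system()].
#' @param pH Solution pH.
#' @param schedule A [cphmd_schedule()].
#' @param seed Optional integer seed.
#' @param bias Optional harmonic umbrella bias: list with `center` (nm),
#'   `k` (kJ mol^-1 nm^-2) and optionally `rate` (nm/ns, a moving
#'   restraint for steered runs; default 0).
#' @param z0 Starting coordinate (default: bias center if biased, else 0).
#' @param init Optional initial protonation state vector.
#' @return A data frame of class `cphmd_traj` with columns `time` (ps),
#'   `z` (nm), one integer state column per site (named `s_<id>`),
#'   `charge` (e) and `bias` (kJ/mol), plus attributes carrying the
#'   schedule, pH, bias and equilibration fraction.
#' @seealso [retained_rows()], [occupancy_means()]
#' @export
run_cphmd <- function(system, pH, schedule = cphmd_schedule(), seed = NULL,
                      bias = NULL, z0 = NULL, init = NULL) {
  stopifnot(inherits(system, "model_system"),
            inherits(schedule, "cphmd_schedule"))
  if (!is.null(seed)) set.seed(seed)
  g <- grid_potential(system)
  sites <- system$sites
  e0 <- site_state_energies(sites, pH, fixed_charges = system$fixed_charges,
                            ionic_strength = system$ionic_strength,
                            temperature = system$temperature)
  fc <- flatten_couplings(system$couplings)
  pairs <- eligible_pairs(system$couplings, schedule$pair_threshold)
  if (is.null(init)) init <- integer(length(sites))
  check_state(sites, init)
  kT_kJ <- kT_kJmol(system$temperature)
  if (is.null(bias)) bias <- list(center = 0, k = 0, rate = 0)
  if (is.null(bias$rate)) bias$rate <- 0
  if (is.null(z0)) z0 <- if (bias$k > 0) bias$center else 0
  D <- 1 / system$friction  # kT/friction in reduced units (kT = 1)
  res <- cphmd_kernel_cpp(
    g$z, g$U, field_params(system$field),
    e0, lapply(sites, `[[`, "charges"), vapply(sites, n_states, 1L),
    fc$ci, fc$cj, fc$mat, rbind(pairs) - 1L,
    bias$center, bias$rate * schedule$timestep / 1e3, bias$k / kT_kJ,
    bias$k, schedule$timestep, D, schedule$total_steps,
    schedule$protonation_period, schedule$mc_cycles,
    z0, system$box[1], system$box[2], as.integer(init))
  m <- res$samples
  ids <- site_ids(sites)
  colnames(m) <- c("time", "z", paste0("s_", ids), "charge", "bias")
  traj <- as.data.frame(m)
  for (col in paste0("s_", ids)) traj[[col]] <- as.integer(traj[[col]])
  attr(traj, "pH") <- pH
  attr(traj, "schedule") <- schedule
  attr(traj, "bias") <- bias
  attr(traj, "site_ids") <- ids
  attr(traj, "equilibration_fraction") <- schedule$equilibration_fraction
  class(traj) <- c("cphmd_traj", "data.frame")
  traj
}

#' Production rows of a trajectory
#'
#' Drops the equilibration fraction recorded with the trajectory (or an
#' explicit `discard` fraction) and returns the retained production rows.
#'
#' @param traj A `cphmd_traj` (or any data frame with an
#'   `equilibration_fraction` attribute).
#' @param discard Fraction to discard from the start; defaults to the
#'   trajectory's own equilibration fraction.
#' @return The retained rows, as a plain data frame.
#' @export
retained_rows <- function(traj, discard = NULL) {
  if (is.null(discard))
    discard <- attr(traj, "equilibration_fraction") %||% 0
  n <- nrow(traj)
  from <- min(n, floor(discard * n) + 1L)
  out <- as.data.frame(traj)[from:n, , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean site occupancies of a trajectory
#'
#' @inheritParams retained_rows
#' @return Named vector of mean protonated fractions over the production
#'   rows.
#' @export
occupancy_means <- function(traj, discard = NULL) {
  ids <- attr(traj, "site_ids")
  d <- retained_rows(traj, discard)
  vapply(setNames(paste0("s_", ids), ids),
         function(col) mean(d[[col]] > 0L), 0)
}

#' Titrate a model system over a pH range
#'
#' Runs replicate constant-pH trajectories at each pH, averages per-site
#' occupancies over production samples, and reports replicate standard
#' errors of the mean together with a Hill fit per site.
#'
#' @param system A [model_system()].
#' @param pH_values Numeric vector of at least 3 pH values spanning the
#'   expected pK.
#' @param schedule A [cphmd_schedule()].
#' @param seeds Integer vector, one seed per replicate (default 3
#'   replicates derived from `seed`).
#' @param seed Base seed used when `seeds` is not given.
#' @return A named list of [titration_curve()] objects, one per site.
#' @export
run_titration <- function(system, pH_values, schedule = cphmd_schedule(),
                          seeds = NULL, seed = 1) {
  if (length(pH_values) < 3)
    stop("at least 3 pH values are required", call. = FALSE)
  if (is.null(seeds)) seeds <- seed + seq_len(3) * 1000L
  ids <- site_ids(system$sites)
  occ <- array(NA_real_, c(length(pH_values), length(seeds), length(ids)),
               dimnames = list(NULL, NULL, ids))
  for (p in seq_along(pH_values)) for (r in seq_along(seeds)) {
    traj <- run_cphmd(system, pH_values[p], schedule,
                      seed = seeds[r] + 7919L * p)
    occ[p, r, ] <- occupancy_means(traj)
  }
  curves <- lapply(ids, function(id) {
    mean_occ <- apply(occ[, , id, drop = FALSE], 1, mean)
    sem <- apply(occ[, , id, drop = FALSE], 1, sd) / sqrt(length(seeds))
    titration_curve(pH_values, mean_occ, sem = sem, site = id)
  })
  setNames(curves, ids)
}

#' Calibrate a model-compound reference pK
#'
#' Given the experimental aqueous pKa of a compound and the pKa shift its
#' model exhibits in simulation (apparent pKa minus the reference pK used),
#' returns the reference pK (pKmod) that makes the simulated bulk titration
#' reproduce the experimental value:
#' `pk_mod = target_pka - simulated_shift`.
#'
#' @param target_pka Experimental aqueous pKa (pK units).
#' @param simulated_shift Simulated pKa shift (pK units), e.g. from
#'   [pka_shift()] on a calibration run with a trial reference pK of zero.
#' @return The calibrated pKmod (pK units).
#' @examples
#' calibrate_pkmod(6.5, 5.97)  # 0.53
#' @export
calibrate_pkmod <- function(target_pka, simulated_shift) {
  stopifnot(all(is.finite(target_pka)), all(is.finite(simulated_shift)))
  target_pka - simulated_shift
}

#' Counter ions from a neutralisation pre-run
#'
#' Runs a short unbiased pre-run (a fraction of the production schedule),
#' estimates the mean total charge, and returns the fixed number of
#' monovalent counter ions that brings the expected total charge nearest
#' to zero (see [counterions_for_neutrality()]).
#'
#' @inheritParams run_cphmd
#' @param fraction Length of the pre-run as a fraction of
#'   `schedule$total_steps` (default 0.2).
#' @return The [counterions_for_neutrality()] result, with the estimated
#'   `mean_charge` attached.
#' @export
neutralize_system <- function(system, pH, schedule = cphmd_schedule(),
                              seed = NULL, fraction = 0.2) {
  pre <- cphmd_schedule(
    total_steps = max(schedule$protonation_period,
                      floor(fraction * schedule$total_steps)),
    timestep = schedule$timestep,
    protonation_period = schedule$protonation_period,
    mc_cycles = schedule$mc_cycles,
    pair_threshold = schedule$pair_threshold,
    equilibration_fraction = schedule$equilibration_fraction)
  traj <- run_cphmd(system, pH, pre, seed = seed)
  q <- mean(retained_rows(traj)$charge)
  out <- counterions_for_neutrality(q)
  out$mean_charge <- q
  out
}
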