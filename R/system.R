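# Model systems and constant-pH schedules.

#' Define a model system
#'
#' A low-dimensional stand-in for a solvated membrane-transporter system:
#' one continuous reaction coordinate z (nm) moving in an external
#' potential, carrying a substrate with titratable sites, optional fixed
#' co-moving charges, and an electrostatic channel field. Dynamics are
#' overdamped Langevin at the given temperature with diffusion coefficient
#' `D = 1/friction` (nm^2/ps, energies in kT).
#'
#' @param sites List of [titratable_site()] objects riding the coordinate.
#' @param potential External potential U(z) in kT: a function of z,
#'   vectorised. Default: flat (zero).
#' @param field A [channel_field()] (default: zero field).
#' @param fixed_charges Optional data frame with columns `q` (e) and
#'   `distance` (nm): always-charged groups co-moving with the substrate
#'   at fixed distance from the origin of the substrate frame.
#' @param couplings Optional [coupling_matrix()] between the titratable
#'   sites; by default computed from the site positions with
#'   [couplings_from_geometry()] when there is more than one site.
#' @param temperature Temperature in K (default 310).
#' @param friction Friction coefficient in 1/ps; the diffusion coefficient
#'   is `kT/friction` in reduced units (default 10 -> D = 0.1 nm^2/ps,
#'   chosen so the Euler-Maruyama discretisation error stays small even
#'   under the stiffest umbrella restraints while positional decorrelation
#'   remains far shorter than a window run).
#' @param box Simulated range of z in nm; trajectories leaving it abort
#'   with an integration error.
#' @param ionic_strength Ionic strength (M) for screened couplings.
#' @return An object of class `model_system`.
#' @export
model_system <- function(sites, potential = NULL, field = channel_field(),
                         fixed_charges = NULL, couplings = NULL,
                         temperature = 310, friction = 10,
                         box = c(-5, 5), ionic_strength = 0.1) {
  check_sites(sites)
  if (is.null(potential)) potential <- function(z) 0 * z
  stopifnot(is.function(potential), temperature > 0, friction > 0,
            length(box) == 2, box[1] < box[2])
  if (!is.null(fixed_charges)) {
    fixed_charges <- as.data.frame(fixed_charges)
    stopifnot(all(c("q", "distance") %in% names(fixed_charges)))
  }
  if (is.null(couplings) && length(sites) > 1L)
    couplings <- couplings_from_geometry(sites,
                                         ionic_strength = ionic_strength,
                                         temperature = temperature)
  structure(list(sites = sites, potential = potential, field = field,
                 fixed_charges = fixed_charges, couplings = couplings,
                 temperature = temperature, friction = friction,
                 box = as.numeric(box), ionic_strength = ionic_strength),
            class = "model_system")
}

#' @export
print.model_system <- function(x, ...) {
  cat(sprintf("<model_system: %d site(s) [%s], T = %g K, box [%g, %g] nm>\n",
              length(x$sites), paste(site_ids(x$sites), collapse = ", "),
              x$temperature, x$box[1], x$box[2]))
  invisible(x)
}

#' Constant-pH dynamics schedule
#'
#' Controls the alternation between conformational dynamics and protonation
#' updates: every `protonation_period` Langevin steps the protonation state
#' is resampled by `mc_cycles` Monte Carlo cycles at the instantaneous
#' conformation, and one sample row is recorded. The leading
#' `equilibration_fraction` of recorded rows is discarded from all reported
#' averages (default 2/15, mirroring a 20 ns discard from 150 ns windows).
#'
#' @param total_steps Total number of Langevin steps.
#' @param timestep Integration time step in ps (default 0.002).
#' @param protonation_period Steps between protonation updates (default 10).
#' @param mc_cycles MC cycles per protonation update (default 20).
#' @param pair_threshold Pair-move threshold in pK units (default 2).
#' @param equilibration_fraction Fraction of each run discarded as
#'   equilibration, in `[0, 1)`.
#' @return An object of class `cphmd_schedule`.
#' @export
cphmd_schedule <- function(total_steps = 5e4, timestep = 0.002,
                           protonation_period = 10L, mc_cycles = 20L,
                           pair_threshold = 2,
                           equilibration_fraction = 2 / 15) {
  total_steps <- as.integer(total_steps)
  protonation_period <- as.integer(protonation_period)
  if (protonation_period < 1L)
    stop("protonation_period must be >= 1", call. = FALSE)
  if (equilibration_fraction < 0 || equilibration_fraction >= 1)
    stop("equilibration_fraction must be in [0, 1)", call. = FALSE)
  if (total_steps < protonation_period)
    stop("total_steps must cover at least one protonation update",
         call. = FALSE)
  structure(list(total_steps = total_steps, timestep = timestep,
                 protonation_period = protonation_period,
                 mc_cycles = as.integer(mc_cycles),
                 pair_threshold = pair_threshold,
                 equilibration_fraction = equilibration_fraction),
            class = "cphmd_schedule")
}
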