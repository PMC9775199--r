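# Microstate energies and the exact-enumeration oracle.

# Per-site state energies in kT at pH, before couplings between titrating
# sites. State 0 (deprotonated) is the reference (0 kT in bulk). Each
# protonated tautomer t costs ln(10)*(pH - pk_int - dpk_t) + log(T)
# (acid convention; the identical expression holds for bases because the
# Henderson-Hasselbalch protonated fraction is the same formula for both —
# only the state charges differ). Optional contributions:
#  * fixed co-moving charges (data.frame q, distance): screened-Coulomb
#    interaction with each state's charge — this is what generates pKa
#    shifts of model compounds (e.g. the always-charged phosphates of ATP);
#  * a channel field evaluated at reaction coordinate z (see field.R).
site_state_energies <- function(sites, pH, fixed_charges = NULL,
                                field = NULL, z = NULL,
                                ionic_strength = 0.1, dielectric = 80,
                                temperature = 310) {
  check_sites(sites)
  lapply(sites, function(s) {
    nt <- s$n_tautomers
    e <- c(0, log(10) * (pH - s$pk_int - s$tautomer_dpk) + log(nt))
    if (!is.null(fixed_charges) && nrow(fixed_charges)) {
      u <- sum(screened_coulomb_kT(abs(fixed_charges$distance - s$position),
                                   qi = 1, qj = fixed_charges$q,
                                   ionic_strength = ionic_strength,
                                   dielectric = dielectric,
                                   temperature = temperature))
      e <- e + s$charges * u
    }
    if (!is.null(field) && !is.null(z))
      e <- e + field_energy_kT(s$charges, z, field)
    e
  })
}

#' Energy of a protonation microstate
#'
#' Total free energy (kT) of one assignment of protonation/tautomer states,
#' at fixed conformation: the sum of per-site terms
#' `ln(10) * (pH - pk_int)` per bound proton (with tautomer degeneracy
#' correction) plus `ln(10)` times the pairwise couplings between the
#' occupied states. This is the energy whose Boltzmann weights the
#' Metropolis sampler targets.
#'
#' @inheritParams microstate_charge
#' @param couplings Optional [coupling_matrix()] (pK units).
#' @param pH Solution pH.
#' @param fixed_charges Optional data frame with columns `q` (e) and
#'   `distance` (nm): fixed charges co-moving with the substrate.
#' @param ionic_strength,dielectric,temperature Screening parameters for
#'   the fixed-charge interactions.
#' @return Energy in kT (a single number).
#' @examples
#' s <- list(titratable_site("A", pk_int = 7))
#' microstate_energy(c(0L), s, pH = 7)  # deprotonated reference: 0
#' microstate_energy(c(1L), s, pH = 7)  # equal at pH = pK: 0
#' @export
microstate_energy <- function(state, sites, couplings = NULL, pH,
                              fixed_charges = NULL, ionic_strength = 0.1,
                              dielectric = 80, temperature = 310) {
  check_state(sites, state)
  e <- site_state_energies(sites, pH, fixed_charges = fixed_charges,
                           ionic_strength = ionic_strength,
                           dielectric = dielectric,
                           temperature = temperature)
  tot <- sum(vapply(seq_along(sites), function(i) e[[i]][state[i] + 1L], 0))
  if (!is.null(couplings) && length(couplings$pairs)) {
    fc <- flatten_couplings(couplings)
    for (k in seq_along(fc$ci)) {
      i <- fc$ci[k] + 1L; j <- fc$cj[k] + 1L
      tot <- tot + log(10) * fc$mat[[k]][state[i] + 1L, state[j] + 1L]
    }
  }
  tot
}

#' Exact protonation occupancies by enumeration
#'
#' Brute-force Boltzmann sum over all protonation/tautomer microstates.
#' Serves as the independent oracle for the Metropolis sampler: for
#' uncoupled sites the result reduces to Henderson-Hasselbalch per site.
#'
#' @inheritParams microstate_energy
#' @param max_states Refuse systems with more microstates than this
#'   (default 1e6).
#' @return A list with `occupancy` (named per-site protonated fraction),
#'   `states` (integer matrix of all microstates), `prob` (their Boltzmann
#'   probabilities) and `charge_mean`.
#' @export
enumerate_exact <- function(sites, couplings = NULL, pH,
                            fixed_charges = NULL, ionic_strength = 0.1,
                            dielectric = 80, temperature = 310,
                            max_states = 1e6) {
  check_sites(sites)
  ns <- vapply(sites, n_states, 1L)
  if (prod(ns) > max_states)
    stop(sprintf("state space too large: %g microstates (limit %g)",
                 prod(ns), max_states), call. = FALSE)
  grid <- as.matrix(expand.grid(lapply(ns, function(n) 0:(n - 1L)),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- site_ids(sites)
  e <- site_state_energies(sites, pH, fixed_charges = fixed_charges,
                           ionic_strength = ionic_strength,
                           dielectric = dielectric,
                           temperature = temperature)
  E <- rowSums(vapply(seq_along(sites),
                      function(i) e[[i]][grid[, i] + 1L],
                      numeric(nrow(grid))))
  if (!is.null(couplings) && length(couplings$pairs)) {
    fc <- flatten_couplings(couplings)
    for (k in seq_along(fc$ci)) {
      i <- fc$ci[k] + 1L; j <- fc$cj[k] + 1L
      E <- E + log(10) *
        fc$mat[[k]][cbind(grid[, i] + 1L, grid[, j] + 1L)]
    }
  }
  w <- exp(-(E - min(E)))
  p <- w / sum(w)
  occ <- colSums(p * (grid > 0L))
  qmat <- vapply(seq_along(sites),
                 function(i) sites[[i]]$charges[grid[, i] + 1L],
                 numeric(nrow(grid)))
  list(occupancy = setNames(occ, site_ids(sites)),
       states = grid, prob = p,
       charge_mean = sum(p * rowSums(qmat)))
}
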