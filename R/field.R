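# Simplified channel electrostatics: Gaussian cationic well + desolvation
# penalty along the reaction coordinate, screened-Coulomb site couplings,
# and counter-ion bookkeeping. This analytic backend stands in for a grid
# Poisson-Boltzmann solve on model systems; the reference PB constants are
# recorded in reference_electrostatics().

#' Channel electrostatic field
#'
#' Two Gaussian components along the reaction coordinate z emulate the
#' environment a substrate meets inside a cationic channel:
#' a *cationic well* (the positive electrostatic funnel that attracts
#' anionic substrates and lowers acid pKs) and a *desolvation* penalty
#' (low-dielectric environment that penalises charged forms and raises
#' acid pKs). Both vanish far from the channel, recovering bulk behaviour.
#'
#' @param cation_depth Depth of the cationic well in pK units (>= 0 for an
#'   attractive well as seen by a -1 e charge).
#' @param cation_center,cation_width Center and Gaussian width in nm.
#' @param desolv_height Height of the desolvation penalty in pK units.
#' @param desolv_center,desolv_width Center and Gaussian width in nm.
#' @return An object of class `channel_field`.
#' @examples
#' f <- channel_field(cation_depth = 3, cation_width = 0.6,
#'                    desolv_height = 2, desolv_width = 0.6)
#' effective_pk(titratable_site("P", 6.5), z = 0, field = f)
#' @export
channel_field <- function(cation_depth = 0, cation_center = 0,
                          cation_width = 1, desolv_height = 0,
                          desolv_center = 0, desolv_width = 1) {
  if (cation_width <= 0 || desolv_width <= 0)
    stop("field widths must be positive", call. = FALSE)
  structure(list(cation_depth = cation_depth, cation_center = cation_center,
                 cation_width = cation_width, desolv_height = desolv_height,
                 desolv_center = desolv_center, desolv_width = desolv_width),
            class = "channel_field")
}

gaussian_bump <- function(z, height, center, width) {
  height * exp(-0.5 * ((z - center) / width)^2)
}

#' @rdname channel_field
#' @param field A `channel_field`.
#' @param z Reaction coordinate (nm), vectorised.
#' @export
field_desolvation <- function(field, z) {
  gaussian_bump(z, field$desolv_height, field$desolv_center,
                field$desolv_width)
}

#' @rdname channel_field
#' @export
field_cation_well <- function(field, z) {
  gaussian_bump(z, field$cation_depth, field$cation_center,
                field$cation_width)
}

# Field free energy (kT) of a state with charge q at coordinate z:
# desolvation penalises any charged form (|q|), the cationic well
# stabilises negative and destabilises positive charges (q * phi).
field_energy_kT <- function(q, z, field) {
  log(10) * (abs(q) * field_desolvation(field, z) +
               q * field_cation_well(field, z))
}

field_force_kT <- function(q_total, abs_q_total, z, field) {
  # -d/dz of the summed field energy for the current microstate charges
  dd <- -(z - field$desolv_center) / field$desolv_width^2 *
    field_desolvation(field, z)
  dw <- -(z - field$cation_center) / field$cation_width^2 *
    field_cation_well(field, z)
  -log(10) * (abs_q_total * dd + q_total * dw)
}

#' Position-dependent effective pK
#'
#' The pK a site would exhibit if titrated while held at reaction
#' coordinate `z` in the given field. For an acid,
#' `pk_eff(z) = pk_int + desolvation(z) - cation_well(z)`:
#' desolvation disfavours the charged deprotonated form (raising the pK)
#' while the cationic environment stabilises it (lowering the pK). For a
#' base the charged form is the protonated one, so both terms lower the pK.
#' Far from the channel `pk_eff` recovers `pk_int`.
#'
#' @param site A [titratable_site()].
#' @param z Reaction coordinate (nm), vectorised.
#' @param field A [channel_field()].
#' @return Effective pK in pK units.
#' @export
effective_pk <- function(site, z, field) {
  d <- field_desolvation(field, z)
  w <- field_cation_well(field, z)
  if (site$kind == "acid") site$pk_int + d - w else site$pk_int - d - w
}

#' Site-site couplings from geometry
#'
#' Builds the full [coupling_matrix()] from site positions using
#' Debye-Hueckel screened-Coulomb pair energies between the state charges,
#' converted to pK units. Symmetric by construction; decays monotonically
#' with distance and with ionic strength.
#'
#' @param sites List of [titratable_site()] objects.
#' @param positions Optional numeric vector of coordinates (nm); defaults
#'   to the sites' own `position` fields.
#' @inheritParams screened_coulomb_kT
#' @return A [coupling_matrix()].
#' @export
couplings_from_geometry <- function(sites, positions = NULL,
                                    ionic_strength = 0.1, dielectric = 80,
                                    temperature = 310) {
  check_sites(sites)
  if (is.null(positions))
    positions <- vapply(sites, `[[`, 0, "position")
  if (length(positions) != length(sites))
    stop("one position per site required", call. = FALSE)
  cm <- coupling_matrix(sites)
  n <- length(sites)
  if (n < 2L) return(cm)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- abs(positions[i] - positions[j])
    if (r < 1e-9)
      stop(sprintf("sites '%s' and '%s' are coincident",
                   sites[[i]]$id, sites[[j]]$id), call. = FALSE)
    u_pk <- screened_coulomb_kT(r, 1, 1, ionic_strength, dielectric,
                                temperature) / log(10)
    cm <- set_coupling(cm, i, j,
                       outer(sites[[i]]$charges, sites[[j]]$charges) * u_pk)
  }
  cm
}

#' Counter ions needed for charge neutrality
#'
#' Given the mean total charge of a system (estimated from a short
#' pre-run), returns the number and sign of monovalent counter ions that
#' bring the expected total charge nearest to zero, leaving only a small
#' residual for the uniform background correction. Rounding ties (x.5) go
#' away from zero (over-neutralise).
#'
#' @param mean_total_charge Mean total charge in e.
#' @return A list with `count` (non-negative integer), `ion_charge`
#'   (-1, 0 or +1 per ion) and `residual` (e, |residual| <= 0.5).
#' @examples
#' counterions_for_neutrality(3.2)   # 3 anions, residual +0.2 e
#' counterions_for_neutrality(-2.6)  # 3 cations, residual +0.4 e
#' @export
counterions_for_neutrality <- function(mean_total_charge) {
  stopifnot(is.finite(mean_total_charge))
  n <- floor(abs(mean_total_charge) + 0.5)  # round half away from zero
  ion <- if (n == 0) 0 else -sign(mean_total_charge)
  list(count = as.integer(n), ion_charge = as.integer(ion),
       residual = mean_total_charge + n * ion)
}

#' Reference continuum-electrostatics constants
#'
#' The fixed constants of the reference finite-difference
#' Poisson-Boltzmann setup that the analytic backend emulates, recorded
#' for provenance: solute/solvent dielectrics 2/80, 0.1 M ionic strength,
#' 1.4 A molecular-surface probe and 2 A ion exclusion layer.
#'
#' @return A named list of constants.
#' @export
reference_electrostatics <- function() {
  list(solute_dielectric = 2, solvent_dielectric = 80,
       ionic_strength = 0.1, probe_radius_A = 1.4, ion_exclusion_A = 2)
}
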