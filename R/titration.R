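# Titration curves, Hill fitting and Henderson-Hasselbalch utilities.
# Acid convention throughout: "occupancy" is the protonated fraction,
# which follows the same Henderson-Hasselbalch expression for bases.

#' Henderson-Hasselbalch protonated fraction
#'
#' Closed-form protonated fraction of an isolated titratable site:
#' `f = 1 / (1 + 10^(pH - pKa))`. Strictly decreasing in pH, with
#' `f(pKa) = 0.5` and the symmetry `f(pKa + d) + f(pKa - d) = 1`.
#'
#' @param pH Solution pH (vectorised).
#' @param pKa Site pKa (pK units).
#' @return Protonated fraction in `[0, 1]`.
#' @examples
#' hh_fraction(7, c(6.3, 6.5))  # ~0.17 and ~0.24: ~20% on average
#' @export
hh_fraction <- function(pH, pKa) 1 / (1 + 10^(pH - pKa))

#' pKa shift
#'
#' Difference between an apparent (simulated or environment-shifted) pKa
#' and a reference pK: `shift = apparent - reference`. Together with
#' [calibrate_pkmod()] this closes the calibration round trip:
#' `calibrate_pkmod(target, pka_shift(apparent, reference))` returns the
#' reference that reproduces `target`.
#'
#' @param apparent_pka,reference_pka pK values (pK units).
#' @return The shift in pK units.
#' @examples
#' pka_shift(6.5, 0.53)  # 5.97
#' @export
pka_shift <- function(apparent_pka, reference_pka) {
  stopifnot(all(is.finite(apparent_pka)), all(is.finite(reference_pka)))
  apparent_pka - reference_pka
}

#' Fit a Hill curve to titration data
#'
#' Least-squares fit of `f = 1 / (1 + 10^(n * (pH - pK)))` in occupancy
#' space, with the Hill coefficient bounded in (0, 5]. A Hill coefficient
#' different from 1 signals coupled titration. Curves that do not cross
#' 0.5 within the sampled pH range carry no information on the midpoint
#' and raise a degenerate-fit error.
#'
#' @param pH Numeric vector of pH values (>= 3 points).
#' @param occupancy Mean protonated fractions in `[0, 1]`.
#' @param weights Optional fit weights (e.g. `1/sem^2`).
#' @return A list of class `hill_fit` with `pk_half`, `hill_n`,
#'   `residual_sse` and `fitted`.
#' @examples
#' ph <- c(4, 5, 6, 7)
#' fit <- hill_fit(ph, hh_fraction(ph, 5.5))
#' c(fit$pk_half, fit$hill_n)  # 5.5, 1
#' @export
hill_fit <- function(pH, occupancy, weights = NULL) {
  if (length(pH) < 3) stop("need at least 3 points", call. = FALSE)
  if (length(pH) != length(occupancy))
    stop("pH and occupancy lengths differ", call. = FALSE)
  if (any(occupancy < -1e-9 | occupancy > 1 + 1e-9))
    stop("occupancies must lie in [0, 1]", call. = FALSE)
  if (!(max(occupancy) > 0.5 && min(occupancy) < 0.5))
    stop(paste("degenerate titration curve: no transition through 0.5",
               "within the sampled pH range"), call. = FALSE)
  start_pk <- pH[which.min(abs(occupancy - 0.5))]
  df <- data.frame(pH = pH, occ = occupancy)
  if (is.null(weights)) weights <- rep(1, length(pH))
  fit <- minpack.lm::nlsLM(
    occ ~ 1 / (1 + 10^(n * (pH - pk))),
    data = df, weights = weights,
    start = list(pk = start_pk, n = 1),
    lower = c(pk = min(pH) - 10, n = 1e-3),
    upper = c(pk = max(pH) + 10, n = 5),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  est <- coef(fit)
  structure(list(pk_half = unname(est["pk"]), hill_n = unname(est["n"]),
                 residual_sse = sum(weights * residuals(fit)^2),
                 fitted = as.numeric(predict(fit))),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit: pK(1/2) = %.3f, n = %.3f, SSE = %.3g>\n",
              x$pk_half, x$hill_n, x$residual_sse))
  invisible(x)
}

#' Titration curve container
#'
#' Bundles mean occupancy versus pH with replicate standard errors and the
#' Hill fit (computed on construction; degenerate curves are flagged with
#' a warning and carry `fit = NULL`).
#'
#' @param pH Numeric vector of pH values.
#' @param occupancy Mean protonated fraction per pH, in `[0, 1]`.
#' @param sem Optional replicate standard errors of the mean.
#' @param site Optional site id label.
#' @return An object of class `titration_curve` with fields `pH`,
#'   `occupancy`, `sem`, `site`, `fit` (a [hill_fit()] or NULL) and
#'   `degenerate`.
#' @export
titration_curve <- function(pH, occupancy, sem = NULL, site = NULL) {
  stopifnot(length(pH) == length(occupancy))
  if (any(occupancy < -1e-9 | occupancy > 1 + 1e-9))
    stop("occupancies must lie in [0, 1]", call. = FALSE)
  fit <- tryCatch(hill_fit(pH, occupancy),
                  error = function(e) {
                    warning(sprintf("fit-degenerate%s: %s",
                                    if (is.null(site)) "" else
                                      paste0(" [", site, "]"),
                                    conditionMessage(e)), call. = FALSE)
                    NULL
                  })
  structure(list(pH = pH, occupancy = occupancy, sem = sem, site = site,
                 fit = fit, degenerate = is.null(fit)),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  lab <- if (is.null(x$site)) "" else paste0(" ", x$site)
  if (x$degenerate) {
    cat(sprintf("<titration_curve%s: %d points, degenerate fit>\n",
                lab, length(x$pH)))
  } else {
    cat(sprintf("<titration_curve%s: pKa = %.3f, Hill n = %.3f>\n",
                lab, x$fit$pk_half, x$fit$hill_n))
  }
  invisible(x)
}

#' @export
as.data.frame.titration_curve <- function(x, ...) {
  data.frame(pH = x$pH, occupancy = x$occupancy,
             sem = if (is.null(x$sem)) NA_real_ else x$sem)
}
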