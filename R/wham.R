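# WHAM potential of mean force, bias re-weighting of observables, and the
# two error estimators (split-half PMF error, autocorrelation block SEM).

# Collect retained samples and bias parameters from a window list.
gather_windows <- function(windows, discard = NULL) {
  if (!length(windows)) stop("no windows supplied", call. = FALSE)
  has <- vapply(windows, function(w) !is.null(w$samples) &&
                  nrow(w$samples) > 0, TRUE)
  if (!all(has)) stop("all windows must carry samples", call. = FALSE)
  ord <- order(vapply(windows, `[[`, 0, "center"))
  windows <- windows[ord]
  list(windows = windows,
       z = lapply(windows, function(w) retained_rows(w$samples, discard)$z),
       data = lapply(windows, function(w) retained_rows(w$samples, discard)),
       center = vapply(windows, `[[`, 0, "center"),
       k = vapply(windows, `[[`, 0, "k"))
}

check_window_overlap <- function(g) {
  n <- length(g$z)
  if (n < 2) return(invisible())
  for (i in seq_len(n - 1)) {
    hi <- max(g$z[[i]]); lo <- min(g$z[[i + 1]])
    if (hi < lo)
      stop(sprintf(paste0("windows at %+0.3f and %+0.3f nm do not overlap ",
                          "(sampling gap %0.3f..%0.3f nm); WHAM cannot ",
                          "converge across the gap"),
                   g$center[i], g$center[i + 1], hi, lo), call. = FALSE)
  }
  invisible()
}

make_breaks <- function(z_all, bin_width) {
  lo <- floor(min(z_all) / bin_width) * bin_width
  seq(lo, max(z_all) + bin_width, by = bin_width)
}

# Bias energy (kT) of window i evaluated at coordinates z.
bias_kT <- function(z, center, k, kT_kJ) 0.5 * k / kT_kJ * (z - center)^2

# Bin-averaged Boltzmann factor of a harmonic bias: with stiff biases
# exp(-c) varies strongly across one histogram bin, and evaluating it at
# bin centers systematically distorts the profile. For harmonic biases
# the bin average has a closed form through the normal CDF.
bin_bias_factor <- function(breaks, center, k, kT_kJ) {
  w <- diff(breaks)
  if (k == 0) return(rep(1, length(w)))
  s <- sqrt(k / kT_kJ)  # 1/nm
  cdf <- stats::pnorm(s * (breaks - center))
  sqrt(2 * pi) / s * diff(cdf) / w
}

# Self-consistent WHAM iteration. Returns bin probabilities and window
# free-energy constants f (kT, f[1] = 0). `expc` holds the bin-averaged
# Boltzmann factors of the window biases.
wham_iterate <- function(H, expc, N, tol, max_iter) {
  f <- numeric(ncol(expc))
  h_tot <- rowSums(H)
  for (it in seq_len(max_iter)) {
    denom <- as.numeric(expc %*% (N * exp(f)))
    P <- ifelse(denom > 0, h_tot / denom, 0)
    P <- P / sum(P)
    fnew <- -log(as.numeric(crossprod(expc, P)))
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < tol) {
      return(list(P = P, f = fnew, iterations = it, residual = 0))
    }
    f <- fnew
  }
  stop(sprintf(paste0("WHAM did not converge in %d iterations ",
                      "(residual %.3g kT > tolerance %.3g kT)"),
               max_iter, max(abs(fnew - f)), tol), call. = FALSE)
}

#' Potential of mean force by WHAM
#'
#' Combines the biased coordinate histograms of all umbrella windows into
#' an unbiased free-energy profile with the weighted histogram analysis
#' method, iterating the self-consistent equations until every window
#' free-energy constant changes by less than `tol` kT. The profile is
#' anchored to zero over the bulk water region (mean over |z| >= `bulk_z`)
#' or, if no bins lie there, to its minimum.
#'
#' @param windows List of sampled [umbrella_window()] objects (see
#'   [sample_windows()]). A single unbiased window (k -> 0) degenerates to
#'   `-kT log(histogram)`.
#' @param bin_width Histogram bin width in nm (default 0.05, half the
#'   finest window spacing).
#' @param tol Convergence tolerance on the window constants in kT.
#' @param max_iter Maximum self-consistency iterations.
#' @param temperature Temperature in K (for kT and kcal/mol conversion).
#' @param anchor `"bulk"` (zero over |z| >= `bulk_z`), `"min"` (zero at
#'   the minimum) or `"none"`.
#' @param bulk_z Bulk anchor boundary in nm (default 3.5).
#' @param discard Equilibration fraction override (default: each
#'   trajectory's own).
#' @param min_count Bins with fewer total samples than this are reported
#'   as NA (default 5): a lone far-tail sample carries an enormous
#'   unbiasing weight and would otherwise corrupt the profile and its
#'   anchor.
#' @param breaks Optional explicit histogram breaks (internal use, e.g. to
#'   force a common grid between split halves).
#' @return A data frame of class `pmf_profile` with columns `z`, `G_kT`,
#'   `G_kcal`, `error_kT`, `error_kcal` (errors NA until filled by
#'   [split_half_pmf_error()]), and attributes `f` (window constants),
#'   `breaks`, `windows` (metadata table) and `settings`.
#' @export
wham <- function(windows, bin_width = 0.05, tol = 1e-6, max_iter = 5e4,
                 temperature = 310, anchor = c("bulk", "min", "none"),
                 bulk_z = 3.5, discard = NULL, min_count = 5,
                 breaks = NULL) {
  anchor <- match.arg(anchor)
  if (tol <= 0) stop("tolerance must be positive", call. = FALSE)
  g <- gather_windows(windows, discard)
  check_window_overlap(g)
  z_all <- unlist(g$z)
  if (is.null(breaks)) breaks <- make_breaks(z_all, bin_width)
  zc <- (head(breaks, -1) + tail(breaks, -1)) / 2
  H <- vapply(g$z, function(z)
    as.numeric(table(cut(z, breaks))), numeric(length(zc)))
  H <- matrix(H, nrow = length(zc))
  N <- colSums(H)
  kT_kJ <- kT_kJmol(temperature)
  expc <- vapply(seq_along(g$center), function(i)
    bin_bias_factor(breaks, g$center[i], g$k[i], kT_kJ),
    numeric(length(zc)))
  expc <- matrix(expc, nrow = length(zc))
  sol <- wham_iterate(H, expc, N, tol, max_iter)
  G <- -log(sol$P)
  G[rowSums(H) < min_count] <- NA_real_
  G <- anchor_profile(G, zc, anchor, bulk_z)
  kcal <- kT_kcalmol(temperature)
  out <- data.frame(z = zc, G_kT = G, G_kcal = G * kcal,
                    error_kT = NA_real_, error_kcal = NA_real_)
  attr(out, "f") <- sol$f
  attr(out, "breaks") <- breaks
  attr(out, "windows") <- windows_table(g$windows)
  attr(out, "settings") <- list(bin_width = bin_width, tol = tol,
                                temperature = temperature, anchor = anchor,
                                bulk_z = bulk_z, discard = discard,
                                iterations = sol$iterations)
  class(out) <- c("pmf_profile", "data.frame")
  out
}

anchor_profile <- function(G, zc, anchor, bulk_z) {
  fin <- is.finite(G)
  if (anchor == "none" || !any(fin)) return(G)
  if (anchor == "bulk") {
    idx <- fin & abs(zc) >= bulk_z
    if (any(idx)) return(G - mean(G[idx]))
    warning("no bins in the bulk anchor region; anchoring to the minimum",
            call. = FALSE)
  }
  G - min(G[fin])
}

#' @export
print.pmf_profile <- function(x, ...) {
  s <- attr(x, "settings")
  fin <- is.finite(x$G_kT)
  cat(sprintf(paste0("<pmf_profile: %d bins over [%.2f, %.2f] nm, ",
                     "range %.2f kT (%.2f kcal/mol), anchor '%s'>\n"),
              nrow(x), min(x$z), max(x$z),
              diff(range(x$G_kT[fin])), diff(range(x$G_kcal[fin])),
              s$anchor))
  invisible(x)
}

#' Helper: protonation observable of one site
#'
#' Returns a function mapping a trajectory data frame to the 0/1
#' protonation indicator of the given site, for use with
#' [reweight_observable()].
#'
#' @param id Site id.
#' @export
protonation_observable <- function(id) {
  col <- paste0("s_", id)
  function(d) as.numeric(d[[col]] > 0L)
}

#' Unbiased observable profile by re-weighting
#'
#' Computes the unbiased conditional mean of an observable along the
#' reaction coordinate from all umbrella windows, removing the harmonic
#' bias with WHAM weights: each sample from window i at coordinate z gets
#' weight `1 / sum_j N_j exp(f_j - c_j(z))`. With all biases zero this
#' reduces to the plain binned average. Empty bins are reported as
#' missing (NA), never interpolated.
#'
#' @inheritParams wham
#' @param observable Either a column name present in the window samples or
#'   a function mapping a sample data frame to a numeric vector (see
#'   [protonation_observable()]).
#' @param pmf Optional converged [wham()] result; computed internally when
#'   omitted. Its window constants, breaks and settings are reused.
#' @return A data frame of class `observable_profile` with columns `z`,
#'   `mean`, `sem` (weighted standard error using the effective sample
#'   size), `n_eff` and `n`.
#' @export
reweight_observable <- function(windows, observable, pmf = NULL,
                                bin_width = 0.05, temperature = 310,
                                discard = NULL, ...) {
  if (is.null(pmf))
    pmf <- wham(windows, bin_width = bin_width, temperature = temperature,
                discard = discard, ...)
  s <- attr(pmf, "settings")
  breaks <- attr(pmf, "breaks")
  f <- attr(pmf, "f")
  g <- gather_windows(windows, discard %||% s$discard)
  kT_kJ <- kT_kJmol(s$temperature)
  obs_fun <- if (is.function(observable)) observable
             else function(d) {
               if (!observable %in% names(d))
                 stop(sprintf("observable column '%s' not found",
                              observable), call. = FALSE)
               as.numeric(d[[observable]])
             }
  N <- vapply(g$z, length, 0L)
  z <- unlist(g$z)
  x <- unlist(lapply(g$data, obs_fun))
  stopifnot(length(x) == length(z))
  # WHAM denominator weight per sample
  denom <- rowSums(vapply(seq_along(g$center), function(j)
    N[j] * exp(f[j] - bias_kT(z, g$center[j], g$k[j], kT_kJ)),
    numeric(length(z))))
  w <- 1 / denom
  bin <- cut(z, breaks, labels = FALSE)
  zc <- (head(breaks, -1) + tail(breaks, -1)) / 2
  nb <- length(zc)
  out <- data.frame(z = zc, mean = NA_real_, sem = NA_real_,
                    n_eff = 0, n = 0L)
  keep <- !is.na(bin)
  bin <- bin[keep]; w <- w[keep]; x <- x[keep]
  sw <- tapply(w, bin, sum)
  swx <- tapply(w * x, bin, sum)
  idx <- as.integer(names(sw))
  m <- as.numeric(swx / sw)
  out$mean[idx] <- m
  mfull <- m[match(bin, idx)]
  sww <- tapply(w^2, bin, sum)
  svar <- as.numeric(tapply(w * (x - mfull)^2, bin, sum) / sw)
  n_eff <- as.numeric(sw)^2 / as.numeric(sww)
  out$n_eff[idx] <- n_eff
  out$n[idx] <- as.integer(table(factor(bin, levels = idx)))
  out$sem[idx] <- sqrt(svar / n_eff)
  class(out) <- c("observable_profile", "data.frame")
  attr(out, "settings") <- s
  out
}

#' Split-half PMF error
#'
#' Splits every window's production samples into two time segments,
#' computes an independently anchored PMF from each half on a common grid,
#' and reports `|G1(z) - G2(z)| / 2` as the per-point error. Anchoring
#' makes the estimator invariant to constant offsets between halves.
#'
#' @inheritParams wham
#' @return The full-data [wham()] profile with `error_kT` / `error_kcal`
#'   filled in (NA where either half has no estimate).
#' @export
split_half_pmf_error <- function(windows, bin_width = 0.05, tol = 1e-6,
                                 max_iter = 5e4, temperature = 310,
                                 anchor = c("bulk", "min", "none"),
                                 bulk_z = 3.5, discard = NULL,
                                 min_count = 5, breaks = NULL) {
  anchor <- match.arg(anchor)
  g <- gather_windows(windows, discard)
  half <- function(which_half) {
    lapply(g$windows, function(w) {
      d <- retained_rows(w$samples, discard)
      if (nrow(d) < 2)
        stop("each window needs at least 2 retained samples", call. = FALSE)
      n <- nrow(d)
      rows <- if (which_half == 1) seq_len(floor(n / 2))
              else (floor(n / 2) + 1L):n
      h <- d[rows, , drop = FALSE]
      attr(h, "equilibration_fraction") <- 0
      umbrella_window(w$center, w$k, w$segment, samples = h)
    })
  }
  full <- wham(windows, bin_width = bin_width, tol = tol,
               max_iter = max_iter, temperature = temperature,
               anchor = anchor, bulk_z = bulk_z, discard = discard,
               min_count = min_count, breaks = breaks)
  breaks <- attr(full, "breaks")
  g1 <- wham(half(1), bin_width = bin_width, tol = tol,
             max_iter = max_iter, temperature = temperature,
             anchor = anchor, bulk_z = bulk_z, min_count = min_count,
             breaks = breaks)
  g2 <- wham(half(2), bin_width = bin_width, tol = tol,
             max_iter = max_iter, temperature = temperature,
             anchor = anchor, bulk_z = bulk_z, min_count = min_count,
             breaks = breaks)
  err <- abs(g1$G_kT - g2$G_kT) / 2
  err[!is.finite(err)] <- NA_real_
  full$error_kT <- err
  full$error_kcal <- err * kT_kcalmol(temperature)
  full
}

#' Standard error of the mean from autocorrelation blocks
#'
#' Estimates the SEM of a correlated series: the first lag at which the
#' normalised autocorrelation function drops below `cutoff` defines the
#' block length, the series is cut into that many independent blocks
#' (block length capped at n/2 so at least two blocks remain), and the SEM
#' is the standard deviation of block means over sqrt(number of blocks).
#' A constant series returns SEM 0 with block length 1.
#'
#' @param series Numeric vector (length >= 10).
#' @param cutoff Autocorrelation cutoff defining independence
#'   (default 0.1).
#' @return A list with `sem`, `block_length`, `n_blocks` and `n`.
#' @export
autocorr_block_error <- function(series, cutoff = 0.1) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 10) stop("series must have at least 10 points", call. = FALSE)
  if (sd(series) == 0)
    return(list(sem = 0, block_length = 1L, n_blocks = n, n = n))
  max_lag <- floor(n / 2)
  # grow the examined lag window geometrically: most series decorrelate
  # after a few lags and a full n/2 correlogram would be quadratic in n
  lag_hi <- min(64L, max_lag)
  tau <- max_lag
  repeat {
    rho <- as.numeric(acf(series, lag.max = lag_hi, plot = FALSE,
                          demean = TRUE)$acf)[-1]
    below <- which(rho < cutoff)
    if (length(below)) {
      tau <- below[1]
      break
    }
    if (lag_hi >= max_lag) break
    lag_hi <- min(2L * lag_hi, max_lag)
  }
  tau <- max(1L, min(as.integer(tau), max_lag))
  n_blocks <- n %/% tau
  block_id <- rep(seq_len(n_blocks), each = tau)
  means <- tapply(series[seq_along(block_id)], block_id, mean)
  list(sem = sd(means) / sqrt(n_blocks),
       block_length = tau, n_blocks = as.integer(n_blocks), n = n)
}
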