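# Metropolis Monte Carlo sampling of protonation/tautomer microstates.

batch_means_sem <- function(x) {
  n <- length(x)
  if (n < 4 || sd(x) == 0) return(0)
  b <- max(2L, as.integer(floor(sqrt(n))))
  n_batches <- n %/% b
  id <- rep(seq_len(n_batches), each = b)
  means <- tapply(x[seq_along(id)], id, mean)
  sd(means) / sqrt(n_batches)
}

#' Sample protonation microstates by Metropolis Monte Carlo
#'
#' Samples the Boltzmann distribution of protonation/tautomer microstates
#' at fixed conformation and pH, attempting changes of individual sites and
#' of pairs of sites whose interactions are larger than
#' `settings$pair_threshold` pK units. One microstate is recorded per cycle
#' after burn-in. Per-site statistical errors are obtained with
#' [autocorr_block_error()] on the per-cycle occupancy indicator.
#'
#' @param sites List of [titratable_site()] objects.
#' @param couplings Optional [coupling_matrix()].
#' @param settings An [mc_settings()] object.
#' @param fixed_charges Optional co-moving fixed charges (see
#'   [microstate_energy()]).
#' @param init Optional integer vector of initial states (default: all
#'   deprotonated).
#' @return A list of class `mc_ensemble` with elements `states` (integer
#'   matrix, one recorded microstate per row), `occupancy`, `sem`
#'   (autocorrelation-block standard errors), `charge_mean`, move
#'   acceptance statistics, and the settings used.
#' @examples
#' s <- list(titratable_site("A", pk_int = 7))
#' r <- mc_sample(s, settings = mc_settings(n_cycles = 2000, pH = 7, seed = 1))
#' r$occupancy  # ~0.5 at pH = pK
#' @export
mc_sample <- function(sites, couplings = NULL, settings = mc_settings(),
                      fixed_charges = NULL, init = NULL) {
  check_sites(sites)
  stopifnot(inherits(settings, "mc_settings"))
  if (!is.null(settings$seed)) set.seed(settings$seed)
  e <- site_state_energies(sites, settings$pH, fixed_charges = fixed_charges)
  fc <- flatten_couplings(couplings)
  pairs <- eligible_pairs(couplings, settings$pair_threshold)
  if (is.null(init)) init <- integer(length(sites))
  check_state(sites, init)
  n_burn <- as.integer(floor(settings$burn_in * settings$n_cycles))
  res <- mc_kernel_cpp(e, vapply(sites, n_states, 1L),
                       fc$ci, fc$cj, fc$mat,
                       rbind(pairs) - 1L, settings$n_cycles, n_burn,
                       as.integer(init))
  colnames(res$states) <- site_ids(sites)
  occ_series <- res$states > 0L
  # batch means with ~sqrt(n) batches: a consistent MCMC error estimate
  # that stays honest for rarely flipping sites, where an empirical
  # autocorrelation cutoff can misjudge the block length
  sem <- vapply(seq_along(sites), function(i)
    batch_means_sem(as.numeric(occ_series[, i])), 0)
  qmat <- vapply(seq_along(sites),
                 function(i) sites[[i]]$charges[res$states[, i] + 1L],
                 numeric(nrow(res$states)))
  structure(
    list(states = res$states,
         occupancy = setNames(colMeans(occ_series), site_ids(sites)),
         sem = setNames(sem, site_ids(sites)),
         charge_mean = mean(rowSums(qmat)),
         n_recorded = nrow(res$states),
         single_attempts = res$single_attempts,
         single_accepts = res$single_accepts,
         pair_attempts = res$pair_attempts,
         pair_accepts = res$pair_accepts,
         eligible_pairs = pairs,
         settings = settings),
    class = "mc_ensemble")
}

#' @export
print.mc_ensemble <- function(x, ...) {
  cat(sprintf("<mc_ensemble: %d recorded cycles, %d site(s)>\n",
              x$n_recorded, length(x$occupancy)))
  print(round(x$occupancy, 4))
  invisible(x)
}

#' Write or read a microstate ensemble table
#'
#' Plain-text integer matrix, one recorded cycle per row, with a header
#' naming the sites.
#'
#' @param ensemble An `mc_ensemble` from [mc_sample()].
#' @param path File path.
#' @return `read_ensemble()` returns the integer state matrix.
#' @export
write_ensemble <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# uscphmd microstate ensemble v1",
               paste(colnames(ensemble$states), collapse = "\t")), con)
  write.table(ensemble$states, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  m <- as.matrix(read.table(text = body[-1], sep = "\t",
                            colClasses = "integer"))
  dimnames(m) <- list(NULL, header)
  m
}
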