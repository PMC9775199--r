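# Titratable sites, coupling matrices and Monte Carlo settings.
#
# State indexing convention (used everywhere, including the C++ kernels):
# state 0 is the deprotonated form; states 1..n_tautomers are the protonated
# tautomers. For an acid the deprotonated form carries -1 e and the
# protonated forms 0 e; for a base the deprotonated form is neutral and the
# protonated forms carry +1 e. The protonated/deprotonated charge difference
# is therefore exactly +1 e in both cases.

#' Create a titratable site
#'
#' A titratable site is one protonatable group with an intrinsic pK
#' (its pKmod: the reference pK that reproduces the experimental aqueous
#' pKa of the model compound), a set of protonated tautomers, and a spatial
#' attachment point in the co-moving frame of the substrate.
#'
#' With `n_tautomers` equivalent tautomers a degeneracy correction
#' `log(n_tautomers)` is applied to each protonated state so that the
#' site-level titration still follows Henderson-Hasselbalch with midpoint
#' `pk_int` when all tautomer offsets are zero. Individual tautomers can be
#' made inequivalent through `tautomer_dpk` (per-tautomer pK offsets).
#'
#' @param id Character label, unique within a system.
#' @param pk_int Intrinsic pK (pK units).
#' @param kind `"acid"` (deprotonated form -1 e) or `"base"` (protonated
#'   form +1 e).
#' @param n_tautomers Number of protonated tautomers (>= 1).
#' @param tautomer_dpk Numeric vector of per-tautomer pK offsets (positive
#'   values stabilise that tautomer).
#' @param position Attachment coordinate in nm, relative to the substrate
#'   reference point that rides the reaction coordinate.
#' @return An object of class `titratable_site`.
#' @examples
#' titratable_site("P3", pk_int = 6.5)                 # terminal phosphate
#' titratable_site("His", pk_int = 6.5, kind = "base", n_tautomers = 2)
#' @export
titratable_site <- function(id, pk_int, kind = c("acid", "base"),
                            n_tautomers = 1L,
                            tautomer_dpk = numeric(n_tautomers),
                            position = 0) {
  kind <- match.arg(kind)
  n_tautomers <- as.integer(n_tautomers)
  if (n_tautomers < 1L)
    stop("a site needs at least one protonated tautomer", call. = FALSE)
  if (length(tautomer_dpk) != n_tautomers)
    stop("tautomer_dpk must have one entry per tautomer", call. = FALSE)
  if (!is.finite(pk_int)) stop("pk_int must be finite", call. = FALSE)
  charges <- if (kind == "acid") c(-1, rep(0, n_tautomers))
             else c(0, rep(1, n_tautomers))
  structure(
    list(id = as.character(id), kind = kind, pk_int = pk_int,
         n_tautomers = n_tautomers, tautomer_dpk = as.numeric(tautomer_dpk),
         charges = charges, position = as.numeric(position)),
    class = "titratable_site")
}

#' @export
print.titratable_site <- function(x, ...) {
  cat(sprintf("<titratable_site %s: %s, pk_int = %.3f, %d tautomer(s)>\n",
              x$id, x$kind, x$pk_int, x$n_tautomers))
  invisible(x)
}

n_states <- function(site) 1L + site$n_tautomers

site_ids <- function(sites) vapply(sites, `[[`, "", "id")

check_sites <- function(sites) {
  if (!length(sites)) stop("empty site list", call. = FALSE)
  if (!all(vapply(sites, inherits, TRUE, "titratable_site")))
    stop("all sites must be titratable_site objects", call. = FALSE)
  ids <- site_ids(sites)
  if (anyDuplicated(ids)) stop("duplicate site ids", call. = FALSE)
  invisible(sites)
}

#' Pairwise site-site coupling matrix
#'
#' Holds the pairwise interaction free energies between protonation states
#' of different sites, in pK units (multiply by `log(10)` for kT). For each
#' ordered pair (i, j) with i < j a matrix of dimension
#' `n_states(i) x n_states(j)` is stored; symmetry under (i,j) <-> (j,i)
#' is enforced by construction (accessing the transposed pair returns the
#' transposed matrix). The diagonal (self) coupling is identically zero.
#'
#' @param sites List of [titratable_site()] objects.
#' @return An object of class `coupling_matrix` with all couplings zero.
#' @seealso [set_coupling()], [charge_coupling()], [couplings_from_geometry()]
#' @export
coupling_matrix <- function(sites) {
  check_sites(sites)
  structure(
    list(ids = site_ids(sites),
         n_states = vapply(sites, n_states, 1L),
         pairs = list()),
    class = "coupling_matrix")
}

pair_key <- function(i, j) paste0(i, ":", j)

#' Set or read one pairwise coupling
#'
#' `set_coupling()` assigns the full state-by-state coupling matrix for a
#' site pair; `coupling_pk()` reads it back (zero matrix if unset).
#' `charge_coupling()` is a convenience wrapper that fills the matrix as
#' `q_i(s_i) * q_j(s_j) * strength_pk`, i.e. a charge-product interaction
#' of the given strength (pK units per unit-charge pair).
#'
#' @param cm A [coupling_matrix()].
#' @param i,j Site indices (1-based, i != j).
#' @param pk Numeric matrix `n_states(i) x n_states(j)` in pK units, or a
#'   scalar recycled to all state pairs.
#' @return `set_coupling()` and `charge_coupling()` return the modified
#'   `coupling_matrix`; `coupling_pk()` returns a numeric matrix.
#' @export
set_coupling <- function(cm, i, j, pk) {
  stopifnot(inherits(cm, "coupling_matrix"))
  if (i == j) stop("self-coupling is identically zero", call. = FALSE)
  if (i > j) { tmp <- i; i <- j; j <- tmp; pk <- t(as.matrix(pk)) }
  ni <- cm$n_states[i]; nj <- cm$n_states[j]
  if (length(pk) == 1L) pk <- matrix(pk, ni, nj)
  pk <- as.matrix(pk)
  if (!all(dim(pk) == c(ni, nj)))
    stop(sprintf("coupling matrix for pair (%d,%d) must be %d x %d",
                 i, j, ni, nj), call. = FALSE)
  if (!all(is.finite(pk))) stop("couplings must be finite", call. = FALSE)
  cm$pairs[[pair_key(i, j)]] <- pk
  cm
}

#' @rdname set_coupling
#' @param sites The site list the matrix was built from (for state charges).
#' @param strength_pk Interaction strength in pK units between unit charges.
#' @export
charge_coupling <- function(cm, sites, i, j, strength_pk) {
  qi <- sites[[i]]$charges; qj <- sites[[j]]$charges
  set_coupling(cm, i, j, outer(qi, qj) * strength_pk)
}

#' @rdname set_coupling
#' @export
coupling_pk <- function(cm, i, j) {
  stopifnot(inherits(cm, "coupling_matrix"))
  if (i == j) return(matrix(0, cm$n_states[i], cm$n_states[i]))
  key <- if (i < j) pair_key(i, j) else pair_key(j, i)
  m <- cm$pairs[[key]]
  if (is.null(m)) return(matrix(0, cm$n_states[i], cm$n_states[j]))
  if (i < j) m else t(m)
}

# Flatten the stored pairs for the C++ kernels: 0-based indices + matrices.
flatten_couplings <- function(cm) {
  if (is.null(cm) || !length(cm$pairs))
    return(list(ci = integer(0), cj = integer(0), mat = list()))
  keys <- names(cm$pairs)
  ij <- do.call(rbind, lapply(strsplit(keys, ":", fixed = TRUE), as.integer))
  list(ci = ij[, 1] - 1L, cj = ij[, 2] - 1L, mat = unname(cm$pairs))
}

#' Pairs eligible for Monte Carlo pair moves
#'
#' A site pair is eligible for concerted pair moves when the magnitude of
#' any of its state-state couplings strictly exceeds `threshold`
#' (interactions larger than 2 pK units by default; ties at exactly the
#' threshold are excluded).
#'
#' @param cm A [coupling_matrix()].
#' @param threshold Eligibility threshold in pK units (default 2).
#' @return Integer matrix with one row per eligible pair (1-based indices),
#'   zero rows if none.
#' @export
eligible_pairs <- function(cm, threshold = 2) {
  if (is.null(cm) || !length(cm$pairs))
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  keys <- names(cm$pairs)
  keep <- vapply(cm$pairs, function(m) max(abs(m)) > threshold, TRUE)
  ij <- do.call(rbind, lapply(strsplit(keys[keep], ":", fixed = TRUE),
                              as.integer))
  if (is.null(ij)) ij <- matrix(integer(0), ncol = 2L)
  dimnames(ij) <- list(NULL, c("i", "j"))
  ij
}

#' Monte Carlo settings
#'
#' One MC cycle attempts, in uniformly random order, `n_sites + n_pairs`
#' elementary moves: single-site state changes and concerted pair moves for
#' the pairs selected by [eligible_pairs()]. On average each site and each
#' eligible pair is attempted once per cycle; drawing each move uniformly
#' from the combined move set makes the per-cycle transition kernel
#' reversible, so detailed balance holds exactly.
#'
#' @param n_cycles Number of MC cycles (default 1e5).
#' @param pair_threshold Pair-move eligibility threshold in pK units
#'   (default 2, strict inequality).
#' @param pH Solution pH.
#' @param seed Optional integer seed (applied with [set.seed()]).
#' @param burn_in Fraction of cycles discarded before recording
#'   (default 0.1).
#' @return An object of class `mc_settings`.
#' @export
mc_settings <- function(n_cycles = 1e5, pair_threshold = 2, pH = 7,
                        seed = NULL, burn_in = 0.1) {
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("n_cycles must be >= 1", call. = FALSE)
  if (pair_threshold < 0) stop("pair_threshold must be >= 0", call. = FALSE)
  if (burn_in < 0 || burn_in >= 1) stop("burn_in must be in [0, 1)",
                                        call. = FALSE)
  structure(list(n_cycles = n_cycles, pair_threshold = pair_threshold,
                 pH = pH, seed = seed, burn_in = burn_in),
            class = "mc_settings")
}

#' Total charge of a protonation microstate
#'
#' @param sites List of [titratable_site()] objects.
#' @param state Integer vector of per-site state indices (0 =
#'   deprotonated, 1..n_tautomers = protonated tautomers).
#' @return Total charge in elementary-charge units.
#' @export
microstate_charge <- function(sites, state) {
  check_state(sites, state)
  sum(vapply(seq_along(sites),
             function(i) sites[[i]]$charges[state[i] + 1L], 0))
}

check_state <- function(sites, state) {
  if (length(state) != length(sites))
    stop("state vector length must equal the number of sites", call. = FALSE)
  ns <- vapply(sites, n_states, 1L)
  bad <- which(state < 0L | state >= ns | state != floor(state))
  if (length(bad))
    stop(sprintf("invalid state %s for site '%s'", state[bad[1]],
                 sites[[bad[1]]]$id), call. = FALSE)
  invisible(state)
}
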