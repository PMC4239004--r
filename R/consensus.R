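# Iteratively refined consensus contact map of a decoy ensemble.

#' Consensus contact map from a list of contact maps
#'
#' Core of the consensus algorithm, operating on precomputed binary maps:
#' (1) M[i, j] = fraction of the currently selected decoys whose map has
#' contact (i, j); (2) threshold S = [M >= mu]; (3) re-select the
#' `ceiling(keep * n)` decoys of the *full* ensemble whose maps have the
#' smallest upper-triangle Hamming distance to S (ties broken by decoy
#' order). Iterate from the full ensemble until S is unchanged or `max_iter`
#' is reached. With fewer than 8 decoys a single averaging + thresholding
#' pass is performed (a 25% subset of so few decoys is degenerate).
#'
#' @param maps Non-empty list of [contact_map()] objects of equal size.
#' @param mu Consensus threshold on the contact fraction (default 0.25).
#' @param keep Fraction of decoys re-selected each iteration (default 0.25).
#' @param max_iter Iteration cap (default 20).
#' @return An object of class `consensus_state`: list with the fraction
#'   matrix `M`, the binary consensus [contact_map()] `S`, the indices of the
#'   currently `selected` decoys, the `iteration` count and a `converged`
#'   flag.
#' @export
consensus_from_maps <- function(maps, mu = 0.25, keep = 0.25, max_iter = 20L) {
  if (!length(maps)) stop("empty ensemble: no contact maps", call. = FALSE)
  stopifnot(all(vapply(maps, inherits, TRUE, "contact_map")),
            mu >= 0, mu <= 1, keep > 0, keep <= 1)
  n <- maps[[1]]$n
  if (!all(vapply(maps, function(x) x$n, 0L) == n))
    stop("contact maps have inconsistent sizes", call. = FALSE)
  ndec <- length(maps)
  ut <- upper.tri(maps[[1]]$contacts)
  bits <- vapply(maps, function(x) x$contacts[ut], logical(sum(ut)))  # |ut| x ndec

  threshold_map <- function(sel) {
    M <- rowMeans(bits[, sel, drop = FALSE])
    list(M = M, S = M >= mu)
  }
  as_state <- function(M, S, sel, it, conv) {
    Mfull <- Sfull <- matrix(0, n, n)
    Mfull[ut] <- M; Mfull <- Mfull + t(Mfull)
    Sfull[ut] <- S; Sfull <- Sfull + t(Sfull)
    Smap <- structure(list(n = n, contacts = Sfull > 0,
                           threshold = maps[[1]]$threshold,
                           min_sep = maps[[1]]$min_sep),
                      class = "contact_map")
    structure(list(M = Mfull, S = Smap, selected = sel,
                   iteration = it, converged = conv),
              class = "consensus_state")
  }

  sel <- seq_len(ndec)
  cur <- threshold_map(sel)
  if (ndec < 8L) return(as_state(cur$M, cur$S, sel, 1L, TRUE))

  nkeep <- ceiling(keep * ndec)
  for (it in seq_len(max_iter)) {
    ham <- colSums(bits != cur$S)               # Hamming to S on the upper triangle
    sel <- order(ham)[seq_len(nkeep)]           # order() breaks ties by index
    nxt <- threshold_map(sel)
    if (identical(nxt$S, cur$S))
      return(as_state(nxt$M, nxt$S, sel, it, TRUE))
    cur <- nxt
  }
  as_state(cur$M, cur$S, sel, max_iter, FALSE)
}

#' Consensus contact map of a decoy ensemble
#'
#' Computes each decoy's contact map at the given threshold and separation
#' filter and runs the iterative consensus of [consensus_from_maps()].
#'
#' @param e A [decoy_ensemble()].
#' @param mu Consensus threshold on the contact fraction (default 0.25).
#' @param keep Fraction of decoys re-selected each iteration (default 0.25).
#' @param max_iter Iteration cap (default 20).
#' @param threshold Contact distance threshold, Angstrom (default 9).
#' @param min_sep Minimum sequence separation (default 3).
#' @return A `consensus_state` (see [consensus_from_maps()]).
#' @export
consensus_contact_map <- function(e, mu = 0.25, keep = 0.25, max_iter = 20L,
                                  threshold = 9, min_sep = 3) {
  stopifnot(inherits(e, "decoy_ensemble"))
  maps <- lapply(e$decoys, contact_map, threshold = threshold,
                 min_sep = min_sep)
  consensus_from_maps(maps, mu = mu, keep = keep, max_iter = max_iter)
}

#' @export
print.consensus_state <- function(x, ...) {
  cat(sprintf(
    "<consensus_state> n=%d, %d consensus contacts, %d decoys selected, %s after %d iteration(s)\n",
    x$S$n, sum(x$S$contacts[upper.tri(x$S$contacts)]), length(x$selected),
    if (x$converged) "converged" else "not converged", x$iteration))
  invisible(x)
}
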