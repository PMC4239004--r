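# Uniform cubic B-spline basis for the pair potentials and the 210-pair
# amino-acid indexing.
#
# The basis has 12 uniform knots at 1, 2, ..., 12 Angstrom and exactly 8
# cubic (order-4) basis functions, each C2-continuous with compact support
# inside [1, 12]. The functions sum to 1 on [4, 9], so the potential shape
# is unconstrained there; between 1-4 and 9-12 Angstrom every spline decays
# smoothly to zero, and any pair farther than 12 Angstrom (or closer than
# 1 Angstrom) contributes no energy.

SPLINE_KNOTS <- 1:12
N_BASIS <- 8L
N_PAIR_TYPES <- 210L

#' Evaluate the 8 cubic B-spline basis functions
#'
#' @param d Numeric vector of C-alpha pair distances (Angstrom), `d >= 0`.
#' @return A `length(d)` x 8 matrix of basis values; all entries nonnegative,
#'   rows are zero for `d <= 1` or `d >= 12` and sum to 1 for `d` in [4, 9].
#' @export
#' @examples
#' rowSums(basis_eval(c(4, 6.5, 9)))   # partition of unity
#' basis_eval(13)                       # outside support: all zero
basis_eval <- function(d) {
  d <- as.numeric(d)
  stopifnot(all(d >= 0))
  out <- matrix(0, length(d), N_BASIS)
  inside <- d > SPLINE_KNOTS[1] & d < SPLINE_KNOTS[length(SPLINE_KNOTS)]
  if (any(inside))
    out[inside, ] <- splines::splineDesign(SPLINE_KNOTS, d[inside], ord = 4,
                                           outer.ok = TRUE)
  out
}

#' Index of an unordered amino-acid pair
#'
#' Bijection from the 210 unordered pairs of the 20 standard amino acids onto
#' 0..209, ordered lexicographically over sorted code pairs: (A,A) -> 0,
#' (A,C) -> 1, ..., (Y,Y) -> 209. Symmetric in its arguments.
#'
#' @param a,b One-letter amino-acid codes (vectorized, equal length).
#' @return Integer index in [0, 209] (add 1 to index the coefficient table).
#' @export
pair_index <- function(a, b) {
  ia <- match(toupper(a), AA_CODES) - 1L
  ib <- match(toupper(b), AA_CODES) - 1L
  if (anyNA(ia) || anyNA(ib))
    stop("non-standard amino-acid code in pair_index", call. = FALSE)
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  as.integer(lo * 20L - (lo * (lo - 1L)) %/% 2L + (hi - lo))
}
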