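# Native-decoy distance measures: RMSD, GDT-TS(*), Q(*), FlexE and MT.
#
# RMSD and GDT-TS* compare superposed coordinates (extrinsic); Q* and the
# elastic-network energies FlexE/MT compare intra-structure distances
# (intrinsic), so they are invariant under rigid motion by construction.

#' Elastic-network configuration for FlexE and MT
#'
#' @param k Force constant on every native contact spring (default 1).
#' @param b Shape parameter of the anharmonic (Toda-form) term (default 0.5).
#' @param contact_threshold Contact distance threshold in Angstrom (default 9).
#' @param min_sep Minimum sequence separation |i - j| counted (default 3);
#'   shorter-range C-alpha distances are fixed by covalent geometry.
#' @return An object of class `elastic_config`.
#' @export
elastic_config <- function(k = 1, b = 0.5, contact_threshold = 9, min_sep = 3) {
  stopifnot(k > 0, b > 0, contact_threshold > 0, min_sep >= 0)
  structure(list(k = k, b = b, contact_threshold = contact_threshold,
                 min_sep = as.integer(min_sep)),
            class = "elastic_config")
}

#' RMSD after optimal superposition
#'
#' @inheritParams superpose
#' @return Nonnegative RMSD in Angstrom.
#' @export
rmsd <- function(A, B) superpose(A, B)$rmsd

# squared deviations of B onto A under the optimal transform of the rows
# indexed by `sub`; returns per-residue distances over the full length
.sub_fit_dists <- function(ca, cb, sub) {
  k <- .kabsch(ca[sub, , drop = FALSE], cb[sub, , drop = FALSE])
  fitted <- sweep(cb %*% t(k$rotation), 2, k$translation, `+`)
  sqrt(rowSums((ca - fitted)^2))
}

#' GDT-TS similarity between two models
#'
#' For each cutoff c in 1, 2, 4, 8 Angstrom, finds the largest set of
#' residues that can be rigidly superposed within c, and averages the four
#' fractions. The maximal superposable subset is searched deterministically:
#' superpositions are seeded from every contiguous fragment of lengths 3, 5,
#' 7 and N (fragment starts strided by 2 when N > 200), and each seed is
#' refined by re-superposing on its inlier set at the cutoff until the inlier
#' set is stable (at most `max_refine` rounds). The count for a cutoff is the
#' maximum inlier count over all seeds.
#'
#' @inheritParams superpose
#' @param max_refine Maximum refinement rounds per seed and cutoff.
#' @return Similarity in [0, 1]; 1 when B is a rigid motion of A.
#' @export
gdt_ts <- function(A, B, max_refine = 10L) {
  ca <- if (inherits(A, "chain_model")) A$coords else as.matrix(A)
  cb <- if (inherits(B, "chain_model")) B$coords else as.matrix(B)
  if (nrow(ca) != nrow(cb))
    stop("gdt_ts: models have different lengths", call. = FALSE)
  n <- nrow(ca)
  if (n < 3L) stop("gdt_ts: need at least 3 residues", call. = FALSE)

  stride <- if (n > 200L) 2L else 1L
  seeds <- list(seq_len(n))
  for (len in c(3L, 5L, 7L)) {
    if (len > n) next
    for (s in seq.int(1L, n - len + 1L, by = stride))
      seeds[[length(seeds) + 1L]] <- seq.int(s, length.out = len)
  }

  cutoffs <- c(1, 2, 4, 8)
  best <- setNames(numeric(4), cutoffs)
  for (sub in seeds) {
    d0 <- .sub_fit_dists(ca, cb, sub)
    for (ci in seq_along(cutoffs)) {
      cut <- cutoffs[ci]
      inl <- which(d0 <= cut)
      cnt <- length(inl)
      prev <- integer(0)
      r <- 0L
      while (cnt >= 3L && !identical(inl, prev) && r < max_refine) {
        prev <- inl
        d <- .sub_fit_dists(ca, cb, inl)
        inl <- which(d <= cut)
        cnt <- max(cnt, length(inl))
        r <- r + 1L
      }
      if (cnt > best[ci]) best[ci] <- cnt
    }
  }
  mean(best / n)
}

#' GDT-TS* distance (1 - GDT-TS)
#' @inheritParams gdt_ts
#' @return Distance in [0, 1]; 0 when B is a rigid motion of A.
#' @export
gdt_ts_star <- function(A, B, max_refine = 10L) 1 - gdt_ts(A, B, max_refine)

#' Binary residue contact map
#'
#' `contacts[i, j] = 1` iff the C-alpha distance |x_i - x_j| is at most
#' `threshold` and the sequence separation |i - j| is at least `min_sep`.
#'
#' @param m A [chain_model()] or an N x 3 coordinate matrix.
#' @param threshold Contact distance threshold in Angstrom (default 9).
#' @param min_sep Minimum sequence separation counted (default 3).
#' @return An object of class `contact_map`: list with `n`, logical symmetric
#'   `contacts` matrix, `threshold`, `min_sep`.
#' @export
contact_map <- function(m, threshold = 9, min_sep = 3) {
  xyz <- if (inherits(m, "chain_model")) m$coords else as.matrix(m)
  n <- nrow(xyz)
  dm <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  cm <- dm <= threshold & sep >= min_sep
  dimnames(cm) <- NULL
  structure(list(n = n, contacts = cm, threshold = threshold,
                 min_sep = as.integer(min_sep)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> n=%d, %d contacts (threshold %g A, min_sep %d)\n",
              x$n, sum(x$contacts[upper.tri(x$contacts)]), x$threshold,
              x$min_sep))
  invisible(x)
}

#' Q* distance: fraction of native contacts lost
#'
#' With native contact set C_N and decoy contact set C_D (both at the same
#' threshold and separation filter), Q = |C_N intersect C_D| / |C_N| is the
#' fraction of native contacts retained and Q* = 1 - Q. Only the native's
#' contacts enter: contacts present in the decoy but not the native never
#' change Q*. A native with zero contacts yields Q = 1 (Q* = 0) by
#' convention, avoiding 0/0.
#'
#' @param native,decoy [chain_model()] objects of equal length.
#' @param threshold Contact threshold in Angstrom (default 9).
#' @param min_sep Minimum sequence separation (default 3).
#' @return Distance in [0, 1].
#' @export
q_star <- function(native, decoy, threshold = 9, min_sep = 3) {
  if (n_residues(native) != n_residues(decoy))
    stop("q_star: models have different lengths", call. = FALSE)
  cn <- contact_map(native, threshold, min_sep)$contacts
  cd <- contact_map(decoy, threshold, min_sep)$contacts
  ut <- upper.tri(cn)
  sc <- sum(cn[ut] & cd[ut])
  lc <- sum(cn[ut] & !cd[ut])
  if (sc + lc == 0L) return(0)   # Q := 1 for a contact-free native
  1 - sc / (sc + lc)
}

# per-pair distance deviations over the native contact map
.contact_deltas <- function(native, decoy, cfg) {
  if (n_residues(native) != n_residues(decoy))
    stop("elastic energy: models have different lengths", call. = FALSE)
  cm <- contact_map(native, cfg$contact_threshold, cfg$min_sep)$contacts
  ut <- upper.tri(cm) & cm
  dn <- as.matrix(stats::dist(native$coords))[ut]
  dd <- as.matrix(stats::dist(decoy$coords))[ut]
  dd - dn
}

#' FlexE: harmonic elastic-network deformation energy
#'
#' Places a spring of constant `k` on every pair in the *native* structure's
#' contact map and scores the decoy by the energetic cost of deforming those
#' pair distances: `sum (k/2) (d_ij^D - d_ij^N)^2`. Using the fixed native
#' contact map keeps the measure well defined for every native-decoy pair.
#'
#' @param native,decoy [chain_model()] objects of equal length.
#' @param cfg An [elastic_config()].
#' @return Nonnegative energy; 0 iff every native contact distance is
#'   preserved.
#' @export
flexe <- function(native, decoy, cfg = elastic_config()) {
  delta <- .contact_deltas(native, decoy, cfg)
  sum(cfg$k / 2 * delta^2)
}

#' MT: anharmonic (Toda-form) elastic deformation energy
#'
#' Same native-contact pair sum as [flexe()], with the harmonic term replaced
#' by the Toda-lattice form `(k/b^2) (exp(-b*delta) - 1 + b*delta)` where
#' `delta = d_ij^D - d_ij^N`. The term vanishes with zero slope at delta = 0,
#' its second-order Taylor expansion equals the harmonic `(k/2) delta^2`, so
#' MT matches FlexE for small perturbations, and for finite perturbations it
#' penalizes compression (delta < 0) more than extension.
#'
#' @inheritParams flexe
#' @return Nonnegative energy.
#' @export
mt <- function(native, decoy, cfg = elastic_config()) {
  delta <- .contact_deltas(native, decoy, cfg)
  sum(cfg$k / cfg$b^2 * (exp(-cfg$b * delta) - 1 + cfg$b * delta))
}

#' Distance-measure names understood by [measure()]
#' @export
DISTANCE_MEASURES <- c("RMSD", "GDT_TS_STAR", "Q_STAR", "MT", "FLEXE")

#' Compute a named native-decoy distance measure
#'
#' Dispatcher over the four distance measures (plus the harmonic FlexE).
#' All measures return 0 for `decoy = native`.
#'
#' @param native,decoy [chain_model()] objects of equal length.
#' @param which One of `"RMSD"`, `"GDT_TS_STAR"`, `"Q_STAR"`, `"MT"`,
#'   `"FLEXE"` (case-insensitive; `"gdt"`, `"q"` accepted as shorthands).
#' @param cfg An [elastic_config()]; also supplies the contact threshold and
#'   separation filter for Q*.
#' @return The distance value.
#' @export
measure <- function(native, decoy, which, cfg = elastic_config()) {
  key <- toupper(gsub("[-*]", "", which))
  key <- switch(key, GDT = , GDTTS = , GDTTSSTAR = "GDT_TS_STAR",
                Q = , QSTAR = "Q_STAR", key)
  switch(key,
    RMSD = rmsd(native, decoy),
    GDT_TS_STAR = gdt_ts_star(native, decoy),
    Q_STAR = q_star(native, decoy, cfg$contact_threshold, cfg$min_sep),
    MT = mt(native, decoy, cfg),
    FLEXE = flexe(native, decoy, cfg),
    stop("unknown distance measure: ", which, call. = FALSE))
}
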