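# Two-step ensemble preprocessing: residue-level filtering, then trailing
# trimming until native and decoys share one identical sequence.

#' Drop residues with an incomplete backbone
#'
#' Keeps exactly the residues whose `backbone_complete` flag is `TRUE`,
#' preserving order. Idempotent.
#'
#' @param m A [chain_model()].
#' @return A [chain_model()] containing only complete residues.
#' @export
drop_incomplete_residues <- function(m) {
  stopifnot(inherits(m, "chain_model"))
  keep <- m$backbone_complete
  if (!any(keep))
    stop("empty model: no residues with a complete backbone in '", m$id, "'",
         call. = FALSE)
  if (all(keep)) return(m)
  chain_model(m$id, m$seq[keep], m$coords[keep, , drop = FALSE],
              m$backbone_complete[keep])
}

# Best end-gapped identity alignment of two sequences: over all relative
# offsets, the overlap must match exactly (mismatches are forbidden, only
# leading/trailing gaps are allowed). Returns the kept index ranges, or NULL
# when every offset has an internal mismatch.
.end_gap_align <- function(a, b) {
  na <- length(a); nb <- length(b)
  best <- NULL; best_len <- 0L
  for (off in (-(nb - 1L)):(na - 1L)) {   # index shift of b relative to a
    ia <- max(1L, 1L + off); ib <- ia - off
    len <- min(na - ia, nb - ib) + 1L
    if (len <= 0L || len <= best_len) next
    sa <- seq.int(ia, length.out = len)
    sb <- seq.int(ib, length.out = len)
    if (all(a[sa] == b[sb])) { best <- list(a = sa, b = sb); best_len <- len }
  }
  best
}

.subset_model <- function(m, idx) {
  chain_model(m$id, m$seq[idx], m$coords[idx, , drop = FALSE],
              m$backbone_complete[idx])
}

#' Harmonize a native model with its decoys
#'
#' Aligns each decoy sequence against the native under a scoring that forbids
#' internal edits (identity match, no mismatches, end gaps only) and trims the
#' unmatched leading/trailing residues from whichever side carries them. The
#' trim is iterated across decoys until the native and every decoy share one
#' identical sequence. A decoy whose best alignment still requires an internal
#' mismatch or gap raises an error naming the decoy: residue substitutions
#' cannot be resolved by trimming.
#'
#' @param native A [chain_model()]; incomplete residues should already have
#'   been removed with [drop_incomplete_residues()].
#' @param decoys List of [chain_model()] objects, same preprocessing.
#' @param provenance Free text recorded on the ensemble.
#' @return A [decoy_ensemble()] whose models all share one sequence.
#' @export
harmonize_ensemble <- function(native, decoys, provenance = "") {
  stopifnot(inherits(native, "chain_model"))
  if (!is.list(decoys) || !length(decoys))
    stop("need at least one decoy", call. = FALSE)
  nat <- native
  dec <- decoys
  repeat {
    changed <- FALSE
    for (k in seq_along(dec)) {
      if (identical(dec[[k]]$seq, nat$seq)) next
      al <- .end_gap_align(nat$seq, dec[[k]]$seq)
      if (is.null(al))
        stop("harmonization error: decoy '", dec[[k]]$id,
             "' has an internal mismatch or gap against the native sequence",
             call. = FALSE)
      if (length(al$a) < length(nat$seq)) { nat <- .subset_model(nat, al$a); changed <- TRUE }
      if (length(al$b) < length(dec[[k]]$seq)) dec[[k]] <- .subset_model(dec[[k]], al$b)
      if (!identical(dec[[k]]$seq, nat$seq)) changed <- TRUE
    }
    if (!changed) break
  }
  if (length(nat$seq) == 0L)
    stop("harmonization error: empty common sequence", call. = FALSE)
  decoy_ensemble(nat, dec, provenance)
}
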