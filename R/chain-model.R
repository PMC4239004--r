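# Core containers: a single C-alpha model and a native + decoys ensemble.

#' The 20 standard amino acids, one-letter codes, alphabetical order
#'
#' @format Character vector of length 20.
#' @export
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a C-alpha chain model
#'
#' A `chain_model` holds one structural model of a protein reduced to its
#' C-alpha trace: a one-letter amino-acid sequence, the ordered C-alpha
#' coordinates in Angstrom, and a per-residue flag recording whether the full
#' backbone (N, CA, C, O) was present in the source coordinates. The flag
#' drives [drop_incomplete_residues()].
#'
#' @param id Character label for the model.
#' @param seq Character vector of one-letter amino-acid codes (length N).
#' @param coords Numeric N x 3 matrix of C-alpha positions (Angstrom).
#' @param backbone_complete Logical vector of length N; defaults to all `TRUE`.
#' @return An object of class `chain_model`.
#' @export
#' @examples
#' m <- chain_model("toy", c("A", "G", "L"), cbind(0:2 * 3.8, 0, 0))
#' m$seq
chain_model <- function(id, seq, coords, backbone_complete = NULL) {
  seq <- toupper(as.character(seq))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(backbone_complete)) backbone_complete <- rep(TRUE, length(seq))
  n <- length(seq)
  if (n == 0L) stop("empty model: no residues with a C-alpha atom", call. = FALSE)
  if (ncol(coords) != 3L || nrow(coords) != n)
    stop("coords must be an N x 3 matrix matching the sequence length", call. = FALSE)
  if (length(backbone_complete) != n)
    stop("backbone_complete must have one flag per residue", call. = FALSE)
  bad <- setdiff(unique(seq), AA_CODES)
  if (length(bad))
    stop("non-standard residue code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite", call. = FALSE)
  structure(
    list(id = as.character(id)[1], seq = seq, coords = unname(coords),
         backbone_complete = as.logical(backbone_complete)),
    class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("<chain_model> %s: %d residues, %d with complete backbone\n",
              x$id, length(x$seq), sum(x$backbone_complete)))
  cat(" seq: ", paste(utils::head(x$seq, 40), collapse = ""),
      if (length(x$seq) > 40) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of residues in a chain model
#' @param m A [chain_model()].
#' @return Integer residue count.
#' @export
n_residues <- function(m) {
  stopifnot(inherits(m, "chain_model"))
  length(m$seq)
}

#' Construct a native + decoys ensemble
#'
#' Checks the harmonization contract: every decoy must have the same length
#' and the same sequence as the native. Use [harmonize_ensemble()] to bring
#' raw models into this state.
#'
#' @param native A [chain_model()].
#' @param decoys List of [chain_model()] objects (at least one).
#' @param provenance Free-text description of where the models came from.
#' @return An object of class `decoy_ensemble`.
#' @export
decoy_ensemble <- function(native, decoys, provenance = "") {
  stopifnot(inherits(native, "chain_model"))
  if (!is.list(decoys) || length(decoys) < 1L)
    stop("an ensemble needs at least one decoy", call. = FALSE)
  for (d in decoys) {
    stopifnot(inherits(d, "chain_model"))
    if (!identical(d$seq, native$seq))
      stop("decoy '", d$id, "' does not match the native sequence; ",
           "harmonize the ensemble first", call. = FALSE)
  }
  structure(list(native = native, decoys = decoys,
                 provenance = as.character(provenance)[1]),
            class = "decoy_ensemble")
}

#' @export
print.decoy_ensemble <- function(x, ...) {
  cat(sprintf("<decoy_ensemble> native %s (N=%d), %d decoys\n",
              x$native$id, length(x$native$seq), length(x$decoys)))
  if (nzchar(x$provenance)) cat(" provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
length.decoy_ensemble <- function(x) length(x$decoys)
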