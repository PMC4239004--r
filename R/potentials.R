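# The spline pair potentials: PPD (all residue pairs of a single model) and
# PPE (pairs restricted to an ensemble's consensus contact map).

#' Construct a potential parameter table
#'
#' The coefficient table theta of the pair potential: one row per unordered
#' amino-acid pair (210, ordered as in [pair_index()]), one column per spline
#' basis function (8), 1680 parameters in total.
#'
#' @param theta Numeric 210 x 8 matrix (or a length-1680 vector, filled
#'   column-major).
#' @param measure Name of the distance measure the potential was trained to
#'   mimic (metadata).
#' @param beta Regularization weight used in training (metadata).
#' @param mode `"PPD"` or `"PPE"` (metadata).
#' @param min_sep Sequence-separation filter the potential was trained with.
#' @return An object of class `potential_params`.
#' @export
potential_params <- function(theta, measure = NA_character_, beta = NA_real_,
                             mode = "PPD", min_sep = 3L) {
  if (is.null(dim(theta))) {
    if (length(theta) != N_PAIR_TYPES * N_BASIS)
      stop("theta must hold exactly 210 x 8 = 1680 coefficients", call. = FALSE)
    theta <- matrix(as.numeric(theta), N_PAIR_TYPES, N_BASIS)
  }
  theta <- as.matrix(theta)
  if (!all(dim(theta) == c(N_PAIR_TYPES, N_BASIS)))
    stop("theta must be a 210 x 8 matrix", call. = FALSE)
  if (!all(is.finite(theta)))
    stop("theta must be finite", call. = FALSE)
  storage.mode(theta) <- "double"
  structure(list(theta = unname(theta),
                 measure = as.character(measure)[1],
                 beta = as.numeric(beta)[1],
                 mode = match.arg(toupper(mode), c("PPD", "PPE")),
                 min_sep = as.integer(min_sep)),
            class = "potential_params")
}

#' @export
print.potential_params <- function(x, ...) {
  cat(sprintf("<potential_params> %s, 210 x 8 coefficients (|theta| = %.4g)\n",
              x$mode, sqrt(sum(x$theta^2))))
  if (!is.na(x$measure)) cat(" trained on:", x$measure, "| beta:", x$beta, "\n")
  invisible(x)
}

# all pairs i < j with j - i >= min_sep, as a 2-column index matrix
.counted_pairs <- function(n, min_sep) {
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij <- ij[ij[, 2] - ij[, 1] >= min_sep, , drop = FALSE]
  colnames(ij) <- c("i", "j")
  ij
}

# accumulate basis values of the given residue pairs into the 210 x 8 feature
# table F(m): energy is then sum(F * theta) for any theta (linearity)
.pair_features <- function(m, pairs) {
  F <- matrix(0, N_PAIR_TYPES, N_BASIS)
  if (nrow(pairs) == 0L) return(F)
  dvec <- sqrt(rowSums((m$coords[pairs[, 1], , drop = FALSE] -
                        m$coords[pairs[, 2], , drop = FALSE])^2))
  B <- basis_eval(dvec)
  grp <- pair_index(m$seq[pairs[, 1]], m$seq[pairs[, 2]]) + 1L
  acc <- rowsum(B, group = grp)
  F[as.integer(rownames(acc)), ] <- acc
  F
}

#' PPD energy of a single model
#'
#' Sums the spline pair potential over every residue pair (i, j) with
#' sequence separation at least `min_sep`:
#' `E = sum_pairs sum_p theta[pair_index(a_i, a_j), p] * B_p(d_ij)`.
#' The energy depends only on intra-model distances, so it is invariant
#' under rigid motion, and it is linear in theta.
#'
#' @param m A [chain_model()].
#' @param params A [potential_params()].
#' @param min_sep Sequence-separation filter; defaults to the value recorded
#'   in `params`.
#' @return Scalar energy (arbitrary units).
#' @export
energy_ppd <- function(m, params, min_sep = params$min_sep) {
  stopifnot(inherits(m, "chain_model"), inherits(params, "potential_params"))
  sum(.pair_features(m, .counted_pairs(n_residues(m), min_sep)) * params$theta)
}

#' PPE energy of a model against a consensus contact map
#'
#' Same spline pair sum as [energy_ppd()], restricted to the pairs flagged in
#' the consensus contact map `S` (see [consensus_contact_map()]). Reduces to
#' PPD when `S` contains every separation-filtered pair.
#'
#' @param m A [chain_model()].
#' @param params A [potential_params()].
#' @param S A [contact_map()] of the same size as `m`.
#' @return Scalar energy.
#' @export
energy_ppe <- function(m, params, S) {
  stopifnot(inherits(m, "chain_model"), inherits(params, "potential_params"),
            inherits(S, "contact_map"))
  if (S$n != n_residues(m))
    stop("energy_ppe: contact map size does not match the model", call. = FALSE)
  ij <- which(upper.tri(S$contacts) & S$contacts, arr.ind = TRUE)
  sum(.pair_features(m, ij) * params$theta)
}

#' Write potential parameters as TSV
#'
#' Long format with columns `aa1`, `aa2`, `p` (basis index 0..7) and `theta`;
#' values are written at full precision so a write/read round trip is
#' bit-exact.
#'
#' @param params A [potential_params()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_potential_tsv <- function(params, path) {
  stopifnot(inherits(params, "potential_params"))
  pairs <- t(utils::combn(AA_CODES, 2))
  pairs <- rbind(cbind(AA_CODES, AA_CODES), pairs)
  ord <- order(pair_index(pairs[, 1], pairs[, 2]))
  pairs <- pairs[ord, , drop = FALSE]
  df <- data.frame(aa1 = rep(pairs[, 1], each = N_BASIS),
                   aa2 = rep(pairs[, 2], each = N_BASIS),
                   p = rep(0:(N_BASIS - 1L), N_PAIR_TYPES),
                   theta = sprintf("%.17g", as.vector(t(params$theta))))
  header <- sprintf("# funnelpot potential: mode=%s measure=%s beta=%s min_sep=%d",
                    params$mode, params$measure,
                    format(params$beta, digits = 17), params$min_sep)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read potential parameters from TSV
#'
#' @param path Path written by [write_potential_tsv()].
#' @return A [potential_params()].
#' @export
read_potential_tsv <- function(path) {
  lines <- readLines(path, n = 1L)
  meta <- list(mode = "PPD", measure = NA_character_, beta = NA_real_,
               min_sep = 3L)
  if (startsWith(lines[1], "#")) {
    kv <- regmatches(lines[1], gregexpr("[a-z_]+=[^ ]+", lines[1]))[[1]]
    for (item in kv) {
      key <- sub("=.*", "", item); val <- sub(".*=", "", item)
      if (key == "mode") meta$mode <- val
      if (key == "measure") meta$measure <- val
      if (key == "beta") meta$beta <- suppressWarnings(as.numeric(val))
      if (key == "min_sep") meta$min_sep <- as.integer(val)
    }
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = c("character", "character", "integer",
                                         "numeric"))
  if (nrow(df) != N_PAIR_TYPES * N_BASIS)
    stop("potential file must hold exactly 1680 coefficient rows, found ",
         nrow(df), call. = FALSE)
  theta <- matrix(0, N_PAIR_TYPES, N_BASIS)
  theta[cbind(pair_index(df$aa1, df$aa2) + 1L, df$p + 1L)] <- df$theta
  potential_params(theta, measure = meta$measure, beta = meta$beta,
                   mode = meta$mode, min_sep = meta$min_sep)
}

#' Write potential parameters as JSON
#' @param params A [potential_params()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_potential_json <- function(params, path) {
  stopifnot(inherits(params, "potential_params"))
  obj <- list(mode = params$mode, measure = params$measure, beta = params$beta,
              min_sep = params$min_sep,
              theta = matrix(sprintf("%.17g", params$theta), N_PAIR_TYPES))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read potential parameters from JSON
#' @param path Path written by [write_potential_json()].
#' @return A [potential_params()].
#' @export
read_potential_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- matrix(as.numeric(obj$theta), N_PAIR_TYPES, N_BASIS)
  potential_params(theta, measure = obj$measure,
                   beta = as.numeric(obj$beta), mode = obj$mode,
                   min_sep = as.integer(obj$min_sep))
}
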