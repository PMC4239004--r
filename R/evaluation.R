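# Evaluation: energy-distance Pearson correlation, the R-score, distance
# vs distance comparison, and mean / mean-absolute-deviation summaries.

#' Pearson correlation with a defined-ness flag
#'
#' Standard product-moment correlation over a decoy set. When either input
#' has zero variance the correlation is undefined and `NA` is returned
#' (a flag, not an error), so degenerate ensembles are reported rather than
#' crashing a batch run.
#'
#' @param x,y Equal-length numeric vectors, length >= 2.
#' @return Correlation in [-1, 1], or `NA` when undefined.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Mean absolute deviation around the mean
#'
#' The l1 dispersion `mean(|x - mean(x)|)`, used instead of the standard
#' deviation to limit the influence of outliers.
#'
#' @param x Numeric vector.
#' @return Nonnegative scalar.
#' @export
mad_l1 <- function(x) mean(abs(x - mean(x)))

#' R-score of an energy function against a distance measure
#'
#' Let s_E be the decoy with the lowest energy and s_d the decoy with the
#' smallest distance to the native (ties broken by first index). The R-score
#' is `(mean(d) - d[s_E]) / (mean(d) - d[s_d])`, clamped below at -1 so that
#' a single outlier decoy cannot produce an arbitrarily negative score. It is
#' 1 when the energy picks the best decoy, 0 is the random expectation on an
#' outlier-free ensemble, and it equals the ratio of the distance z-scores of
#' the best-energy and best-distance models. Depends on E only through its
#' argmin, so it is invariant to strictly increasing transforms of E.
#'
#' @param E Per-decoy energies (or any pseudo-energy, e.g. a second distance
#'   measure).
#' @param d Per-decoy distances to the native.
#' @return Value in [-1, 1], or `NA` when all distances are equal.
#' @export
r_score <- function(E, d) {
  stopifnot(length(E) == length(d), length(d) >= 2L)
  s_E <- which.min(E)
  s_d <- which.min(d)
  denom <- mean(d) - d[s_d]
  if (denom == 0) return(NA_real_)
  max(-1, (mean(d) - d[s_E]) / denom)
}

#' Evaluate a trained potential on an ensemble
#'
#' Computes every decoy's energy once (PPD, or PPE against the ensemble's
#' recomputed consensus contact map) and, for each requested distance
#' measure, the energy-distance Pearson correlation, the R-score, and the
#' identities of the best-by-energy and best-by-distance decoys.
#'
#' @param params A [potential_params()].
#' @param e A harmonized [decoy_ensemble()].
#' @param mode `"PPD"` or `"PPE"`; defaults to the mode recorded in `params`.
#' @param measures Character vector of distance-measure names (see
#'   [measure()]).
#' @param cfg An [elastic_config()].
#' @return A data.frame with one row per measure: `ensemble_id`, `measure`,
#'   `corr`, `r_score`, `best_by_energy`, `best_by_distance`, `d_mean`.
#'   Undefined correlations / R-scores appear as `NA`.
#' @export
evaluate_energy <- function(params, e, mode = params$mode,
                            measures = c("RMSD", "GDT_TS_STAR", "Q_STAR", "MT"),
                            cfg = elastic_config()) {
  stopifnot(inherits(params, "potential_params"), inherits(e, "decoy_ensemble"))
  mode <- match.arg(toupper(mode), c("PPD", "PPE"))
  ids <- vapply(e$decoys, function(x) x$id, character(1))
  E <- if (mode == "PPE") {
    S <- consensus_contact_map(e, threshold = cfg$contact_threshold,
                               min_sep = cfg$min_sep)$S
    vapply(e$decoys, energy_ppe, numeric(1), params = params, S = S)
  } else {
    vapply(e$decoys, energy_ppd, numeric(1), params = params)
  }
  out <- lapply(measures, function(ms) {
    d <- vapply(e$decoys, function(dec) measure(e$native, dec, ms, cfg),
                numeric(1))
    data.frame(ensemble_id = e$native$id, measure = toupper(ms),
               corr = pearson(E, d), r_score = r_score(E, d),
               best_by_energy = ids[which.min(E)],
               best_by_distance = ids[which.min(d)],
               d_mean = mean(d))
  })
  do.call(rbind, out)
}

#' Compare two distance measures on an ensemble
#'
#' Treats each measure in turn as a pseudo energy for the other: reports the
#' Pearson correlation of the two per-decoy distance vectors and the two
#' (generally asymmetric) R-scores `r12 = R(d1, E = d2)` and
#' `r21 = R(d2, E = d1)`.
#'
#' @param e A harmonized [decoy_ensemble()] with at least 2 decoys.
#' @param d1,d2 Distance-measure names (see [measure()]).
#' @param cfg An [elastic_config()].
#' @return List with `corr`, `r12`, `r21`.
#' @export
compare_distances <- function(e, d1, d2, cfg = elastic_config()) {
  stopifnot(inherits(e, "decoy_ensemble"), length(e$decoys) >= 2L)
  v1 <- vapply(e$decoys, function(dec) measure(e$native, dec, d1, cfg),
               numeric(1))
  v2 <- vapply(e$decoys, function(dec) measure(e$native, dec, d2, cfg),
               numeric(1))
  list(corr = pearson(v1, v2), r12 = r_score(E = v2, d = v1),
       r21 = r_score(E = v1, d = v2))
}

#' All-pairs distance comparison matrices for an ensemble
#'
#' @param e A harmonized [decoy_ensemble()].
#' @param measures Distance-measure names (default the four paper measures).
#' @param cfg An [elastic_config()].
#' @return List of two `length(measures)` square matrices: `corr` (symmetric)
#'   and `r` (`r[i, j]` = R-score of measure i with measure j as pseudo
#'   energy); both have unit diagonal for non-degenerate ensembles.
#' @export
compare_distance_matrix <- function(e,
                                    measures = c("RMSD", "MT", "GDT_TS_STAR",
                                                 "Q_STAR"),
                                    cfg = elastic_config()) {
  stopifnot(inherits(e, "decoy_ensemble"), length(e$decoys) >= 2L)
  vals <- lapply(measures, function(ms)
    vapply(e$decoys, function(dec) measure(e$native, dec, ms, cfg),
           numeric(1)))
  k <- length(measures)
  corr <- r <- matrix(NA_real_, k, k, dimnames = list(measures, measures))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    corr[i, j] <- pearson(vals[[i]], vals[[j]])
    r[i, j] <- r_score(E = vals[[j]], d = vals[[i]])
  }
  list(corr = corr, r = r)
}

#' Aggregate evaluation records by group
#'
#' Summarizes `corr` and `r_score` per group as mean and mean absolute
#' deviation ([mad_l1()]), mirroring the "value (mad)" reporting convention.
#' Records with an undefined (NA) value are excluded and counted.
#'
#' @param records Data.frame as returned by (rbinding) [evaluate_energy()].
#' @param by Name of the grouping column (default `"measure"`).
#' @return Data.frame with one row per group and statistic: `group`, `stat`,
#'   `mean`, `mad`, `n`, `n_excluded`.
#' @export
aggregate_records <- function(records, by = "measure") {
  stopifnot(is.data.frame(records), by %in% names(records))
  out <- list()
  for (g in unique(records[[by]])) {
    sub <- records[records[[by]] == g, , drop = FALSE]
    for (stat in c("corr", "r_score")) {
      v <- sub[[stat]]
      ok <- !is.na(v)
      out[[length(out) + 1L]] <- data.frame(
        group = g, stat = stat,
        mean = if (any(ok)) mean(v[ok]) else NA_real_,
        mad = if (any(ok)) mad_l1(v[ok]) else NA_real_,
        n = sum(ok), n_excluded = sum(!ok))
    }
  }
  do.call(rbind, out)
}
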