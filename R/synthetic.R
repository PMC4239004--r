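# Synthetic decoy ensembles: self-avoiding compact C-alpha walks, noise-
# perturbed decoys, and planted energy-distance funnels for recovery tests.

#' Configuration for the synthetic decoy generator
#'
#' @param n_res Chain length (>= 5).
#' @param n_decoys Number of decoys per ensemble.
#' @param noise_grid Per-coordinate Gaussian noise levels sigma (Angstrom);
#'   decoys are split evenly across the grid. Default `c(1, 2, 4)` spans
#'   near-native to clearly non-native perturbations.
#' @param bond_length Consecutive C-alpha spacing (Angstrom, default 3.8).
#' @param min_clash Minimum distance between non-adjacent residues in the
#'   native walk (default 4).
#' @param seed Integer seed; fixes the full output stream.
#' @param sequence Optional fixed one-letter sequence of length `n_res`;
#'   default a random standard-amino-acid sequence drawn from the seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_res = 40L, n_decoys = 100L, noise_grid = c(1, 2, 4),
                         bond_length = 3.8, min_clash = 4.0, seed = 1L,
                         sequence = NULL) {
  stopifnot(n_res >= 5L, n_decoys >= 1L, all(noise_grid >= 0),
            bond_length > 0, min_clash > 0)
  if (!is.null(sequence)) stopifnot(length(sequence) == n_res)
  structure(list(n_res = as.integer(n_res), n_decoys = as.integer(n_decoys),
                 noise_grid = as.numeric(noise_grid),
                 bond_length = bond_length, min_clash = min_clash,
                 seed = as.integer(seed), sequence = sequence),
            class = "synth_config")
}

# compact self-avoiding walk; returns n x 3 matrix or NULL if stuck
.try_walk <- function(n, bond, clash, r_target, max_step_tries = 60L) {
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    placed <- FALSE
    centroid <- colMeans(xyz[1:(i - 1), , drop = FALSE])
    away <- sqrt(sum((xyz[i - 1, ] - centroid)^2))
    pull <- 0.6 * max(0, away / r_target - 0.5)   # steer back toward the core
    for (try in seq_len(max_step_tries)) {
      u <- stats::rnorm(3)
      bias <- centroid - xyz[i - 1, ]
      nb <- sqrt(sum(bias^2))
      if (nb > 0) u <- u + pull * bias / nb * sqrt(3)
      u <- u / sqrt(sum(u^2))
      cand <- xyz[i - 1, ] + bond * u
      if (i <= 2L) { xyz[i, ] <- cand; placed <- TRUE; break }
      dmin <- min(sqrt(rowSums(sweep(xyz[1:(i - 2), , drop = FALSE], 2,
                                     cand)^2)))
      if (dmin >= clash) { xyz[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed) return(NULL)
  }
  xyz
}

#' Generate a synthetic native C-alpha chain
#'
#' A self-avoiding random walk with exact consecutive spacing
#' `bond_length`, all non-adjacent pairs at least `min_clash` apart, and a
#' compactness bias: steps are steered toward the running centroid and whole
#' walks are rejected until the radius of gyration is below a bound scaling
#' as `n^(1/3)` (globular scaling). Compact chains are required because
#' stretched ones carry almost no contacts and give the contact-based
#' measures nothing to work with.
#'
#' @param cfg A [synth_config()]; `cfg$seed` fixes the output bit-exactly.
#' @param id Model label.
#' @return A [chain_model()].
#' @export
gen_native <- function(cfg, id = sprintf("synth%d", cfg$seed)) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  seqs <- if (is.null(cfg$sequence))
    sample(AA_CODES, cfg$n_res, replace = TRUE) else toupper(cfg$sequence)
  r_target <- 2.7 * cfg$n_res^(1 / 3)
  rg_max <- 1.15 * r_target
  for (restart in seq_len(500L)) {
    xyz <- .try_walk(cfg$n_res, cfg$bond_length, cfg$min_clash, r_target)
    if (is.null(xyz)) next
    cen <- colMeans(xyz)
    rg <- sqrt(mean(rowSums(sweep(xyz, 2, cen)^2)))
    if (rg <= rg_max)
      return(chain_model(id, seqs, xyz))
  }
  stop("generation error: could not build a compact self-avoiding walk; ",
       "try relaxing min_clash", call. = FALSE)
}

# window-3 moving average down the chain, truncated at the ends
.smooth3 <- function(v) {
  n <- length(v)
  cnt <- c(2, rep(3, n - 2), 2)
  (c(0, v[-n]) + v + c(v[-1], 0)) / cnt
}

#' Generate noise-perturbed decoys for a native chain
#'
#' For each noise level sigma in `cfg$noise_grid`, an equal share of
#' `cfg$n_decoys` decoys is produced by adding zero-mean Gaussian noise
#' (sigma per coordinate) smoothed along the chain with a window-3 moving
#' average -- which roughly preserves bond lengths -- followed by a random
#' rigid motion. The rigid motion leaves the intrinsic measures (Q*, FlexE,
#' MT) untouched while exercising the superposition of RMSD and GDT-TS*.
#'
#' @param native A [chain_model()].
#' @param cfg A [synth_config()]; randomness is drawn from `cfg$seed`
#'   (offset from the native's stream so native and decoys are independent).
#' @return A [decoy_ensemble()]; the per-decoy noise level is recorded in
#'   attribute `"sigma"` and in the decoy ids.
#' @export
gen_decoys <- function(native, cfg) {
  stopifnot(inherits(native, "chain_model"), inherits(cfg, "synth_config"))
  set.seed(cfg$seed %% 1000000L + 1000003L)
  g <- length(cfg$noise_grid)
  counts <- rep(cfg$n_decoys %/% g, g)
  if (cfg$n_decoys %% g) counts[seq_len(cfg$n_decoys %% g)] <-
    counts[seq_len(cfg$n_decoys %% g)] + 1L
  n <- n_residues(native)
  decoys <- vector("list", cfg$n_decoys)
  sigmas <- numeric(cfg$n_decoys)
  k <- 0L
  for (gi in seq_len(g)) {
    sigma <- cfg$noise_grid[gi]
    for (rep_i in seq_len(counts[gi])) {
      k <- k + 1L
      noise <- matrix(stats::rnorm(n * 3, sd = sigma), n, 3)
      noise <- apply(noise, 2, .smooth3)
      xyz <- native$coords + noise
      # random rigid motion: rotation from QR of a Gaussian matrix + shift
      qrm <- qr(matrix(stats::rnorm(9), 3))
      R <- qr.Q(qrm)
      if (det(R) < 0) R[, 1] <- -R[, 1]
      xyz <- sweep(xyz %*% t(R), 2, stats::runif(3, -30, 30), `+`)
      decoys[[k]] <- chain_model(sprintf("%s_dec%03d", native$id, k),
                                 native$seq, xyz)
      sigmas[k] <- sigma
    }
  }
  ens <- decoy_ensemble(native, decoys,
                        provenance = sprintf(
                          "synthetic: smoothed Gaussian noise, sigma grid {%s}, seed %d",
                          paste(cfg$noise_grid, collapse = ", "), cfg$seed))
  attr(ens, "sigma") <- sigmas
  ens
}

#' Spline coefficients of a quadratic distance well
#'
#' Exact B-spline representation (via the cubic blossom on the uniform knot
#' vector) of the per-pair energy `u(d) = 0.5 (d - center)^2` on the freely
#' modeled window [4, 9], optionally scaled per amino-acid pair. Every
#' counted pair then penalizes deviations of its distance from `center`, so
#' perturbing a structure almost surely raises its energy -- the shape used
#' to plant recoverable funnels.
#'
#' @param center Well position in Angstrom (default 6.5, mid-window).
#' @param pair_scale Optional positive length-210 vector of per-pair scale
#'   factors (default all 1).
#' @return A [potential_params()].
#' @export
make_well_potential <- function(center = 6.5, pair_scale = NULL) {
  if (is.null(pair_scale)) pair_scale <- rep(1, N_PAIR_TYPES)
  stopifnot(length(pair_scale) == N_PAIR_TYPES, all(pair_scale > 0))
  base <- vapply(seq_len(N_BASIS), function(j) {
    t3 <- SPLINE_KNOTS[j + 1:3]            # inner knots of basis j
    e1 <- mean(t3)
    e2 <- (t3[1] * t3[2] + t3[1] * t3[3] + t3[2] * t3[3]) / 3
    0.5 * e2 - center * e1 + 0.5 * center^2
  }, numeric(1))
  potential_params(outer(pair_scale, base), mode = "PPD")
}

#' Generate ensembles with a planted linear energy-distance funnel
#'
#' Builds `n_proteins` synthetic ensembles and assigns each decoy a target
#' distance `d = max(eps, phi . theta_star)`, where phi is the decoy's
#' feature gap ([featurize()]): the planted distance IS a realizable energy
#' gap under the known coefficients `theta_star`, so the trainer can in
#' principle reproduce it exactly in the noiseless case.
#'
#' When `theta_star` is not supplied it is constructed from the generated
#' decoys themselves as the minimum-norm ridge interpolant of their RMSD to
#' the native: with fewer feature-gap rows than the 1680 coefficients the
#' interpolation is exact, so the planted targets coincide with the (always
#' nonnegative) RMSD values while remaining an exactly realizable linear
#' funnel. This sidesteps the sign ambiguity of hand-picked coefficient
#' tables, whose energy gaps on random perturbations are negative about as
#' often as positive. Optional Gaussian noise of sd `sigma_d` is added to
#' the targets (re-floored at `eps`: distances are nonnegative).
#'
#' @param cfg A [synth_config()]; protein i uses seed `cfg$seed + 7919 * i`.
#' @param theta_star Optional [potential_params()] holding planted
#'   coefficients; default as described above.
#' @param n_proteins Number of ensembles (default 10).
#' @param sigma_d Target-noise standard deviation (default 0, noiseless).
#' @param eps Floor on planted distances (default 1e-6).
#' @param cfg_elastic An [elastic_config()] (separation filter for features).
#' @return List with `ensembles`, `rows` (per-ensemble `phi`/`d` ready for
#'   [training_problem()]), `targets`, and `theta_star` (a
#'   [potential_params()]).
#' @export
gen_planted_funnel <- function(cfg, theta_star = NULL, n_proteins = 10L,
                               sigma_d = 0, eps = 1e-6,
                               cfg_elastic = elastic_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  ensembles <- feats <- vector("list", n_proteins)
  for (i in seq_len(n_proteins)) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer((cfg$seed + 7919 * i) %% .Machine$integer.max)
    native <- gen_native(cfg_i, id = sprintf("planted%02d", i))
    ens <- gen_decoys(native, cfg_i)
    ensembles[[i]] <- ens
    feats[[i]] <- featurize(ens, mode = "PPD", d_measure = "RMSD",
                            cfg = cfg_elastic)
  }
  if (is.null(theta_star)) {
    phi_all <- do.call(rbind, lapply(feats, `[[`, "phi"))
    t_all <- unlist(lapply(feats, `[[`, "d"), use.names = FALSE)
    K <- tcrossprod(phi_all)            # n x n Gram matrix
    diag(K) <- diag(K) + 1e-8
    alpha <- solve(K, t_all)
    theta_star <- potential_params(as.vector(crossprod(phi_all, alpha)))
  }
  stopifnot(inherits(theta_star, "potential_params"))
  xvec <- as.vector(theta_star$theta)
  rows <- targets <- vector("list", n_proteins)
  for (i in seq_len(n_proteins)) {
    raw <- as.vector(feats[[i]]$phi %*% xvec)
    if (sigma_d > 0) {
      set.seed(as.integer((cfg$seed + 104729 * i) %% .Machine$integer.max))
      raw <- raw + stats::rnorm(length(raw), sd = sigma_d)
    }
    d <- pmax(eps, raw)
    rows[[i]] <- list(phi = feats[[i]]$phi, d = d,
                      decoy_ids = feats[[i]]$decoy_ids)
    targets[[i]] <- d
  }
  list(ensembles = ensembles, rows = rows, targets = targets,
       theta_star = theta_star)
}

#' Planted feature gaps and targets for a fresh ensemble
#'
#' Featurizes an ensemble and evaluates the planted targets
#' `d = max(eps, phi . theta_star)` under known coefficients -- used to score
#' a trained potential on held-out decoys of the same native.
#'
#' @param e A [decoy_ensemble()].
#' @param theta_star A [potential_params()].
#' @param eps Floor on planted distances (default 1e-6).
#' @param cfg_elastic An [elastic_config()].
#' @return List with `phi` and `d` (same layout as [featurize()]).
#' @export
planted_targets <- function(e, theta_star, eps = 1e-6,
                            cfg_elastic = elastic_config()) {
  stopifnot(inherits(e, "decoy_ensemble"),
            inherits(theta_star, "potential_params"))
  ft <- featurize(e, mode = "PPD", d_measure = function(a, b) 0,
                  cfg = cfg_elastic)
  list(phi = ft$phi,
       d = pmax(eps, as.vector(ft$phi %*% as.vector(theta_star$theta))),
       decoy_ids = ft$decoy_ids)
}
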