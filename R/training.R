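# Funnel sculpting: fit the 210 x 8 coefficient table so that native-decoy
# energy gaps are proportional to a chosen distance measure.
#
# Objective, jointly convex in (X, c):
#     min_{X, c}  sum_{i,j} (phi_{i,j} . X - c_i d_{i,j})^2 + beta ||X||^2
#     subject to  c_i >= c_bound                        (default c_bound = 1)
# phi_{i,j} is the 1680-long feature gap of decoy j of protein i (decoy minus
# native spline-basis counts per amino-acid pair), so phi . X is exactly the
# energy gap Delta E under coefficients X. The lower bound on the per-protein
# proportionality constants c_i excludes the trivial X = 0, c = 0 optimum and
# fixes the overall energy scale.

#' Feature gaps and target distances for one ensemble
#'
#' For each decoy, accumulates the spline basis values of all counted residue
#' pairs into the 210 x 8 table and subtracts the native's table, yielding a
#' 1680-long feature vector phi (column-major layout, matching
#' `as.vector(theta)`) such that `phi %*% as.vector(theta)` equals
#' `energy(decoy) - energy(native)` for any coefficients theta. Also computes
#' the per-decoy target distance.
#'
#' @param e A harmonized [decoy_ensemble()].
#' @param mode `"PPD"` (all separation-filtered pairs) or `"PPE"` (pairs
#'   restricted to the ensemble's consensus contact map, computed here).
#' @param d_measure Distance-measure name for [measure()], or a function
#'   `(native, decoy) -> value`.
#' @param cfg An [elastic_config()] (supplies contact threshold / min_sep).
#' @return List with `phi` (n_decoys x 1680 matrix), `d` (numeric vector) and
#'   `decoy_ids`.
#' @export
featurize <- function(e, mode = c("PPD", "PPE"), d_measure = "RMSD",
                      cfg = elastic_config()) {
  stopifnot(inherits(e, "decoy_ensemble"))
  mode <- match.arg(toupper(mode[1]), c("PPD", "PPE"))
  n <- n_residues(e$native)
  pairs <- if (mode == "PPE") {
    S <- consensus_contact_map(e, threshold = cfg$contact_threshold,
                               min_sep = cfg$min_sep)$S
    which(upper.tri(S$contacts) & S$contacts, arr.ind = TRUE)
  } else {
    .counted_pairs(n, cfg$min_sep)
  }
  dfun <- if (is.function(d_measure)) d_measure else
    function(a, b) measure(a, b, d_measure, cfg)
  f_native <- as.vector(.pair_features(e$native, pairs))
  phi <- t(vapply(e$decoys, function(dec)
    as.vector(.pair_features(dec, pairs)) - f_native,
    numeric(N_PAIR_TYPES * N_BASIS)))
  d <- vapply(e$decoys, function(dec) dfun(e$native, dec), numeric(1))
  list(phi = phi, d = d,
       decoy_ids = vapply(e$decoys, function(x) x$id, character(1)))
}

#' Assemble a training problem from featurized ensembles
#'
#' @param rows List with one element per ensemble, each as returned by
#'   [featurize()].
#' @param beta Regularization weight (>= 0). `NULL` selects the default
#'   `1e-3 * total number of rows`.
#' @param c_bound Lower bound on every proportionality constant (default 1).
#' @return An object of class `training_problem`.
#' @export
training_problem <- function(rows, beta = NULL, c_bound = 1) {
  stopifnot(length(rows) >= 1L)
  phi <- do.call(rbind, lapply(rows, `[[`, "phi"))
  d <- unlist(lapply(rows, `[[`, "d"), use.names = FALSE)
  protein <- rep(seq_along(rows),
                 vapply(rows, function(r) length(r$d), 0L))
  if (is.null(beta)) beta <- 1e-3 * nrow(phi)
  stopifnot(beta >= 0, ncol(phi) == N_PAIR_TYPES * N_BASIS,
            all(d >= 0), nrow(phi) == length(d))
  structure(list(phi = phi, d = d, protein = protein,
                 M = length(rows), beta = beta, c_bound = c_bound),
            class = "training_problem")
}

# objective of the sculpting problem
.sculpt_objective <- function(p, X, cvec) {
  resid <- as.vector(p$phi %*% X) - cvec[p$protein] * p$d
  sum(resid^2) + p$beta * sum(X^2)
}

#' Solve the funnel-sculpting quadratic program
#'
#' Two routes to the same convex optimum:
#' * `"profile"` (default): eliminates X in closed form through the Cholesky
#'   factor of `phi' phi + beta I`, leaving a small box-constrained quadratic
#'   in the M proportionality constants, solved with L-BFGS-B.
#' * `"altmin"`: alternating closed-form minimization over X (ridge solve)
#'   and c (`c_i = max(c_bound, sum_j dE d / sum_j d^2)`), iterated to
#'   tolerance; slower, used as an independent cross-check.
#'
#' @param problem A [training_problem()].
#' @param method `"profile"` or `"altmin"`.
#' @param max_iter Iteration cap for `"altmin"`.
#' @param tol Relative objective tolerance for `"altmin"`.
#' @return An object of class `fit_result`: list with `params`
#'   (a [potential_params()]), `c`, `objective`, `solver_status`.
#' @export
solve_funnel_qp <- function(problem, method = c("profile", "altmin"),
                            max_iter = 200L, tol = 1e-10) {
  stopifnot(inherits(problem, "training_problem"))
  method <- match.arg(method)
  p <- problem
  if (all(p$d == 0))
    stop("degenerate training problem: all target distances are zero",
         call. = FALSE)
  if (max(p$d) - min(p$d) < 1e-12)
    stop("degenerate training problem: target distances are constant, ",
         "no funnel to sculpt", call. = FALSE)
  nq <- ncol(p$phi)
  G <- crossprod(p$phi)
  diag(G) <- diag(G) + p$beta
  ch <- tryCatch(chol(G), error = function(e)
    stop("solver failure: normal matrix not positive definite ",
         "(beta too small for a rank-deficient problem): ",
         conditionMessage(e), call. = FALSE))
  ridge_solve <- function(rhs) backsolve(ch, backsolve(ch, rhs, transpose = TRUE))

  if (method == "profile") {
    # Y maps c to per-row targets: Y[row, i] = d[row] * 1{protein == i}
    Y <- matrix(0, nrow(p$phi), p$M)
    Y[cbind(seq_len(nrow(p$phi)), p$protein)] <- p$d
    W <- crossprod(p$phi, Y)            # 1680 x M
    Z <- ridge_solve(W)                 # X = Z c at the inner optimum
    H <- crossprod(Y) - crossprod(W, Z) # reduced quadratic form in c
    H <- (H + t(H)) / 2
    fn <- function(cc) as.numeric(cc %*% H %*% cc)
    gr <- function(cc) as.numeric(2 * H %*% cc)
    opt <- stats::optim(rep(p$c_bound, p$M), fn, gr, method = "L-BFGS-B",
                        lower = rep(p$c_bound, p$M),
                        control = list(maxit = 500L, factr = 1e4))
    cvec <- opt$par
    X <- as.vector(Z %*% cvec)
    status <- if (opt$convergence == 0) "converged (profiled QP, L-BFGS-B)"
              else paste0("L-BFGS-B code ", opt$convergence, ": ", opt$message)
  } else {
    cvec <- rep(max(p$c_bound, 1), p$M)
    obj_prev <- Inf
    status <- "iteration cap reached"
    d2 <- tapply(p$d^2, p$protein, sum)
    for (it in seq_len(max_iter)) {
      X <- as.vector(ridge_solve(crossprod(p$phi, cvec[p$protein] * p$d)))
      dE <- as.vector(p$phi %*% X)
      num <- tapply(dE * p$d, p$protein, sum)
      cvec <- pmax(p$c_bound, as.numeric(num / pmax(d2, .Machine$double.eps)))
      obj <- .sculpt_objective(p, X, cvec)
      if (is.finite(obj_prev) && abs(obj_prev - obj) <= tol * max(1, obj)) {
        status <- sprintf("converged (alternating minimization, %d iterations)", it)
        break
      }
      obj_prev <- obj
    }
  }
  obj <- .sculpt_objective(p, X, cvec)
  structure(list(params = potential_params(matrix(X, N_PAIR_TYPES, N_BASIS),
                                           beta = p$beta),
                 c = as.numeric(cvec), objective = obj,
                 solver_status = status),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> objective %.6g, c in [%.3g, %.3g], %s\n",
              x$objective, min(x$c), max(x$c), x$solver_status))
  invisible(x)
}

#' Train a pair potential on decoy ensembles
#'
#' End-to-end trainer: featurizes every ensemble ([featurize()]), assembles
#' the sculpting problem with one proportionality constant per ensemble and
#' solves it ([solve_funnel_qp()]). Training metadata (distance measure,
#' beta, mode, separation filter) is recorded on the returned parameters.
#'
#' @param ensembles List of harmonized [decoy_ensemble()] objects.
#' @param mode `"PPD"` or `"PPE"`.
#' @param d_measure Distance-measure name (see [measure()]) or a function.
#' @param beta Regularization weight; `NULL` for the row-count default.
#' @param c_bound Lower bound on the proportionality constants (default 1).
#' @param cfg An [elastic_config()].
#' @param method Solver route, see [solve_funnel_qp()].
#' @return A `fit_result`.
#' @export
fit_potential <- function(ensembles, mode = c("PPD", "PPE"),
                          d_measure = "RMSD", beta = NULL, c_bound = 1,
                          cfg = elastic_config(),
                          method = c("profile", "altmin")) {
  if (inherits(ensembles, "decoy_ensemble")) ensembles <- list(ensembles)
  stopifnot(length(ensembles) >= 1L)
  mode <- match.arg(toupper(mode[1]), c("PPD", "PPE"))
  rows <- lapply(ensembles, featurize, mode = mode, d_measure = d_measure,
                 cfg = cfg)
  fit <- solve_funnel_qp(training_problem(rows, beta = beta,
                                          c_bound = c_bound),
                         method = match.arg(method))
  fit$params$mode <- mode
  fit$params$measure <- if (is.function(d_measure)) "custom"
                        else toupper(d_measure)
  fit$params$min_sep <- cfg$min_sep
  fit
}
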