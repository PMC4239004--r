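# Featurization and the funnel-sculpting QP.

test_that("featurize gives zero feature gaps and zero distance for the native", {
  native <- rand_model(15, seed = 30, spread = 4, id = "nat")
  self_dec <- chain_model("self", native$seq, native$coords)
  e <- decoy_ensemble(native, list(self_dec))
  ft <- featurize(e, "PPD", d_measure = "RMSD")
  expect_equal(dim(ft$phi), c(1L, 1680L))
  expect_equal(max(abs(ft$phi)), 0)
  expect_equal(ft$d, 0, tolerance = 1e-9)
})

test_that("phi . theta reproduces the PPD energy gap for random theta", {
  e <- noisy_ensemble(n = 18, n_dec = 6, sigma = 1.5, seed = 31)
  ft <- featurize(e, "PPD", d_measure = "RMSD")
  set.seed(6)
  for (rep in 1:3) {
    th <- potential_params(matrix(rnorm(1680), 210, 8))
    en <- energy_ppd(e$native, th)
    for (j in c(1, 4, 6)) {
      gap <- energy_ppd(e$decoys[[j]], th) - en
      expect_equal(as.numeric(ft$phi[j, ] %*% as.vector(th$theta)), gap,
                   tolerance = 1e-9)
    }
  }
  expect_equal(ft$decoy_ids, vapply(e$decoys, function(x) x$id, ""))
})

test_that("PPE featurization reduces to PPD when the consensus map is full", {
  # all residues inside a 9 A ball: every separation-filtered pair in contact
  set.seed(33)
  native <- chain_model("ball", sample(AA_CODES, 8, replace = TRUE),
                        matrix(runif(24, -2.5, 2.5), 8, 3))
  decs <- lapply(1:9, function(k)
    chain_model(paste0("d", k), native$seq,
                native$coords + matrix(rnorm(24, sd = 0.1), 8, 3)))
  e <- decoy_ensemble(native, decs)
  st <- consensus_contact_map(e)
  expect_true(all(st$S$contacts[abs(row(st$S$contacts) -
                                    col(st$S$contacts)) >= 3]))
  fp <- featurize(e, "PPD", d_measure = "RMSD")
  fe <- featurize(e, "PPE", d_measure = "RMSD")
  expect_equal(fe$phi, fp$phi, tolerance = 1e-12)
})

small_planted <- function(seed = 5, n_proteins = 3) {
  cfg <- synth_config(n_res = 30, n_decoys = 30, noise_grid = c(1, 2, 4),
                      seed = seed)
  gen_planted_funnel(cfg, n_proteins = n_proteins)
}

test_that("the trainer recovers a noiseless planted funnel", {
  pf <- small_planted()
  fit <- solve_funnel_qp(training_problem(pf$rows, beta = 1e-8, c_bound = 1))
  X <- as.vector(fit$params$theta)
  for (i in seq_along(pf$rows)) {
    pred <- as.vector(pf$rows[[i]]$phi %*% X)
    expect_gte(cor(pred, pf$targets[[i]]), 0.999)
  }
  expect_true(all(fit$c >= 1 - 1e-9))
  expect_gte(fit$objective, 0)
})

test_that("profile and alternating-minimization solvers agree", {
  pf <- small_planted(seed = 6)
  prob <- training_problem(pf$rows, beta = 1e-4 * 90, c_bound = 1)
  f1 <- solve_funnel_qp(prob, method = "profile")
  f2 <- solve_funnel_qp(prob, method = "altmin", max_iter = 500)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-6)
  # optimal c given X has the closed form max(c_bound, <dE, d>/<d, d>)
  X <- as.vector(f1$params$theta)
  for (i in seq_along(pf$rows)) {
    dE <- as.vector(pf$rows[[i]]$phi %*% X)
    d <- pf$rows[[i]]$d
    expect_equal(f1$c[i], max(1, sum(dE * d) / sum(d^2)), tolerance = 1e-4)
  }
})

test_that("strong regularization drives X to zero and c to the bound", {
  pf <- small_planted(seed = 7, n_proteins = 2)
  fit <- solve_funnel_qp(training_problem(pf$rows, beta = 1e12, c_bound = 1))
  expect_lt(sqrt(sum(fit$params$theta^2)), 1e-3)
  expect_equal(fit$c, rep(1, 2), tolerance = 1e-6)
})

test_that("duplicating every row leaves the optimum unchanged", {
  pf <- small_planted(seed = 8, n_proteins = 2)
  p1 <- training_problem(pf$rows, beta = 1e-6, c_bound = 1)
  rows2 <- lapply(pf$rows, function(r)
    list(phi = rbind(r$phi, r$phi), d = c(r$d, r$d),
         decoy_ids = c(r$decoy_ids, r$decoy_ids)))
  p2 <- training_problem(rows2, beta = 2e-6, c_bound = 1)  # beta scales with rows
  f1 <- solve_funnel_qp(p1); f2 <- solve_funnel_qp(p2)
  expect_equal(as.vector(f2$params$theta), as.vector(f1$params$theta),
               tolerance = 1e-6)
  expect_equal(2 * f1$objective, f2$objective, tolerance = 1e-6)
})

test_that("the data-fit term is non-increasing as beta decreases", {
  pf <- small_planted(seed = 9, n_proteins = 2)
  datafit <- vapply(c(1e2, 1e-2, 1e-6), function(b) {
    f <- solve_funnel_qp(training_problem(pf$rows, beta = b, c_bound = 1))
    f$objective - b * sum(f$params$theta^2)
  }, numeric(1))
  expect_true(all(diff(datafit) < 1e-8))
})

test_that("degenerate target vectors are rejected", {
  pf <- small_planted(seed = 10, n_proteins = 1)
  r0 <- pf$rows
  r0[[1]]$d[] <- 0
  expect_error(solve_funnel_qp(training_problem(r0, beta = 1)), "zero")
  r1 <- pf$rows
  r1[[1]]$d[] <- 1e-6
  expect_error(solve_funnel_qp(training_problem(r1, beta = 1)), "constant")
})

test_that("fit_potential records training metadata end to end", {
  e <- noisy_ensemble(n = 20, n_dec = 12, sigma = 1.5, seed = 34)
  fit <- fit_potential(list(e), mode = "PPD", d_measure = "RMSD",
                       beta = 1e-4)
  expect_s3_class(fit$params, "potential_params")
  expect_equal(fit$params$measure, "RMSD")
  expect_equal(fit$params$mode, "PPD")
  expect_equal(length(fit$c), 1L)
  # trained energies correlate with the target distance on the training set
  rec <- evaluate_energy(fit$params, e, measures = "RMSD")
  expect_gte(rec$corr, 0.9)
})
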