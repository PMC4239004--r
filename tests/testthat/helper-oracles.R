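# Independent oracles, kept free of the implementation's code paths.

# Cox-de Boor recursion written out by hand: basis j of order `ord` on
# `knots`, evaluated at scalar x. Oracle for basis_eval().
deboor_basis_one <- function(j, x, knots = 1:12, ord = 4) {
  nb <- function(i, k, x) {
    if (k == 1)
      return(as.numeric(x >= knots[i] & x < knots[i + 1]))
    left <- 0
    if (knots[i + k - 1] != knots[i])
      left <- (x - knots[i]) / (knots[i + k - 1] - knots[i]) * nb(i, k - 1, x)
    right <- 0
    if (knots[i + k] != knots[i + 1])
      right <- (knots[i + k] - x) / (knots[i + k] - knots[i + 1]) *
        nb(i + 1, k - 1, x)
    left + right
  }
  nb(j, ord, x)
}

deboor_basis <- function(x, knots = 1:12, ord = 4) {
  vapply(seq_len(length(knots) - ord), deboor_basis_one, numeric(1),
         x = x, knots = knots, ord = ord)
}

# Brute-force RMSD: numeric minimization over axis-angle rotation +
# translation from many random starts; independent of the Kabsch route.
brute_rmsd <- function(A, B, n_starts = 25, seed = 99) {
  rot_from <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    u <- v / th
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj <- function(par) {
    R <- rot_from(par[1:3])
    fitted <- sweep(B %*% t(R), 2, par[4:6], `+`)
    sqrt(mean(rowSums((A - fitted)^2)))
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    par0 <- c(runif(3, -pi, pi), colMeans(A) - colMeans(B) + rnorm(3))
    fit <- optim(par0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# Exhaustive-seed GDT oracle for small N: seeds from every contiguous
# fragment of every length >= 3, simple fixed-count refinement loop.
oracle_gdt <- function(A, B, rounds = 10) {
  n <- nrow(A)
  fit_d <- function(sub) {
    a <- A[sub, , drop = FALSE]; b <- B[sub, , drop = FALSE]
    ca <- colMeans(a); cb <- colMeans(b)
    H <- crossprod(sweep(b, 2, cb), sweep(a, 2, ca))
    sv <- svd(H)
    s <- sign(det(sv$v %*% t(sv$u))); if (s == 0) s <- 1
    R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
    fitted <- sweep(sweep(B, 2, cb) %*% t(R), 2, ca, `+`)
    sqrt(rowSums((A - fitted)^2))
  }
  total <- 0
  for (cutoff in c(1, 2, 4, 8)) {
    best <- 0
    for (len in 3:n) for (st in 1:(n - len + 1)) {
      sub <- st:(st + len - 1)
      for (r in seq_len(rounds)) {
        d <- fit_d(sub)
        inl <- which(d <= cutoff)
        best <- max(best, length(inl))
        if (length(inl) < 3 || identical(inl, sub)) break
        sub <- inl
      }
    }
    total <- total + best / n
  }
  total / 4
}

# two-pass mean/mad oracle
oracle_mean_mad <- function(x) {
  m <- sum(x) / length(x)
  c(mean = m, mad = sum(abs(x - m)) / length(x))
}
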