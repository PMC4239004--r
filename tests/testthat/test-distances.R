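# Superposition and the four native-decoy distance measures.

test_that("superpose returns identity and zero RMSD for identical models", {
  m <- rand_model(10, seed = 1)
  s <- superpose(m, m)
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  expect_equal(s$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(s$transform$translation, rep(0, 3), tolerance = 1e-9)
})

test_that("RMSD vanishes under rigid motion and rejects degenerate input", {
  m <- rand_model(20, seed = 3)
  expect_equal(rmsd(m, rigidly_moved(m, 7)), 0, tolerance = 1e-9)
  m2 <- rand_model(2, seed = 3, spread = 1)
  expect_error(superpose(m2, m2), "at least 3")
  m3 <- rand_model(25, seed = 4)
  expect_error(superpose(m, m3), "different lengths")
})

test_that("RMSD matches a brute-force rotation/translation search", {
  A <- rbind(c(0, 0, 0), c(4, 0, 0), c(2, 3.5, 0), c(2, 1.2, 3.3))
  B <- A
  B[3, ] <- B[3, ] + c(0.6, -0.8, 0)   # one vertex displaced 1 A
  got <- superpose(A, B)$rmsd
  expect_lt(abs(got - brute_rmsd(A, B)), 1e-3)
  # and against bio3d's least-squares fit as a second independent route
  fitted <- suppressWarnings(bio3d::fit.xyz(as.vector(t(A)),
                                            as.vector(t(B))))
  ref <- sqrt(mean(rowSums((A - matrix(fitted, 4, 3, byrow = TRUE))^2)))
  expect_lt(abs(got - ref), 1e-6)
})

test_that("RMSD behaves as a metric on random equal-length triples", {
  for (s in 1:30) {
    a <- rand_model(12, seed = 3 * s, spread = 5)$coords
    b <- rand_model(12, seed = 3 * s + 1, spread = 5)$coords
    c <- rand_model(12, seed = 3 * s + 2, spread = 5)$coords
    dab <- superpose(a, b)$rmsd; dba <- superpose(b, a)$rmsd
    dac <- superpose(a, c)$rmsd; dbc <- superpose(b, c)$rmsd
    expect_equal(dab, dba, tolerance = 1e-8)
    expect_lte(dac, dab + dbc + 1e-8)
  }
})

test_that("GDT-TS is 1 for rigid motions and sub-cutoff perturbations", {
  m <- rand_model(20, seed = 8, spread = 6)
  expect_equal(gdt_ts(m, rigidly_moved(m, 2)), 1)
  expect_equal(gdt_ts_star(m, rigidly_moved(m, 2)), 0)
  set.seed(21)
  pert <- chain_model("p", m$seq,
                      m$coords + matrix(runif(60, -0.17, 0.17), 20, 3))
  expect_equal(gdt_ts(m, pert), 1)   # every |dx| < 0.3 A
})

test_that("GDT-TS agrees with the exhaustive-seed oracle on a scaled chain", {
  m <- rand_model(20, seed = 13, spread = 6)
  stretched <- chain_model("x10", m$seq, m$coords * 10)
  got <- gdt_ts(m, stretched)
  expect_lt(got, 1)
  expect_equal(got, oracle_gdt(m$coords, stretched$coords), tolerance = 0.05)
})

test_that("GDT-TS decreases (on average) with noise amplitude", {
  m <- rand_model(25, seed = 5, spread = 6)
  mean_gdt <- function(sigma) {
    mean(vapply(1:5, function(s) {
      set.seed(100 * sigma + s)
      gdt_ts(m, chain_model("n", m$seq,
                            m$coords + matrix(rnorm(75, sd = sigma), 25, 3)))
    }, numeric(1)))
  }
  g <- vapply(c(0.5, 2, 8), mean_gdt, numeric(1))
  expect_true(all(diff(g) < 0))
})

test_that("contact_map applies the distance threshold and separation filter", {
  two <- line_model(2)
  expect_equal(sum(contact_map(two, 9, 3)$contacts), 0)

  chain <- line_model(10)   # 3.8 A spacing: |i-j| = 3 pairs at 11.4 A
  expect_equal(sum(contact_map(chain, 9, 3)$contacts), 0)
  cm12 <- contact_map(chain, 12, 3)$contacts
  expect_true(all(cm12[abs(row(cm12) - col(cm12)) == 3]))
  expect_equal(sum(cm12) / 2, 7)   # exactly the seven |i-j| = 3 pairs
})

test_that("Q* counts lost native contacts and only native contacts", {
  m <- rand_model(20, seed = 9, spread = 4)
  expect_equal(q_star(m, m), 0)
  stretched <- chain_model("s", m$seq, m$coords * 5)
  expect_equal(q_star(m, stretched), 1)

  # 13-residue straight chain, spacing 4.5, threshold 14: native contacts are
  # exactly the ten |i-j| = 3 pairs (13.5 <= 14 < 18); displacing residues 1
  # and 7 breaks exactly (1,4), (4,7), (7,10) -> Q* = 3/10
  nat <- line_model(13, spacing = 4.5)
  dec_xyz <- nat$coords
  dec_xyz[1, ] <- c(0, 100, 0)
  dec_xyz[7, ] <- c(0, -100, 0)
  dec <- chain_model("d", nat$seq, dec_xyz)
  expect_equal(q_star(nat, dec, threshold = 14, min_sep = 3), 0.3)

  # non-native contacts in the decoy never change Q*: bring the two displaced
  # residues (1 and 7, a non-native pair) next to each other
  dec2_xyz <- dec_xyz
  dec2_xyz[7, ] <- dec_xyz[1, ] + c(0, 4, 0)    # new (1,7) contact
  dec2 <- chain_model("d2", nat$seq, dec2_xyz)
  expect_equal(q_star(nat, dec2, threshold = 14, min_sep = 3), 0.3)
})

# single native contact pair: residues 1 and 4 at 5 A, everything else remote
single_contact_pair <- function(d_decoy) {
  nat <- chain_model("n", c("A", "C", "D", "E", "F"),
                     rbind(c(0, 0, 0), c(30, 0, 0), c(60, 0, 0),
                           c(0, 5, 0), c(90, 0, 0)))
  dec_xyz <- nat$coords
  dec_xyz[4, ] <- c(0, d_decoy, 0)
  list(nat = nat, dec = chain_model("d", nat$seq, dec_xyz))
}

test_that("FlexE is the harmonic deformation energy over native contacts", {
  m <- rand_model(20, seed = 10, spread = 4)
  expect_equal(flexe(m, m), 0)

  p <- single_contact_pair(6)   # delta = +1
  expect_equal(flexe(p$nat, p$dec), 0.5)
  p2 <- single_contact_pair(4)  # delta = -1: quadratic is sign-symmetric
  expect_equal(flexe(p$nat, p2$dec), 0.5)
})

test_that("MT matches FlexE for small deformations, penalizes compression", {
  m <- rand_model(20, seed = 11, spread = 4)
  expect_equal(mt(m, m), 0)

  for (dd in c(5.01, 4.99)) {   # |delta| = 0.01
    p <- single_contact_pair(dd)
    ratio <- mt(p$nat, p$dec) / flexe(p$nat, p$dec)
    expect_gte(ratio, 0.99)
    expect_lte(ratio, 1.01)
  }
  compressed <- single_contact_pair(3)  # delta = -2
  extended <- single_contact_pair(7)    # delta = +2
  nat <- compressed$nat
  expect_gt(mt(nat, compressed$dec), mt(nat, extended$dec))
  expect_gte(mt(nat, compressed$dec), 0)
})

test_that("intrinsic measures ignore rigid motion of either structure", {
  m <- rand_model(25, seed = 12, spread = 5)
  set.seed(55)
  dec <- chain_model("d", m$seq, m$coords + matrix(rnorm(75), 25, 3))
  dec_moved <- rigidly_moved(dec, 31)
  expect_equal(q_star(m, dec), q_star(m, dec_moved), tolerance = 1e-12)
  expect_equal(flexe(m, dec), flexe(m, dec_moved), tolerance = 1e-9)
  expect_equal(mt(m, dec), mt(m, dec_moved), tolerance = 1e-9)
  m_moved <- rigidly_moved(m, 32)
  expect_equal(flexe(m, dec), flexe(m_moved, dec), tolerance = 1e-9)
})

test_that("the measure dispatcher returns zero for decoy = native", {
  m <- rand_model(15, seed = 14, spread = 5)
  for (w in DISTANCE_MEASURES)
    expect_equal(measure(m, m, w), 0, tolerance = 1e-9)
  expect_equal(measure(m, m, "gdt"), 0)      # shorthand
  expect_equal(measure(m, m, "GDT-TS*"), 0)  # starred spelling
  expect_error(measure(m, m, "TM"), "unknown")
})
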