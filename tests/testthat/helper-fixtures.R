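# Fixtures are built in code at test time; nothing binary is stored.

# deterministic compact-ish random model
rand_model <- function(n, seed, spread = 6, id = paste0("rand", seed)) {
  set.seed(seed)
  chain_model(id, sample(AA_CODES, n, replace = TRUE),
              matrix(rnorm(n * 3, sd = spread), n, 3))
}

# straight chain along x with fixed spacing
line_model <- function(n, spacing = 3.8, seq = rep("A", n),
                       id = "line") {
  chain_model(id, seq, cbind((seq_len(n) - 1) * spacing, 0, 0))
}

random_rotation <- function(seed) {
  set.seed(seed)
  qrm <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qrm)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigidly_moved <- function(m, seed = 1) {
  R <- random_rotation(seed)
  set.seed(seed + 1)
  shift <- runif(3, -20, 20)
  chain_model(paste0(m$id, "_moved"), m$seq,
              sweep(m$coords %*% t(R), 2, shift, `+`), m$backbone_complete)
}

# one PDB ATOM record, wwPDB v3.3 fixed columns
pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, alt = " ") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, paste0(" ", name), alt, resid, chain, resno, x, y, z,
          occ, 0)
}

# full-backbone poly-ALA PDB text; `drop_atoms` removes named atoms from
# given residues, e.g. list(resno = 4, atom = "O")
poly_ala_pdb <- function(n, drop_atoms = NULL) {
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n)) {
    base <- c((i - 1) * 3.8, 0, 0)
    atoms <- list(N = base + c(-1.0, 0.8, 0), CA = base,
                  C = base + c(1.2, 0.6, 0), O = base + c(1.4, 1.8, 0))
    for (nm in names(atoms)) {
      if (!is.null(drop_atoms) &&
          any(drop_atoms$resno == i & drop_atoms$atom == nm)) next
      serial <- serial + 1L
      p <- atoms[[nm]]
      lines <- c(lines, pdb_atom_line(serial, nm, "ALA", "A", i,
                                      p[1], p[2], p[3]))
    }
  }
  c(lines, "END")
}

write_tmp_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# fabricate a contact_map from a binary upper-triangle specification
fake_map <- function(mat, threshold = 9, min_sep = 3) {
  mat <- mat | t(mat)
  diag(mat) <- FALSE
  structure(list(n = nrow(mat), contacts = mat, threshold = threshold,
                 min_sep = as.integer(min_sep)),
            class = "contact_map")
}

# random symmetric min_sep-respecting binary map with contact density p
random_fake_map <- function(n, p, seed, min_sep = 3) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  ut <- which(upper.tri(m) & abs(row(m) - col(m)) >= min_sep)
  m[sample(ut, round(p * length(ut)))] <- TRUE
  fake_map(m, min_sep = min_sep)
}

# small harmonizable ensemble of noisy copies of a native
noisy_ensemble <- function(n = 20, n_dec = 10, sigma = 1, seed = 42) {
  native <- rand_model(n, seed, spread = 4, id = "nat")
  set.seed(seed + 1)
  decs <- lapply(seq_len(n_dec), function(k)
    chain_model(sprintf("dec%02d", k), native$seq,
                native$coords + matrix(rnorm(n * 3, sd = sigma), n, 3)))
  decoy_ensemble(native, decs, "test fixture")
}
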