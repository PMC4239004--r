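# PDB input/output for C-alpha models, built on bio3d.

# Modified residues with an unambiguous standard parent.
.NONSTD_MAP <- c(MSE = "MET", MLY = "LYS", HYP = "PRO", SEP = "SER",
                 TPO = "THR", PTR = "TYR", CSO = "CYS", PCA = "GLU",
                 KCX = "LYS", LLP = "LYS", CME = "CYS", MLE = "LEU")

.THREE_TO_ONE <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
                   GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
                   MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
                   SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")

.ONE_TO_THREE <- structure(names(.THREE_TO_ONE), names = unname(.THREE_TO_ONE))

#' Read a C-alpha model from a PDB file
#'
#' Parses ATOM records (HETATM is ignored), keeps the first MODEL of
#' multi-model files, resolves alternate locations by highest occupancy and
#' then file order, and reduces the chain to its C-alpha trace. Each residue
#' is flagged `backbone_complete` iff all four backbone atoms (N, CA, C, O)
#' are present. Modified residues with an unambiguous parent (e.g. MSE) are
#' mapped to the parent; other non-standard residues are dropped with a
#' warning. Insertion-coded residues are kept in file order.
#'
#' @param path Path to a PDB file.
#' @param chain Optional single chain identifier; default is the first chain
#'   carrying a protein C-alpha atom.
#' @param id Label for the model; default the file name without extension.
#' @return A [chain_model()].
#' @export
read_ca_model <- function(path, chain = NULL, id = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error for '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("empty model: no ATOM records in ", path, call. = FALSE)

  # map modified residues to their parent before anything else
  mapped <- .NONSTD_MAP[at$resid]
  at$resid[!is.na(mapped)] <- mapped[!is.na(mapped)]

  is_ca <- at$elety == "CA" & at$resid %in% names(.THREE_TO_ONE)
  if (!any(is_ca)) stop("empty model: no standard C-alpha atoms in ", path, call. = FALSE)
  if (is.null(chain)) chain <- at$chain[which(is_ca)[1]]
  at <- at[at$chain %in% chain, , drop = FALSE]

  # residue key in file order
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert))
  ukey <- unique(key)

  pick_alt <- function(rows, name) {
    sel <- rows[at$elety[rows] == name]
    if (!length(sel)) return(NA_integer_)
    if (length(sel) == 1L) return(sel)
    occ <- at$o[sel]
    occ[is.na(occ)] <- 1
    sel[which.max(occ)]  # max occupancy, ties resolved to first listed
  }

  seqs <- character(0); xyz <- NULL; flags <- logical(0); dropped <- character(0)
  for (k in ukey) {
    rows <- which(key == k)
    ca <- pick_alt(rows, "CA")
    if (is.na(ca)) next
    res3 <- at$resid[ca]
    if (!res3 %in% names(.THREE_TO_ONE)) { dropped <- c(dropped, res3); next }
    complete <- !anyNA(c(ca, pick_alt(rows, "N"), pick_alt(rows, "C"),
                         pick_alt(rows, "O")))
    seqs <- c(seqs, .THREE_TO_ONE[[res3]])
    xyz <- rbind(xyz, c(at$x[ca], at$y[ca], at$z[ca]))
    flags <- c(flags, complete)
  }
  if (length(dropped))
    warning("dropped non-standard residue(s): ",
            paste(unique(dropped), collapse = ", "), call. = FALSE)
  if (!length(seqs)) stop("empty model: no usable residues in ", path, call. = FALSE)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  chain_model(id, seqs, xyz, flags)
}

#' Write a C-alpha model as a PDB file
#'
#' Emits one ATOM record per residue (element CA, chain A, occupancy 1).
#' Coordinates are written at standard PDB precision (3 decimals), so a
#' write/read round trip preserves them to 1e-3 Angstrom.
#'
#' @param m A [chain_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ca_model <- function(m, path) {
  stopifnot(inherits(m, "chain_model"))
  n <- n_residues(m)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(m$coords)),
                   resno = seq_len(n),
                   resid = unname(.ONE_TO_THREE[m$seq]),
                   elety = rep("CA", n),
                   chain = rep("A", n),
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}
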