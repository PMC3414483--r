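#' @title Structure data model
#' @description An `hla_structure` holds a (possibly multi-chain) protein
#'   structure as a flat atom table plus metadata. The atom table mirrors the
#'   columns of a PDB ATOM record: `elety` (atom name), `resid` (3-letter
#'   residue name), `chain`, `resno` (author residue number), `icode`
#'   (insertion code, "" when absent), Cartesian coordinates `x`, `y`, `z` in
#'   Angstrom, occupancy `o`, B-factor `b` and element symbol `elesy`.
#' @name structure-model
NULL

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

AA3 <- structure(names(AA1), names = unname(AA1))

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct a structure object
#'
#' @param id character label (e.g. a PDB code).
#' @param atoms data.frame with columns `elety`, `resid`, `chain`, `resno`,
#'   `icode`, `x`, `y`, `z`, `o`, `b`, `elesy`.
#' @param resolution crystallographic resolution in Angstrom, or `NA`.
#' @return An object of class `hla_structure`.
#' @export
hla_structure <- function(id, atoms, resolution = NA_real_) {
  need <- c("elety", "resid", "chain", "resno", "icode",
            "x", "y", "z", "o", "b", "elesy")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table missing column(s): ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms[, need], stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$elety))) stop("empty atom name in atom table")
  obj <- list(id = id, atoms = atoms, resolution = resolution)
  class(obj) <- "hla_structure"
  obj
}

#' @export
print.hla_structure <- function(x, ...) {
  ch <- chain_ids(x)
  lens <- vapply(ch, function(cc) n_residues(x, cc), integer(1))
  cat(sprintf("<hla_structure> %s: %d atoms, %d chain(s)\n",
              x$id, nrow(x$atoms), length(ch)))
  for (i in seq_along(ch))
    cat(sprintf("  chain %s: %d residues\n", ch[i], lens[i]))
  if (!is.na(x$resolution))
    cat(sprintf("  resolution: %.2f A\n", x$resolution))
  invisible(x)
}

#' Chain identifiers of a structure
#' @param s an `hla_structure`.
#' @return character vector of chain ids in order of first appearance.
#' @export
chain_ids <- function(s) unique(s$atoms$chain)

# unique residue key within a chain (resno + icode), in file order
residue_keys <- function(s, chain) {
  a <- s$atoms[s$atoms$chain == chain, ]
  unique(paste(a$resno, a$icode, sep = "|"))
}

#' Number of residues in a chain
#' @param s an `hla_structure`.
#' @param chain chain id.
#' @export
n_residues <- function(s, chain) length(residue_keys(s, chain))

#' One-letter sequence of a chain
#' @param s an `hla_structure`.
#' @param chain chain id.
#' @return character scalar; non-standard residues become `X`.
#' @export
chain_sequence <- function(s, chain) {
  a <- s$atoms[s$atoms$chain == chain, ]
  key <- paste(a$resno, a$icode, sep = "|")
  res3 <- a$resid[!duplicated(key)]
  paste(ifelse(res3 %in% STANDARD_AA, AA1[res3], "X"), collapse = "")
}

#' Atom selection by field values
#'
#' @param s an `hla_structure`.
#' @param chain,resno,elety,resid optional filters (vectors allowed).
#' @param backbone if TRUE restrict to N, CA, C, O.
#' @return integer row indices into `s$atoms`.
#' @export
atom_select <- function(s, chain = NULL, resno = NULL, elety = NULL,
                        resid = NULL, backbone = FALSE) {
  keep <- rep(TRUE, nrow(s$atoms))
  if (!is.null(chain)) keep <- keep & s$atoms$chain %in% chain
  if (!is.null(resno)) keep <- keep & s$atoms$resno %in% resno
  if (!is.null(elety)) keep <- keep & s$atoms$elety %in% elety
  if (!is.null(resid)) keep <- keep & s$atoms$resid %in% resid
  if (backbone) keep <- keep & s$atoms$elety %in% BACKBONE_ATOMS
  which(keep)
}

#' Coordinate matrix of (selected) atoms
#' @param s an `hla_structure`.
#' @param sel integer row indices (default all atoms).
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(s, sel = NULL) {
  a <- if (is.null(sel)) s$atoms else s$atoms[sel, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

#' Replace coordinates of (selected) atoms
#' @param s an `hla_structure`.
#' @param xyz numeric matrix (n x 3).
#' @param sel integer row indices (default all atoms).
#' @return the modified structure.
#' @export
set_coords <- function(s, xyz, sel = NULL) {
  if (is.null(sel)) sel <- seq_len(nrow(s$atoms))
  stopifnot(length(sel) == nrow(xyz))
  s$atoms$x[sel] <- xyz[, 1]
  s$atoms$y[sel] <- xyz[, 2]
  s$atoms$z[sel] <- xyz[, 3]
  s
}

#' Identify the peptide chain of a p-HLA complex
#'
#' The peptide chain is the unique chain of length 8-12 residues.
#'
#' @param s an `hla_structure`.
#' @return chain id of the peptide chain.
#' @export
peptide_chain <- function(s) {
  ch <- chain_ids(s)
  lens <- vapply(ch, function(cc) n_residues(s, cc), integer(1))
  cand <- ch[lens >= 8 & lens <= 12]
  if (length(cand) == 0)
    stop("no candidate peptide chain (length 8-12) in '", s$id, "'")
  if (length(cand) > 1)
    stop("ambiguous peptide chain in '", s$id, "': chains ",
         paste(cand, collapse = ", "), " all have length 8-12")
  cand
}

#' Identify the HLA heavy chain of a complex
#'
#' The heavy chain is the longest chain that is not the peptide chain.
#'
#' @param s an `hla_structure`.
#' @return chain id.
#' @export
heavy_chain <- function(s) {
  ch <- chain_ids(s)
  lens <- vapply(ch, function(cc) n_residues(s, cc), integer(1))
  pep <- tryCatch(peptide_chain(s), error = function(e) NA_character_)
  pool <- if (is.na(pep)) ch else setdiff(ch, pep)
  if (!length(pool)) stop("no heavy chain in '", s$id, "'")
  pool[which.max(lens[match(pool, ch)])]
}

#' Keep a subset of chains
#' @param s an `hla_structure`.
#' @param keep chain ids to retain.
#' @return an `hla_structure` restricted to `keep`.
#' @export
subset_chains <- function(s, keep) {
  hla_structure(s$id, s$atoms[s$atoms$chain %in% keep, , drop = FALSE],
                s$resolution)
}

#' The 37-residue HLA-A*02:01 binding-groove definition
#'
#' Residue numbers (heavy-chain author numbering) of the 37 solvent-accessible
#' residues delineating the HLA-A*02:01 peptide-binding groove, between the
#' alpha-1/alpha-2 helices and the beta-sheet floor.
#'
#' @param residue_numbers optional custom integer vector (ordered).
#' @return An object of class `groove_definition` (an ordered integer vector).
#' @export
groove_definition <- function(residue_numbers = NULL) {
  if (is.null(residue_numbers))
    residue_numbers <- c(5L, 7L, 9L, 26L, 45L, 58L, 59L, 62L, 63L, 66L, 67L,
                         69L, 70L, 73L, 74L, 77L, 80L, 81L, 84L, 97L, 99L,
                         114L, 116L, 123L, 124L, 133L, 143L, 146L, 147L,
                         152L, 155L, 156L, 159L, 163L, 164L, 167L, 171L)
  residue_numbers <- as.integer(residue_numbers)
  class(residue_numbers) <- "groove_definition"
  residue_numbers
}

#' @export
print.groove_definition <- function(x, ...) {
  cat(sprintf("<groove_definition> %d residues: %s\n", length(x),
              paste(unclass(x), collapse = ", ")))
  invisible(x)
}
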