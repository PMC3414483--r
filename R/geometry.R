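# Internal-coordinate machinery: atom placement from bond/angle/torsion,
# idealized side-chain geometry for the 20 standard residues, and a
# phi/psi-driven backbone builder. All lengths in Angstrom, angles in degrees.

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate geometry: zero-length vector")
  v / n
}

#' Dihedral angle of four points
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Bond angle of three points
#' @param p1,p2,p3 numeric 3-vectors; vertex at `p2`.
#' @return angle in degrees.
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- unit3(p1 - p2); v <- unit3(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# NeRF placement: position d bonded to c with |d-c| = bond,
# angle(b,c,d) = angle and dihedral(a,b,c,d) = torsion.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         -bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Side-chain geometry table. Each atom row: parents a/b/c (c = bonded
# parent), bond length, bond angle at c, torsion reference ("chi1".."chi4"
# or "fix") and an offset added to the chi value (or the fixed torsion).
# Values from ideal residue templates. CB is common to all non-GLY residues:
# dihedral(N, C, CA, CB) = +120 deg fixes L-chirality.
.sc_row <- function(name, a, b, c, bond, angle, tors, offset) {
  data.frame(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
             tors = tors, offset = offset, stringsAsFactors = FALSE)
}

.CB <- .sc_row("CB", "N", "C", "CA", 1.530, 109.5, "fix", 120)

SIDECHAIN_GEOMETRY <- list(
  GLY = NULL,
  ALA = .CB,
  SER = rbind(.CB, .sc_row("OG",  "N",  "CA", "CB", 1.417, 110.8, "chi1", 0)),
  CYS = rbind(.CB, .sc_row("SG",  "N",  "CA", "CB", 1.808, 113.8, "chi1", 0)),
  THR = rbind(.CB,
    .sc_row("OG1", "N",  "CA", "CB", 1.433, 109.6, "chi1", 0),
    .sc_row("CG2", "N",  "CA", "CB", 1.521, 110.5, "chi1", -120)),
  VAL = rbind(.CB,
    .sc_row("CG1", "N",  "CA", "CB", 1.527, 110.7, "chi1", 0),
    .sc_row("CG2", "N",  "CA", "CB", 1.527, 110.7, "chi1", 120)),
  LEU = rbind(.CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.530, 116.3, "chi1", 0),
    .sc_row("CD1", "CA", "CB", "CG", 1.530, 109.5, "chi2", 0),
    .sc_row("CD2", "CA", "CB", "CG", 1.530, 109.5, "chi2", 120)),
  ILE = rbind(.CB,
    .sc_row("CG1", "N",  "CA", "CB", 1.530, 110.4, "chi1", 0),
    .sc_row("CG2", "N",  "CA", "CB", 1.521, 110.5, "chi1", -120),
    .sc_row("CD1", "CA", "CB", "CG1", 1.513, 113.8, "chi2", 0)),
  MET = rbind(.CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.520, 114.0, "chi1", 0),
    .sc_row("SD",  "CA", "CB", "CG", 1.814, 109.5, "chi2", 0),
    .sc_row("CE",  "CB", "CG", "SD", 1.814, 100.0, "chi3", 0)),
  PRO = rbind(.CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.543, 105.1, "fix", -23.8),
    .sc_row("CD",  "CA", "CB", "CG", 1.544, 105.1, "fix", 14.0)),
  PHE = rbind(.CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.510, 113.8, "chi1", 0),
    .sc_row("CD1", "CA", "CB", "CG", 1.382, 120.8, "chi2", 0),
    .sc_row("CD2", "CA", "CB", "CG", 1.382, 120.8, "chi2", 180),
    .sc_row("CE1", "CB", "CG", "CD1", 1.382, 120.0, "fix", 180),
    .sc_row("CE2", "CB", "CG", "CD2", 1.382, 120.0, "fix", 180),
    .sc_row("CZ",  "CG", "CD1", "CE1", 1.382, 120.0, "fix", 0)),
  TYR = rbind(.CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.510, 113.8, "chi1", 0),
    .sc_row("CD1", "CA", "CB", "CG", 1.382, 120.8, "chi2", 0),
    .sc_row("CD2", "CA", "CB", "CG", 1.382, 120.8, "chi2", 180),
    .sc_row("CE1", "CB", "CG", "CD1", 1.382, 120.0, "fix", 180),
    .sc_row("CE2", "CB", "CG", "CD2", 1.382, 120.0, "fix", 180),
    .sc_row("CZ",  "CG", "CD1", "CE1", 1.382, 120.0, "fix", 0),
    .sc_row("OH",  "CD1", "CE1", "CZ", 1.376, 120.1, "fix", 180)),
  TRP = rbind(.CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.500, 113.8, "chi1", 0),
    .sc_row("CD1", "CA", "CB", "CG", 1.370, 126.5, "chi2", 0),
    .sc_row("CD2", "CA", "CB", "CG", 1.430, 126.5, "chi2", 180),
    .sc_row("NE1", "CB", "CG", "CD1", 1.380, 109.9, "fix", 180),
    .sc_row("CE2", "CB", "CG", "CD2", 1.410, 106.1, "fix", 180),
    .sc_row("CE3", "CB", "CG", "CD2", 1.400, 134.0, "fix", 0),
    .sc_row("CZ2", "CG", "CD2", "CE2", 1.400, 119.3, "fix", 180),
    .sc_row("CZ3", "CG", "CD2", "CE3", 1.390, 119.8, "fix", 180),
    .sc_row("CH2", "CD2", "CE2", "CZ2", 1.370, 119.8, "fix", 0)),
  HIS = rbind(.CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.500, 113.8, "chi1", 0),
    .sc_row("ND1", "CA", "CB", "CG", 1.380, 122.7, "chi2", 0),
    .sc_row("CD2", "CA", "CB", "CG", 1.360, 131.2, "chi2", 180),
    .sc_row("CE1", "CB", "CG", "ND1", 1.320, 107.9, "fix", 180),
    .sc_row("NE2", "CB", "CG", "CD2", 1.370, 105.3, "fix", 180)),
  ASP = rbind(.CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.520, 112.6, "chi1", 0),
    .sc_row("OD1", "CA", "CB", "CG", 1.250, 120.0, "chi2", 0),
    .sc_row("OD2", "CA", "CB", "CG", 1.250, 120.0, "chi2", 180)),
  ASN = rbind(.CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.520, 112.6, "chi1", 0),
    .sc_row("OD1", "CA", "CB", "CG", 1.231, 120.8, "chi2", 0),
    .sc_row("ND2", "CA", "CB", "CG", 1.328, 116.4, "chi2", 180)),
  GLU = rbind(.CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.520, 114.1, "chi1", 0),
    .sc_row("CD",  "CA", "CB", "CG", 1.520, 112.6, "chi2", 0),
    .sc_row("OE1", "CB", "CG", "CD", 1.250, 120.0, "chi3", 0),
    .sc_row("OE2", "CB", "CG", "CD", 1.250, 120.0, "chi3", 180)),
  GLN = rbind(.CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.520, 114.1, "chi1", 0),
    .sc_row("CD",  "CA", "CB", "CG", 1.520, 112.6, "chi2", 0),
    .sc_row("OE1", "CB", "CG", "CD", 1.231, 120.8, "chi3", 0),
    .sc_row("NE2", "CB", "CG", "CD", 1.328, 116.4, "chi3", 180)),
  LYS = rbind(.CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.520, 114.1, "chi1", 0),
    .sc_row("CD",  "CA", "CB", "CG", 1.520, 111.3, "chi2", 0),
    .sc_row("CE",  "CB", "CG", "CD", 1.520, 111.3, "chi3", 0),
    .sc_row("NZ",  "CG", "CD", "CE", 1.489, 111.9, "chi4", 0)),
  ARG = rbind(.CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.520, 114.1, "chi1", 0),
    .sc_row("CD",  "CA", "CB", "CG", 1.520, 111.3, "chi2", 0),
    .sc_row("NE",  "CB", "CG", "CD", 1.460, 112.0, "chi3", 0),
    .sc_row("CZ",  "CG", "CD", "NE", 1.406, 123.0, "chi4", 0),
    .sc_row("NH1", "CD", "NE", "CZ", 1.391, 121.0, "fix", 180),
    .sc_row("NH2", "CD", "NE", "CZ", 1.391, 121.0, "fix", 0))
)

# extra ring-closing bonds not expressed by the placement tree
RING_CLOSURES <- list(
  PHE = list(c("CE2", "CZ")),
  TYR = list(c("CE2", "CZ")),
  TRP = list(c("NE1", "CE2"), c("CZ3", "CH2")),
  HIS = list(c("CE1", "NE2")),
  PRO = list(c("CD", "N"))
)

#' Canonical heavy atoms of a standard residue
#' @param resid 3-letter residue name.
#' @return character vector of atom names (backbone first).
#' @export
canonical_atoms <- function(resid) {
  if (!resid %in% STANDARD_AA) stop("non-standard residue: ", resid)
  c(BACKBONE_ATOMS, SIDECHAIN_GEOMETRY[[resid]]$name)
}

#' Number of rotatable chi angles of a residue type
#' @param resid 3-letter residue name.
#' @export
n_chi <- function(resid) {
  g <- SIDECHAIN_GEOMETRY[[resid]]
  if (is.null(g)) return(0L)
  sum(grepl("^chi", unique(g$tors)))
}

# Build all side-chain heavy atoms of residue `resid` given named backbone
# coordinates (list/matrix with rows N, CA, C) and a chi vector (degrees).
# Returns a matrix with rownames = atom names.
build_side_chain <- function(bb, resid, chi = numeric(0)) {
  g <- SIDECHAIN_GEOMETRY[[resid]]
  if (is.null(g)) return(matrix(numeric(0), ncol = 3))
  pos <- list(N = bb["N", ], CA = bb["CA", ], C = bb["C", ])
  nch <- n_chi(resid)
  if (length(chi) < nch)
    stop(resid, " needs ", nch, " chi angle(s), got ", length(chi))
  out <- matrix(NA_real_, nrow = nrow(g), ncol = 3,
                dimnames = list(g$name, NULL))
  for (i in seq_len(nrow(g))) {
    r <- g[i, ]
    tor <- if (r$tors == "fix") r$offset else
      chi[as.integer(substr(r$tors, 4, 4))] + r$offset
    p <- place_atom(pos[[r$a]], pos[[r$b]], pos[[r$c]],
                    r$bond, r$angle, tor)
    pos[[r$name]] <- p
    out[i, ] <- p
  }
  out
}

# Measure chi angles of a residue from an atom-name -> coordinate matrix.
measure_chi <- function(xyz, resid) {
  g <- SIDECHAIN_GEOMETRY[[resid]]
  if (is.null(g)) return(numeric(0))
  defs <- g[grepl("^chi", g$tors) & g$offset == 0, , drop = FALSE]
  vapply(seq_len(nrow(defs)), function(i) {
    r <- defs[i, ]
    dihedral_angle(xyz[r$a, ], xyz[r$b, ], xyz[r$c, ], xyz[r$name, ])
  }, numeric(1))
}

# Build an n-residue poly-backbone (N, CA, C, O per residue) from phi/psi
# (recycled to length n). Returns an atom data.frame in hla_structure layout.
build_backbone <- function(n, phi, psi, omega = 180, chain = "C",
                           resid = "ALA", resno_start = 1L) {
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  omega <- rep_len(omega, n)
  resid <- rep_len(resid, n)
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  # C1 at angle N-CA-C = 111 deg from CA->N, in the xy-plane
  th <- 111 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i < n) {
      N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.6, psi[i])
      CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], 1.458, 121.7,
                                omega[i])
      C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], 1.525, 111.0,
                               phi[i + 1])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.4, psi[i] + 180)
  }
  rows <- lapply(seq_len(n), function(i) {
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    data.frame(elety = BACKBONE_ATOMS, resid = resid[i], chain = chain,
               resno = resno_start + i - 1L, icode = "",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
               elesy = c("N", "C", "C", "O"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# element symbol from a heavy-atom PDB name
element_of <- function(elety) substr(gsub("^[0-9]", "", elety), 1, 1)

# rigid motion helpers -------------------------------------------------------

rotation_matrix_axis <- function(axis, angle_deg) {
  u <- unit3(axis); th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st,
           ux * uz * (1 - ct) + uy * st,
           uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),
           uy * uz * (1 - ct) - ux * st,
           uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st,
           ct + uz^2 * (1 - ct)),
         nrow = 3, byrow = TRUE)
}
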