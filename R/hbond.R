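# Geometric hydrogen-bond matching and the soft van der Waals score used in
# rigid-body pose refinement. Heavy-atom criterion: donor-acceptor distance
# 2.6-3.4 A with antecedent-donor-acceptor angle > 120 deg.

# donor atom name -> antecedent atom name (same residue)
.HB_DONOR_ANTE <- c(N = "CA", OG = "CB", OG1 = "CB", OH = "CZ", NE1 = "CD1",
                    ND2 = "CG", NE = "CD", NH1 = "CZ", NH2 = "CZ", NZ = "CE",
                    NE2 = "CD")  # GLN NE2; HIS NE2 antecedent fixed below

.HB_ACCEPTORS <- c("O", "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH", "ND1")

.hb_sites <- function(atoms) {
  don <- atoms[atoms$elety %in% names(.HB_DONOR_ANTE), , drop = FALSE]
  if (nrow(don)) {
    ante_name <- unname(.HB_DONOR_ANTE[don$elety])
    ante_name[don$resid == "HIS" & don$elety == "NE2"] <- "CE1"
    key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety)
    ai <- match(paste(don$chain, don$resno, don$icode, ante_name), key)
    ok <- !is.na(ai)
    don <- don[ok, , drop = FALSE]
    don$ax <- atoms$x[ai[ok]]; don$ay <- atoms$y[ai[ok]]
    don$az <- atoms$z[ai[ok]]
  }
  acc <- atoms[atoms$elety %in% .HB_ACCEPTORS, , drop = FALSE]
  list(don = don, acc = acc)
}

# count satisfied donor-acceptor pairs between atom sets A and B (both
# directions)
count_hbonds <- function(atoms_a, atoms_b, dmin = 2.6, dmax = 3.4,
                         amin = 120) {
  one_way <- function(d, a) {
    if (!nrow(d) || !nrow(a)) return(0L)
    dm <- as.matrix(d[, c("x", "y", "z")])
    am <- as.matrix(a[, c("x", "y", "z")])
    an <- as.matrix(d[, c("ax", "ay", "az")])
    cnt <- 0L
    for (k in seq_len(nrow(dm))) {
      dist <- sqrt(colSums((t(am) - dm[k, ])^2))
      cand <- which(dist >= dmin & dist <= dmax)
      for (j in cand) {
        ang <- bond_angle(an[k, ], dm[k, ], am[j, ])
        if (ang > amin) cnt <- cnt + 1L
      }
    }
    cnt
  }
  sa <- .hb_sites(atoms_a); sb <- .hb_sites(atoms_b)
  one_way(sa$don, sb$acc) + one_way(sb$don, sa$acc)
}

# capped soft Lennard-Jones interaction energy between two atom sets
# (kcal/mol, per-pair cap +10)
soft_vdw <- function(atoms_a, atoms_b, ap_a, ap_b, cap = 10) {
  if (!nrow(atoms_a) || !nrow(atoms_b)) return(0)
  xa <- as.matrix(atoms_a[, c("x", "y", "z")])
  xb <- as.matrix(atoms_b[, c("x", "y", "z")])
  tot <- 0
  for (k in seq_len(nrow(xa))) {
    r <- sqrt(colSums((t(xb) - xa[k, ])^2))
    eps <- sqrt(ap_a$epsilon[k] * ap_b$epsilon)
    rmin <- ap_a$rmin2[k] + ap_b$rmin2
    sr6 <- (rmin / pmax(r, 0.5))^6
    tot <- tot + sum(pmin(eps * (sr6^2 - 2 * sr6), cap))
  }
  tot
}

# rigid-refinement pose score: H-bond matching weighted 1.0 plus capped
# soft vdW weighted 0.2 (higher is better)
pose_score <- function(pep_atoms, rec_atoms, ap_pep, ap_rec) {
  hb <- count_hbonds(pep_atoms, rec_atoms)
  ev <- soft_vdw(pep_atoms, rec_atoms, ap_pep, ap_rec)
  hb * 1.0 - 0.2 * ev
}
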