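#' Energy decomposition container
#'
#' All terms in kcal/mol; `total` is their sum (exact by construction).
#'
#' @param bond,angle,torsion,lj,coulomb,gb_polar,sasa_nonpolar term values.
#' @return object of class `energy_breakdown`.
#' @export
energy_breakdown <- function(bond = 0, angle = 0, torsion = 0, lj = 0,
                             coulomb = 0, gb_polar = 0, sasa_nonpolar = 0) {
  out <- list(bond = bond, angle = angle, torsion = torsion, lj = lj,
              coulomb = coulomb, gb_polar = gb_polar,
              sasa_nonpolar = sasa_nonpolar)
  out$total <- sum(unlist(out))
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("  %-14s %12.4f kcal/mol\n", nm, x[[nm]]))
  invisible(x)
}

# vectorized LJ and Coulomb over a pair table
.pair_energies <- function(xyz, ap, pairs, params) {
  if (!nrow(pairs)) return(c(lj = 0, coulomb = 0))
  i <- pairs[, 1]; j <- pairs[, 2]
  d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  eps <- sqrt(ap$epsilon[i] * ap$epsilon[j])
  rmin <- ap$rmin2[i] + ap$rmin2[j]
  sr6 <- (rmin / d)^6
  lj <- sum(pairs[, 3] * eps * (sr6^2 - 2 * sr6))
  coul <- sum(pairs[, 4] * params$coulomb_k * ap$charge[i] * ap$charge[j] /
                (params$e_in * d))
  c(lj = lj, coulomb = coul)
}

#' Molecular-mechanics (vacuum) energy
#'
#' Bonded terms are harmonic about the idealized geometry (torsion
#' preferences are carried by the rotamer priors during packing, so the
#' torsion term is reported as 0); nonbonded Lennard-Jones and Coulomb sums
#' run over all pairs with 1-2/1-3 exclusions and scaled 1-4 interactions,
#' with no distance cutoff.
#'
#' @param s an [hla_structure()] with all atoms parameterizable.
#' @param params [ff_default_params()].
#' @return an [energy_breakdown()] with vacuum terms only.
#' @export
mm_energy <- function(s, params = ff_default_params()) {
  ap <- atom_params(s, params)
  xyz <- coords(s)
  topo <- build_topology(s)
  eb <- 0
  if (nrow(topo$bonds)) {
    bi <- topo$bonds[, 1]; bj <- topo$bonds[, 2]
    r <- sqrt(rowSums((xyz[bi, , drop = FALSE] - xyz[bj, , drop = FALSE])^2))
    eb <- sum(params$bond_k * (r - topo$bonds[, 3])^2)
  }
  ea <- 0
  if (nrow(topo$angles)) {
    th <- vapply(seq_len(nrow(topo$angles)), function(k)
      bond_angle(xyz[topo$angles[k, 1], ], xyz[topo$angles[k, 2], ],
                 xyz[topo$angles[k, 3], ]), numeric(1))
    ea <- sum(params$angle_k * ((th - topo$angles[, 4]) * pi / 180)^2)
  }
  nb <- .pair_energies(xyz, ap, nonbonded_pairs(topo, params), params)
  energy_breakdown(bond = eb, angle = ea, torsion = 0,
                   lj = nb[["lj"]], coulomb = nb[["coulomb"]])
}

# closed-form HCT descreening integral of 1/(4 pi r^4) over the scaled
# sphere (radius sc, centre distance d) outside the intrinsic radius rho
.descreen_I <- function(d, rho, sc) {
  out <- numeric(length(d))
  act <- d + sc > rho & sc > 0
  if (!any(act)) return(out)
  d1 <- d[act]; s1 <- sc[act]
  L <- pmax(rho[act], abs(d1 - s1)); U <- d1 + s1
  f <- function(r, dd, ss)
    -1 / (2 * r) + (dd^2 - ss^2) / (8 * dd * r^2) - log(r) / (4 * dd)
  val <- f(U, d1, s1) - f(L, d1, s1)
  eng <- d1 < s1 & rho[act] < (s1 - d1)   # atom centre engulfed: full shell
  val[eng] <- val[eng] + 1 / rho[act][eng] - 1 / (s1[eng] - d1[eng])
  out[act] <- val
  out
}

#' Effective Born radii (pairwise descreening)
#'
#' HCT-style analytic pairwise descreening: each neighbour j reduces atom i's
#' solvation by the integral of the Coulomb-field kernel over j's scaled
#' sphere, so 1/R_i = 1/rho_i - sum_j I_ij. An isolated atom's effective
#' radius equals its intrinsic radius.
#'
#' @param s an [hla_structure()].
#' @param params [ff_default_params()].
#' @return numeric vector of per-atom effective radii (Angstrom).
#' @export
born_radii <- function(s, params = ff_default_params()) {
  ap <- atom_params(s, params)
  xyz <- coords(s)
  n <- nrow(xyz)
  inv <- 1 / ap$gb_radius
  for (i in seq_len(n)) {
    j <- setdiff(seq_len(n), i)
    d <- sqrt(colSums((t(xyz[j, , drop = FALSE]) - xyz[i, ])^2))
    inv[i] <- inv[i] - sum(.descreen_I(d, rep(ap$gb_radius[i], length(j)),
                                       ap$gb_screen[j] * ap$gb_radius[j]))
  }
  1 / pmax(inv, 1e-3)
}

#' Generalized-Born polar solvation energy
#'
#' \deqn{\Delta G_{pol} = -\tfrac12 C (1/\epsilon_{in} - 1/\epsilon_{out})
#'   \sum_{ij} q_i q_j / f_{GB}} with
#' \eqn{f_{GB} = \sqrt{r_{ij}^2 + R_i R_j \exp(-r_{ij}^2/(4 R_i R_j))}} and
#' C = 332.06 kcal A / mol / e^2. Reduces to the Born formula for a single
#' ion and to the screened-Coulomb limit at large separation.
#'
#' @param s an [hla_structure()].
#' @param params [ff_default_params()].
#' @param radii optional precomputed [born_radii()].
#' @return polar solvation energy, kcal/mol.
#' @export
gb_polar <- function(s, params = ff_default_params(), radii = NULL) {
  ap <- atom_params(s, params)
  if (all(ap$charge == 0)) return(0)
  if (is.null(radii)) radii <- born_radii(s, params)
  xyz <- coords(s)
  n <- nrow(xyz)
  pref <- -0.5 * params$coulomb_k * (1 / params$e_in - 1 / params$e_out)
  tot <- sum(ap$charge^2 / radii)    # self terms
  if (n > 1) {
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- pr[, 1]; j <- pr[, 2]
    r2 <- rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2)
    rr <- radii[i] * radii[j]
    fgb <- sqrt(r2 + rr * exp(-r2 / (4 * rr)))
    tot <- tot + 2 * sum(ap$charge[i] * ap$charge[j] / fgb)
  }
  pref * tot
}

# deterministic Fibonacci sphere point set
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic sphere-point estimate with a water-sized probe.
#'
#' @param s an [hla_structure()].
#' @param probe probe radius, Angstrom (default 1.4).
#' @param n_points sphere points per atom (default 960).
#' @param params [ff_default_params()] (for atomic radii).
#' @return list with `per_atom` (A^2 vector) and `total` (A^2).
#' @export
sasa <- function(s, probe = 1.4, n_points = 960,
                 params = ff_default_params()) {
  ap <- atom_params(s, params)
  xyz <- coords(s)
  n <- nrow(xyz)
  rad <- ap$gb_radius + probe
  pts <- .fib_sphere(n_points)
  per <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2)) < rad[i] + rad - 1e-9)
    nb <- setdiff(nb, i)
    p <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      d2 <- rowSums(sweep(p[free, , drop = FALSE], 2, xyz[j, ])^2)
      free[free] <- d2 > rad[j]^2
    }
    per[i] <- 4 * pi * rad[i]^2 * mean(free)
  }
  list(per_atom = per, total = sum(per))
}

# total single-state free energy G = E_MM + G_GB + gamma*SASA + b
.state_g <- function(s, params) {
  mm <- mm_energy(s, params)
  gb <- gb_polar(s, params)
  sa <- sasa(s, params = params)$total
  bd <- energy_breakdown(bond = mm$bond, angle = mm$angle,
                         torsion = mm$torsion, lj = mm$lj,
                         coulomb = mm$coulomb, gb_polar = gb,
                         sasa_nonpolar = params$gamma * sa + params$b)
  bd
}

#' Binding free energy (single-geometry MM-GBSA)
#'
#' \eqn{\Delta G = G(complex) - G(receptor) - G(peptide)} with every state
#' evaluated at the complex geometry (single-trajectory decomposition, no
#' entropy term). Each G combines vacuum molecular mechanics, generalized-
#' Born polar solvation and a surface-area nonpolar term.
#'
#' @param s the complex, an [hla_structure()].
#' @param receptor_sel,peptide_sel chain ids (or atom index vectors) of the
#'   two binding partners; must not overlap and must cover disjoint atoms.
#' @param params [ff_default_params()].
#' @return object of class `binding_dg`: list with `dg` (kcal/mol), per-state
#'   `parts` breakdowns and the parameter fingerprint.
#' @export
binding_dg <- function(s, receptor_sel = NULL, peptide_sel = NULL,
                       params = ff_default_params()) {
  if (is.null(peptide_sel)) peptide_sel <- peptide_chain(s)
  if (is.null(receptor_sel))
    receptor_sel <- setdiff(chain_ids(s), peptide_sel)
  to_idx <- function(sel) {
    if (is.character(sel)) atom_select(s, chain = sel) else as.integer(sel)
  }
  ri <- to_idx(receptor_sel); pi_ <- to_idx(peptide_sel)
  if (length(intersect(ri, pi_)))
    stop("receptor and peptide selections overlap")
  sub <- function(idx, id) hla_structure(id, s$atoms[idx, , drop = FALSE],
                                         s$resolution)
  g_c <- .state_g(s, params)
  g_r <- .state_g(sub(ri, "receptor"), params)
  g_p <- .state_g(sub(pi_, "peptide"), params)
  out <- list(dg = g_c$total - g_r$total - g_p$total,
              parts = list(complex = g_c, receptor = g_r, peptide = g_p),
              fingerprint = params$fingerprint)
  class(out) <- "binding_dg"
  out
}

#' @export
print.binding_dg <- function(x, ...) {
  cat(sprintf("<binding_dg> dG = %.3f kcal/mol\n", x$dg))
  invisible(x)
}

#' Binding free-energy difference between receptor variants
#'
#' \eqn{\Delta\Delta G = \Delta G_{variant} - \Delta G_{reference}}; negative
#' values predict higher binding affinity for the variant.
#'
#' @param dg_variant,dg_reference [binding_dg()] results computed with
#'   identical parameters.
#' @return delta-delta-G, kcal/mol.
#' @export
ddg <- function(dg_variant, dg_reference) {
  if (!identical(dg_variant$fingerprint, dg_reference$fingerprint))
    stop("binding_dg objects were computed with different parameters")
  dg_variant$dg - dg_reference$dg
}
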