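# Force-field parameterization: united-heavy-atom Lennard-Jones, partial
# charges, generalized-Born radii/screening, and covalent topology
# (bonds/angles/exclusions) derived from the idealized geometry tables.

.ad_cache <- new.env(parent = emptyenv())

#' Default force-field parameters
#'
#' Minimal amber-style heavy-atom parameter set (united hydrogens): per-type
#' LJ epsilon (kcal/mol) and r_min/2 (Angstrom), per-atom partial charges (e)
#' summing to each residue's formal charge, intrinsic GB radii and HCT
#' screening factors, plus global dielectrics and the nonpolar surface
#' coefficient. All values are config-overridable.
#'
#' @param e_in,e_out interior and solvent dielectric constants.
#' @param gamma nonpolar surface coefficient, kcal/mol/A^2.
#' @param b nonpolar offset, kcal/mol (a per-state constant; it cancels in
#'   delta-delta-G comparisons and defaults to 0 so that the binding free
#'   energy of a non-interacting pair is exactly 0).
#' @return object of class `ff_params`.
#' @export
ff_default_params <- function(e_in = 1, e_out = 78.5, gamma = 0.00542,
                              b = 0) {
  if (is.null(.ad_cache$ff_tables)) {
    types <- utils::read.delim(system.file("extdata", "ff_types.tsv",
                                           package = "anchordock"),
                               stringsAsFactors = FALSE)
    atoms <- utils::read.delim(system.file("extdata", "ff_atoms.tsv",
                                           package = "anchordock"),
                               stringsAsFactors = FALSE)
    .ad_cache$ff_tables <- list(types = types, atoms = atoms)
  }
  tb <- .ad_cache$ff_tables
  p <- list(types = tb$types, atoms = tb$atoms,
            e_in = e_in, e_out = e_out, gamma = gamma, b = b,
            coulomb_k = 332.06, scale14_lj = 0.5, scale14_coul = 1 / 1.2,
            bond_k = 300, angle_k = 40)
  p$fingerprint <- paste(format(c(e_in, e_out, gamma, b), digits = 10),
                         collapse = "|")
  class(p) <- "ff_params"
  p
}

#' Per-atom force-field assignment
#'
#' @param s an [hla_structure()].
#' @param params an `ff_params` object.
#' @return data.frame aligned with `s$atoms`: `epsilon`, `rmin2`, `charge`,
#'   `gb_radius`, `gb_screen`.
#' @export
atom_params <- function(s, params = ff_default_params()) {
  key <- paste(s$atoms$resid, s$atoms$elety)
  tkey <- paste(params$atoms$resid, params$atoms$elety)
  idx <- match(key, tkey)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("cannot parameterize atom '", s$atoms$elety[bad], "' of residue ",
         s$atoms$resid[bad], " ", s$atoms$resno[bad], " (chain ",
         s$atoms$chain[bad], ")")
  }
  at <- params$atoms[idx, , drop = FALSE]
  ti <- match(at$type, params$types$type)
  data.frame(epsilon = params$types$epsilon[ti],
             rmin2 = params$types$rmin2[ti],
             charge = at$charge,
             gb_radius = params$types$gb_radius[ti],
             gb_screen = params$types$gb_screen[ti])
}

# backbone reference angles (vertex in middle); inter-residue handled apart
.BB_ANGLES <- list(c("N", "CA", "C", 111.0), c("CA", "C", "O", 120.4),
                   c("N", "CA", "CB", 110.5))

# Covalent topology of a structure: bonds with ideal lengths, angles with
# ideal values, and the bonded graph (for 1-2/1-3/1-4 exclusions).
build_topology <- function(s) {
  a <- s$atoms
  n <- nrow(a)
  akey <- paste(a$chain, a$resno, a$icode, a$elety, sep = "|")
  find <- function(chain, resno, icode, elety)
    match(paste(chain, resno, icode, elety, sep = "|"), akey)
  bonds <- list()
  add_bond <- function(i, j, r0) {
    if (!is.na(i) && !is.na(j))
      bonds[[length(bonds) + 1]] <<- c(i, j, r0)
  }
  rkey <- paste(a$chain, a$resno, a$icode, sep = "|")
  for (rk in unique(rkey)) {
    rows <- which(rkey == rk)
    ch <- a$chain[rows[1]]; rn <- a$resno[rows[1]]; ic <- a$icode[rows[1]]
    res <- a$resid[rows[1]]
    f <- function(el) find(ch, rn, ic, el)
    add_bond(f("N"), f("CA"), 1.458)
    add_bond(f("CA"), f("C"), 1.525)
    add_bond(f("C"), f("O"), 1.231)
    g <- SIDECHAIN_GEOMETRY[[res]]
    if (!is.null(g))
      for (i in seq_len(nrow(g)))
        add_bond(f(g$c[i]), f(g$name[i]), g$bond[i])
    cl <- RING_CLOSURES[[res]]
    if (!is.null(cl)) {
      r0s <- c(PHE = 1.38, TYR = 1.38, TRP = 1.37, HIS = 1.32, PRO = 1.47)
      for (b in cl) add_bond(f(b[1]), f(b[2]), r0s[[res]])
    }
    # peptide bond to the next residue (consecutive author numbering and
    # physically adjacent -- numbering alone must not bridge chain breaks)
    nxt <- which(a$chain == ch & a$resno == rn + 1L & a$elety == "N")
    ci <- f("C")
    if (length(nxt) && !is.na(ci)) {
      d <- sqrt(sum((c(a$x[ci], a$y[ci], a$z[ci]) -
                       c(a$x[nxt[1]], a$y[nxt[1]], a$z[nxt[1]]))^2))
      if (d < 2.5) add_bond(ci, nxt[1], 1.329)
    }
  }
  B <- if (length(bonds)) do.call(rbind, bonds) else
    matrix(numeric(0), ncol = 3)
  if (nrow(B))
    B <- B[!duplicated(paste(pmin(B[, 1], B[, 2]), pmax(B[, 1], B[, 2]))), ,
           drop = FALSE]
  # adjacency + angles
  adj <- vector("list", n)
  for (k in seq_len(nrow(B))) {
    i <- B[k, 1]; j <- B[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  angles <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    cmb <- utils::combn(sort(nb), 2)
    for (k in seq_len(ncol(cmb)))
      angles[[length(angles) + 1]] <- c(cmb[1, k], j, cmb[2, k])
  }
  A <- if (length(angles)) do.call(rbind, angles) else
    matrix(numeric(0), ncol = 3)
  theta0 <- vapply(seq_len(nrow(A)), function(k) {
    i <- A[k, 1]; j <- A[k, 2]; l <- A[k, 3]
    .angle_theta0(a$resid[j], a$elety[i], a$elety[j], a$elety[l],
                  a$resno[i], a$resno[j], a$resno[l])
  }, numeric(1))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(B))
    g <- igraph::add_edges(g, as.vector(t(B[, 1:2, drop = FALSE])))
  list(bonds = B, angles = cbind(A, theta0), graph = g, n = n)
}

.angle_theta0 <- function(res_j, ni, nj, nl, ri, rj, rl) {
  # inter-residue peptide-bond angles
  if (ri != rj || rj != rl) {
    key <- paste(sort(c(ni, nl)), collapse = "-")
    if (nj == "C" && key == "CA-N") return(116.6)
    if (nj == "C" && key == "N-O") return(123.0)
    if (nj == "N" && key == "C-CA") return(121.7)
    if (nj == "N" && key == "C-CD") return(125.0)   # proline
    return(115.0)
  }
  for (bb in .BB_ANGLES)
    if (nj == bb[2] && setequal(c(ni, nl), c(bb[1], bb[3])))
      return(as.numeric(bb[4]))
  g <- SIDECHAIN_GEOMETRY[[res_j]]
  if (!is.null(g)) {
    for (k in seq_len(nrow(g))) {
      if (g$c[k] == nj && setequal(c(ni, nl), c(g$b[k], g$name[k])))
        return(g$angle[k])
    }
  }
  # fallback by vertex element/context
  el <- substr(nj, 1, 1)
  if (el == "S") return(100)
  if (el == "O") return(109)
  if (res_j %in% names(RING_CLOSURES) || el == "N") return(118)
  111
}

# pair table with exclusion handling: columns i, j, slj, scoul
nonbonded_pairs <- function(topo, params) {
  n <- topo$n
  if (n < 2) return(matrix(numeric(0), ncol = 4))
  D <- igraph::distances(topo$graph)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  gd <- D[pr]
  keep <- gd >= 3  # graph distance 3 = 1-4; >3 (incl Inf) = full
  pr <- pr[keep, , drop = FALSE]; gd <- gd[keep]
  slj <- ifelse(gd == 3, params$scale14_lj, 1)
  scoul <- ifelse(gd == 3, params$scale14_coul, 1)
  cbind(i = pr[, 1], j = pr[, 2], slj = slj, scoul = scoul)
}
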