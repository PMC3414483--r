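# Short gradient-based Cartesian minimization of a subset of atoms.
# Objective: softened Lennard-Jones + Coulomb (1-2/1-3 excluded, 1-4
# scaled), harmonic bonds and harmonic angles about their idealized
# values, plus an optional harmonic positional restraint to the starting
# coordinates (used where adherence to a template matters more than full
# relaxation). Terms entirely within the fixed region are constant and
# dropped.

.lj_soft <- function(r, eps, rmin) {
  rs <- 0.7 * rmin
  rr <- pmax(r, rs)
  sr6 <- (rmin / rr)^6
  e <- eps * (sr6^2 - 2 * sr6)
  de <- 12 * eps * (sr6 - sr6^2) / rr
  low <- r < rs
  e[low] <- e[low] + de[low] * (r[low] - rs[low])
  list(e = e, de = de)
}

.coul_soft <- function(r, qq, params) {
  rf <- 0.8
  rr <- pmax(r, rf)
  k <- params$coulomb_k / params$e_in
  e <- k * qq / rr
  de <- -k * qq / rr^2
  low <- r < rf
  e[low] <- e[low] + de[low] * (r[low] - rf)
  list(e = e, de = de)
}

# vectorized angle values and derivative frames for triples (i, j, k)
.angle_eval <- function(xyz, tri) {
  u <- xyz[tri[, 1], , drop = FALSE] - xyz[tri[, 2], , drop = FALSE]
  v <- xyz[tri[, 3], , drop = FALSE] - xyz[tri[, 2], , drop = FALSE]
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  ct <- rowSums(u * v) / pmax(nu * nv, 1e-12)
  ct <- pmin(1 - 1e-10, pmax(-1 + 1e-10, ct))
  th <- acos(ct)
  st <- sqrt(1 - ct^2)
  # d(theta)/d(ri) and d(theta)/d(rk)
  gi <- (u * (ct / nu) - v * (1 / nv)) / (nu * st)
  gk <- (v * (ct / nv) - u * (1 / nu)) / (nv * st)
  list(theta = th, gi = gi, gk = gk)
}

#' Minimize a structure with a mobile atom subset
#'
#' Short conjugate-gradient minimization in Cartesian coordinates. Only the
#' atoms in `mobile` move; everything else is a fixed environment. The
#' objective combines softened nonbonded terms with harmonic bond and angle
#' terms about the idealized geometry, plus an optional positional
#' restraint of strength `restraint_k` (kcal/mol/A^2) to the input
#' coordinates.
#'
#' @param s an [hla_structure()].
#' @param mobile integer atom indices allowed to move.
#' @param params [ff_default_params()].
#' @param maxit maximum optimizer iterations (default 80).
#' @param restraint_k positional restraint constant (default 1); a weak
#'   tether that stands in for the absent torsional potential.
#' @return list: `structure` (minimized), `e_initial`, `e_final` (objective
#'   values, kcal/mol), `converged`.
#' @export
minimize_structure <- function(s, mobile, params = ff_default_params(),
                               maxit = 80, restraint_k = 1) {
  mobile <- sort(unique(as.integer(mobile)))
  ap <- atom_params(s, params)
  topo <- build_topology(s)
  pairs <- nonbonded_pairs(topo, params)
  is_mob <- seq_len(topo$n) %in% mobile
  keep <- is_mob[pairs[, 1]] | is_mob[pairs[, 2]]
  pairs <- pairs[keep, , drop = FALSE]
  # pairs far beyond interaction range at the start stay negligible; drop
  # them from the working list
  if (nrow(pairs)) {
    xyz_i <- coords(s)
    d0 <- sqrt(rowSums((xyz_i[pairs[, 1], , drop = FALSE] -
                          xyz_i[pairs[, 2], , drop = FALSE])^2))
    pairs <- pairs[d0 < 14, , drop = FALSE]
  }
  bonds <- topo$bonds[is_mob[topo$bonds[, 1]] | is_mob[topo$bonds[, 2]], ,
                      drop = FALSE]
  tri <- topo$angles
  tri <- tri[is_mob[tri[, 1]] | is_mob[tri[, 2]] | is_mob[tri[, 3]], ,
             drop = FALSE]
  xyz0 <- coords(s)
  x0 <- as.vector(t(xyz0[mobile, , drop = FALSE]))
  mmap <- match(seq_len(topo$n), mobile)     # atom -> mobile slot or NA

  acc_grad <- function(grad, idx, gm) {
    ok <- !is.na(mmap[idx])
    if (any(ok)) {
      acc <- rowsum(gm[ok, , drop = FALSE], mmap[idx][ok])
      rows <- as.integer(rownames(acc))
      grad[rows, ] <- grad[rows, , drop = FALSE] + acc
    }
    grad
  }

  eval_all <- function(x, want_grad) {
    xyz <- xyz0
    xyz[mobile, ] <- matrix(x, ncol = 3, byrow = TRUE)
    grad <- if (want_grad) matrix(0, length(mobile), 3) else NULL
    e <- 0
    if (nrow(pairs)) {
      i <- pairs[, 1]; j <- pairs[, 2]
      dvec <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
      r <- sqrt(rowSums(dvec^2))
      lj <- .lj_soft(r, pairs[, 3] * sqrt(ap$epsilon[i] * ap$epsilon[j]),
                     ap$rmin2[i] + ap$rmin2[j])
      cl <- .coul_soft(r, pairs[, 4] * ap$charge[i] * ap$charge[j], params)
      e <- e + sum(lj$e) + sum(cl$e)
      if (want_grad) {
        gm <- dvec * ((lj$de + cl$de) / pmax(r, 1e-8))
        grad <- acc_grad(grad, i, gm)
        grad <- acc_grad(grad, j, -gm)
      }
    }
    if (nrow(bonds)) {
      i <- bonds[, 1]; j <- bonds[, 2]
      dvec <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
      r <- sqrt(rowSums(dvec^2))
      e <- e + sum(params$bond_k * (r - bonds[, 3])^2)
      if (want_grad) {
        gm <- dvec * (2 * params$bond_k * (r - bonds[, 3]) / pmax(r, 1e-8))
        grad <- acc_grad(grad, i, gm)
        grad <- acc_grad(grad, j, -gm)
      }
    }
    if (nrow(tri)) {
      av <- .angle_eval(xyz, tri)
      dth <- av$theta - tri[, 4] * pi / 180
      e <- e + sum(params$angle_k * dth^2)
      if (want_grad) {
        w <- 2 * params$angle_k * dth
        grad <- acc_grad(grad, tri[, 1], av$gi * w)
        grad <- acc_grad(grad, tri[, 3], av$gk * w)
        grad <- acc_grad(grad, tri[, 2], -(av$gi + av$gk) * w)
      }
    }
    dx <- x - x0
    if (restraint_k > 0) e <- e + restraint_k * sum(dx^2)
    if (want_grad) {
      grad <- as.vector(t(grad))
      if (restraint_k > 0) grad <- grad + 2 * restraint_k * dx
      return(list(e = e, grad = grad))
    }
    e
  }

  fn <- function(x) eval_all(x, FALSE)
  gr <- function(x) eval_all(x, TRUE)$grad
  e0 <- fn(x0)
  res <- stats::optim(x0, fn, gr, method = "CG",
                      control = list(maxit = maxit))
  best <- if (res$value <= e0) res$par else x0
  e1 <- min(res$value, e0)
  out <- set_coords(s, matrix(best, ncol = 3, byrow = TRUE), mobile)
  list(structure = out, e_initial = e0, e_final = e1,
       converged = res$convergence == 0)
}
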