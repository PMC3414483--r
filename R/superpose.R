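#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares optimal rotation + translation mapping `mob` onto `ref`,
#' computed by singular value decomposition of the cross-covariance matrix
#' with the usual determinant correction so the rotation is proper
#' (det = +1, no reflection).
#'
#' @param ref,mob numeric n x 3 coordinate matrices (n >= 3, non-collinear).
#' @return list of class `rigid_transform` with elements `rotation` (3 x 3),
#'   `translation` (length-3) and `rmsd` (Angstrom); the transform acts as
#'   `x %*% t(rotation) + translation`.
#' @export
kabsch <- function(ref, mob) {
  ref <- as.matrix(ref); mob <- as.matrix(mob)
  if (nrow(ref) != nrow(mob))
    stop("coordinate sets differ in length (", nrow(ref), " vs ",
         nrow(mob), ")")
  if (nrow(ref) < 3) stop("need at least 3 points")
  cr <- colMeans(ref); cm <- colMeans(mob)
  P <- sweep(mob, 2, cm); Q <- sweep(ref, 2, cr)
  s <- svd(crossprod(P, Q))
  if (min(s$d) < 1e-10 && sum(s$d > 1e-10) < 2)
    stop("degenerate geometry: points are (near-)collinear")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)            # maps centered mob -> centered ref
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  tr <- cr - as.vector(R %*% cm)
  out <- list(rotation = R, translation = tr, rmsd = rmsd)
  class(out) <- "rigid_transform"
  out
}

#' Apply a rigid transform to coordinates or a structure
#' @param x an n x 3 matrix or an [hla_structure()].
#' @param transform a `rigid_transform` from [kabsch()].
#' @return object of the same type with transformed coordinates.
#' @export
apply_transform <- function(x, transform) {
  if (inherits(x, "hla_structure")) {
    xyz <- coords(x)
    return(set_coords(x, sweep(xyz %*% t(transform$rotation), 2,
                               transform$translation, "+")))
  }
  sweep(as.matrix(x) %*% t(transform$rotation), 2, transform$translation, "+")
}

# matched atom indices between two complexes on the heavy chain
matched_heavy_atoms <- function(ref, mob, selection = "backbone",
                                exclude_peptide = TRUE) {
  rc <- if (exclude_peptide) heavy_chain(ref) else chain_ids(ref)
  mc <- if (exclude_peptide) heavy_chain(mob) else chain_ids(mob)
  ra <- ref$atoms[ref$atoms$chain %in% rc, , drop = FALSE]
  ma <- mob$atoms[mob$atoms$chain %in% mc, , drop = FALSE]
  if (selection == "backbone") {
    ra <- ra[ra$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    ma <- ma[ma$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  }
  rk <- paste(ra$resno, ra$icode, ra$elety)
  mk <- paste(ma$resno, ma$icode, ma$elety)
  common <- intersect(rk, mk)
  list(ref_rows = as.integer(rownames(ra))[match(common, rk)],
       mob_rows = as.integer(rownames(ma))[match(common, mk)])
}

#' Superpose one p-HLA complex onto another
#'
#' Computes the optimal rigid transform using only HLA heavy-chain atoms
#' (peptide excluded by default), matching residues by author residue number,
#' and applies it to the whole mobile structure.
#'
#' @param ref,mobile [hla_structure()] complexes.
#' @param selection `"backbone"` (N, CA, C, O) or `"allatom"`.
#' @param exclude_peptide exclude the peptide chain from the fit
#'   (default TRUE).
#' @return list with `structure` (transformed mobile), `rmsd` (Angstrom over
#'   the fitted atoms) and `transform`.
#' @export
superpose_complexes <- function(ref, mobile,
                                selection = c("backbone", "allatom"),
                                exclude_peptide = TRUE) {
  selection <- match.arg(selection)
  m <- matched_heavy_atoms(ref, mobile, selection, exclude_peptide)
  if (length(m$ref_rows) < 3)
    stop("fewer than 3 matched atoms between '", ref$id, "' and '",
         mobile$id, "'")
  tr <- kabsch(coords(ref, m$ref_rows), coords(mobile, m$mob_rows))
  list(structure = apply_transform(mobile, tr), rmsd = tr$rmsd,
       transform = tr)
}

# residue-wise pairwise RMSD summary over a list of already-superposed
# coordinate extractors: fetch(s, pos) -> matrix of selected atoms
.position_rmsd_table <- function(structures, positions, fetch) {
  n <- length(structures)
  pairs <- utils::combn(n, 2)
  rows <- lapply(positions, function(pos) {
    mats <- lapply(structures, fetch, pos = pos)
    base <- sort(Reduce(intersect, lapply(mats, rownames)))
    if (!length(base))
      stop("no common atoms at position ", pos)
    vals <- apply(pairs, 2, function(pr) {
      a <- mats[[pr[1]]][base, , drop = FALSE]
      b <- mats[[pr[2]]][base, , drop = FALSE]
      sqrt(mean(rowSums((a - b)^2)))
    })
    q <- stats::quantile(vals, c(.25, .5, .75), names = FALSE)
    iqr <- q[3] - q[1]
    out_lo <- q[1] - 1.5 * iqr; out_hi <- q[3] + 1.5 * iqr
    data.frame(position = pos, n_pairs = length(vals), mean = mean(vals),
               median = q[2], q1 = q[1], q3 = q[3],
               min = min(vals), max = max(vals),
               n_outliers = sum(vals < out_lo | vals > out_hi))
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("conservation_table", class(tab))
  tab
}

#' Per-position RMSD conservation table
#'
#' For every pair of (already superposed) structures and every listed heavy-
#' chain residue position, the RMSD over that residue's selected atoms is
#' computed and summarised (mean, median, quartiles, min/max, 1.5 x IQR
#' outlier count) — the numbers behind a per-residue conservation boxplot.
#'
#' @param structures list of superposed [hla_structure()] objects (>= 2).
#' @param positions integer residue numbers (e.g. a [groove_definition()]).
#' @param selection `"backbone"` or `"allatom"`.
#' @return a `conservation_table` data.frame, one row per position.
#' @export
per_position_rmsd <- function(structures, positions,
                              selection = c("backbone", "allatom")) {
  selection <- match.arg(selection)
  if (length(structures) < 2) stop("need at least 2 structures")
  positions <- as.integer(unclass(positions))
  fetch <- function(s, pos) {
    ch <- heavy_chain(s)
    a <- s$atoms[s$atoms$chain == ch & s$atoms$resno == pos, , drop = FALSE]
    if (!nrow(a)) stop("position ", pos, " absent from '", s$id, "'")
    if (selection == "backbone")
      a <- a[a$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    m <- as.matrix(a[, c("x", "y", "z")]); rownames(m) <- a$elety
    m
  }
  .position_rmsd_table(structures, positions, fetch)
}

#' Peptide variability after heavy-chain superposition
#'
#' Maps each complex's peptide into the shared reference frame using the
#' transform obtained from a peptide-excluded superposition, then summarises
#' per-position (P1..P9) pairwise backbone RMSD across the set.
#'
#' @param structures list of p-HLA complexes (>= 2) with equal-length
#'   peptides.
#' @param transforms optional list of `rigid_transform`s (one per structure).
#'   When `NULL`, each complex is superposed onto the first by heavy-chain
#'   backbone with the peptide excluded.
#' @param selection `"backbone"` or `"allatom"`.
#' @return a `conservation_table` over peptide positions.
#' @export
peptide_variability <- function(structures, transforms = NULL,
                                selection = c("backbone", "allatom")) {
  selection <- match.arg(selection)
  if (length(structures) < 2) stop("need at least 2 structures")
  if (is.null(transforms)) {
    transforms <- lapply(structures, function(s)
      superpose_complexes(structures[[1]], s, "backbone")$transform)
  }
  peps <- mapply(function(s, tr) apply_transform(extract_peptide(s), tr),
                 structures, transforms, SIMPLIFY = FALSE)
  lens <- vapply(peps, function(p) n_residues(p, chain_ids(p)[1]), integer(1))
  if (length(unique(lens)) != 1)
    stop("peptide length mismatch across set: ",
         paste(unique(lens), collapse = ", "))
  fetch <- function(p, pos) {
    a <- p$atoms[p$atoms$resno == pos, , drop = FALSE]
    if (selection == "backbone")
      a <- a[a$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    m <- as.matrix(a[, c("x", "y", "z")]); rownames(m) <- a$elety
    m
  }
  .position_rmsd_table(peps, seq_len(lens[1]), fetch)
}

#' Plain RMSD between two coordinate sets (no fitting)
#' @param a,b n x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd_between <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}
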