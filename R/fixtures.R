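# Deterministic synthetic-data generation: an idealized binding-groove
# receptor (two helical walls over a strand floor, ~32 A cavity with
# hydrogen-bond partners at both end pockets), an anchored 9-mer peptide,
# noisy conformer ensembles and labelled score distributions. Fixtures use
# the real HLA-A*02:01 groove residue numbering so groove-definition code
# paths run unchanged.

#' Fixture generation specification
#'
#' Identical specs produce bit-identical fixtures; every generator draws
#' from its own seeded stream and leaves the global RNG untouched.
#'
#' @param seed integer seed.
#' @param n_structures ensemble size.
#' @param coordinate_noise_sigma Gaussian coordinate noise, Angstrom.
#' @param peptide_sequences character vector of 9-mers.
#' @param groove_variant label reserved for alternative groove geometries.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_structures = 10L,
                         coordinate_noise_sigma = 0.3,
                         peptide_sequences = "ILKEPVHGV",
                         groove_variant = "default") {
  out <- list(seed = as.integer(seed), n_structures = as.integer(n_structures),
              coordinate_noise_sigma = coordinate_noise_sigma,
              peptide_sequences = toupper(peptide_sequences),
              groove_variant = groove_variant)
  class(out) <- "fixture_spec"
  out
}

# evaluate fn with a local RNG stream; global .Random.seed untouched
with_local_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv())
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# rigidly place an atom table: rotate about its centroid, then translate the
# centroid of `anchor_atoms` rows (or all rows) to `target`
.place_segment <- function(df, axis_from, axis_to = NULL, target) {
  xyz <- as.matrix(df[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  xyz <- sweep(xyz, 2, ctr)
  if (!is.null(axis_to)) {
    u <- unit3(axis_from); v <- unit3(axis_to)
    ax <- cross3(u, v); s <- sqrt(sum(ax^2)); cth <- sum(u * v)
    if (s > 1e-9) {
      R <- rotation_matrix_axis(ax, atan2(s, cth) * 180 / pi)
      xyz <- xyz %*% t(R)
    } else if (cth < 0) {
      xyz <- -xyz
    }
  }
  xyz <- sweep(xyz, 2, target, "+")
  df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
  df
}

# principal CA-direction of a backbone atom table
.segment_axis <- function(df) {
  ca <- as.matrix(df[df$elety == "CA", c("x", "y", "z")])
  as.vector(ca[nrow(ca), ] - ca[1, ])
}

# a poly-ALA segment with CBs, built from phi/psi and laid along `dir`
.make_segment <- function(n, phi, psi, resno_start, centre, dir = c(1, 0, 0),
                          chain = "A") {
  bb <- build_backbone(n, phi, psi, chain = chain, resid = "ALA",
                       resno_start = as.integer(resno_start))
  s <- hla_structure("seg", bb)
  cbs <- lapply(unique(bb$resno), function(rn) {
    m <- residue_bb_matrix(s, rn)
    cb <- build_side_chain(m, "ALA", numeric(0))
    data.frame(elety = "CB", resid = "ALA", chain = chain, resno = rn,
               icode = "", x = cb["CB", 1], y = cb["CB", 2], z = cb["CB", 3],
               o = 1, b = 0, elesy = "C", stringsAsFactors = FALSE)
  })
  df <- rbind(bb, do.call(rbind, cbs))
  df <- df[order(df$resno, match(df$elety, c(BACKBONE_ATOMS, "CB"))), ]
  if (n == 1)
    return(.place_segment(df, c(1, 0, 0), NULL, centre))
  .place_segment(df, .segment_axis(df), dir, centre)
}

#' Generate an idealized binding-groove receptor
#'
#' Two parallel poly-alanine helical walls over beta-strand floor segments,
#' numbered so every residue of the default [groove_definition()] is
#' present. A standalone serine at position 171 (A pocket, OG accepting
#' from the P1 amide) and lysine at position 116 (F pocket, NZ donating to
#' the P9 carbonyl) sit at the cavity ends, providing hydrogen-bond
#' partners for the peptide termini about 32 Angstrom apart.
#'
#' @param spec a [fixture_spec()].
#' @return receptor [hla_structure()] (chain A).
#' @export
generate_groove <- function(spec = fixture_spec()) {
  segs <- list(
    # helical walls: alpha-1 (57-85), alpha-2 split into 132-148 / 151-169
    .make_segment(29, -57, -47, 57, c(0, -8, -0.5)),
    .make_segment(17, -57, -47, 132, c(-15.5, 7.5, -0.5)),
    .make_segment(19, -57, -47, 151, c(17.5, 8.5, -0.5)),
    # beta-strand floor segments: two staggered y lanes at z = -8 over a
    # deeper central strand carrying residues 5-9
    .make_segment(7, -139, 135, 4, c(-10, 0, -13)),
    .make_segment(3, -139, 135, 25, c(-8, -2.6, -8.8)),
    .make_segment(3, -139, 135, 44, c(4, -2.6, -8.8)),
    .make_segment(2, -139, 135, 123, c(14, -2.6, -8.8)),
    .make_segment(3, -139, 135, 97, c(-8, 2.6, -8.8)),
    .make_segment(3, -139, 135, 113, c(4, 2.6, -8.8)),
    # standalone end-pocket residues
    .make_segment(1, -139, 135, 171, c(-16.6, 0, -4.2)),
    .make_segment(1, -139, 135, 116, c(16.1, 0, -4.2))
  )
  atoms <- do.call(rbind, segs)
  s <- hla_structure(sprintf("groove_%s_%d", spec$groove_variant, spec$seed),
                     atoms)
  # A-pocket acceptor (Ser171 OG) placed along the P1 amide direction and
  # F-pocket donor (Lys116 NZ) along the P9 carbonyl direction, so both
  # terminal hydrogen bonds have near-linear geometry
  pb <- .peptide_backbone_placed(NULL)
  gxyz <- function(rn, el) unlist(pb[pb$resno == rn & pb$elety == el,
                                     c("x", "y", "z")])
  n1 <- gxyz(1, "N"); ca1 <- gxyz(1, "CA")
  o9 <- gxyz(9, "O"); c9 <- gxyz(9, "C")
  site_a <- n1 + 2.9 * unit3(unit3(n1 - ca1) + c(-0.55, 0, -1.0))
  u_f <- unit3(unit3(o9 - c9) + c(0.55, 0, -1.0))
  site_f <- o9 + 2.9 * u_f
  s <- .make_pocket_serine(s, 171L, c(1, 0, 0.3), site_a)
  s <- .make_pocket_lysine(s, 116L, site_f, u_f)
  s
}

# mutate the standalone residue `rn` to LYS, oriented so the CE-NZ bond
# lies along `axis` (the donor direction) with NZ exactly at `site`; the
# residue body extends outward beyond the pocket
.make_pocket_lysine <- function(s, rn, site, axis) {
  a <- s$atoms
  a$resid[a$resno == rn] <- "LYS"
  a <- a[!(a$resno == rn & !a$elety %in% BACKBONE_ATOMS), , drop = FALSE]
  s <- hla_structure(s$id, a)
  bb <- residue_bb_matrix(s, rn)
  sc <- build_side_chain(bb, "LYS", c(180, 180, 180, 180))
  # rigid-rotate residue + side chain so CB->NZ aligns with site -> out
  sel <- which(s$atoms$resno == rn)
  res_xyz <- rbind(coords(s, sel), sc)
  axis_from <- sc["NZ", ] - sc["CB", ]
  axis_to <- -unit3(axis)   # CB -> NZ antiparallel to the donor direction
  u <- unit3(axis_from); v <- unit3(axis_to)
  ax <- cross3(u, v); sn <- sqrt(sum(ax^2)); cs <- sum(u * v)
  R <- if (sn > 1e-9)
    rotation_matrix_axis(ax, atan2(sn, cs) * 180 / pi) else diag(3)
  ctr <- sc["NZ", ]
  res_xyz <- sweep(sweep(res_xyz, 2, ctr) %*% t(R), 2, site, "+")
  nb <- length(sel)
  s <- set_coords(s, res_xyz[seq_len(nb), , drop = FALSE], sel)
  add <- data.frame(elety = rownames(sc), resid = "LYS", chain = "A",
                    resno = rn, icode = "",
                    x = res_xyz[-seq_len(nb), 1],
                    y = res_xyz[-seq_len(nb), 2],
                    z = res_xyz[-seq_len(nb), 3], o = 1, b = 0,
                    elesy = element_of(rownames(sc)),
                    stringsAsFactors = FALSE)
  a <- rbind(s$atoms, add)
  a <- a[order(match(a$resno, unique(a$resno)),
               match(a$elety, c(BACKBONE_ATOMS, "CB", "OG"))), ]
  hla_structure(s$id, a)
}

# mutate residue `rn` to SER; chi1 chosen so OG points along `dir` (into
# the cavity), making OG the pocket's hydrogen-bond partner; when `site` is
# given the whole residue is translated so OG lands exactly there
.make_pocket_serine <- function(s, rn, dir, site = NULL) {
  a <- s$atoms
  a$resid[a$resno == rn] <- "SER"
  s <- hla_structure(s$id, a)
  bb <- residue_bb_matrix(s, rn)
  cb <- build_side_chain(bb, "ALA", numeric(0))["CB", ]
  best <- NULL; best_p <- -Inf
  for (chi in c(-66, 64, 178)) {
    sc <- build_side_chain(bb, "SER", chi)
    proj <- sum((sc["OG", ] - cb) * unit3(dir))
    if (proj > best_p) { best_p <- proj; best <- sc }
  }
  og <- best["OG", ]
  if (!is.null(site)) {
    shift <- site - og
    sel <- s$atoms$resno == rn
    s$atoms$x[sel] <- s$atoms$x[sel] + shift[1]
    s$atoms$y[sel] <- s$atoms$y[sel] + shift[2]
    s$atoms$z[sel] <- s$atoms$z[sel] + shift[3]
    og <- site
  }
  add <- data.frame(elety = "OG", resid = "SER", chain = "A", resno = rn,
                    icode = "", x = og[1], y = og[2], z = og[3], o = 1,
                    b = 0, elesy = "O", stringsAsFactors = FALSE)
  a <- rbind(s$atoms, add)
  a <- a[order(match(a$resno, unique(a$resno)),
               match(a$elety, c(BACKBONE_ATOMS, "CB", "OG"))), ]
  hla_structure(s$id, a)
}

#' End-pocket hydrogen-bond sites of the fixture groove
#' @param groove receptor from [generate_groove()].
#' @return 2 x 3 matrix: the Ser171 OG (A pocket) and Lys116 NZ (F pocket)
#'   coordinates.
#' @export
pocket_sites <- function(groove) {
  a <- groove$atoms
  rbind(A = unlist(a[a$resno == 171 & a$elety == "OG", c("x", "y", "z")]),
        F = unlist(a[a$resno == 116 & a$elety == "NZ", c("x", "y", "z")]))
}

# the fixture peptide backbone (gently arced extended 9-mer) placed along x
# at z = -0.8, then shifted on a fine deterministic grid so both termini sit
# in the pockets' hydrogen-bond wells (target donor-acceptor 2.9 A)
.peptide_backbone_placed <- function(groove = NULL) {
  bb <- build_backbone(9, phi = -125, psi = 130, chain = "C", resid = "ALA")
  n1 <- unlist(bb[bb$resno == 1 & bb$elety == "N", c("x", "y", "z")])
  c9 <- unlist(bb[bb$resno == 9 & bb$elety == "C", c("x", "y", "z")])
  df <- .place_segment(bb, c9 - n1, c(1, 0, 0), c(0, 0, -0.8))
  if (is.null(groove)) return(df)
  sites <- pocket_sites(groove)
  n1 <- unlist(df[df$resno == 1 & df$elety == "N", c("x", "y", "z")])
  o9 <- unlist(df[df$resno == 9 & df$elety == "O", c("x", "y", "z")])
  obj <- function(dx, dz) {
    d1 <- sqrt(sum((n1 + c(dx, 0, dz) - sites["A", ])^2))
    d2 <- sqrt(sum((o9 + c(dx, 0, dz) - sites["F", ])^2))
    (d1 - 2.9)^2 + (d2 - 2.9)^2
  }
  grid <- expand.grid(dx = seq(-1.5, 1.5, 0.05), dz = seq(-0.75, 0.75, 0.05))
  vals <- mapply(obj, grid$dx, grid$dz)
  k <- which.min(vals)
  df$x <- df$x + grid$dx[k]
  df$z <- df$z + grid$dz[k]
  df
}

#' Generate a peptide bound in the fixture groove
#'
#' Builds the arced backbone inside the cavity (termini adjacent to the end
#' pockets), relabels it with the requested sequence and places side chains
#' against the groove. The backbone is sequence-independent.
#'
#' @param spec a [fixture_spec()]; the first entry of
#'   `spec$peptide_sequences` is used.
#' @param groove receptor from [generate_groove()].
#' @param rotamer_lib a `rotamer_library`.
#' @return peptide [hla_structure()] (chain C).
#' @export
generate_bound_peptide <- function(spec = fixture_spec(),
                                   groove = generate_groove(spec),
                                   rotamer_lib = read_rotamer_library()) {
  seqs <- spec$peptide_sequences[1]
  if (nchar(seqs) != 9) stop("sequence length ", nchar(seqs), " != 9")
  letters1 <- strsplit(seqs, "")[[1]]
  if (!all(letters1 %in% names(AA3)))
    stop("non-standard residue letter(s) in sequence")
  bb <- .peptide_backbone_placed(groove)
  bb$resid <- AA3[letters1][bb$resno]
  pep <- hla_structure(paste0("fixpep_", seqs), bb)
  place_side_chains(pep, rotamer_lib, environment = groove)
}

#' Generate the full fixture complex (groove + bound peptide)
#'
#' The assembled complex is relaxed by a short minimization of the peptide
#' and groove residues (like a crystal structure, it sits at a local energy
#' minimum), so redocking it is a genuine round-trip test.
#'
#' @param spec a [fixture_spec()].
#' @param resolution synthetic resolution label, Angstrom.
#' @param relax run the relaxation minimization (default TRUE).
#' @return complex [hla_structure()] with chains A (receptor) and C
#'   (peptide).
#' @export
generate_complex <- function(spec = fixture_spec(), resolution = 2.0,
                             relax = TRUE) {
  groove <- generate_groove(spec)
  pep <- generate_bound_peptide(spec, groove)
  cx <- hla_structure(sprintf("fixture_%d", spec$seed),
                      rbind(groove$atoms, pep$atoms), resolution)
  if (relax) {
    mobile <- c(atom_select(cx, chain = "C"),
                atom_select(cx, chain = "A",
                            resno = unclass(groove_definition())))
    for (round in 1:2)
      cx <- minimize_structure(cx, mobile, maxit = 150)$structure
  }
  cx
}

#' Generate an ensemble of noisy complex copies
#'
#' Independent Gaussian coordinate noise of sd `coordinate_noise_sigma` plus
#' a random rigid displacement per copy (removed again by superposition).
#'
#' @param spec a [fixture_spec()].
#' @return list of [hla_structure()] complexes of length
#'   `spec$n_structures`.
#' @export
generate_ensemble <- function(spec = fixture_spec()) {
  if (spec$n_structures < 2) stop("n_structures must be >= 2")
  base <- generate_complex(spec)
  with_local_seed(spec$seed, function() {
    lapply(seq_len(spec$n_structures), function(i) {
      xyz <- coords(base)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0,
                                       spec$coordinate_noise_sigma),
                          ncol = 3)
      R <- rotation_matrix_axis(stats::rnorm(3), stats::runif(1, 0, 180))
      xyz <- sweep(xyz %*% t(R), 2, stats::runif(3, -10, 10), "+")
      out <- set_coords(base, xyz)
      out$id <- sprintf("%s_copy%02d", base$id, i)
      out$resolution <- round(stats::runif(1, 1.5, 2.8), 2)
      out
    })
  })
}

#' Generate a labelled synthetic score dataset
#'
#' Gaussian score draws per class, emulating calculated binding free-energy
#' distributions for binder and non-binder peptide pools.
#'
#' @param n_bind,n_non class sizes.
#' @param mu_bind,mu_non class means (kcal/mol).
#' @param sd common standard deviation.
#' @param seed integer seed.
#' @return data.frame with `score` and logical `binder`.
#' @export
generate_score_dataset <- function(n_bind, n_non, mu_bind, mu_non, sd,
                                   seed = 1L) {
  stopifnot(n_bind >= 1, n_non >= 1)
  with_local_seed(seed, function() {
    data.frame(
      score = c(stats::rnorm(n_bind, mu_bind, sd),
                stats::rnorm(n_non, mu_non, sd)),
      binder = rep(c(TRUE, FALSE), c(n_bind, n_non)))
  })
}
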