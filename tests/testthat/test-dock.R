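test_that("initial_pose places anchors optimally onto the consensus", {
  cx <- fx_complex()
  lib <- fx_library()
  pep <- extract_peptide(cx)
  # anchors already on the consensus: identity placement
  pose <- initial_pose(pep, lib$consensus_anchor)
  expect_equal(coords(pose$peptide), coords(pep), tolerance = 1e-9)
  expect_equal(pose$anchor_rmsd, 0, tolerance = 1e-9)
  # translated 10 A away: anchors return to the consensus within noise
  moved <- set_coords(pep, sweep(coords(pep), 2, c(10, 0, 0), "+"))
  pose2 <- initial_pose(moved, lib$consensus_anchor)
  expect_equal(coords(pose2$peptide), coords(pep), tolerance = 1e-9)
  # optimality: anchor RMSD after placement is minimal over random rigid
  # perturbations of the placed pose
  set.seed(31)
  cons <- as.matrix(lib$consensus_anchor[, c("x", "y", "z")])
  placed_anchor <- anchordock:::anchor_coords(pose2$peptide)
  base <- rmsd_between(placed_anchor, cons)
  for (k in 1:25) {
    R <- anchordock:::rotation_matrix_axis(rnorm(3), runif(1, 0.2, 5))
    ctr <- colMeans(placed_anchor)
    pert <- sweep(sweep(placed_anchor, 2, ctr) %*% t(R), 2,
                  ctr + rnorm(3, 0, 0.3), "+")
    expect_gte(rmsd_between(pert, cons) + 1e-9, base)
  }
  nobb <- pep
  nobb$atoms <- nobb$atoms[!(nobb$atoms$resno == 2 &
                               nobb$atoms$elety == "CA"), ]
  expect_error(initial_pose(hla_structure("x", nobb$atoms),
                            lib$consensus_anchor), "anchor")
})

test_that("rigid_refine respects the displacement cap, zero budget, and
           score monotonicity", {
  cx <- fx_complex()
  lib <- fx_library()
  groove <- subset_chains(cx, "A")
  pep <- extract_peptide(cx)
  pose <- initial_pose(pep, lib$consensus_anchor)
  # zero search budget leaves the pose unchanged
  same <- rigid_refine(pose, groove, dock_config(max_iter = 0))
  expect_identical(coords(same$peptide), coords(pose$peptide))
  ref <- rigid_refine(pose, groove)
  expect_true(all(diff(ref$score_history) > 0))
  disp <- sqrt(rowSums((coords(ref$peptide) - pose$initial_coords)^2))
  expect_lte(max(disp), 0.5 + 1e-9)
})

test_that("rigid refinement recovers a hydrogen bond displaced at setup", {
  cx <- fx_complex()
  lib <- fx_library()
  groove <- subset_chains(cx, "A")
  pep <- extract_peptide(cx)
  # compress the F-pocket donor-acceptor pair 0.3 A below the hydrogen-bond
  # window: the geometry breaks and lies within the 0.5 A recovery range
  st <- pocket_sites(groove)
  o9 <- unlist(pep$atoms[pep$atoms$resno == 9 & pep$atoms$elety == "O",
                         c("x", "y", "z")])
  u <- (st["F", ] - o9) / sqrt(sum((st["F", ] - o9)^2))
  shifted <- set_coords(pep, sweep(coords(pep), 2, 0.3 * u, "+"))
  pose <- list(peptide = shifted, transform_history = list(),
               rigid_score = NA_real_, stage = "initial",
               initial_coords = coords(shifted))
  class(pose) <- "dock_pose"
  hb0 <- anchordock:::count_hbonds(shifted$atoms, groove$atoms)
  ref <- rigid_refine(pose, groove)
  hb1 <- anchordock:::count_hbonds(ref$peptide$atoms, groove$atoms)
  expect_gte(hb1, hb0 + 1)
})

test_that("flexible_refine descends, resolves clashes, and moves only
           groove residues of the receptor", {
  cx <- fx_complex()
  lib <- fx_library()
  groove <- subset_chains(cx, "A")
  pep <- extract_peptide(cx)
  pose <- initial_pose(pep, lib$consensus_anchor)
  fr <- flexible_refine(pose, groove)
  expect_lte(fr$e_final, fr$e_initial)
  # receptor atoms outside the groove set never move
  out_idx <- atom_select(fr$complex, chain = "A")
  fixed <- !fr$complex$atoms$resno[out_idx] %in%
    unclass(groove_definition())
  expect_identical(coords(fr$complex, out_idx[fixed]),
                   coords(groove,
                          atom_select(groove)[!groove$atoms$resno %in%
                                                unclass(groove_definition())]))
  # an already-minimized complex barely changes on re-refinement
  pose2 <- list(peptide = hla_structure("rp",
                                        fr$complex$atoms[
                                          atom_select(fr$complex,
                                                      chain = "C"), ,
                                          drop = FALSE]),
                transform_history = list(), rigid_score = NA_real_,
                stage = "initial")
  pose2$initial_coords <- coords(pose2$peptide)
  class(pose2) <- "dock_pose"
  # residual descent stays within ~2% of the initial relaxation release
  # (finite optimizer budget + restraint re-centring; see methods vignette)
  fr2 <- flexible_refine(pose2, groove)
  expect_lt(fr2$e_initial - fr2$e_final, 10)
  d2 <- sqrt(rowSums((coords(fr2$complex) - coords(fr$complex))^2))
  expect_lt(mean(d2), 0.1)
  # pose stability judged on the peptide backbone; the standalone pocket
  # residues are the least-constrained atoms and jitter slightly more
  bbsel <- fr2$complex$atoms$elety %in% c("N", "CA", "C", "O") &
    fr2$complex$atoms$chain == "C"
  expect_lt(max(d2[bbsel]), 0.5)
  # a deliberately planted steric clash is pulled back apart
  clash <- pep
  sel <- atom_select(clash, resno = 5)
  tgt <- coords(groove, atom_select(groove, resno = 97))[1, ]
  shift <- tgt - colMeans(coords(clash, sel))
  clash <- set_coords(clash,
                      sweep(coords(clash, sel), 2, 0.7 * shift, "+"), sel)
  pre <- anchordock:::min_contact(clash$atoms[clash$atoms$resno == 5, ],
                                  groove$atoms[groove$atoms$resno == 97, ])
  expect_lt(pre, 2.4)
  posec <- list(peptide = clash, transform_history = list(),
                rigid_score = NA_real_, stage = "initial",
                initial_coords = coords(clash))
  class(posec) <- "dock_pose"
  frc <- flexible_refine(posec, groove,
                         config = dock_config(minimize_maxit = 150))
  pepi <- atom_select(frc$complex, chain = "C")
  p5 <- frc$complex$atoms[pepi, ][frc$complex$atoms$resno[pepi] == 5, ]
  r97 <- frc$complex$atoms[frc$complex$atoms$chain == "A" &
                             frc$complex$atoms$resno == 97, ]
  expect_gt(anchordock:::min_contact(p5, r97), 2.4)
})

test_that("redocking and ab initio docking round-trip the fixture", {
  cx <- fx_complex()
  lib <- fx_library()
  b1 <- redock_benchmark(list(cx), lib, mode = "redock")
  expect_false(b1$failed)
  expect_lt(b1$rmsd_backbone, 0.5)
  expect_true(all(c(b1$rmsd_backbone, b1$rmsd_allatom,
                    b1$rmsd_complex) >= 0))
  b2 <- redock_benchmark(list(cx), lib, mode = "abinitio")
  expect_false(b2$failed)
  expect_lt(b2$rmsd_backbone, 1.0)
})

test_that("the docking pipeline is bitwise deterministic at md_steps = 0", {
  cx <- fx_complex()
  lib <- fx_library()
  groove <- subset_chains(cx, "A")
  pep <- build_peptide("ILKEPVHGV", lib, fx_rotlib(),
                       receptor_frame = groove)
  r1 <- dock_peptide(pep, groove, lib)
  r2 <- dock_peptide(pep, groove, lib)
  expect_identical(coords(r1$complex), coords(r2$complex))
  expect_identical(r1$e_final, r2$e_final)
})

test_that("per-complex benchmark failures are recorded, not fatal", {
  cx <- fx_complex()
  lib <- fx_library()
  broken <- subset_chains(cx, "A")   # no peptide chain at all
  out <- redock_benchmark(list(broken, cx), lib, mode = "redock")
  expect_equal(nrow(out), 2)
  expect_true(out$failed[1])
  expect_match(out$reason[1], "peptide")
  expect_false(out$failed[2])
})
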