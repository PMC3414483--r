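#' Docking configuration
#'
#' @param max_disp cumulative per-atom displacement cap during rigid
#'   refinement, Angstrom (default 0.5).
#' @param trans_step,rot_step rigid search steps (0.1 A, 1 degree).
#' @param max_iter greedy rigid-refinement iteration cap.
#' @param md_steps stochastic perturbation-reminimization cycles after the
#'   first minimization (default 0 = fully deterministic).
#' @param seed seed for the md stage.
#' @param minimize_maxit minimizer iterations in flexible refinement.
#' @return object of class `dock_config`.
#' @export
dock_config <- function(max_disp = 0.5, trans_step = 0.1, rot_step = 1,
                        max_iter = 100, md_steps = 0, seed = 1L,
                        minimize_maxit = 40) {
  out <- list(max_disp = max_disp, trans_step = trans_step,
              rot_step = rot_step, max_iter = max_iter,
              md_steps = as.integer(md_steps), seed = as.integer(seed),
              minimize_maxit = minimize_maxit)
  class(out) <- "dock_config"
  out
}

# peptide anchor backbone atoms (P1, P2, P9 x N/CA/C/O), consensus order
anchor_coords <- function(pep) {
  a <- pep$atoms[pep$atoms$resno %in% c(1L, 2L, 9L) &
                   pep$atoms$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  a <- a[order(a$resno, match(a$elety, BACKBONE_ATOMS)), , drop = FALSE]
  if (nrow(a) != 12)
    stop("peptide lacks complete anchor backbone (P1, P2, P9)")
  as.matrix(a[, c("x", "y", "z")])
}

#' Initial anchored placement of a peptide
#'
#' Superimposes the peptide's P1/P2/P9 backbone atoms (N, CA, C, O; 12
#' atoms) onto the consensus anchor coordinates and applies the resulting
#' rigid transform to the whole peptide.
#'
#' @param peptide peptide [hla_structure()] with anchor backbone atoms.
#' @param consensus_anchor data.frame `pos`, `elety`, `x`, `y`, `z` (12
#'   rows), e.g. a `template_library$consensus_anchor`.
#' @return object of class `dock_pose`.
#' @export
initial_pose <- function(peptide, consensus_anchor) {
  ca <- consensus_anchor[order(consensus_anchor$pos,
                               match(consensus_anchor$elety,
                                     BACKBONE_ATOMS)), , drop = FALSE]
  ref <- as.matrix(ca[, c("x", "y", "z")])
  tr <- kabsch(ref, anchor_coords(peptide))
  pep <- apply_transform(peptide, tr)
  out <- list(peptide = pep, transform_history = list(tr),
              rigid_score = NA_real_, stage = "initial",
              initial_coords = coords(pep), anchor_rmsd = tr$rmsd)
  class(out) <- "dock_pose"
  out
}

#' @export
print.dock_pose <- function(x, ...) {
  cat(sprintf("<dock_pose> stage=%s, rigid_score=%s\n", x$stage,
              format(x$rigid_score)))
  invisible(x)
}

#' Rigid-body pose refinement under a displacement cap
#'
#' Deterministic greedy search over small translations (0.1 A steps) and
#' rotations about the peptide centroid (1 degree steps), maximizing the
#' pose score (hydrogen-bond matching weighted 1.0 plus capped soft van der
#' Waals weighted 0.2). Every atom's cumulative displacement from the
#' initial pose is capped at `max_disp`, preserving the anchor contacts.
#' The score never decreases across iterations.
#'
#' @param pose a `dock_pose` from [initial_pose()].
#' @param receptor receptor [hla_structure()].
#' @param config [dock_config()].
#' @param params [ff_default_params()].
#' @return refined `dock_pose` (stage `rigid_refined`) with `rigid_score`
#'   and the score trace in `score_history`.
#' @export
rigid_refine <- function(pose, receptor, config = dock_config(),
                         params = ff_default_params()) {
  pep <- pose$peptide
  ap_pep <- atom_params(pep, params)
  ap_rec <- atom_params(receptor, params)
  x0 <- pose$initial_coords
  cur <- coords(pep)
  score_of <- function(xyz) {
    p <- set_coords(pep, xyz)
    pose_score(p$atoms, receptor$atoms, ap_pep, ap_rec)
  }
  cur_score <- score_of(cur)
  history <- cur_score
  if (config$max_iter > 0) {
    moves <- c(lapply(1:3, function(k) {
      m <- c(0, 0, 0); m[k] <- config$trans_step; list(t = m)
    }), lapply(1:3, function(k) {
      m <- c(0, 0, 0); m[k] <- -config$trans_step; list(t = m)
    }), lapply(1:3, function(k) {
      ax <- c(0, 0, 0); ax[k] <- 1; list(r = ax, a = config$rot_step)
    }), lapply(1:3, function(k) {
      ax <- c(0, 0, 0); ax[k] <- 1; list(r = ax, a = -config$rot_step)
    }))
    for (it in seq_len(config$max_iter)) {
      best_xyz <- NULL; best_score <- cur_score
      ctr <- colMeans(cur)
      for (mv in moves) {
        cand <- if (!is.null(mv$t)) sweep(cur, 2, mv$t, "+") else {
          R <- rotation_matrix_axis(mv$r, mv$a)
          sweep(sweep(cur, 2, ctr) %*% t(R), 2, ctr, "+")
        }
        if (max(sqrt(rowSums((cand - x0)^2))) > config$max_disp) next
        sc <- score_of(cand)
        if (sc > best_score + 1e-9) { best_score <- sc; best_xyz <- cand }
      }
      if (is.null(best_xyz)) break
      cur <- best_xyz; cur_score <- best_score
      history <- c(history, cur_score)
    }
  }
  pose$peptide <- set_coords(pep, cur)
  pose$rigid_score <- cur_score
  pose$score_history <- history
  pose$stage <- "rigid_refined"
  pose
}

# assemble a complex, relabelling the peptide chain if it collides
.assemble_complex <- function(receptor, pep) {
  if (chain_ids(pep)[1] %in% chain_ids(receptor)) {
    free <- setdiff(c("C", "P", "B", "D", LETTERS), chain_ids(receptor))
    pep$atoms$chain <- free[1]
  }
  hla_structure(paste0(receptor$id, "+", pep$id),
                rbind(receptor$atoms, pep$atoms), receptor$resolution)
}

#' Flexible refinement of the docked complex
#'
#' Short conjugate-gradient minimization of the complex with the peptide
#' and the binding-groove residues mobile and every other receptor atom
#' fixed. With `md_steps > 0`, seeded overdamped stochastic
#' perturbation-reminimization cycles follow the first minimization;
#' the default `md_steps = 0` is fully deterministic.
#'
#' @param pose a `dock_pose`.
#' @param receptor receptor [hla_structure()].
#' @param groove_def [groove_definition()] giving the mobile receptor
#'   residues.
#' @param config [dock_config()].
#' @param params [ff_default_params()].
#' @return list: `pose` (stage `minimized`), `complex`, `e_initial`,
#'   `e_final` (objective, kcal/mol), `clash_failed` (irreconcilable
#'   peptide-receptor contact < 1.5 A surviving refinement).
#' @export
flexible_refine <- function(pose, receptor,
                            groove_def = groove_definition(),
                            config = dock_config(),
                            params = ff_default_params()) {
  cx <- .assemble_complex(receptor, pose$peptide)
  pc <- setdiff(chain_ids(cx), chain_ids(receptor))
  if (!length(pc)) pc <- chain_ids(pose$peptide)[1]
  hc <- heavy_chain(cx)
  mobile <- c(atom_select(cx, chain = pc),
              atom_select(cx, chain = hc, resno = unclass(groove_def)))
  m <- minimize_structure(cx, mobile, params, maxit = config$minimize_maxit)
  if (config$md_steps > 0) {
    m <- with_local_seed(config$seed, function() {
      cur <- m
      for (s in seq_len(config$md_steps)) {
        xyz <- coords(cur$structure)
        xyz[mobile, ] <- xyz[mobile, ] +
          matrix(stats::rnorm(3 * length(mobile), 0, 0.05), ncol = 3)
        jit <- set_coords(cur$structure, xyz)
        nxt <- minimize_structure(jit, mobile, params,
                                  maxit = config$minimize_maxit)
        if (nxt$e_final <= cur$e_final) cur <- nxt
      }
      cur
    })
  }
  out_cx <- m$structure
  pep_idx <- atom_select(out_cx, chain = pc)
  pose$peptide <- hla_structure(pose$peptide$id,
                                out_cx$atoms[pep_idx, , drop = FALSE])
  pose$stage <- "minimized"
  clash <- min_contact(out_cx$atoms[pep_idx, , drop = FALSE],
                       out_cx$atoms[-pep_idx, , drop = FALSE]) < 1.5
  list(pose = pose, complex = out_cx, e_initial = m$e_initial,
       e_final = m$e_final, clash_failed = clash)
}

#' Dock a peptide into a receptor
#'
#' Anchored initial placement, displacement-capped rigid refinement and
#' flexible minimization in one call.
#'
#' @param peptide peptide [hla_structure()] (from [extract_peptide()] or
#'   [build_peptide()]).
#' @param receptor receptor [hla_structure()].
#' @param library a `template_library` (for the consensus anchor).
#' @param groove_def [groove_definition()].
#' @param config [dock_config()].
#' @param params [ff_default_params()].
#' @return the [flexible_refine()] result.
#' @export
dock_peptide <- function(peptide, receptor, library,
                         groove_def = groove_definition(),
                         config = dock_config(),
                         params = ff_default_params()) {
  pose <- initial_pose(peptide, library$consensus_anchor)
  pose <- rigid_refine(pose, receptor, config, params)
  flexible_refine(pose, receptor, groove_def, config, params)
}

# matched-atom RMSDs between a docked peptide and the crystal peptide
.peptide_rmsds <- function(docked, crystal) {
  dk <- paste(docked$atoms$resno, docked$atoms$elety)
  ck <- paste(crystal$atoms$resno, crystal$atoms$elety)
  common <- intersect(dk, ck)
  di <- match(common, dk); ci <- match(common, ck)
  bb <- docked$atoms$elety[di] %in% BACKBONE_ATOMS
  c(backbone = rmsd_between(coords(docked, di[bb]), coords(crystal, ci[bb])),
    allatom = rmsd_between(coords(docked, di), coords(crystal, ci)))
}

#' Redocking / ab initio docking benchmark
#'
#' For each complex the peptide is either extracted from the crystal
#' (`mode = "redock"`) or rebuilt from its sequence (`mode = "abinitio"`),
#' docked back into its receptor, and compared with the crystal pose:
#' peptide backbone and all-atom RMSD plus the overall complex RMSD, all in
#' the receptor frame. Per-complex failures are recorded, not fatal.
#'
#' @param complexes list of validated p-HLA [hla_structure()]s.
#' @param library a `template_library`.
#' @param mode `"redock"` or `"abinitio"`.
#' @param groove_def [groove_definition()].
#' @param config [dock_config()].
#' @param params [ff_default_params()].
#' @param rotamer_lib a `rotamer_library` (ab initio mode).
#' @return data.frame, one row per complex: `id`, `rmsd_backbone`,
#'   `rmsd_allatom`, `rmsd_complex`, `failed`, `reason`.
#' @export
redock_benchmark <- function(complexes, library,
                             mode = c("redock", "abinitio"),
                             groove_def = groove_definition(),
                             config = dock_config(),
                             params = ff_default_params(),
                             rotamer_lib = read_rotamer_library()) {
  mode <- match.arg(mode)
  rows <- lapply(complexes, function(cxin) {
    res <- tryCatch({
      pepx <- extract_peptide(cxin)
      receptor <- subset_chains(cxin, setdiff(chain_ids(cxin),
                                              peptide_chain(cxin)))
      pep <- if (mode == "redock") pepx else
        build_peptide(chain_sequence(pepx, chain_ids(pepx)[1]), library,
                      rotamer_lib, receptor_frame = receptor,
                      params = params)
      fr <- dock_peptide(pep, receptor, library, groove_def, config, params)
      pr <- .peptide_rmsds(fr$pose$peptide, pepx)
      # complex RMSD over all matched atoms (receptor + peptide)
      rec_idx <- atom_select(fr$complex,
                             chain = intersect(chain_ids(fr$complex),
                                               chain_ids(receptor)))
      rec_ref <- receptor$atoms
      rk <- paste(rec_ref$chain, rec_ref$resno, rec_ref$elety)
      dk <- paste(fr$complex$atoms$chain[rec_idx],
                  fr$complex$atoms$resno[rec_idx],
                  fr$complex$atoms$elety[rec_idx])
      common <- intersect(dk, rk)
      d_rec <- coords(fr$complex, rec_idx[match(common, dk)])
      r_rec <- as.matrix(rec_ref[match(common, rk), c("x", "y", "z")])
      pep_idx <- setdiff(seq_len(nrow(fr$complex$atoms)), rec_idx)
      pd <- hla_structure("dockpep",
                          fr$complex$atoms[pep_idx, , drop = FALSE])
      dkp <- paste(pd$atoms$resno, pd$atoms$elety)
      ckp <- paste(pepx$atoms$resno, pepx$atoms$elety)
      cp <- intersect(dkp, ckp)
      d_all <- rbind(d_rec, coords(pd, match(cp, dkp)))
      r_all <- rbind(r_rec, coords(pepx, match(cp, ckp)))
      data.frame(id = cxin$id, rmsd_backbone = pr[["backbone"]],
                 rmsd_allatom = pr[["allatom"]],
                 rmsd_complex = rmsd_between(d_all, r_all),
                 failed = fr$clash_failed,
                 reason = if (fr$clash_failed) "irreconcilable clash" else "",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(id = cxin$id, rmsd_backbone = NA_real_,
                 rmsd_allatom = NA_real_, rmsd_complex = NA_real_,
                 failed = TRUE, reason = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}
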