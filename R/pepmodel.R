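#' Default mapping of template-less P1 residues
#'
#' P1 residues never observed in the benchmark complexes are mapped to the
#' most similar observed template key by heavy-atom count and side-chain
#' volume. User-overridable wherever a template library is built.
#' @return named character vector (unseen residue -> template key).
#' @export
default_unseen_map <- function() {
  c(H = "F", W = "Y", D = "N", E = "M", Q = "M", P = "A", C = "S")
}

#' Build the P1-keyed template library
#'
#' Templates are nonameric peptides with side chains stripped to the
#' backbone at positions 2-9 (the P1 side chain is retained); for each P1
#' residue the highest-resolution example is kept (resolution ties broken by
#' id order). The consensus anchor is the arithmetic mean of the N, CA, C, O
#' backbone coordinates at P1, P2 and P9 over all input complexes after
#' peptide-excluded superposition onto the first complex (sorted by id).
#'
#' Two input modes are supported: full structural mode (`complexes`), and a
#' threading mode (`sequences` + `resolutions` + a `backbone` donor peptide)
#' where templates are synthesized by threading each best-resolution
#' sequence onto the shared donor backbone.
#'
#' @param complexes list of validated nonamer p-HLA [hla_structure()]s with
#'   resolutions.
#' @param sequences character vector of 9-mer sequences (threading mode).
#' @param resolutions numeric vector parallel to `sequences`.
#' @param ids optional labels parallel to `sequences`.
#' @param backbone donor peptide [hla_structure()] (threading mode).
#' @param rotamer_lib rotamer library for building P1 side chains in
#'   threading mode.
#' @param unseen_map named map for template-less P1 residues.
#' @return object of class `template_library`.
#' @export
build_template_library <- function(complexes = NULL, sequences = NULL,
                                   resolutions = NULL, ids = NULL,
                                   backbone = NULL,
                                   rotamer_lib = read_rotamer_library(),
                                   unseen_map = default_unseen_map()) {
  if (!is.null(complexes)) {
    if (!length(complexes)) stop("empty complex list")
    ids_c <- vapply(complexes, function(s) s$id, character(1))
    complexes <- complexes[order(ids_c)]
    ref <- complexes[[1]]
    peps <- c(list(extract_peptide(ref)),   # reference frame: untouched
              lapply(complexes[-1], function(s) {
                tr <- superpose_complexes(ref, s, "backbone")$transform
                apply_transform(extract_peptide(s), tr)
              }))
    res <- vapply(complexes, function(s)
      ifelse(is.na(s$resolution), Inf, s$resolution), numeric(1))
    p1 <- vapply(peps, function(p) substr(chain_sequence(p, chain_ids(p)[1]),
                                          1, 1), character(1))
    entries <- list()
    for (k in sort(unique(p1))) {
      cand <- which(p1 == k)
      pick <- cand[order(res[cand])][1]
      entries[[k]] <- list(peptide = strip_template(peps[[pick]]),
                           source_id = complexes[[pick]]$id,
                           resolution = res[pick])
    }
    anchor <- consensus_anchor_of(peps)
  } else {
    if (is.null(sequences) || is.null(backbone))
      stop("provide either complexes or sequences + backbone")
    if (!length(sequences)) stop("empty sequence list")
    if (is.null(resolutions)) resolutions <- rep(NA_real_, length(sequences))
    if (is.null(ids)) ids <- sprintf("seq%03d", seq_along(sequences))
    res <- ifelse(is.na(resolutions), Inf, resolutions)
    p1 <- substr(sequences, 1, 1)
    bad <- setdiff(unique(p1), names(AA3))
    if (length(bad)) stop("non-standard P1 letter(s): ",
                          paste(bad, collapse = ", "))
    entries <- list()
    for (k in sort(unique(p1))) {
      cand <- which(p1 == k)
      pick <- cand[order(res[cand], ids[cand])][1]
      entries[[k]] <- list(
        peptide = thread_p1_on_backbone(backbone, k, rotamer_lib),
        source_id = ids[pick], resolution = resolutions[pick])
    }
    anchor <- consensus_anchor_of(list(backbone))
  }
  lib <- list(p1_templates = entries,
              unseen_map = unseen_map[!names(unseen_map) %in% names(entries)],
              consensus_anchor = anchor)
  class(lib) <- "template_library"
  lib
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("<template_library> %d P1 templates: %s\n",
              length(x$p1_templates),
              paste(names(x$p1_templates), collapse = ", ")))
  invisible(x)
}

# strip side chains at positions 2..n to backbone atoms (P1 kept whole)
strip_template <- function(pep) {
  a <- pep$atoms
  keep <- a$resno == 1 | a$elety %in% BACKBONE_ATOMS
  hla_structure(pep$id, a[keep, , drop = FALSE], pep$resolution)
}

# donor backbone with P1 replaced by residue `key` (top-prior rotamer)
thread_p1_on_backbone <- function(backbone, key, rotamer_lib) {
  tmpl <- strip_template(backbone)
  a <- tmpl$atoms
  a <- a[!(a$resno == 1 & !a$elety %in% BACKBONE_ATOMS), , drop = FALSE]
  res3 <- AA3[[key]]
  a$resid[a$resno == 1] <- res3
  s <- hla_structure(paste0("tmpl_", key), a, backbone$resolution)
  bb <- residue_bb_matrix(s, 1)
  rot <- rotamers_for(rotamer_lib, res3)
  chi <- rot$chi[[which.max(rot$prob)]]
  sc <- build_side_chain(bb, res3, chi)
  if (nrow(sc)) {
    add <- data.frame(elety = rownames(sc), resid = res3,
                      chain = a$chain[1], resno = 1L, icode = "",
                      x = sc[, 1], y = sc[, 2], z = sc[, 3], o = 1, b = 0,
                      elesy = element_of(rownames(sc)),
                      stringsAsFactors = FALSE)
    s <- hla_structure(s$id, rbind(s$atoms, add), s$resolution)
  }
  s
}

# N/CA/C coordinate matrix of one residue (by resno, single-chain structure)
residue_bb_matrix <- function(s, resno, chain = NULL) {
  a <- s$atoms
  if (!is.null(chain)) a <- a[a$chain == chain, , drop = FALSE]
  a <- a[a$resno == resno, , drop = FALSE]
  m <- rbind(N = unlist(a[a$elety == "N", c("x", "y", "z")]),
             CA = unlist(a[a$elety == "CA", c("x", "y", "z")]),
             C = unlist(a[a$elety == "C", c("x", "y", "z")]))
  if (nrow(m) != 3 || anyNA(m))
    stop("incomplete backbone at residue ", resno)
  m
}

# mean anchor backbone coordinates (P1, P2, P9; N/CA/C/O) over peptides
consensus_anchor_of <- function(peps) {
  grab <- function(p) {
    a <- p$atoms[p$atoms$resno %in% c(1L, 2L, 9L) &
                   p$atoms$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    a <- a[order(a$resno, match(a$elety, BACKBONE_ATOMS)), , drop = FALSE]
    if (nrow(a) != 12) stop("incomplete anchor backbone in '", p$id, "'")
    a
  }
  mats <- lapply(peps, function(p) as.matrix(grab(p)[, c("x", "y", "z")]))
  avg <- Reduce(`+`, mats) / length(mats)
  ref <- grab(peps[[1]])
  data.frame(pos = ref$resno, elety = ref$elety,
             x = avg[, 1], y = avg[, 2], z = avg[, 3],
             stringsAsFactors = FALSE)
}

#' Map a P1 residue to its template key
#'
#' Observed residues map to themselves; residues without a template map via
#' the library's unseen-residue table.
#'
#' @param residue one-letter amino-acid code.
#' @param library a `template_library`.
#' @return one-letter template key.
#' @export
map_p1 <- function(residue, library) {
  if (!residue %in% names(AA3)) stop("non-standard residue: ", residue)
  if (residue %in% names(library$p1_templates)) return(residue)
  key <- unname(library$unseen_map[residue])
  if (is.na(key) || !key %in% names(library$p1_templates))
    stop("no template or unseen-map entry for P1 residue ", residue)
  key
}

#' Thread a sequence onto its P1 template backbone
#'
#' Relabels the template backbone with the target sequence, retains the
#' template's P1 side chain when the P1 residue matches the template key
#' (otherwise P1 is stubbed), and adds CB stubs at positions 2-9 for
#' non-glycine residues. Side chains are completed by
#' [place_side_chains()].
#'
#' @param sequence 9-mer amino-acid string.
#' @param library a `template_library`.
#' @return peptide [hla_structure()] (backbone + P1 side chain + CB stubs).
#' @export
thread_sequence <- function(sequence, library) {
  sequence <- toupper(sequence)
  if (nchar(sequence) != 9)
    stop("sequence length ", nchar(sequence), " != 9")
  letters1 <- strsplit(sequence, "")[[1]]
  if (!all(letters1 %in% names(AA3)))
    stop("non-standard residue letter(s) in sequence")
  key <- map_p1(letters1[1], library)
  tmpl <- library$p1_templates[[key]]$peptide
  a <- tmpl$atoms
  keep_p1_sc <- letters1[1] == key
  if (!keep_p1_sc)
    a <- a[!(a$resno == 1 & !a$elety %in% BACKBONE_ATOMS), , drop = FALSE]
  for (i in 1:9) {
    if (i == 1 && keep_p1_sc) next
    a$resid[a$resno == i] <- AA3[[letters1[i]]]
  }
  s <- hla_structure(paste0("pep_", sequence), a, NA_real_)
  # CB stubs for residues lacking them
  stubs <- list()
  for (i in 1:9) {
    res3 <- AA3[[letters1[i]]]
    if (res3 == "GLY") next
    have <- s$atoms$elety[s$atoms$resno == i]
    if ("CB" %in% have) next
    bb <- residue_bb_matrix(s, i)
    cb <- build_side_chain(bb, "ALA", numeric(0))
    stubs[[length(stubs) + 1]] <- data.frame(
      elety = "CB", resid = res3, chain = s$atoms$chain[1], resno = i,
      icode = "", x = cb["CB", 1], y = cb["CB", 2], z = cb["CB", 3],
      o = 1, b = 0, elesy = "C", stringsAsFactors = FALSE)
  }
  if (length(stubs))
    s <- hla_structure(s$id, rbind(s$atoms, do.call(rbind, stubs)),
                       s$resolution)
  ord <- order(s$atoms$resno,
               match(s$atoms$elety, c(BACKBONE_ATOMS, "CB"),
                     nomatch = 99))
  hla_structure(s$id, s$atoms[ord, , drop = FALSE], s$resolution)
}

# rotamer score: -w_rot ln(p) + capped soft vdW + H-bond well, against a
# context atom table (other residues + environment)
score_rotamer <- function(sc_df, prob, context, ap_sc, ap_ctx,
                          w_rot = 3.0) {
  e <- -w_rot * log(prob)
  if (nrow(context)) {
    e <- e + soft_vdw(sc_df, context, ap_sc, ap_ctx)
    e <- e - count_hbonds(sc_df, context)
  }
  e
}

# minimum heavy-atom contact distance between two atom tables
min_contact <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(Inf)
  xa <- as.matrix(a[, c("x", "y", "z")]); xb <- as.matrix(b[, c("x", "y", "z")])
  min(vapply(seq_len(nrow(xa)), function(k)
    min(sqrt(colSums((t(xb) - xa[k, ])^2))), numeric(1)))
}

#' Place side chains with a rotamer library
#'
#' Residues with incomplete side chains are completed N-to-C by greedy
#' rotamer assignment minimizing
#' \eqn{E = -w_{rot} \ln p + E_{vdW}^{soft} + E_{Hbond}} against the
#' backbone, the environment and already-placed neighbours, followed by one
#' clash-repair sweep. Internal geometry is idealized.
#'
#' @param peptide peptide [hla_structure()] with complete backbone.
#' @param rotamer_lib a `rotamer_library`.
#' @param environment optional [hla_structure()] receptor reference frame
#'   (may be NULL).
#' @param params [ff_default_params()].
#' @param w_rot rotamer-prior weight, kcal/mol (default 3).
#' @return peptide [hla_structure()] with all heavy atoms.
#' @export
place_side_chains <- function(peptide, rotamer_lib = read_rotamer_library(),
                              environment = NULL,
                              params = ff_default_params(), w_rot = 3.0) {
  env_atoms <- if (is.null(environment)) peptide$atoms[0, , drop = FALSE]
               else environment$atoms
  resnos <- unique(peptide$atoms$resno)
  todo <- c()
  for (i in resnos) {
    res3 <- peptide$atoms$resid[peptide$atoms$resno == i][1]
    have <- peptide$atoms$elety[peptide$atoms$resno == i]
    if (length(setdiff(canonical_atoms(res3), have))) todo <- c(todo, i)
  }
  place_one <- function(s, i) {
    res3 <- s$atoms$resid[s$atoms$resno == i][1]
    bb <- residue_bb_matrix(s, i)
    rot <- rotamers_for(rotamer_lib, res3)
    context <- rbind(s$atoms[s$atoms$resno != i, , drop = FALSE], env_atoms)
    ap_ctx <- atom_params(hla_structure("ctx", context), params)
    best <- NULL; best_e <- Inf; any_clash_free <- FALSE
    for (k in seq_along(rot$chi)) {
      sc <- build_side_chain(bb, res3, rot$chi[[k]])
      sc_df <- data.frame(elety = rownames(sc), resid = res3,
                          chain = s$atoms$chain[1], resno = i, icode = "",
                          x = sc[, 1], y = sc[, 2], z = sc[, 3], o = 1,
                          b = 0, elesy = element_of(rownames(sc)),
                          stringsAsFactors = FALSE)
      ap_sc <- atom_params(hla_structure("sc", sc_df), params)
      e <- score_rotamer(sc_df, rot$prob[k], context, ap_sc, ap_ctx, w_rot)
      if (min_contact(sc_df, context) >= 1.5) any_clash_free <- TRUE
      if (e < best_e) { best_e <- e; best <- sc_df }
    }
    if (!any_clash_free)
      stop("side-chain placement failure at position ", i,
           " (", res3, "): no clash-free rotamer")
    a <- s$atoms[!(s$atoms$resno == i & !s$atoms$elety %in% BACKBONE_ATOMS), ,
                 drop = FALSE]
    hla_structure(s$id, rbind(a, best), s$resolution)
  }
  s <- peptide
  for (i in todo) s <- place_one(s, i)
  # one clash-repair sweep
  for (i in todo) {
    own <- s$atoms[s$atoms$resno == i & !s$atoms$elety %in% BACKBONE_ATOMS, ,
                   drop = FALSE]
    rest <- rbind(s$atoms[s$atoms$resno != i, , drop = FALSE], env_atoms)
    if (min_contact(own, rest) < 2.4) s <- place_one(s, i)
  }
  ord <- order(s$atoms$resno,
               match(s$atoms$elety, c(BACKBONE_ATOMS, "CB"), nomatch = 99),
               s$atoms$elety)
  hla_structure(s$id, s$atoms[ord, , drop = FALSE], s$resolution)
}

#' Build a 9-mer peptide model from sequence
#'
#' Threads the sequence onto its P1 template, places side chains against the
#' optional receptor reference frame, and applies a short conjugate-gradient
#' minimization. Deterministic for fixed inputs.
#'
#' @param sequence 9-mer amino-acid string.
#' @param library a `template_library`.
#' @param rotamer_lib a `rotamer_library`.
#' @param receptor_frame optional receptor [hla_structure()] used as fixed
#'   environment for packing and minimization.
#' @param params [ff_default_params()].
#' @param minimize run the final minimization (default TRUE).
#' @param maxit minimizer iterations (default 30).
#' @return peptide [hla_structure()] with all heavy atoms.
#' @export
build_peptide <- function(sequence, library,
                          rotamer_lib = read_rotamer_library(),
                          receptor_frame = NULL,
                          params = ff_default_params(), minimize = TRUE,
                          maxit = 30) {
  pep <- thread_sequence(sequence, library)
  pep <- place_side_chains(pep, rotamer_lib, receptor_frame, params)
  if (minimize) {
    if (is.null(receptor_frame)) {
      m <- minimize_structure(pep, seq_len(nrow(pep$atoms)), params,
                              maxit = maxit, restraint_k = 2)
      pep <- m$structure
    } else {
      comb <- hla_structure(pep$id,
                            rbind(receptor_frame$atoms, pep$atoms))
      mob <- which(seq_len(nrow(comb$atoms)) > nrow(receptor_frame$atoms))
      m <- minimize_structure(comb, mob, params, maxit = maxit,
                              restraint_k = 2)
      pep <- hla_structure(pep$id, m$structure$atoms[mob, , drop = FALSE])
    }
  }
  pep
}

#' Serialize a template library to disk
#'
#' Writes one PDB file per P1 template plus a JSON index carrying the
#' source ids, resolutions, the unseen-residue map and the consensus
#' anchor coordinates.
#'
#' @param library a `template_library`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_template_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- list(unseen_map = as.list(library$unseen_map),
              consensus_anchor = library$consensus_anchor,
              templates = list())
  for (k in names(library$p1_templates)) {
    e <- library$p1_templates[[k]]
    f <- paste0("template_", k, ".pdb")
    write_pdb(e$peptide, file.path(dir, f))
    idx$templates[[k]] <- list(file = f, source_id = e$source_id,
                               resolution = e$resolution)
  }
  jsonlite::write_json(idx, file.path(dir, "index.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a template library written by [write_template_library()]
#' @param dir directory containing `index.json` and the template PDBs.
#' @return a `template_library`.
#' @export
read_template_library <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "index.json"),
                             simplifyVector = TRUE)
  entries <- list()
  tpl <- idx$templates
  for (k in if (is.data.frame(tpl)) rownames(tpl) else names(tpl)) {
    e <- if (is.data.frame(tpl)) as.list(tpl[k, ]) else tpl[[k]]
    entries[[k]] <- list(peptide = read_pdb(file.path(dir, e$file)),
                         source_id = e$source_id,
                         resolution = as.numeric(e$resolution))
  }
  lib <- list(p1_templates = entries,
              unseen_map = unlist(idx$unseen_map),
              consensus_anchor = as.data.frame(idx$consensus_anchor))
  class(lib) <- "template_library"
  lib
}
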