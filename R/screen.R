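#' Load and curate a peptide affinity table
#'
#' Reads a delimited file with columns `peptide` and at least one of
#' `ic50_nM` / `qualitative`, then applies the curation rules: duplicate
#' sequences collapse to the first occurrence, records whose quantitative
#' and qualitative labels disagree are dropped, non-9-mers and sequences
#' with non-standard letters are dropped, and the binder label follows the
#' 500 nM rule (IC50 <= 500 nM = binder, boundary inclusive). Qualitative-
#' only records map "Positive"-like labels to binder and "Negative"-like to
#' non-binder.
#'
#' @param path TSV/CSV path (delimiter inferred from the extension).
#' @return data.frame with `peptide`, `ic50_nM`, `qualitative`, `binder`;
#'   the number of records dropped per rule is in `attr(, "dropped")`.
#' @export
load_affinity_table <- function(path) {
  tab <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    utils::read.csv(path, stringsAsFactors = FALSE)
  else utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"peptide" %in% names(tab))
    stop("missing required column 'peptide'")
  if (!any(c("ic50_nM", "qualitative") %in% names(tab)))
    stop("need at least one of 'ic50_nM' or 'qualitative'")
  if (!"ic50_nM" %in% names(tab)) tab$ic50_nM <- NA_real_
  if (!"qualitative" %in% names(tab)) tab$qualitative <- NA_character_
  tab$peptide <- toupper(trimws(tab$peptide))
  tab$qualitative[!nzchar(trimws(tab$qualitative)) |
                    is.na(tab$qualitative)] <- NA_character_
  dropped <- c(duplicate = 0L, conflict = 0L, length = 0L, alphabet = 0L)
  dup <- duplicated(tab$peptide)
  dropped["duplicate"] <- sum(dup)
  tab <- tab[!dup, , drop = FALSE]
  len_ok <- nchar(tab$peptide) == 9
  dropped["length"] <- sum(!len_ok)
  tab <- tab[len_ok, , drop = FALSE]
  ok_alpha <- !grepl(paste0("[^", paste(names(AA3), collapse = ""), "]"),
                     tab$peptide)
  dropped["alphabet"] <- sum(!ok_alpha)
  tab <- tab[ok_alpha, , drop = FALSE]
  quant <- ifelse(is.na(tab$ic50_nM), NA, tab$ic50_nM <= 500)
  qual <- rep(NA, nrow(tab))
  pos <- grepl("^pos", tab$qualitative, ignore.case = TRUE)
  neg <- grepl("^neg", tab$qualitative, ignore.case = TRUE)
  qual[pos] <- TRUE; qual[neg] <- FALSE
  conflict <- !is.na(quant) & !is.na(qual) & quant != qual
  dropped["conflict"] <- sum(conflict)
  tab <- tab[!conflict, , drop = FALSE]
  quant <- quant[!conflict]; qual <- qual[!conflict]
  tab$binder <- ifelse(!is.na(quant), quant, qual)
  out <- tab[, c("peptide", "ic50_nM", "qualitative", "binder")]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Fit a binder/non-binder threshold from score distributions
#'
#' A Gaussian kernel density (Silverman bandwidth) is fitted per class; the
#' cutoff is the midpoint between the two density modes (the alternative
#' class-mean midpoint reading is available via `rule`). A two-sample
#' t-test on the class means is reported alongside.
#'
#' @param binder_scores,nonbinder_scores numeric vectors (>= 20 each).
#' @param rule `"mode-midpoint"` (default) or `"mean-midpoint"`.
#' @return object of class `threshold_model`: `cutoff`, `binder_mode`,
#'   `nonbinder_mode`, `t_statistic`, `p_value`, `kde_bandwidth`, `rule`,
#'   `usable` (binder mode below non-binder mode).
#' @export
fit_threshold <- function(binder_scores, nonbinder_scores,
                          rule = c("mode-midpoint", "mean-midpoint")) {
  rule <- match.arg(rule)
  if (length(binder_scores) < 20 || length(nonbinder_scores) < 20)
    stop("need at least 20 scores per class")
  if (stats::sd(binder_scores) == 0 || stats::sd(nonbinder_scores) == 0)
    stop("degenerate (zero-variance) score class")
  db <- stats::density(binder_scores)
  dn <- stats::density(nonbinder_scores)
  mb <- db$x[which.max(db$y)]
  mn <- dn$x[which.max(dn$y)]
  cutoff <- if (rule == "mode-midpoint") (mb + mn) / 2 else
    (mean(binder_scores) + mean(nonbinder_scores)) / 2
  tt <- stats::t.test(binder_scores, nonbinder_scores)
  out <- list(cutoff = cutoff, binder_mode = mb, nonbinder_mode = mn,
              t_statistic = unname(tt$statistic), p_value = tt$p.value,
              kde_bandwidth = c(binder = db$bw, nonbinder = dn$bw),
              rule = rule, usable = mb < mn)
  class(out) <- "threshold_model"
  out
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> cutoff %.3f (modes %.3f / %.3f, %s)\n",
              x$cutoff, x$binder_mode, x$nonbinder_mode, x$rule))
  cat(sprintf("  t = %.2f, p = %.3g%s\n", x$t_statistic, x$p_value,
              if (x$usable) "" else "  [not usable: modes inverted]"))
  invisible(x)
}

#' Classify scores against a fitted threshold
#'
#' A score is a binder if and only if it is strictly less than the cutoff.
#'
#' @param score numeric vector of binding free energies (kcal/mol).
#' @param model a `threshold_model`.
#' @return character vector, `"binder"` / `"nonbinder"`.
#' @export
classify <- function(score, model) {
  ifelse(score < model$cutoff, "binder", "nonbinder")
}

#' ROC curve and AUC for binder scoring
#'
#' Lower scores are more binder-like. The AUC equals the probability that a
#' random binder outscores (scores lower than) a random non-binder, ties
#' counting one half — identical to the trapezoid area over all distinct
#' cutoffs.
#'
#' @param scores numeric scores.
#' @param labels logical (TRUE = binder) or anything coercible.
#' @return list with `auc` and `curve` (data.frame `cutoff`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  nb <- sum(labels); nn <- sum(!labels)
  if (nb == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  # Mann-Whitney: P(binder score < nonbinder score) + 0.5 P(tie)
  auc <- (sum(r[!labels]) - nn * (nn + 1) / 2) / (nb * nn)
  cuts <- c(-Inf, sort(unique(scores)), Inf)
  curve <- data.frame(
    cutoff = cuts,
    fpr = vapply(cuts, function(ct) mean(scores[!labels] < ct), numeric(1)),
    tpr = vapply(cuts, function(ct) mean(scores[labels] < ct), numeric(1)))
  list(auc = auc, curve = curve)
}

# replace one heavy-chain residue's side chain (top-prior rotamer, clash
# fallback at 2.4 A); returns list(structure, flagged)
mutate_residue <- function(s, resno, new_res3, rotamer_lib, chain = NULL,
                           clash_tol = 2.4) {
  if (is.null(chain)) chain <- heavy_chain(s)
  sel <- s$atoms$chain == chain & s$atoms$resno == resno
  if (!any(sel)) stop("residue ", resno, " absent from chain ", chain)
  cur <- s$atoms$resid[sel][1]
  if (cur == new_res3 &&
      !length(setdiff(canonical_atoms(new_res3), s$atoms$elety[sel])))
    return(list(structure = s, flagged = FALSE, noop = TRUE))
  a <- s$atoms
  a <- a[!(sel & !a$elety %in% BACKBONE_ATOMS), , drop = FALSE]
  a$resid[a$chain == chain & a$resno == resno] <- new_res3
  base <- hla_structure(s$id, a, s$resolution)
  bb <- residue_bb_matrix(base, resno, chain)
  rot <- rotamers_for(rotamer_lib, new_res3)
  ord <- order(-rot$prob)
  rest <- base$atoms[!(base$atoms$chain == chain &
                         base$atoms$resno == resno), , drop = FALSE]
  best <- NULL; best_min <- -Inf; chosen <- NULL
  for (k in ord) {
    sc <- build_side_chain(bb, new_res3, rot$chi[[k]])
    if (!nrow(sc)) { chosen <- sc; break }
    mc <- min_contact(data.frame(x = sc[, 1], y = sc[, 2], z = sc[, 3]),
                      rest)
    if (mc >= clash_tol) { chosen <- sc; break }
    if (mc > best_min) { best_min <- mc; best <- sc }
  }
  flagged <- is.null(chosen)
  if (flagged) chosen <- best
  if (nrow(chosen)) {
    add <- data.frame(elety = rownames(chosen), resid = new_res3,
                      chain = chain, resno = resno, icode = "",
                      x = chosen[, 1], y = chosen[, 2], z = chosen[, 3],
                      o = 1, b = 0, elesy = element_of(rownames(chosen)),
                      stringsAsFactors = FALSE)
    base <- hla_structure(base$id, rbind(base$atoms, add), base$resolution)
  }
  ord2 <- order(match(base$atoms$chain, chain_ids(base)),
                match(base$atoms$resno, unique(base$atoms$resno)),
                match(base$atoms$elety, c(BACKBONE_ATOMS, "CB"),
                      nomatch = 99))
  list(structure = hla_structure(base$id, base$atoms[ord2, , drop = FALSE],
                                 base$resolution),
       flagged = flagged, noop = FALSE)
}

#' Build the high-risk substitution model set
#'
#' For every observed residue at every listed high-risk position, the
#' reference side chain is replaced by the target residue in its highest-
#' prior rotamer, falling back to the next rotamer when a steric clash
#' (heavy-atom pair below 2.4 A) occurs; in `"full"` mode a short local
#' minimization of the mutated side chain follows. Models that admit no
#' clash-free rotamer are flagged and retained best-effort.
#'
#' @param reference_hla receptor [hla_structure()] covering the positions.
#' @param table2 data.frame as from [high_risk_positions()].
#' @param rotamer_lib a `rotamer_library`.
#' @param params [ff_default_params()].
#' @param mode `"full"` (with minimization) or `"enumerate"`.
#' @return object of class `substitution_model_set`: named list `models`
#'   ("p<position><residue>"), plus `reference_id` and `provenance`.
#' @export
build_substitution_models <- function(reference_hla,
                                      table2 = high_risk_positions(),
                                      rotamer_lib = read_rotamer_library(),
                                      params = ff_default_params(),
                                      mode = c("full", "enumerate")) {
  mode <- match.arg(mode)
  chain <- heavy_chain(reference_hla)
  models <- list()
  for (i in seq_len(nrow(table2))) {
    pos <- table2$position[i]
    for (r in strsplit(table2$observed_residues[i], "")[[1]]) {
      mut <- mutate_residue(reference_hla, pos, AA3[[r]], rotamer_lib,
                            chain = chain)
      st <- mut$structure
      if (mode == "full" && !mut$noop) {
        mob <- atom_select(st, chain = chain, resno = pos)
        mob <- mob[!st$atoms$elety[mob] %in% BACKBONE_ATOMS]
        if (length(mob))
          st <- minimize_structure(st, mob, params, maxit = 15)$structure
      }
      models[[sprintf("p%d%s", pos, r)]] <-
        list(structure = st, position = pos, residue = r,
             flagged = mut$flagged)
    }
  }
  out <- list(models = models, reference_id = reference_hla$id,
              provenance = table2)
  class(out) <- "substitution_model_set"
  out
}

#' @export
print.substitution_model_set <- function(x, ...) {
  cat(sprintf("<substitution_model_set> %d models on %s\n",
              length(x$models), x$reference_id))
  invisible(x)
}

#' Screen peptides against substituted HLA models
#'
#' Docks and scores every peptide against the reference receptor and every
#' substitution model, reporting per-pair delta-delta-G and predicted loss
#' of binding (variant binding free energy at or above the threshold
#' cutoff). Per-item failures are recorded, never fatal; scored plus failed
#' always equals peptides x models.
#'
#' @param peptides character vector of 9-mer sequences (reference binders).
#' @param reference_hla reference receptor [hla_structure()].
#' @param model_set a `substitution_model_set`.
#' @param library a `template_library`.
#' @param threshold a `threshold_model`.
#' @param config [dock_config()].
#' @param params [ff_default_params()].
#' @param rotamer_lib a `rotamer_library`.
#' @return object of class `screen_result`: `pairs` (long data.frame:
#'   model, peptide, dg_reference, dg_variant, ddg, lost, failed) and
#'   `summary` (per model: fraction_lost among scored, n_failed).
#' @export
substitution_screen <- function(peptides, reference_hla, model_set, library,
                                threshold, config = dock_config(),
                                params = ff_default_params(),
                                rotamer_lib = read_rotamer_library()) {
  dock_score <- function(receptor, seqs) {
    tryCatch({
      pep <- build_peptide(seqs, library, rotamer_lib,
                           receptor_frame = receptor, params = params)
      fr <- dock_peptide(pep, receptor, library, config = config,
                         params = params)
      if (fr$clash_failed) return(NA_real_)
      pc <- setdiff(chain_ids(fr$complex), chain_ids(receptor))
      binding_dg(fr$complex, peptide_sel = pc, params = params)$dg
    }, error = function(e) NA_real_)
  }
  dg_ref <- vapply(peptides, function(sq) dock_score(reference_hla, sq),
                   numeric(1))
  rows <- list()
  for (mn in names(model_set$models)) {
    rec <- model_set$models[[mn]]$structure
    for (i in seq_along(peptides)) {
      dgv <- dock_score(rec, peptides[i])
      failed <- is.na(dgv) || is.na(dg_ref[i])
      rows[[length(rows) + 1]] <- data.frame(
        model = mn, peptide = peptides[i],
        dg_reference = dg_ref[i], dg_variant = dgv,
        ddg = dgv - dg_ref[i],
        lost = if (failed) NA else dgv >= threshold$cutoff,
        failed = failed, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(pairs, pairs$model), function(d) {
    data.frame(model = d$model[1],
               n_scored = sum(!d$failed), n_failed = sum(d$failed),
               fraction_lost = if (any(!d$failed))
                 mean(d$lost[!d$failed]) else NA_real_,
               mean_ddg = if (any(!d$failed))
                 mean(d$ddg[!d$failed]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  out <- list(pairs = pairs, summary = summ)
  class(out) <- "screen_result"
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d peptide x model pairs\n", nrow(x$pairs)))
  print(x$summary)
  invisible(x)
}
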