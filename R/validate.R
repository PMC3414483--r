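#' Extract the bound peptide from a p-HLA complex
#'
#' The peptide is the unique chain of length 8-12 residues; it is returned as
#' a standalone structure with residues relabelled P1..Pn by chain order
#' (resno 1..n), independent of author numbering.
#'
#' @param s an [hla_structure()] of a p-HLA complex.
#' @return an `hla_structure` containing only the peptide chain.
#' @export
extract_peptide <- function(s) {
  pc <- peptide_chain(s)
  a <- s$atoms[s$atoms$chain == pc, , drop = FALSE]
  key <- paste(a$resno, a$icode, sep = "|")
  a$resno <- match(key, unique(key))
  a$icode <- ""
  hla_structure(paste0(s$id, "_pep"), a, s$resolution)
}

#' Select binding-groove residues from the HLA heavy chain
#'
#' @param s an [hla_structure()] containing the HLA heavy chain.
#' @param groove_def a [groove_definition()]; default is the 37-residue
#'   HLA-A*02:01 groove.
#' @param chain heavy-chain id; auto-detected when `NULL`.
#' @return data.frame of groove atoms (all atoms of the listed residues), in
#'   definition order, with a `groove_pos` column giving the residue number.
#' @export
select_groove <- function(s, groove_def = groove_definition(), chain = NULL) {
  if (is.null(chain)) chain <- heavy_chain(s)
  a <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  missing <- setdiff(unclass(groove_def), unique(a$resno))
  if (length(missing))
    stop("groove residue(s) absent from chain ", chain, ": ",
         paste(missing, collapse = ", "))
  out <- do.call(rbind, lapply(unclass(groove_def), function(rn) {
    b <- a[a$resno == rn, , drop = FALSE]
    b$groove_pos <- rn
    b
  }))
  rownames(out) <- NULL
  out
}

#' Validate a p-HLA complex for benchmark use
#'
#' Applies the curation filters used to assemble the benchmark set: the
#' peptide must have no sequence-number gaps, only standard residues, and a
#' complete canonical heavy-atom set per residue. In strict-nonamer mode
#' (default) the peptide must be exactly 9 residues long.
#'
#' @param s an [hla_structure()] of a p-HLA complex.
#' @param strict_nonamer reject peptides of length != 9 (default TRUE).
#' @return list with `accept` (logical) and `reasons` (character vector,
#'   empty when accepted).
#' @export
validate_complex <- function(s, strict_nonamer = TRUE) {
  reasons <- character(0)
  pc <- tryCatch(peptide_chain(s), error = function(e) {
    reasons <<- c(reasons, conditionMessage(e))
    NA_character_
  })
  if (is.na(pc)) return(list(accept = FALSE, reasons = reasons))
  a <- s$atoms[s$atoms$chain == pc, , drop = FALSE]
  key <- paste(a$resno, a$icode, sep = "|")
  res3 <- a$resid[!duplicated(key)]
  resno <- a$resno[!duplicated(key)]
  n <- length(res3)
  if (strict_nonamer && n != 9)
    reasons <- c(reasons, sprintf("peptide length %d != 9", n))
  if (any(diff(resno) != 1))
    reasons <- c(reasons, "gapped peptide (non-consecutive residue numbers)")
  bad <- unique(res3[!res3 %in% STANDARD_AA])
  if (length(bad))
    reasons <- c(reasons, paste0("non-standard residue(s): ",
                                 paste(bad, collapse = ", ")))
  for (i in seq_len(n)) {
    if (!res3[i] %in% STANDARD_AA) next
    have <- a$elety[key == unique(key)[i]]
    need <- canonical_atoms(res3[i])
    miss <- setdiff(need, have)
    if (length(miss))
      reasons <- c(reasons, sprintf(
        "incomplete side chain at peptide position %d (%s): missing %s",
        i, res3[i], paste(miss, collapse = ",")))
  }
  list(accept = length(reasons) == 0, reasons = reasons)
}
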