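#' Read a PDB file into a structure object
#'
#' Loads ATOM records of the first MODEL of a PDB file (via bio3d), skipping
#' HETATM records and waters. Alternate locations are resolved by keeping the
#' highest-occupancy conformer, ties broken by altloc label order.
#' Crystallographic resolution is captured from the REMARK 2 record when
#' present.
#'
#' @param path path to an existing PDB-format file.
#' @param id structure label; defaults to the file name without extension.
#' @return an [hla_structure()].
#' @export
read_pdb <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  atom_idx <- grep("^ATOM  ", lines)
  if (!length(atom_idx))
    stop("parse error in '", path, "': no ATOM records (line 1)")
  bad <- atom_idx[nchar(lines[atom_idx]) < 54]
  if (length(bad))
    stop("parse error in '", path, "': truncated ATOM record at line ", bad[1])
  # coordinates must be numeric
  for (i in atom_idx) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (any(is.na(xyz)))
      stop("parse error in '", path, "': bad coordinates at line ", i)
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM" & !(a$resid %in% c("HOH", "WAT", "DOD")), ,
         drop = FALSE]
  if (!nrow(a)) stop("parse error in '", path, "': no usable ATOM records")
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  a$b[is.na(a$b)] <- 0
  # altloc: keep highest occupancy, ties by altloc label order
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  ord <- order(match(key, unique(key)), -a$o, a$alt)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety, sep = "|")), ,
         drop = FALSE]
  elesy <- a$elesy
  elesy[is.na(elesy) | !nzchar(elesy)] <-
    substr(gsub("[^A-Za-z].*$", "", a$elety[is.na(elesy) | !nzchar(elesy)]),
           1, 1)
  atoms <- data.frame(elety = a$elety, resid = a$resid, chain = a$chain,
                      resno = a$resno, icode = a$insert,
                      x = a$x, y = a$y, z = a$z, o = a$o, b = a$b,
                      elesy = elesy, stringsAsFactors = FALSE)
  res <- NA_real_
  rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem2)) {
    m <- regmatches(rem2[1], regexpr("[0-9]+\\.[0-9]+", rem2[1]))
    if (length(m)) res <- as.numeric(m)
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  hla_structure(id, atoms, res)
}

#' Write a structure to a PDB file
#'
#' Emits standards-conformant fixed-width ATOM records (coordinates to three
#' decimals) plus a REMARK 2 resolution record when known.
#'
#' @param s an [hla_structure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (any(abs(xyz) > 9999.999))
    stop("cannot format coordinates beyond +/-9999.999 A ",
         "(PDB fixed-width column limit)")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  if (!is.na(s$resolution))
    writeLines(sprintf(
      "REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", s$resolution), con)
  name4 <- ifelse(nchar(a$elety) >= 4, substr(a$elety, 1, 4),
                  sprintf(" %-3s", a$elety))
  lines <- sprintf(
    "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000, name4, a$resid, a$chain, a$resno,
    ifelse(nzchar(a$icode), a$icode, " "),
    a$x, a$y, a$z, a$o, a$b, a$elesy)
  # TER after each chain
  out <- character(0)
  for (ch in unique(a$chain)) {
    out <- c(out, lines[a$chain == ch], "TER")
  }
  writeLines(c(out, "END"), con)
  invisible(path)
}
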