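#' Load a side-chain rotamer library
#'
#' The packaged library is a backbone-independent table of modal chi-angle
#' sets with prior probabilities per residue type (columns `resid`, `chi1` ..
#' `chi4`, `prob`). Priors sum to 1 per residue. Richer libraries in the same
#' format can be supplied.
#'
#' @param path TSV path; default is the packaged library.
#' @return object of class `rotamer_library`: named list per residue type of
#'   data.frames with a `chi` matrix column set and `prob`.
#' @export
read_rotamer_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rotamers.tsv", package = "anchordock")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lib <- split(tab, tab$resid)
  lib <- lapply(lib, function(d) {
    p <- sum(d$prob)
    if (abs(p - 1) > 1e-6)
      stop("rotamer priors for ", d$resid[1], " sum to ", p, ", not 1")
    chi <- as.matrix(d[, c("chi1", "chi2", "chi3", "chi4")])
    bad <- chi[!is.na(chi)]
    if (any(bad <= -180 | bad > 180))
      stop("chi angles must lie in (-180, 180]")
    d
  })
  class(lib) <- "rotamer_library"
  lib
}

# chi vectors (list) + priors for a residue type; ALA/GLY/PRO have a single
# chi-less "rotamer" with prior 1.
rotamers_for <- function(rotlib, resid) {
  d <- rotlib[[resid]]
  if (is.null(d))
    return(list(chi = list(numeric(0)), prob = 1))
  nch <- n_chi(resid)
  chi <- lapply(seq_len(nrow(d)), function(i)
    as.numeric(d[i, paste0("chi", seq_len(nch))]))
  list(chi = chi, prob = d$prob)
}
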