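#' The 50-complex benchmark table
#'
#' PDB code, resolution (Angstrom) and nonameric peptide sequence of the 50
#' unique HLA-A*02:01 p-HLA complexes used throughout as the benchmark set.
#'
#' @return data.frame with columns `pdb`, `resolution`, `sequence`.
#' @export
benchmark_set <- function() {
  utils::read.delim(system.file("extdata", "table1_benchmark.tsv",
                                package = "anchordock"),
                    stringsAsFactors = FALSE)
}

#' Observed residues at the five high-risk HLA positions
#'
#' The amino acids observed across known HLA-A alleles at the five
#' non-permissive-mismatch positions of the binding groove (9, 114, 116, 152,
#' 156), with their groove location, contacted peptide positions and the
#' HLA-A*02:01 reference residue.
#'
#' @return data.frame with one row per position; `observed_residues` is a
#'   string of one-letter codes.
#' @export
high_risk_positions <- function() {
  utils::read.delim(system.file("extdata", "table2_residues.tsv",
                                package = "anchordock"),
                    stringsAsFactors = FALSE)
}
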