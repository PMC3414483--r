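# Shared fixture cache: the synthetic groove/complex and derived objects are
# deterministic and moderately expensive, so they are built once per run.

.fx <- new.env(parent = emptyenv())

fx_groove <- function() {
  if (is.null(.fx$groove)) .fx$groove <- generate_groove()
  .fx$groove
}

fx_complex <- function() {
  if (is.null(.fx$complex)) .fx$complex <- generate_complex()
  .fx$complex
}

fx_library <- function() {
  if (is.null(.fx$library))
    .fx$library <- build_template_library(complexes = list(fx_complex()))
  .fx$library
}

fx_lib13 <- function() {
  if (is.null(.fx$lib13)) {
    tb <- benchmark_set()
    .fx$lib13 <- build_template_library(
      sequences = tb$sequence, resolutions = tb$resolution, ids = tb$pdb,
      backbone = extract_peptide(fx_complex()))
  }
  .fx$lib13
}

fx_rotlib <- function() {
  if (is.null(.fx$rotlib)) .fx$rotlib <- read_rotamer_library()
  .fx$rotlib
}

fx_params <- function() {
  if (is.null(.fx$params)) .fx$params <- ff_default_params()
  .fx$params
}

# a small single-chain structure from an atom spec list:
# list(list(elety=, resid=, resno=, x=, y=, z=), ...)
toy_structure <- function(atoms, id = "toy", chain = "A") {
  df <- do.call(rbind, lapply(atoms, function(a) {
    data.frame(elety = a$elety, resid = a$resid, chain = chain,
               resno = a$resno, icode = "", x = a$x, y = a$y, z = a$z,
               o = 1, b = 0,
               elesy = substr(a$elety, 1, 1), stringsAsFactors = FALSE)
  }))
  hla_structure(id, df)
}

# single free atom (parameterizable as an alanine CB carbon)
toy_atom <- function(x = 0, y = 0, z = 0, elety = "CB", resid = "ALA",
                     resno = 1) {
  toy_structure(list(list(elety = elety, resid = resid, resno = resno,
                          x = x, y = y, z = z)))
}

# independent soft-vdW + prior rotamer scoring used as packing oracle
oracle_rotamer_energy <- function(sc, prob, ctx_xyz, ctx_eps, ctx_rmin2,
                                  sc_eps, sc_rmin2, w_rot = 3) {
  e <- -w_rot * log(prob)
  if (!nrow(ctx_xyz) || !nrow(sc)) return(e)
  for (k in seq_len(nrow(sc))) {
    r <- sqrt(colSums((t(ctx_xyz) - sc[k, ])^2))
    eps <- sqrt(sc_eps[k] * ctx_eps)
    rmin <- sc_rmin2[k] + ctx_rmin2
    sr6 <- (rmin / pmax(r, 0.5))^6
    e <- e + sum(pmin(eps * (sr6^2 - 2 * sr6), 10))
  }
  e
}
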