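write_affinity_fixture <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("affinity curation applies the 500 nM rule and drops ambiguity", {
  f <- write_affinity_fixture(c(
    "peptide\tic50_nM\tqualitative",
    "ILKEPVHGV\t500\t",            # boundary: binder (inclusive)
    "ILKEPVHGV\t800\t",            # duplicate sequence: first kept
    "LLFGYPVYV\t501\t",            # non-binder
    "SLYNTVATL\t\tPositive",       # qualitative-only
    "GILGFVFTL\t\tNegative",
    "KLTPLCVTL\t100\tNegative",    # conflict: dropped
    "AAAAXAAAA\t50\t",             # non-standard letter: dropped
    "ALAVILKE\t50\t",              # 8-mer: dropped
    "NLVPMVATV\t2000\tNegative"))  # agreeing quantitative + qualitative
  tab <- load_affinity_table(f)
  expect_equal(nrow(tab), 5)
  expect_true(tab$binder[tab$peptide == "ILKEPVHGV"])
  expect_equal(tab$ic50_nM[tab$peptide == "ILKEPVHGV"], 500)
  expect_false(tab$binder[tab$peptide == "LLFGYPVYV"])
  expect_true(tab$binder[tab$peptide == "SLYNTVATL"])
  expect_false(tab$binder[tab$peptide == "GILGFVFTL"])
  expect_false("KLTPLCVTL" %in% tab$peptide)
  expect_equal(unname(attr(tab, "dropped")["conflict"]), 1L)
  bad <- write_affinity_fixture(c("sequence\tvalue", "AAA\t1"))
  expect_error(load_affinity_table(bad), "peptide")
})

test_that("fit_threshold recovers the midpoint of two Gaussian modes", {
  for (seed in 1:5) {
    d <- generate_score_dataset(500, 500, -50, -20, sd = 3, seed = seed)
    m <- fit_threshold(d$score[d$binder], d$score[!d$binder])
    expect_true(m$usable)
    expect_equal(m$cutoff, -35, tolerance = 1 / 35)  # within +/- 1 kcal/mol
    expect_lt(m$p_value, 1e-10)
  }
  expect_error(fit_threshold(rnorm(10), rnorm(30)), "20")
  expect_error(fit_threshold(rep(1, 30), rnorm(30)), "degenerate")
})

test_that("classification is strict at the cutoff and monotone", {
  d <- generate_score_dataset(200, 200, -50, -20, sd = 5, seed = 3)
  m <- fit_threshold(d$score[d$binder], d$score[!d$binder])
  expect_equal(classify(m$cutoff, m), "nonbinder")   # strict inequality
  expect_equal(classify(m$cutoff - 10, m), "binder")
  expect_equal(classify(Inf, m), "nonbinder")
  expect_equal(classify(-Inf, m), "binder")
  # monotone: lowering a score never flips binder -> nonbinder
  s <- seq(-60, -10, 2)
  cl <- classify(s, m)
  expect_true(all(diff(cl == "binder") <= 0))
  # identical distributions: accuracy ~ 0.5; separated: accuracy 1.0
  same <- generate_score_dataset(300, 300, -30, -30, sd = 4, seed = 5)
  msame <- fit_threshold(same$score[same$binder], same$score[!same$binder])
  acc <- mean((classify(same$score, msame) == "binder") == same$binder)
  expect_lt(abs(acc - 0.5), 0.1)
  sep <- generate_score_dataset(100, 100, -80, -10, sd = 1, seed = 7)
  msep <- fit_threshold(sep$score[sep$binder], sep$score[!sep$binder])
  expect_equal(mean((classify(sep$score, msep) == "binder") == sep$binder),
               1.0)
})

test_that("roc_auc equals the pair-counting oracle and known endpoints", {
  oracle_auc <- function(scores, labels) {
    b <- scores[labels]; n <- scores[!labels]
    tot <- 0
    for (x in b) for (y in n)
      tot <- tot + if (x < y) 1 else if (x == y) 0.5 else 0
    tot / (length(b) * length(n))
  }
  set.seed(17)
  for (rep in 1:8) {
    scores <- sample(round(rnorm(10), 1))  # ties likely
    labels <- sample(c(rep(TRUE, 5), rep(FALSE, 5)))
    got <- roc_auc(scores, labels)$auc
    expect_identical(got, oracle_auc(scores, labels))
  }
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(5, 8), rep(c(TRUE, FALSE), 4))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
  # cross-check against an independent ROC implementation
  d <- generate_score_dataset(80, 90, -45, -25, sd = 8, seed = 9)
  got <- roc_auc(d$score, d$binder)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = d$binder,
                                        predictor = d$score,
                                        direction = ">", quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("the full high-risk table yields 35 substitution models", {
  groove <- fx_groove()
  t2 <- high_risk_positions()
  expect_equal(sum(nchar(t2$observed_residues)), 35)
  ms <- build_substitution_models(groove, t2, fx_rotlib(),
                                  mode = "enumerate")
  expect_length(ms$models, 35)
  expect_setequal(unique(vapply(ms$models, function(m) m$position,
                                numeric(1))),
                  c(9, 114, 116, 152, 156))
  # restricting a position restricts the set
  one <- build_substitution_models(groove,
                                   data.frame(position = 9,
                                              observed_residues = "T"),
                                   fx_rotlib(), mode = "enumerate")
  expect_length(one$models, 1)
  expect_equal(one$models$p9T$residue, "T")
  expect_equal(one$models$p9T$structure$atoms$resid[
    one$models$p9T$structure$atoms$resno == 9][1], "THR")
})

test_that("self-substitution reproduces the reference coordinates", {
  groove <- fx_groove()
  # position 152 is alanine in the fixture and alanine is an observed
  # residue there, so p152A is a true self-substitution
  ms <- build_substitution_models(groove,
                                  data.frame(position = 152,
                                             observed_residues = "A"),
                                  fx_rotlib(), mode = "full")
  expect_identical(coords(ms$models$p152A$structure), coords(groove))
})

test_that("substitution screen conserves bookkeeping and self-model ddg
           is exactly zero", {
  cx <- fx_complex()
  groove <- subset_chains(cx, "A")
  lib <- fx_library()
  thr <- local({
    d <- generate_score_dataset(100, 100, -8, -2, sd = 1, seed = 2)
    fit_threshold(d$score[d$binder], d$score[!d$binder])
  })
  ms <- build_substitution_models(groove,
                                  data.frame(position = 152,
                                             observed_residues = "A"),
                                  fx_rotlib(), mode = "full")
  res <- substitution_screen("ILKEPVHGV", groove, ms, lib, thr)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(sum(res$summary$n_scored) + sum(res$summary$n_failed), 1)
  # identical receptor, deterministic pipeline: ddg is exactly 0
  expect_identical(res$pairs$ddg, 0)
  expect_identical(res$pairs$lost, res$pairs$dg_variant >= thr$cutoff)
  # the reference binder stays a binder, so nothing is lost
  expect_false(res$pairs$lost)
  expect_equal(res$summary$fraction_lost, 0)
})

test_that("a pocket-blocking variant loses more peptides than the
           self-substitution", {
  cx <- fx_complex()
  groove <- subset_chains(cx, "A")
  lib <- fx_library()
  # variant: mutate the F-pocket lysine to bulky TRP, obstructing the
  # C-terminal pocket; compare ddg against the self-substitution
  msW <- build_substitution_models(groove,
                                   data.frame(position = 116,
                                              observed_residues = "W"),
                                   fx_rotlib(), mode = "full")
  msA <- build_substitution_models(groove,
                                   data.frame(position = 152,
                                              observed_residues = "A"),
                                   fx_rotlib(), mode = "full")
  d <- generate_score_dataset(100, 100, -8, -2, sd = 1, seed = 2)
  thr <- fit_threshold(d$score[d$binder], d$score[!d$binder])
  rW <- substitution_screen("ILKEPVHGV", groove, msW, lib, thr)
  rA <- substitution_screen("ILKEPVHGV", groove, msA, lib, thr)
  okW <- !rW$pairs$failed; okA <- !rA$pairs$failed
  expect_true(all(okA))
  if (any(okW)) {
    # losing the engineered terminal contact costs binding free energy
    expect_gt(rW$pairs$ddg[okW][1], rA$pairs$ddg[okA][1])
  } else {
    expect_gt(rW$summary$n_failed, 0)
  }
})
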