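# anchordock

Structure-based modelling of nonameric peptide binding to the human
class I molecule HLA-A*02:01, for immunoinformaticians and structural
biologists who need peptide-level, interpretable binding predictions:
vaccine epitope triage, and screening of donor-patient HLA amino acid
mismatches (the "non-permissive" positions 9, 114, 116, 152 and 156 of
the binding groove) in hematopoietic stem cell transplantation.

## The method

The peptide-binding groove of HLA-A*02:01 — 37 solvent-accessible
residues between the alpha-1/alpha-2 helices and the beta-sheet floor —
holds its ligands by conformationally fixed anchor contacts at peptide
positions P1, P2 and P9. `anchordock` turns that conservation into a
docking shortcut:

1. **Template construction.** A 9-mer is threaded onto a template backbone
   keyed by its P1 residue (highest-resolution example per key; unseen P1
   residues map to the closest observed key). Side chains are packed with
   a rotamer library minimizing
   `E = -w_rot ln p + E_vdW(soft) + E_Hbond` against the receptor frame.
2. **Anchored docking.** The 12 anchor backbone atoms (P1/P2/P9 ×
   N, CA, C, O) are superimposed onto consensus anchor coordinates
   (Kabsch); a greedy rigid refinement maximizes hydrogen-bond matching +
   soft van der Waals contact under a hard 0.5 Å per-atom displacement
   cap; a short conjugate-gradient minimization then relaxes the peptide
   and the groove residues.
3. **Scoring.** Single-geometry MM-GBSA:
   `ΔG = G(complex) − G(receptor) − G(peptide)`, each
   `G = E_MM + ΔG_GB + γ·SASA`, with pairwise-descreening Born radii and
   `f_GB = sqrt(r² + R_i R_j exp(−r²/4R_iR_j))`.
4. **Classification.** Kernel densities of binder (IC50 ≤ 500 nM) and
   non-binder score pools; the cutoff is the midpoint of the two density
   modes; a peptide binds iff `ΔG < cutoff`. ROC/AUC quantify separation.
5. **Substitution screening.** 35 receptor variants (the residues
   observed across HLA-A alleles at the five high-risk positions) are
   built by rotamer replacement; each peptide is docked against reference
   and variant, and `ΔΔG = ΔG_variant − ΔG_reference` plus an
   absolute-threshold loss call are reported.

A deterministic synthetic fixture generator (an idealized groove with
helical walls, strand floor and hydrogen-bonding end pockets 32 Å apart)
makes every stage runnable and testable without downloads.

## Worked example

```r
library(anchordock)

cx  <- generate_complex(fixture_spec(seed = 1))   # synthetic "crystal"
lib <- build_template_library(complexes = list(cx))
lib
#> <template_library> 1 P1 templates: I

redock_benchmark(list(cx), lib, mode = "redock")[, 1:4]
#>          id rmsd_backbone rmsd_allatom rmsd_complex
#> 1 fixture_1     0.2937201    0.2932713    0.1154889

redock_benchmark(list(cx), lib, mode = "abinitio")[, 1:4]
#>          id rmsd_backbone rmsd_allatom rmsd_complex
#> 1 fixture_1     0.4021516    0.5516658    0.2187037
```

Redocking the fixture peptide into its own groove recovers the pose to
0.29 Å backbone RMSD; rebuilding the peptide from sequence alone and
docking it recovers 0.40 Å (the ab initio all-atom value is larger
because packed side chains need not reproduce crystallographic
rotamers). Threshold
fitting on synthetic score pools recovers the known class structure:

```r
d <- generate_score_dataset(500, 500, mu_bind = -50, mu_non = -20,
                            sd = 3, seed = 1)
fit_threshold(d$score[d$binder], d$score[!d$binder])
#> <threshold_model> cutoff -35.399 (modes -50.728 / -20.070, mode-midpoint)
#>   t = -151.74, p = 0
```

The cutoff lands midway between the true modes (−50, −20); scores below
it are classified as binders.

## Command-line interface

A thin wrapper over the exported functions lives at `inst/cli/anchordock`
(installed under `system.file("cli", "anchordock")`):

```sh
anchordock validate complex.pdb
anchordock fixtures --out fixtures/ --seed 1 --n 5 --sigma 0.3
anchordock conserve *.pdb --selection backbone --out conservation.tsv
anchordock dock ILKEPVHGV --receptor groove.pdb --out docked.pdb
anchordock score docked.pdb --peptide-chain C
```
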