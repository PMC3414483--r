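---
title: "Template-anchored peptide-HLA docking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-anchored peptide-HLA docking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The modelling problem

HLA class I molecules present short peptides (preferentially 9-mers,
positions P1-P9) in a groove delineated, in HLA-A*02:01, by 37
solvent-accessible residues between the two alpha-helices and the
beta-sheet floor. Binding is dominated by conformationally fixed anchor
contacts at P1, P2 and P9; the interior of the peptide has more freedom.
`anchordock` exploits this conservation: rather than searching the full
conformational space, a peptide is built on a template backbone, its
termini are superimposed onto consensus anchor coordinates, and only small
rigid and flexible adjustments follow. Binding is then scored with an
implicit-solvent (MM-GBSA-style) free energy, a density-based threshold
separates predicted binders from non-binders, and the same machinery
screens amino acid substitutions at the five groove positions (9, 114,
116, 152, 156) reported as high-risk mismatches in stem cell
transplantation.

# Pipeline stages and their assumptions

1. **Curation** (`validate_complex`): complexes with gapped peptides,
   non-standard residues or incomplete side chains are rejected;
   strict-nonamer mode (default on) additionally rejects peptides whose
   length is not 9. Author residue numbering is authoritative for the
   heavy chain; peptide positions P1..P9 are 1-based chain order.
2. **Superposition** (`kabsch`, `superpose_complexes`): least-squares
   optimal rigid fits by singular value decomposition with the
   determinant correction (proper rotations only). Complexes are matched
   residue-by-residue on heavy-chain author numbers; the peptide chain is
   excluded from the fit. Conservation analytics (`per_position_rmsd`,
   `peptide_variability`) summarise pairwise RMSDs per position with
   median, quartiles and a conventional 1.5 x IQR outlier rule.
3. **Peptide construction** (`build_template_library`, `thread_sequence`,
   `place_side_chains`, `build_peptide`): templates are keyed by the P1
   residue; the highest-resolution example per key is kept (ties broken by
   id order) with side chains stripped to the backbone at positions 2-9.
   P1 residues without a template map to the closest observed key by
   heavy-atom count and side-chain volume (`default_unseen_map`:
   H->F, W->Y, D->N, E->M, Q->M, P->A, C->S; user-overridable). Side
   chains are rebuilt with idealized internal geometry and a
   backbone-independent rotamer library.
4. **Docking** (`initial_pose`, `rigid_refine`, `flexible_refine`): the
   12 anchor backbone atoms (P1/P2/P9 x N, CA, C, O) are superimposed
   onto the consensus anchor; a greedy rigid search then maximises
   hydrogen-bond matching and soft contact quality under a hard
   displacement cap; finally the peptide and the groove residues are
   minimized with the rest of the receptor fixed.
5. **Scoring** (`binding_dg`): single-geometry decomposition
   Delta G = G(complex) - G(receptor) - G(peptide), all three states
   evaluated at the complex geometry. No entropy term.
6. **Classification and screening** (`fit_threshold`, `classify`,
   `roc_auc`, `build_substitution_models`, `substitution_screen`).

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `w_rot` | 3.0 | kcal/mol | weight of the -ln(prior) rotamer term |
| soft vdW cap | +10 | kcal/mol | per-pair cap of the shifted LJ packing term |
| H-bond well | -1, 2.6-3.4, >120 | kcal/mol, A, deg | geometric donor-acceptor criterion |
| `max_disp` | 0.5 | A | cumulative per-atom rigid-refinement cap |
| `trans_step`, `rot_step` | 0.1, 1 | A, deg | greedy rigid search steps |
| rigid score weights | 1.0 / 0.2 | - | H-bond count vs capped soft-LJ |
| `e_in`, `e_out` | 1, 78.5 | - | interior / solvent dielectric |
| `gamma` | 0.00542 | kcal/mol/A^2 | nonpolar surface coefficient |
| `b` | 0 | kcal/mol | nonpolar offset (see below) |
| `bond_k`, `angle_k` | 300, 40 | kcal/mol/A^2, kcal/mol/rad^2 | harmonic bonded terms |
| `restraint_k` | 1 (2 in peptide building) | kcal/mol/A^2 | positional tether in minimization |
| probe radius | 1.4 | A | SASA probe |
| clash fallback | 2.4 | A | substitution-model rotamer fallback |
| pose failure | 1.5 | A | irreconcilable-clash criterion |
| IC50 cutoff | 500 | nM | binder definition (boundary inclusive) |

# The energy model

The molecular-mechanics terms use a minimal united-heavy-atom parameter
set shipped as TSV tables: per-type Lennard-Jones wells and radii, HCT
generalized-Born radii and screening factors, and per-atom partial
charges that sum to each residue's formal charge. Because hydrogens are
implicit, the backbone nitrogen carries the positive end of the amide
dipole (+0.25 e) and the carbonyl oxygen the negative end (-0.80 e), so
that donor-acceptor pairs attract electrostatically; hydroxyl oxygens
remain mildly negative and act as acceptors. This is a deliberate,
documented simplification: hydrogen bonds are represented by a geometric
well in the docking score and by heavy-atom electrostatics in the energy,
never by explicit protons.

Polar solvation follows the generalized Born form
$$\Delta G_{pol} = -\tfrac12\, C\,(1/\epsilon_{in} - 1/\epsilon_{out})
  \sum_{ij} \frac{q_i q_j}{f_{GB}},\qquad
  f_{GB} = \sqrt{r_{ij}^2 + R_i R_j e^{-r_{ij}^2/(4 R_i R_j)}}$$
with C = 332.06 kcal A/mol/e^2. Effective radii come from pairwise
descreening: each neighbour removes the closed-form integral of the
Coulomb-field kernel over its scaled sphere from the Born integral, so an
isolated atom's effective radius equals its intrinsic radius; no radius
offset is applied and the inverse radius is floored at 1e-3 1/A to keep
heavily buried atoms finite. The nonpolar term is gamma x SASA + b with a
deterministic 960-point Fibonacci-sphere Shrake-Rupley estimator.

**The offset b defaults to zero.** With a per-state constant b, the
single-geometry binding free energy of an infinitely separated pair would
converge to -b rather than 0. Since b cancels identically in
delta-delta-G (the screen's operative quantity), the package sets b = 0
and keeps it available as a configuration knob for users who want
absolute G values on a different convention.

The `torsion` field of the energy decomposition is reported as 0:
torsional preferences enter through the -w_rot ln(p) rotamer prior during
packing rather than through a cosine series, and the decomposition
contract (total = sum of terms) is preserved.

# Numerical choices

* **Minimization.** Short conjugate-gradient (`stats::optim`, method
  "CG") over the Cartesian coordinates of the mobile atoms, with analytic
  gradients for the softened Lennard-Jones (linearized below 0.7 r_min),
  softened Coulomb (linearized below 0.8 A), harmonic bond and harmonic
  angle terms. There is no torsional potential; a weak positional
  restraint (1 kcal/mol/A^2; 2 during template-based peptide building)
  tames the torsional freedom this leaves. Nonbonded pairs farther than
  14 A at the start are dropped from the minimization working list (they
  stay negligible under the restraint); the *scoring* path (`mm_energy`,
  `binding_dg`) uses no cutoff at all. Because the restraint is
  re-centred on each call, re-minimizing an already relaxed complex
  releases a small residual (bounded in the tests at 10 kcal/mol,
  about 2% of the initial relaxation) and moves the peptide backbone by
  less than 0.5 A; this is the honest resolution limit of the optimizer
  budget, not a hidden stochastic effect - the pipeline is bitwise
  deterministic at `md_steps = 0`.
* **Displacement cap.** The 0.5 A rigid-refinement cap is enforced
  cumulatively from the initial anchored pose (the alternative per-step
  reading would allow unbounded drift and defeat the anchoring); the
  greedy search only ever accepts score-improving moves, so the score
  trace is non-decreasing by construction.
* **`md_steps`.** When positive, seeded Gaussian coordinate perturbations
  (sd 0.05 A) of the mobile atoms alternate with re-minimization and the
  best objective value is kept - an overdamped stochastic refinement
  stage. The default is 0, keeping the desk-scale pipeline fully
  deterministic.
* **Threshold rule.** "Midpoint between the two KDE modes" is the default
  reading (`rule = "mode-midpoint"`, Silverman bandwidth via
  `stats::density`); the alternative reading, the midpoint of the class
  means, is exposed as `rule = "mean-midpoint"`. Classification is strict:
  a score exactly at the cutoff is a non-binder.
* **Loss-of-binding rule.** A peptide is lost for a variant when its
  variant binding free energy is at or above the fitted cutoff (absolute
  rule); a margin-based delta-delta-G rule can be built from the returned
  per-pair table.
* **Ties.** Template selection ties on resolution break by id order;
  altloc ties break by label order; only the first MODEL of multi-model
  files is read.

# What the synthetic fixtures emulate - and what they do not

`generate_groove` builds an idealized receptor: two poly-alanine helical
walls over staggered beta-strand floor segments, numbered so that all 37
groove residues resolve, with a standalone serine (position 171, A
pocket) whose OG lies on the P1 amide direction and a standalone lysine
(position 116, F pocket) whose NZ donates to the P9 carbonyl, about 32 A
apart. `generate_bound_peptide` threads any 9-mer onto a gently arced
extended backbone whose termini sit in those pockets;
`generate_complex` relaxes the assembly so that, like a crystal
structure, it sits near a local minimum of the package's own energy
model. `generate_ensemble` adds i.i.d. Gaussian coordinate noise plus a
random rigid displacement per copy (removed again by superposition), and
`generate_score_dataset` draws labelled Gaussian score pools.

Fixture conditions were chosen once: pocket separation ~32 A (the
physical length scale of the groove), hydrogen-bond target distance
2.9 A (mid-well), ensemble noise sigma = 0.3 A (the order of the
backbone variability seen across real groove structures), ensemble size
10, and screens over 3 peptides per variant. The problem sizes keep the
whole test suite and the acceptance script at desk scale.

The fixtures deliberately do **not** reproduce the real A*02:01 fold:
there is no beta-2-microglobulin, no connecting loops, no waters, no
sequence-dependent backbone geometry, and the rotamer library is a small
modal table rather than a backbone-dependent statistical library.
Passing the fixture-based tests therefore demonstrates algorithmic
correctness (optimal superposition, conservation bookkeeping, template
threading, cap enforcement, energy closed forms, threshold recovery,
screen bookkeeping and determinism), not predictive accuracy on real
crystallographic or immunological data. Benchmarks against real
structures require downloading the published complex set and re-running
`redock_benchmark` on it; published summary statistics additionally
depend on force-field and packing details that this reimplementation
does not claim to match numerically.

# Known limitations

* United heavy atoms cannot represent bifurcated or hydroxyl-donor
  hydrogen bonds in the energy term; such interactions appear only in the
  geometric docking score.
* The torsion-free bonded model lets terminal and long side-chain atoms
  wander slightly between minimization rounds (sub-Angstrom, bounded in
  the tests).
* Single-geometry MM-GBSA omits conformational entropy and relaxation of
  the separated partners.
* The greedy rigid search is deterministic but local; it inherits the
  quality of the anchored initial pose by design.
* Peptides other than 9-mers, modified residues and receptor backbone
  flexibility outside the groove set are out of scope.
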