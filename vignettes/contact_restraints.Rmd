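---
title: "Contact restraints, ensemble convergence and model evaluation"
author: "evrestraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact restraints, ensemble convergence and model evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evrestraints)
```

## The problem

Coevolutionary analysis of deep sequence alignments yields ranked lists of
residue pairs likely to be in spatial contact in a protein's native fold.
Fed into a fragment-assembly sampler as distance restraints, such
predictions can carry *ab initio* structure prediction to near-native
accuracy — but only if three conditions are handled carefully:

1. The predictions contain false positives at an unknown rate, so the
   restraint potential must be unable to tear a model apart when a
   restraint is simply wrong.
2. The sampler's output is an ensemble, not a structure; whether the
   prediction is trustworthy at all must be decided from the ensemble's
   internal convergence, because in a blind setting there is no reference
   to compare against.
3. A second, refinement round can recycle what the first round learned —
   but only the converged part, and only together with additional contact
   information chosen so it cannot contradict the established core.

`evrestraints` implements these stages plus the evaluation battery used to
benchmark them. The sampler itself (Rosetta RASREC in our target setup) is
deliberately out of scope: the package prepares its inputs and analyses its
outputs, and everything is testable against synthetic fixtures with planted
ground truth.

## Restraint model

**Top-L selection.** Predicted contacts are ordered by confidence; pairs
closer than 5 residues in sequence are dropped (they are trivially satisfied
and carry no fold information) and the top L kept, where L is the sequence
length rounded down to the nearest multiple of 10. L is computed from the
*input sequence* length, not from the residues resolved in any particular
model or reference structure — the two can differ, and the selection rule is
defined before any structure exists. Ties in confidence are broken by
ascending (i, j); the choice is arbitrary but must be fixed for bit-level
reproducibility across platforms.

**Sigmoidal potential (first round).** Each selected contact becomes a
Cβ–Cβ restraint (Cα for glycine, which has no Cβ) scored with

$$f_\mathrm{sig}(x) = \frac{1}{1 + e^{-m(x - x_0)}} - 0.5,
\qquad x_0 = 8\ \mathrm{Å},\ m = 1\ \mathrm{Å}^{-1}.$$

Satisfied restraints (distance ≤ 8 Å, the conventional Cβ contact cutoff)
contribute a negative bonus approaching −0.5; violated ones approach +0.5
with an exponentially vanishing derivative, which is the operational meaning
of "false positives are ignored": beyond the transition region the restraint
exerts no force. In the constraint file the potential is emitted as a
sigmoid function plus a constant −0.5 offset, matching how sum-of-function
constraints are expressed in the target engine's dialect.

**Bounded potential (refinement round).** Distances that the first-round
ensemble has pinned down are re-imposed strictly with a flat-bottom
potential: zero on $[lb, ub]$, quadratic $((x - b)/sd)^2$ just outside, and
linear with slope $1/sd$ beyond $ub + 0.5\,sd$, continuous at every branch
point. Converged Cα pairs (ensemble mean distance $\bar d \le 8$ Å,
population SD < 1 Å over the 30 lowest-energy models) get
$lb = \bar d - 1$, $ub = \bar d + 1$, $sd = 1$. Contacts rescued from lower
ranks get deliberately wide bounds, 1.5–8 Å, so unconverged regions can
still relax into energetically favourable conformations.

**Ambiguous restraints.** The rescued set is additionally combined into
random pairs scored by the better-satisfied member, so a single wrong
restraint in a pair costs nothing as long as its partner can be satisfied.
Group size 2 and the wide bounded potential for members are our reading of
"random pairs" — the pairing semantics follow ambiguous-constraint handling
in NMR-style structure calculation, where the group minimum is standard. A
fresh pairing is drawn per trajectory; all draws derive from one seed. The
partition algorithm (random permutation cut into consecutive pairs) is
provably uniform over perfect matchings, which the test suite verifies by a
chi-square test against the 15 matchings of 6 elements.

## Convergence analysis

"Coordinate variability" of a residue is operationalised as the RMSF of its
Cα about the ensemble mean after iterative all-Cα Kabsch superposition: each
model is superposed onto the current mean, the mean is recomputed, and the
loop runs to a fixed point (mean shift < 10⁻³ Å; typically 2–3 iterations).
RMSF about the converged mean is the standard estimator for this quantity
and, unlike pairwise-RMSD variants, gives a per-residue number directly
comparable to the 2 Å threshold. A residue converges strictly below 2 Å; a
prediction is *unsuccessful* when fewer than half the residues converge, and
a *refinement* round is warranted when fewer than 90% do. All thresholds are
strict inequalities, read directly off their verbal definitions ("less
than 2 Å", "less than half", "< 90%"); the boundary cases are unit-tested so
the choice is frozen.

For pair statistics the population (not sample) SD is used; at n = 30 the
difference is irrelevant scientifically but must be fixed for exact
reproducibility, and the population form matches the brute-force oracle in
the tests. "A contact affects an unconverged region" is read as: the pair's
own ensemble distance SD exceeds 1 Å — supported by the protocol's
parenthetical definition of unconverged pairs, and cleaner to test than any
residue-window interpretation.

Whether the refinement round also re-uses the original top-L sigmoidal
restraints is left to the caller: the derivation functions return the two
new restraint classes separately, and the pipeline driver writes them as
separate files so either combination can be fed to the engine. Every
qualifying rescued contact is admitted (no cap); the selection is already
limited by the SD > 1 Å and mean ≤ 8 Å filters.

## Evaluation battery

**PPV.** Fraction of selected contacts whose reference Cβ–Cβ (Gly: Cα)
distance is ≤ 8 Å. Contacts involving residues absent from the reference
are excluded from the denominator and counted in the report attributes.

**RMSD / RMSD over secondary structure.** Cα RMSD after optimal (Kabsch)
superposition over all residues present in the reference — never trimmed,
so every model is judged on identical residues — and the same quantity
restricted to helix/strand residues of an externally supplied assignment
(we do not re-implement Stride/DSSP; the assignment is an input).

**TM-score.** $\frac{1}{L_{ref}} \max \sum_i (1 + (d_i/d_0)^2)^{-1}$ with
$d_0 = 1.24\,(L_{ref}-15)^{1/3} - 1.8$ (floored at 0.5 Å for very short
chains). Model and reference share a residue numbering, so no alignment
search is needed — only superposition optimisation, done with the standard
fragment-seeding heuristic: seeds of length L, L/2, L/4 slide over the
chain, each seed's superposition is refined by iterating "keep residues
within a distance cutoff, refit on them" to a fixed point, and the best
score over all fits is kept. The full-length Kabsch fit is always among the
seeds, making the plain-superposition score a guaranteed lower bound; the
test suite additionally checks dominance over 10⁴ random rigid placements.

**SASA and rotamer recovery.** Side-chain solvent accessibility is computed
by Shrake–Rupley sphere sampling with a deterministic Fibonacci lattice
(960 points per atom by default; the lattice avoids RNG dependence and
converges to within 2 Å² of a 5000-point reference on our fixtures), probe
1.4 Å, van der Waals radii C 1.70 / N 1.55 / O 1.52 / S 1.80 Å. A side
chain is *buried* below 40 Å² in the reference (Ala/Gly excluded), and
*converged* when the circular SD of its χ1 over the 10 lowest-energy models
is below 10°. χ1 wells are the canonical staggered states g+/t/g− at
+60°/180°/−60°, assigned by nearest centre under circular distance; the
model-side well is taken from the circular-mean χ1 across the ensemble
(at SD < 10° every member is in the same well, so any member would give the
same answer). The all-χ fraction requires every defined side-chain χ to
match; both published denominators (converged-and-buried, and buried) are
reported because the source material is ambiguous between them.

**Restraint confusion.** Restraints are partitioned by native satisfaction
(≤ 8 Å in the reference) and the models' satisfaction rates are reported
for each class — the fraction of natively-satisfied restraints the models
keep, and the fraction of natively-violated ones they correctly reject.

## Synthetic fixtures: what they emulate, and what they do not

`make_structure` builds idealised folds — a single α-helix (exact 3.8 Å Cα
spacing, 1.5 Å rise, 100°/turn), an antiparallel two-helix bundle with an
8.5 Å axis separation (guaranteeing genuine long-range Cβ contacts), and a
paired β-sheet — with pseudo backbone N/C atoms, tetrahedral Cβ, and a
single γ heavy atom placed at a planted χ1 well that is recorded as ground
truth. `make_ensemble` adds isotropic per-atom Gaussian noise (0.5 Å in
"converged" regions, 5 Å in planted diverged regions — values chosen so the
two populations straddle the 2 Å threshold with a comfortable margin on
either side), a per-model noise factor, a random rigid transform per model,
and synthetic energies linear in the noise factor with small jitter, so
energy ranking is informative but not degenerate. `make_contact_map`
samples exactly round(ppv·n) true pairs and fills the rest with
false pairs (> 8 Å), scores drawn so true contacts rank higher on average.
Every generator is a pure function of its spec and seed and leaves the
caller's RNG stream untouched.

These fixtures exercise the machinery, not the physics: noise is isotropic
and residue-independent, energies are a one-factor caricature of a score
function, pseudo side chains stop at the γ atom, and the folds are exactly
ideal. Passing tests therefore demonstrate correctness of the selection,
scoring, convergence, derivation and evaluation logic under controlled
truth — not that the protocol folds real proteins; that evidence requires
the external sampler and is outside this package. One practical consequence
appears in the worked example: at folding-round backbone noise (0.5 Å per
atom) no side chain passes the 10° χ1 convergence cut, because a 0.5 Å
displacement on a 1.5 Å bond swings dihedrals by tens of degrees. χ1
recovery is therefore measured on low-noise ensembles (0.05–0.15 Å)
emulating refined, full-atom-quality models — which is also the regime the
original analysis applied it to.

## Numerical choices

- Kabsch superposition uses SVD with the determinant correction, so mirror
  images are never "fitted" by an improper rotation.
- The iterative-mean superposition tolerance is 10⁻³ Å on the maximum
  per-residue mean shift; tightening it further changes variabilities by
  less than the coordinate precision of a PDB file (10⁻³ Å).
- Restraint files freeze a canonical number format (up to 15 significant
  digits, no scientific notation), making write → read → write
  byte-identical; golden-file tests pin the grammar.
- Circular mean and SD use the resultant-vector formulas
  ($\sqrt{-2\ln\bar R}$ for the SD), so χ1 values straddling ±180° are
  handled correctly.
- Duplicate contact records keep the maximum score (all-by-all tables may
  list both orientations); residue indices are 1-based and sequential over
  the input sequence, with the PDB reader mapping author numbering onto
  that frame and rejecting insertion codes outright rather than guessing.
- Degenerate inputs fail loudly: chains shorter than 10 residues (L would
  be 0), ensembles of fewer than 2 models, selections with fewer than 3
  atoms for superposition, missing atoms in restraint evaluation.

## Problem sizes

The test suite and the acceptance script run on 12–60-residue fixtures with
ensembles of up to 30 models, and the oracle-equivalence batteries use on
the order of a hundred random instances; at these sizes the whole pipeline
(simulate → restraints → convergence → refinement → evaluation) completes
in a few seconds, which keeps the full loop practical to run on every
change. The implementation itself is size-agnostic: selection and pair
statistics are vectorised and the 247-residue benchmark-scale selection
cases in the acceptance script run in well under a second.

## Known limitations

- The PDB reader handles single-chain, single-model coordinate files with
  standard atom naming; insertion codes are rejected, altloc A is kept.
- SASA is O(atoms × neighbours × points) in plain R — fine for fixtures
  and single structures, slow for large batches.
- The TM-score heuristic is a faithful re-implementation of the published
  search strategy, not the reference binary; agreement is expected to ~0.01
  and the score is guaranteed to be a lower bound of the true maximum only
  through the seeds it tries (the tests bound it from below by Kabsch and
  random-superposition baselines).
- No contact inference, no folding, no fragment picking, no
  secondary-structure assignment: predictions, models, energies and SSE
  strings are inputs.
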