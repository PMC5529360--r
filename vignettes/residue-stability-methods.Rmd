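---
title: "Residue stability from MD trajectories and the T790M cohort analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue stability from MD trajectories and the T790M cohort analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resiflex)
```

## The model

resiflex quantifies, per residue, how much a protein–inhibitor complex
fluctuates around its own time-averaged conformation over an MD
trajectory, and relates that flexibility to a focal residue — EGFR T790,
the position whose mutation confers acquired TKI resistance.

The statistic is deliberately simple. After discarding hydrogens (too
small and light to carry structural signal) the pipeline proceeds in a
fixed order:

1. **Best-fit superposition.** Every frame is rigid-body aligned
   (rotation + translation, unweighted least squares via the Kabsch SVD
   solution with the determinant correction for the reflection branch)
   to the *original* structure, fitting on all protein heavy atoms.
   Ligand atoms are carried along but never drive the fit.
2. **Average-structure reference.** The per-atom mean of the aligned
   frames. It is more representative of the whole trajectory than any
   single frame; it is used as-is — it need not be chemically
   plausible, it is a statistical reference only, so it is never re-fit
   or idealised.
3. **Per-residue displacement.** For residue $i$ in frame $j$,
   `residue_dist`$_{ij}$ is the mean over the residue's $K_i$ heavy
   atoms of the Euclidean distance to the matching reference atom
   (atoms paired by id). The **stability mean** is the average of
   `residue_dist`$_{ij}$ over frames; the **stability std** is its
   sample standard deviation (denominator $J-1$, undefined at $J=1$).
   Both are in Å; *higher = less stable*.
4. **Focal ordering.** Residue centers are unweighted heavy-atom
   centroids per frame; the distance of residue $i$ to the focal
   residue is the frame-average of the center–center distance. Ranking
   ascending puts the focal residue at rank 0 (distance exactly 0);
   ties break by ascending residue number so outputs are deterministic.
5. **Trimming.** Reporting is restricted to residues 716–976 (first to
   last helix of the EGFR kinase domain) because the modelled chain
   termini fluctuate arbitrarily. Trimming happens at the reporting
   stage only — the fit and the average structure always use the whole
   structure.
6. **Cumulative average.** At rank position $k$ the curve holds the
   running mean of the chosen statistic over the $k{+}1$ residues
   closest to the focal residue. Its first value is the focal residue's
   own stability; its last equals the plain mean over all profiled
   residues (an exact identity used as a test invariant).
   `compare_mutants()` orders complexes by the mean of the first
   `k_window` curve values, descending.

Two readings of the pipeline order were possible from its verbal
description ("best-fit to the original structure", "average structure as
the reference frame"); the order fixed above — align to the original,
then average, then measure against the average — is the only one
consistent with both phrases and is frozen as the default.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| fit mask | all protein heavy atoms | the superposition is *not* narrowed to backbone or CA, and is unweighted (no masses appear in the statistic) |
| focal residue | 790 | EGFR T790 |
| trim range | 716–976 | helix-bounded reporting span |
| curve statistic | mean | std curves are always emitted too; which component feeds the comparison is configurable because the source analysis plots both and does not name one |
| `k_window` | 50 | "around the focal residue" made explicit; the first few dozen rank positions. The comparison reports the window it used |

Profiles are keyed by author residue number, never positional index, so
deletion mutants (e.g. delE746_A750 lacking 746–750) naturally omit
those residues; cross-mutant comparison joins on *rank position*, which
is what a shared cumulative-curve axis implies.

## The synthetic trajectory generator

Production MD data for the original complexes are not deposited, so the
generator emulates the statistical structure the pipeline consumes, not
the physics: no force field, solvent, thermostat, or bonded structure.
A recipe fixes a heavy-atom topology (residue centroids on a coarse 3D
curve so focal-distance ordering is nontrivial; default numbering from
697 with optional deletion gaps), a per-residue Gaussian fluctuation
amplitude σ per coordinate, optional per-frame rigid-body jitter
(rotation axis uniform on the sphere, angle uniform up to a maximum,
translation uniform in a cube — exactly the degrees of freedom the
alignment must remove), and a frame count (default 5000 at 2 ps,
mirroring the emulated 10 ns runs; validation runs use smaller sizes
stated below). Everything is deterministic given the recipe seed.

Frames are i.i.d. by default: the stability statistic is order-agnostic,
so temporal autocorrelation cannot change its expectation. An AR(1) mode
with matched marginal variance exists to demonstrate precisely that
invariance (a test compares its profile to the i.i.d. one within
Monte-Carlo error). What the generator does *not* emulate — anisotropic
and correlated atomic motion, conformational substates, ligand-coupled
dynamics — bounds what passing tests prove about real trajectories:
they validate the estimator, not MD itself.

With isotropic Gaussian noise the per-atom displacement is chi-distributed
(3 d.o.f.), giving closed forms used throughout the tests:
stability_mean → $2\sqrt{2/\pi}\,\sigma \approx 0.798\,\sigma$ and
stability_std → $\sigma\sqrt{3-8/\pi}/\sqrt{K}$. Measured values run
about 1% below the closed form because the reference is *estimated* from
the same frames (the average structure absorbs part of each frame's
noise) and the per-frame fit absorbs six more degrees of freedom; the
2–5% test tolerances account for this known, small bias. For the same
reason a best-fit alignment couples residues: when a few residues are
much hotter than the rest, the fit distributes a little of their motion
onto cold residues. The generator-calibration tests that isolate the
linear-in-σ law therefore profile unjittered trajectories directly
(they are already aligned by construction).

Sizes used by the validation suite, chosen to keep the statistics tight
at interactive runtimes: chi-limit check at 12 residues × 8 atoms ×
5000 frames; σ-ordering recovery at 50 residues × 2000 frames (Spearman
≥ 0.95); the three-mutant experiment at 60 residues × 4 atoms × 150
frames × 100 replicates, with near-focal σ of 0.55/0.45/0.35 Å against
a 0.25 Å background and modest rigid jitter (15°, 3 Å).

## The cohort analysis

The clinical side works from a reconstructed per-patient table
(`t790m_cohort()`): the real registry was never published, so a
68-patient table is synthesised *in code* to reproduce every published
summary count — the mutation-by-TKI outcome grid over the 65 evaluable
patients, the bone-metastasis 2×2 (21/34 vs 6/34), the
bone-plus-delE746_A750 subgroup (15/18), single-site patients (14/15
negative), and the baseline margins (sex, smoking, site prevalences,
site counts, treatment lines, ages). Cells not pinned by a published
count are an arbitrary deterministic fill and carry no information; in
particular, attribute rankings computed on this fixture reflect the fill
as much as the data and are *not* expected to reproduce the published
ranking — ranking validity is established on synthetic cohorts with
planted effects instead. The three patients with exon 19 LRE deletions
other than delE746_A750 are the ones excluded from the 65-patient
mutation-by-TKI grid (they acquired no T790M), which is the only reading
that makes the published margins add up.

Proportions are reported both exactly and rounded half-up to one decimal
(the printing convention of the source tables; note 6/34 = 17.647%
rounds to 17.6 even though 17.7 was printed — treated as a printing
artefact). The two-sided Fisher's exact test is the hypergeometric
point-probability rule — the sum of the probabilities of all tables, at
the observed margins, no more probable than the observed one, with the
customary 1e-7 relative slack against floating-point ties — matching
standard exact-test implementations, which serve as an independent
oracle in the tests, never as the implementation.

### Attribute ranking

Each of the 24 categorical attributes is scored individually against the
binary outcome and sorted (Ranker-style search). Evaluators:

* **chi2** — Pearson χ² statistic of the attribute × outcome table
  (degenerate single-level tables score 0, never error);
* **info_gain** — $H(\text{outcome}) - H(\text{outcome}\mid a)$ in bits;
* **symmetrical_uncertainty** — $2\,IG/(H(a)+H(\text{outcome}))$,
  normalised to $[0,1]$;
* **correlation** — mean absolute Pearson correlation between the
  attribute's indicator (one-hot) encodings and the outcome indicator;
  a binary attribute reduces to the single $|r|$;
* **relieff** — Kononenko ReliefF, $k = 10$ neighbours per class under
  Hamming distance on the categorical encodings, prior-weighted miss
  contributions. All instances are probed up to $n = 1000$; larger
  cohorts probe a seeded sample of 1000, keeping the evaluator
  deterministic given its seed and fast at cohort scale;
* **filtered** — information gain applied after the package's cohort
  validation filter, the package's rendition of a filtered
  information-based evaluator.

`number_sites_met` is treated as a five-level categorical attribute.
Ties in score break by attribute name.

The cohort generator draws attributes independently from recipe
marginals, except where dependence is structural: the six age-threshold
booleans derive from one latent age draw (guaranteeing monotonicity),
the site count is the number of drawn sites (floored at one site, capped
at the five-level encoding by shedding the rarest site in the rare
six-site draw), and usage flags follow line counts. The outcome is
logistic: baseline odds times the recipe's per-attribute odds
multipliers.

## Numerical and design notes

* Coordinates are always Å; no unit options. PDB I/O round-trips at the
  format's 3-decimal precision; the package's JSON+CSV fixture format
  stores full `%.17g` doubles and round-trips bit-exactly (the basis of
  golden tests).
* Multi-chain PDB input is rejected: the analysis targets a single
  kinase domain, and collapsing residue identity to the author residue
  number is only unambiguous for one chain. Altloc conformers resolve
  to highest occupancy, ties to first encountered. HETATM atoms (the
  TKI ligand) are kept in a separate partition: they are read and
  transformed but excluded from residue profiles and from the fit mask,
  since per-residue stability is defined over protein residues; whether
  the original fit mask included the ligand is unknowable from the
  description, and excluding it is this package's documented choice.
* Kabsch degeneracy: fewer than three mask atoms or a collinear mask is
  an error (the rotation would be underdetermined); the reflection case
  is handled by negating the smallest singular axis.
* Equality tolerances: rigid-motion removal and alignment idempotence
  at 1e-8–1e-10 Å; pipeline-vs-naive-oracle equivalence at 1e-10;
  rigid-body invariance of the full profile at 1e-6 Å (the fit is
  iterative only in the sense of per-frame independence, so the bound
  is loose against accumulated rounding).
* The comparison's `k_window` and the trim bounds are reported in every
  output; `run_stability_pipeline()` and `run_cohort_pipeline()` stamp
  a config echo, config checksum and package version into
  `run_metadata.json`, and identical inputs yield byte-identical CSVs.

## Limitations

* The stability statistic is a displacement summary; it estimates
  neither free energies nor binding affinities, and no steric or
  ATP-affinity mechanism is computed here.
* Synthetic-data validation bounds the estimator's correctness, not the
  realism of MD; conclusions about real mutant–TKI complexes require
  real trajectories supplied as multi-model PDB or fixture input.
* The reconstructed cohort supports exactly the published summary
  statistics and nothing finer; per-patient inferences from its
  unconstrained cells are meaningless by construction.
* Fisher's exact test is implemented for 2×2 tables only (r×c tables
  are cross-tabulated but not tested exactly).
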