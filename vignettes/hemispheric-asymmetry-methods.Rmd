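---
title: "Hemispheric white-matter network asymmetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemispheric white-matter network asymmetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemiconn)
```

## The analysis in one paragraph

hemiconn quantifies *lateralization* of structural brain connectivity: for
each subject it builds one white-matter network per hemisphere over
homologous node sets, summarizes each network by weighted graph efficiency,
and expresses left/right differences as the asymmetry index
$AI = (M_R - M_L)/(M_R + M_L)$, positive for rightward asymmetry. Group
differences in AI (e.g. Alzheimer's disease vs. mild cognitive impairment
vs. controls) and AI-cognition associations are then tested with
covariate-adjusted linear models. Because homologous correspondence between
hemispheres is what makes AI meaningful, the node template is built to be
*exactly* mirror-symmetric, and the whole pipeline preserves that symmetry:
on perfectly symmetric input the AI is exactly zero, in floating point, end
to end. That invariant is the backbone of the test suite.

## Node template: symmetric random parcellation

A binary cortical mask is symmetrized by flipping along world x and
combining with the original. The combine rule for the "average" of mask and
flipped mask is not uniquely determined by a binarized average, so both
readings are implemented: `union` (default; a voxel is kept if present on
either side, preserving coverage) and `intersection` (stricter). The grid
must be flip-alignable — x-axis aligned with the grid and voxel columns
centered on the midplane — because the left template is produced by an
*index* flip; anything else would require resampling, which the package
deliberately refuses to do silently.

The right hemisphere (world $x > 0$; $x = 0$ columns are excluded to keep
the hemisphere contract explicit) is partitioned into `n_rois` ROIs
(default 512) by seeded region growing: seed voxels drawn uniformly without
replacement, then single-voxel accretion under 6-connectivity, always
growing the currently smallest ROI, ties broken by lowest linear voxel
index. This yields near-equal ROI sizes (max/min voxel count ≤ 2 in
practice; asserted as a construction target, not a hard guarantee) and is
fully deterministic given the seed. Voxels unreachable from any seed are
assigned to the nearest ROI centroid so that the ROIs always tile the mask;
on fragmented masks this can break ROI connectedness, which is the price of
guaranteed tiling and is logged rather than hidden. The left hemisphere is
the exact x-flip of the right, giving one-to-one homologous node pairs.

## Tractography: a FACT-style reference tracker

Edges come from deterministic streamline tracking on the diffusion-tensor
field with the two classical stopping rules: terminate when the next voxel
has FA < 0.2 or the turn between consecutive path segments exceeds 45°.
The published descriptions of FACT leave several details open; this tracker
fixes them explicitly so every contract is testable:

* principal eigenvector looked up at the *nearest voxel* (no interpolation),
  matching the voxel-wise character of FACT;
* fixed step of half the smallest voxel dimension;
* bidirectional propagation from each seed, eigenvector sign chosen to
  minimize turning, the two half-tracks concatenated;
* angle measured between successive displacement vectors, in degrees;
  the termination point is the last accepted point;
* one seed per voxel with FA ≥ 0.2 (whole-brain seeding) by default;
* a `max_len` guard of 300 mm against cycles — a numerical safety net, not
  a biological parameter.

It is a documented reference implementation of the FACT family, not a
bit-level clone of any particular pipeline tool. Raising `fa_stop` or
lowering `angle_stop` can only truncate streamlines (a prefix property),
and tracking an x-flipped tensor field yields the x-flip of every
streamline; both are asserted as properties in the tests.

## Edge weights

A streamline contributes to the edge between the two ROIs containing its
endpoints, provided both lie in the same hemisphere (the networks are
intra-hemispheric by construction); self-loops and unlabelled endpoints are
dropped and counted. The edge weight is the *mean FA of the connected
fibers*. Two estimators are defensible — the pooled mean over all points of
all connecting streamlines, or the mean of per-fiber means — and the pooled
mean is the default because it has a simple brute-force oracle (accumulate
every FA sample) and weights long fibers in proportion to the evidence they
carry. FA is sampled nearest-voxel at streamline points, consistent with
the non-interpolating tracker.

The phrase "an edge if more than one fiber connects" admits a strict
(≥ 2 fibers) and an inclusive (≥ 1) reading. The default is
`edge_min_fibers = 1`; the strict reading is a flag. On the sparse
single-subject phantoms used in testing the inclusive default keeps the
networks non-degenerate; on dense real cohorts the choice matters little,
but it is recorded in every result bundle.

## Efficiency metrics

With weights $w_{ij} \in (0, 1]$, edge lengths are $1/w_{ij}$ — the
weight-to-length conversion is the single most consequential unstated
convention in weighted-efficiency analysis, so it is an explicit, recorded
parameter (`"inverse"` default, `-log(w)` alternative) rather than a buried
constant. Shortest path lengths $L_{ij}$ use Dijkstra's algorithm;
disconnected pairs are infinite and contribute zero to efficiency sums
(the standard Latora–Marchiori contract). Then

* global efficiency $E_{glob} = \frac{1}{N(N-1)} \sum_{i \ne j} 1/L_{ij}$;
* nodal efficiency $E_{nodal}(i) = \frac{1}{N-1} \sum_{j \ne i} 1/L_{ij}$,
  whose mean over nodes equals $E_{glob}$ identically (asserted to 1e-12);
* local efficiency $E_{loc} = \frac{1}{N} \sum_i E_{glob}(G_i)$, where
  $G_i$ is the subgraph of $i$'s neighbors (excluding $i$) with their
  original interconnecting weights; nodes with fewer than two neighbors
  contribute zero because the $N(N-1)$ normalization requires two nodes.

Weights are used as-is (FA is already in $(0,1]$); no re-normalization is
applied before the length conversion. All three measures are validated
against exhaustive brute-force path enumeration on complete grids of small
graphs and on random graphs.

The AI of a measure is undefined when $M_R + M_L = 0$ and is returned as
`NA` with a warning, never silently coerced to zero. This case is real:
sparse tube-like phantoms produce chain-topology networks whose local
efficiency is zero in *both* hemispheres.

## The statistical battery

All tests are two-sided at α = 0.05 unless stated.

**Within-group hemisphere test.** The repeated-measures GLM with hemisphere
as a two-level within-subject factor is fitted as its exact equivalent: the
per-subject difference $d = right - left$ regressed on mean-centered
covariates (age, sex, hemispheric-ICV difference, TR, TE), testing the
intercept. For a two-level factor this paired-difference regression
reproduces the repeated-measures F exactly ($t^2 = F$, asserted to 1e-8
against an independent long-form fit with subject fixed effects), which is
why no general mixed-model machinery is needed. Sex is coded male = 1,
female = 0; centering makes the intercept the adjusted mean asymmetry.
Degenerate input (a constant difference vector) is decided exactly
($t = 0, p = 1$ for identical hemispheres) rather than producing 0/0.

**Nodal screening.** The within-group nodal tests are corrected per group by
Benjamini–Hochberg FDR at q = 0.05 with m = the full node count per group
(pooling across groups is the alternative reading; per-group was chosen and
is recorded). Downstream group comparisons of nodal AI are confined to the
union of nodes significant in at least one group.

**Group comparisons.** For each AI measure the sex x group interaction is
screened first; if significant the group analysis is stratified by sex
(dropping sex from the covariates), otherwise the interaction term is
dropped and groups are compared pooled, adjusting for age, sex, whole-brain
ICV, hemispheric-ICV difference, TR and TE. Post hoc pairwise contrasts
(AD−NC, AD−MCI, MCI−NC) are covariate-adjusted t-tests with Bonferroni
correction for the three comparisons. Nodal group effects are reported at
uncorrected p < 0.05 with BH-adjusted values additionally stored — both
conventions appear in practice, so both are emitted with the adjustment
recorded on every row.

**AI–score associations.** Memory scores (RAVLT TOTAL, TOT6, RECOG) are
regressed on each AI measure with the same covariates; nodal associations
are restricted to nodes with significant group effects and BH-corrected per
score. Missing scores are handled per-regression by complete cases, with
counts logged. A negative t means rightward asymmetry predicts lower
scores.

Type-I error of the paired test, the group F-test, and the association
regression is verified by 2000-replicate null simulations (rejection rate
within [0.04, 0.06]); the BH mask is checked against an independently coded
step-up oracle and its empirical FDR at m = 512 under the complete null.

## The synthetic cohort generator

The generator stands in for a real multi-site cohort and defines the
conditions under which the statistical claims are tested. Defaults follow
the study-cohort structure: group sizes 48 NC / 95 MCI / 25 AD; group-wise
age distributions (75.0 ± 6.0, 74.9 ± 7.4, 77.4 ± 8.4 years); sex as
Bernoulli with group-specific probability male (21/48, 57/95, 19/25 — the
AD group is strongly male-imbalanced, which is what makes the sex x group
screen worth simulating); whole-brain ICV ~ N(1.45e6, 1.3e5) mm³ split
near-evenly between hemispheres; and site-varying scanner timing
(TR ~ N(12500, 400) ms, TE ~ N(68, 3) ms).

Each subject's left network is drawn once (edge presence Bernoulli at
`density`, weights Gaussian around `base_weight_mean` = 0.45 like an FA
weight, clipped into (0, 1]; the clipping rate is reported). The right
network adds to the shared edges a group-level shift
(`global_asym_delta`), a per-subject random shift (`subject_asym_sd`), and
an extra shift on edges incident to a chosen node subset
(`nodal_asym_delta`). The additive-then-clip construction is the simplest
monotone link between the planted shift and the resulting AI. The
per-subject component exists because a group-constant shift alone gives
near-zero within-group AI variance, making AI–score regressions degenerate;
real cohorts show substantial within-group AI spread. With every shift
component zero, the hemispheres are bit-identical and all AIs are exactly
zero — the generator-level null invariant.

Scores are generated as
$score = \beta_0 + \beta_{AI} \cdot AI + \beta_{age}(age - 75) +
\beta_{sex} \cdot male + \varepsilon$, with the realized global-efficiency
AI as the coupling variable and negative $\beta_{AI}$ defaults, so that
rightward asymmetry predicts lower memory performance. Scores are not
truncated to the bounded RAVLT range; the linearity of the association
model is the property under test.

Reproducibility: the cohort seed is split into per-subject streams by one
`sample.int` draw, so any subject regenerates identically regardless of
cohort size.

**What the generator does not emulate.** No raw diffusion-weighted signal
or scanner noise model, no registration error, no spatially structured
covariance between edges, no topological constraints (real FA networks are
not Erdős–Rényi), and no floor/ceiling effects in the scores. Passing tests
therefore demonstrate the correctness and calibration of the *pipeline*,
not the effect sizes of any real population.

## Planted-effect calibration

Effect sizes for the recovery tests were chosen by Monte-Carlo calibration
and then frozen. With 200 subjects per group, 24-node networks at density
0.35, within-group AI spread from `subject_asym_sd = 0.012`, and an AD-only
global shift of 0.006 (MCI 0.002), the AD-vs-NC detection (group F plus
Bonferroni post hoc, rightward sign) has power 0.98 over 200 calibration
replicates; the acceptance test asserts power ≥ 0.9 over 60 replicates.
For the association direction, $\beta_{AI} = -120$ on the TOTAL score with
AI spread 0.02 and 40 subjects per group recovers a negative t in
effectively all replicates; the test asserts ≥ 95% over 100. The paper-like
cohort reports no effect sizes, so these deltas are free parameters sized
for test power, not estimates of any real effect.

Problem sizes throughout the simulations (24- and 16-node networks for the
Monte-Carlo batteries, 6-ROI templates for the imaging chain, 2000-replicate
null calibrations) were chosen so the whole suite runs in minutes on one
CPU while keeping every Monte-Carlo standard error far below the asserted
margins; they are stated here as the package's own design choices.

## Numerical choices and degenerate inputs

* Phantom tensors are cylindrically symmetric, $\lambda_1 = 1$,
  $\lambda_2 = \lambda_3$ solved in closed form from the target FA via
  $FA = (1 - b)/\sqrt{1 + 2b^2}$ — invertible, so the FA postcondition is
  exact and testable to 1e-12 in the noise-free case.
* FA maps use the rotation-invariant Frobenius form, avoiding per-voxel
  diagonalization; eigenvectors are computed only where tracking needs
  them.
* Overlapping phantom bundles are an error unless their axes are parallel
  (first bundle keeps the voxel) — a silent direction average would
  invalidate the angle-rule tests.
* Voxel/world conventions: 0-based indices in the affine (NIfTI style),
  1-based arrays in R, converted in exactly one place; world x < 0 is left.
* ROI growth ties (equal-size ROIs, multiple frontier voxels) are broken by
  lowest index — determinism is a contract, not an accident.
* The battery logs and skips degenerate measures (constant AI columns,
  e.g. under a perfect null) instead of failing, so a fully symmetric
  cohort runs end to end.

## Known limitations

Single-tensor deterministic tracking cannot represent crossing fibers; the
tracker is for validated pipeline testing on phantoms, not for competitive
tractography. The parcellation assumes the mask is already in the image's
own space — no nonlinear template registration is provided. The simulated
networks are structurally unrealistic (independent edges), so calibration
results transfer to real data only insofar as the statistical models are
correctly specified there. Handedness, site effects beyond TR/TE, and
longitudinal structure are out of scope.
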