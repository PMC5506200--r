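---
title: "Weighted motor-network analysis with homotopic connectivity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted motor-network analysis with homotopic connectivity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During unilateral limb movement, many brain regions activate in
mirror-symmetric (homotopic) pairs across the two hemispheres, and the
functional networks built from task fMRI tend to be organised around the
interhemispheric links between those homologs. `homonet` implements a
complete analysis chain for quantifying that organisation in block-design
task fMRI: condition-specific weighted connectivity, random-effects group
edge statistics with FDR control, weighted graph metrics, and a set of
homotopy statistics — strongest-link anchoring, within-module pairing, and
symmetry ratios — each with a chance null. Because the motivating study
deposited no raw data, the package also contains a first-class synthetic
BOLD generator with planted coupling structure, so every stage is testable
end to end and the behaviour of the statistics can be studied under known
ground truth.

## The experimental design being modelled

The emulated paradigm is ten 16 s movement blocks (alternating left and
right foot) separated by 20 s rests, preceded by a 26 s initial rest and
followed by a 22 s final rest, sampled at TR = 2 s. The segment sum gives
388 s (194 scans); the scanner run is nominally longer (a 4 s lead-in and a
stated 396 s total whose per-cycle accounting is ambiguous), so the
paradigm is built from the segment durations and the nominal figures are
kept as metadata only. `default_paradigm()` encodes this; every piece of
timing is configurable through `task_paradigm()`.

Condition regressors are boxcars convolved with a canonical double-gamma
haemodynamic response function (response gamma shape 6, undershoot shape
16, both rate 1/s, undershoot ratio 1/6, 32 s support, peak normalised to
1). The "canonical HRF" is named but not specified by most task-fMRI
pipelines; the double-gamma with these constants is the convention of the
major analysis packages and is adopted here. Note that the convolved
response to a 16 s block peaks roughly 10-12 s after block onset (5-6
scans at TR 2 s) — the lag at which the regressor crosses its own
undershoot — which the regression tests pin down by direct discrete
convolution.

## Node set

The vertex universe is 28 motor regions: 12 homotopic pairs (SMA, CMA,
PMd, PMv, SFG, SPL, IPC, S2, anterior insula, putamen, caudate, cerebellar
hemisphere) and 4 unpaired regions (M1, S1, thalamus — contralateral to
the dominant foot — and the midline cerebellar vermis), so 24 of the 28
regions belong to a pair. The bundled coordinates are schematic MNI
placements, mirrored in x across hemispheres and spaced so that 3 mm ROI
spheres never overlap. They are stand-ins: activation-peak coordinates
would come from data this package does not ship. Users supply their own
node table (TSV: label, x, y, z, hemisphere, pair_id) for real analyses.

## The synthetic generator

`simulate_subject()` draws a region x scan matrix as the sum of

* correlated Gaussian noise whose population correlation is `r_homotopic`
  on homotopic pairs, `r_intra` between distinct same-hemisphere regions,
  and `r_other` elsewhere (matrix square root of the target correlation
  applied to white noise — the simplest generator whose population
  correlation equals the target; the matrix is validated positive
  semi-definite, with an eigenvalue-floor repair that errors beyond an
  entry tolerance of 0.05);
* an HRF-convolved task response with contralateral weighting
  (contralateral 1, ipsilateral 0.4, midline 0.7) scaled by `task_gain`;
* low-frequency drift (a 0.002-0.005 Hz sinusoid plus linear trend, below
  the 0.008 Hz filter edge by construction);
* six motion traces (smoothed random walks) and WM/CSF series
  (low-frequency smoothed noise) leaking into the data with amplitude
  `motion_coupling`, and returned verbatim in the confound table;
* i.i.d. measurement noise (`measurement_sd`, default 0.05 so planted
  correlations are attenuated by under one percent).

Defaults are 18 subjects and the default paradigm's 194 scans, matching
the emulated study's cohort. The planted couplings default to
`r_homotopic = 0.6 > r_intra = 0.3 > r_other = 0.1`: the study reports no
numeric effect sizes for its connectivity, so these values were fixed once
for clear separation between coupling classes at the cohort's power, and
the package's recovery claims are made under exactly these conditions.

What the generator does **not** emulate: spatial autocorrelation and EPI
artifacts, scanner noise spectra, condition-dependent coupling
(connectivity differences between left- and right-foot movement), and the
spatially clustered connectivity of real cortex. Passing tests therefore
demonstrate correctness of the chain and sensible behaviour of the
statistics under the planted model — not fidelity to any particular real
dataset.

## Signal chain

The fixed order is extraction → bandpass → nuisance regression.

* **Extraction**: each region is the mean over voxels whose centers lie
  within 3 mm (Euclidean, mm space) of the node center. The
  center-in-sphere rule is deterministic and robust to grid resolution,
  unlike any-overlap rules.
* **Bandpass**: order-4 Butterworth, 0.008-0.09 Hz, applied forward and
  backward (zero phase, so no lag distorts the block-weighted
  correlation), with odd-reflection edge padding to suppress transients,
  and exact demeaning (DC is outside the band).
* **Nuisance regression**: least-squares projection on an intercept, the
  six motion parameters, WM and CSF series, and the first temporal
  derivatives of WM/CSF only — following the emulated pipeline's wording,
  which lists derivatives for the tissue signals but not for motion.
  Confounds are bandpassed with the same filter first; regressing
  unfiltered confounds from filtered data would reintroduce removed
  frequencies. Rank-deficient designs are an error naming the offending
  columns.

## Connectivity and group inference

Condition-specific correlation is a weighted Pearson coefficient with the
HRF-convolved block regressor (negative undershoot clipped to zero) as
per-scan weights — restricting the correlation to scans where the
condition's response is active while respecting haemodynamic delay. With
constant weights it reduces exactly to the ordinary Pearson coefficient.

Per edge, subject Fisher z values (z = atanh r) enter a one-sample
two-sided t test (df = n-1); Benjamini-Hochberg FDR at q = 0.05 over the
n(n-1)/2 = 378 edge tests selects the network. Edge weights default to
`tanh(mean z)` — the back-transformed group-mean correlation, which keeps
W in (0,1) so that the distance transform D = 1 - W stays in (0,1] —
with raw mean z available by configuration, since descriptions of such
networks vary between "correlation magnitude" and Fisher-value weights.
Significant negative-mean edges are excluded from W (the emulated networks
contain only positive connections) but retained in the edge table. Edges
with zero across-subject variance get p = 0 with a warning rather than an
error; they arise only in degenerate synthetic corners.

## Graph metrics

Strength, D = 1 - W distances with unreachable markers, Dijkstra shortest
paths, Brandes betweenness normalised by (n-1)(n-2)/2, global efficiency
(unreachable pairs contribute zero), Onnela geometric-mean weighted
clustering, strength-strength assortativity over edges, and small-world
indices against degree-preserving rewired references (10 rewires per edge,
observed weights reshuffled over the surviving edges; sigma =
(C/C_rand)/(L/L_rand); disconnected graphs are analysed with a flag and
unreachable pairs excluded from L).

Modularity is the weighted Newman-Girvan objective with resolution gamma.
The search runs Louvain under random node permutations, alternating with
random K-way initialisations, each refined by a deterministic
single-node-move plus whole-module-merge pass (ties toward the lowest
index). The diversified restarts matter: on strongly symmetric weight
matrices plain Louvain locks into pair-sized modules from which no single
merge improves Q even when a coarse partition is far better. The returned
`q_value` is always recomputed from the assignment by the direct formula,
and on all 8-node-or-smaller test fixtures the search attains the optimum
found by exhaustive enumeration of set partitions.

## Homotopy statistics and their nulls

For each region, the incident edge of maximal weight is selected (one
selection per region, so a link can be chosen by both endpoints; exact
ties go to the lowest index and are flagged; isolated regions are dropped
from denominators with a warning). **Anchoring** counts paired regions
whose selection is their contralateral homolog, out of 24. **Pairing**
counts homotopic pairs with both members in one Louvain module, out of
12; **symmetry ratios** express the same per module (k_m/n_m, totals
K/N with K = 2 x pairs co-located).

Chance nulls, defined by this package (the emulated study's probability
computations are not available in its published text):

* **Anchoring null**: edge weights of the complete graph are i.i.d.
  exchangeable. Permutation mode redraws weights and recomputes the count
  (p = (1 + #{null >= obs})/(1 + n_perm)). Exact mode (n <= 10) evaluates
  the null pmf in closed form: inclusion-exclusion over joint
  strongest-link events, with each joint probability an order-statistic
  integral over orderings of the forced-maximal edges. At n = 4 the
  closed form reproduces the full 6!-edge-ranking enumeration exactly,
  and it matches Monte-Carlo at n = 6 and 8 within sampling error.
* **Co-location null**: node labels are permuted over the observed
  module sizes; exact mode enumerates all assignments for n <= 10.

Anchoring is invariant under any strictly monotone transform of the
weights, so the nulls depend only on weight ranks.

Calibration is checked by simulation: under a homogeneous-coupling
generator (equal couplings, no task/drift/motion, so edge weights carry
no homotopic preference), the permutation p-values are super-uniform —
empirical type-I ≈ 0.01-0.03 at nominal 0.05 over 200 replicates. The
calibration scenario deliberately sets the task gain to zero: a shared
task response under homogeneous coupling induces correlated weight noise
that is not the exchangeable null the permutation scheme draws from.

## What recovery tests show — and a structural caveat

Under the planted conditions (18 subjects, 0.6/0.3/0.1, FDR q = 0.05),
the pipeline recovers homotopic dominance essentially perfectly: all 12
homotopic edges survive FDR, anchoring is 24/24 in nearly every seeded
replicate with permutation p at the attainable minimum, and the
reverse-planted control (intra 0.6, homotopic 0.1) collapses anchoring to
~0/24 — the statistic discriminates rather than saturates.

Module-level symmetry behaves differently, and deliberately so. With
*uniform* intrahemispheric coupling, the 105 + 66 within-hemisphere edges
at ~0.3 carry far more total weight than the 12 homotopic links at ~0.6,
so the modularity optimum is the two-module hemispheric split, which
co-locates no pair — and the Louvain search correctly finds it (Q ≈ 0.25
versus ≈ 0.02 for pair-respecting four-module partitions). Bilateral
modules in real data arise from spatially clustered connectivity (e.g.,
SMA/CMA/PMd forming a dorsomedial cluster in both hemispheres) that a
three-level coupling model cannot express. The package therefore treats
within-module pairing as what it is: a statistic whose value is an
empirical property of the network analysed, not something the planted
generator can be expected to reproduce. The module-pairing operations and
their nulls are validated by construction (planted partitions, exact
combinatorial oracles) rather than by end-to-end generator recovery.

## Numerical choices

* Fisher transform refuses |r| >= 1 unless clipping (to 1 - 1e-7) is
  requested; the subject-connectivity wrapper clips, since degenerate
  identical series otherwise poison a whole matrix.
* Weighted correlation needs >= 3 positively weighted scans and positive
  weighted variance; violations are errors tagged with the node pair.
* Dijkstra, Louvain and strongest-link ties break by node index;
  together with seeded restarts this makes every stochastic stage
  reproducible bit for bit under a fixed seed.
* PSD repair of planted correlation matrices floors eigenvalues at zero
  and re-normalises the diagonal, errors if any entry moves more than
  0.05, and flags the repair.
* Problem sizes used by the test-suite recovery studies: 20 replicates
  of the full 18-subject pipeline for planted and reverse-planted
  conditions, and 200 replicates at n_perm = 199 for null calibration;
  oracle-equivalence fixtures use 4-8 nodes where exhaustive enumeration
  is exact.

## Known limitations

* ROI extraction expects isotropic-ish affines and spheres wholly inside
  the field of view; partial-volume weighting is not modelled.
* The generator's drift/motion families are simple; they exercise the
  denoising path but do not span real scanner artifact diversity.
* Exact anchoring nulls are closed-form up to 10 nodes; beyond that the
  permutation mode is the only option.
* Small-world references rewire the binary structure and reshuffle
  weights; strength sequences are not preserved exactly.
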