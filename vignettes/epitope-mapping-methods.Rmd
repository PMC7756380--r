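---
title: "Methods: linear epitope mapping from peptide tiling microarrays"
author: "epimapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear epitope mapping from peptide tiling microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimapr)
```

# The measurement model

A peptide tiling microarray represents an antigen's mature sequence
(signal peptide removed; all coordinates in this package are 1-based
on that sequence) as overlapping synthetic peptides — by default
15-mers whose start positions advance by 3 residues, so consecutive
probes share 12 residues. Serum is incubated on the array and bound
IgE and IgG4 are detected in two fluorescence channels. Each peptide
is printed in triplicate, and the array carries blank spots (no
peptide) that sample the null signal distribution of that particular
serum incubation.

The analysis chain is:

1. per spot, `S = log2(total / background)` — the log2 signal-to-noise
   ratio;
2. per probe, the median S over replicates (robust to one failed spot;
   computed after the log transform);
3. per serum and channel, `z = (S - median(S_blank)) / MAD(S_blank)`,
   where MAD is the *unscaled* median absolute deviation about the
   median;
4. epitopes are maximal runs of 2–4 contiguous reactive peptides
   (`z >= 3` for each peptide), named by the intersection of the run's
   peptide intervals.

## Numerical conventions and edge cases

* **Median deviation.** The scale estimator carries no Gaussian
  consistency constant by default (`mad_scale = 1`). The constant
  1.4826 would only rescale the z-threshold uniformly; it is exposed
  as a configuration switch because either convention is defensible.
* **Replicates.** Aggregation is the median of however many valid
  replicates exist (≥ 1); spots with background ≤ 0 or negative total
  fluorescence are flagged invalid and excluded, never imputed.
* **Blanks.** Each physical blank unit is identified
  (`BLANK_01`, ...) so triplicates of a blank aggregate exactly like a
  probe. At least 2 blank units are required; identical blanks (MAD
  zero) abort with an instruction to inspect the array rather than
  silently producing infinite z-scores.
* **Contiguity.** A run is contiguous when consecutive probe starts
  differ by exactly the tiling offset. A missing probe (failed spots)
  breaks contiguity — the conservative reading.
* **Runs longer than 4.** The epitope definition is bounded at 4
  peptides. Longer maximal reactive runs are split left-to-right into
  windows of 4 with the remainder kept when it is ≥ 2; a remainder of
  1 is avoided by rebalancing the last two windows to lengths 3 and 2.
  Every window is flagged `split-from-long-run`. The bound also
  guarantees the interval intersection is nonempty for the default
  geometry (a 5-run's intersection would be empty at 15/3 only beyond
  width 4 · offset).
* **Run rule.** "Recognition of 2–4 contiguous peptides" is read as
  *each* peptide being reactive (`run_rule = "all_above"`); this
  reading reproduces the conventional 12-residue two-peptide epitope
  names exactly. The weaker reading — only the window median must pass
  — is available as `run_rule = "median_only"` (greedy left-to-right,
  longest window first) but is not the default because it admits runs
  anchored by a single strong peptide.
* **Epitope naming.** `consensus_region()` intersects the run's
  intervals: `start = max(starts)`, `end = min(ends)`. For 15/3 this
  yields 12, 9 and 6 residues for runs of 2, 3 and 4 peptides.

# Surface exposure

Whether an epitope lies on the surface of the folded antigen is
decided from per-residue relative solvent accessibility:

* solvent-accessible surface area (SASA) is computed with the
  Shrake–Rupley method — each atom's solvent-expanded sphere
  (van der Waals radius + 1.4 Å water probe) is sampled with a
  golden-spiral lattice of 960 points, and a point is accessible when
  it lies outside every neighbouring expanded sphere. The kernel is
  Rcpp and is validated against the analytic area of an isolated atom
  (exact to the lattice discretization) and a monotone-burial
  property (adding atoms never increases accessibility);
* residue ASA is divided by a published per-residue maximum (Tien et
  al. 2013; the theoretical set by default, the empirical set by
  option) to give a relative accessibility ratio;
* a residue is *exposed* when the ratio is strictly greater than 0.5;
  an epitope is *surface-exposed* when at least 25% of its residues
  are exposed (boundary inclusive). Both thresholds are parameters.

Because deposited structures use author numbering, residue indices
are remapped onto mature coordinates by global pairwise alignment of
the chain sequence against the mature sequence (BLOSUM62), not by
trusting the numbering. Residues missing from the structure
(unresolved loops) count as not exposed, with a warning. Whether the
accessibility "probability" should use whole-residue or
side-chain-only area is not decidable from first principles; both are
offered (`sidechain_only`), whole-residue being the default, and
results under the alternative convention should be reported as such.

The test suite exercises this module exclusively on programmatically
generated structures: an idealized extended chain (backbone + CB,
CA spacing 3.8 Å) whose central Gly-X-Gly residue recovers ~0.87–0.90
of its reference maximum, and burial shells of dummy atoms dense
enough that no probe-sized sphere point escapes. Burial shells also
shadow chain neighbours at physical spacing — as in a real protein —
so fixtures that need burial confined to the flagged residues widen
the chain (`ca_spacing = 9`), making residues sterically independent.

# Diagnostics

* **EAST classes.** EUROLINE band intensities (response units) map to
  ordinal classes 0–6 through the published step bands (<3 → 0, 3–6 →
  1, 7–15 → 2, 16–30 → 3, 31–50 → 4, 51–100 → 5, >100 → 6). The bands
  have integer bounds; a non-integer value falling in an open gap
  between bands (e.g. 6.5 RU) is rounded to the nearest integer
  first, everywhere else the bands apply literally. The mapping is a
  total monotone step function.
* **sIgE/sIgG4 ratios** are defined only for positive IgG4; undefined
  ratios are flagged and excluded from medians; the log transform is
  base 10.
* **Classifier.** A patient is positive when at least one IgE epitope
  call covers a *majority* (> 50%) of any designated discriminative
  region (defaults aa30-41, aa39-50, aa84-95). A 1-residue overlap
  rule was considered and rejected: on an offset-3 tiling, adjacent
  but distinct epitopes (e.g. aa45-56 next to aa39-50) share up to
  half a region, and the permissive rule conflates them, destroying
  specificity whenever the neighbouring epitope is common. The
  permissive rule remains available (`min_overlap = 0`).
* **Titre thresholds** are inclusive (`titre >= cutoff`) by default;
  the strict variant is a flag, since reports rarely state the
  convention.
* **Mann–Whitney U.** For combined n ≤ 25 the two-sided p-value is
  exact: the rank-sum permutation distribution is enumerated by
  dynamic programming over midranks (ties handled exactly), and p is
  twice the smaller tail, capped at 1. Larger samples use the normal
  approximation with tie correction and no continuity correction.
  `wilcox.test` is not used as the implementation because it
  abandons exactness under ties; it serves as a cross-check oracle in
  the tests on tie-free inputs.
* **PCA.** Patients × features (peptide z-scores or epitope mean z),
  centered, scaled by default; the contribution of a feature to a
  component is `100 ·loading²` (unit-norm eigenvectors, so
  contributions sum to 100 per component). Eigenvector sign is fixed
  by making the largest-magnitude loading positive. Constant features
  are dropped with a warning. No multiple-testing correction is
  applied anywhere in the diagnostics layer; the package reports raw
  p-values, and summaries round rates to 2 decimals and percentages
  to whole numbers.

# The synthetic cohort generator

The generator emulates the data the pipeline consumes — spot-level
fluorescence for a two-channel triplicate array, patient metadata,
and a truth table of planted recognition events — under a seeded,
reproducible model. Defaults describe a small adult cohort: 13
allergic and 15 tolerant patients, a 186-residue antigen (58 probes),
60 blank units, lognormal background (meanlog log 500, sdlog 0.4),
probe-level null noise σ = 0.2 log2 units, 10% replicate CV.

Per patient × channel and probe/blank unit the model is

```
total = background · 2^(delta + eps),    background ~ lognormal
eps   ~ N(0, sigma_null)            for non-reactive probes
eps   ~ N(0, 2 · sigma_null)        for blank units
delta = effect_z · qnorm(0.75) · 2 · sigma_null   for reactive probes
```

with independent multiplicative jitter per replicate. Effects are
planted on the log2 scale and scaled by the *expected blank MAD*, so
`effect_z` maps linearly onto the z-score a reactive probe attains —
the detection threshold is analytically predictable.

Design choices worth recording:

* **Blank scatter.** Blanks carry twice the probe-null scatter by
  default (`blank_sigma_scale = 2`). With equal scatter, a z of 3
  under the unscaled MAD corresponds to only ~2 probe-noise SDs, and
  isolated false-positive peptides appear at several percent per
  probe — a regime in which the 2-peptide contiguity rule produces
  0.1–0.3 false epitopes per patient and cohort-scale arithmetic is
  swamped by noise. Blank spots carry no peptide layer and plausibly
  scatter more than peptide-occupied spots; the factor-2 default
  places the z ≥ 3 threshold at ≈ 4 probe-noise SDs, the regime the
  calling rule is designed for (false calls well below 0.1 per
  patient, measured ≈ 0 over 500 simulated null patients). Setting
  `blank_sigma_scale = 1` reproduces the heavy-tail regime for
  robustness studies.
* **Planted regions are grid-snapped.** A planted 12-residue region
  whose start lies on the probe grid is fully contained in exactly
  two probes, so at detectable effect sizes the called consensus
  region equals the planted region exactly — which makes
  parameter-recovery oracles sharp. The defaults (aa31-42, aa40-51,
  aa85-96, aa46-57) each cover 11 of 12 residues of the corresponding
  discriminative classifier region. Planting two regions whose
  covering probes are contiguous on the grid merges them into one
  longer run — a property of the assay, not a bug — so recovery
  experiments use well-separated regions.
* **Recognition structure.** IgE recognition is Bernoulli per region,
  patient and group; the three discriminative regions use per-region
  probability 0.186 (allergic) / 0.023 (tolerant), calibrated so the
  probability of recognizing at least one is ≈ 46% / 7%; the shared
  region uses 38% / 27% directly. IgG4 co-recognizes an
  IgE-recognized region with probability 0.8 (clonal overlap).
  Fixed-count planting (`n_allergic`, `n_tolerant` columns) makes the
  first k patients of a group recognize deterministically, for
  experiments that need exact cohort arithmetic.
* **Randomness.** A mandatory master seed feeds per-patient
  substreams (deterministic arithmetic splitting), so enlarging the
  cohort never perturbs earlier patients, and identical
  configurations are byte-identical.
* **What is not modelled:** spatial slide artifacts, scanner
  saturation, dye bias, sequence-dependent nonspecific binding, and
  correlation of nonspecific signal between overlapping probes.
  Passing tests on synthetic data therefore demonstrate the
  statistical machinery, not robustness to real-array artifacts;
  inter-array normalization beyond per-array blanks is explicitly out
  of scope.

# Problem sizes in the test suite

The suite runs entirely on generated data: oracle-equivalence checks
use 1000 random 60-peptide arrays against a brute-force window
enumerator; null calibration simulates 500 patients on the default
58-probe antigen; parameter recovery uses saturated effect sizes on
6-patient cohorts; SASA checks use short toy chains. These sizes keep
the full suite under a minute of simulation while leaving every
statistical assertion comfortably powered.

# Known limitations

* The epitope classifier and recognition fractions assume one antigen
  per analysis call; multi-antigen layouts are supported end to end,
  but discriminative regions are interpreted on whichever antigen a
  call belongs to unless `antigen_id` is given.
* The SASA reference maxima and radii sets are conventions; relative
  accessibility near the 0.5 decision boundary can flip between
  conventions, and verdicts for such residues should be treated as
  convention-dependent.
* The exact Mann–Whitney enumerator is quadratic in total midrank sum
  and is capped (default combined n ≤ 25) before switching to the
  tie-corrected normal approximation.
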