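---
title: "Models and methods behind methylmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylmorph)
```

`methylmorph` re-implements, as a tested pipeline, the quantitative
workflow of multiple-myeloma studies that connect promoter
hypermethylation of a microRNA (miR-23) to overexpression of its target
gene (uPA/PLAU) and to tumor phenotype: bisulfite-sequencing methylation
rates, tumor-shape regularity, intrahepatic invasion depth, and
stage-wise association statistics. This vignette records the models, the
parameters that matter, and the design decisions taken where the
underlying methodology is conventionally under-specified.

## Methylation calling

### CpG sites and islands

A CpG site is the 0-based offset of a `C` immediately followed by `G`.
Island detection uses the de facto standard sliding-window criteria
(Gardiner–Garden & Frommer, as implemented by most primer-design tools):
window 200 bp, step 1, a window qualifies when GC ≥ 0.50 and
observed/expected CpG = N~CG~·L/(N~C~·N~G~) ≥ 0.60. Overlapping
qualifying windows are merged and the merged interval is trimmed one base
at a time from its GC-poorer end until the whole interval meets the
criteria; intervals shorter than 200 bp are dropped. All thresholds are
configurable through `island_criteria()`. Two consequences are worth
knowing: (i) a uniform `CG` repeat has obs/exp exactly 2.0
(N~CG~ = L/2, N~C~ = N~G~ = L/2), which the tests use as a closed-form
anchor; (ii) detected islands legitimately extend up to ~100 bp into
CpG-free flanks, because windows straddling the boundary still qualify —
hence `amplicon_around_island()` centers amplicons on the island midpoint
rather than its reported start.

### Conversion, alignment and calls

Bisulfite chemistry is modeled on the plus strand only (BSP primers
target one converted strand): every unmethylated cytosine converts to
thymine with probability `conversion_rate` (default 1); methylated CpG
cytosines are protected. Reads are aligned by global Needleman–Wunsch
(match +1, mismatch −1, linear gap −2; compiled via Rcpp) against the
*fully converted* reference in which non-CpG `C` becomes `T` and CpG
cytosines are scored as a match for either `C` or `T`. This
converted-reference construction makes the aligner insensitive to
methylation state without an asymmetric scoring matrix; amplicon reads
are near-exact, so sensitivity beyond this is unnecessary. Traceback
ties are broken deterministically (diagonal, then reference-consuming
gap, then read-consuming gap). Low-scoring alignments are flagged rather
than rejected.

At each covered CpG site the read base is mapped `C`→M, `T`→U, anything
else (including gaps) →N; N calls are excluded from both numerator and
denominator of every rate. The region rate defaults to the *pooled*
convention r~m~ = ΣM/Σ(M+U) over all read-level calls, which is
depth-weighted and well defined at uneven coverage; a per-site mode
(mean of site rates) is available, and the two agree at equal depth.
Which convention the field's wet-lab reports use is typically ambiguous,
so both are provided. With incomplete conversion c < 1 and true
methylation p, the expected pooled rate is p + (1−p)(1−c) — the known
BSP overestimation artifact — and the test suite asserts this bias
law on simulated reads.

## Read simulation

`simulate_bisulfite_reads()` draws an independent template molecule per
read (each CpG site methylated with its profile probability), applies
conversion, then uniform substitution errors at `seq_error_rate` per
base. Reads default to spanning the whole amplicon, so `depth` is
per-site coverage — the natural parametrization for amplicon sequencing,
and the study's actual sequencing depth is unreported, leaving depth a
free simulation parameter. Qualities are constant Q40 (`I`) unless an
error model is active, in which case Q = −10·log10(error). FASTQ I/O is
Phred+33 via Biostrings. No PCR bias, paired ends, minus-strand reads or
indel errors are simulated.

## Synthetic promoters

`generate_promoter()` embeds `n_islands` island segments (default 3, in
a 2000-bp region mirroring a −2000..−1 promoter window) in a background
that *cannot* contain islands: background letters are drawn with
GC = 0.40 but a `G` is never emitted after a `C`, so the background's
obs/exp is exactly 0. Island segments are emitted from a two-state model
(`CG` dinucleotide with probability q, single bases otherwise) whose q
is solved numerically from the requested island GC and obs/exp; segments
are rejection-sampled until they clear the detector thresholds with a
margin, and the assembled sequence is verified with `find_cpg_islands()`
before being returned. Infeasible requests (island GC below the
detector's threshold, obs/exp beyond the emission model's reachable
range, or a length that cannot hold the islands with window-sized
separations) fail with explicit parameter errors. This gives
detector-agnostic ground truth: the island count is guaranteed by
construction, not by tuning.

## Tumor-shape regularity (F-value)

The F-value compares the tumor area with an enclosing "selected area":
F = (A~sel~ − A~tumor~)/A~sel~. The source methodology designates the
selected area interactively in an imaging tool without defining it
geometrically; `methylmorph` adopts the **minimum enclosing circle** of
the tumor boundary, which is parameter-free, guarantees
A~sel~ ≥ A~tumor~, and matches the method's intent of scoring closeness
to a circle. (An alternative reading — the circle on the long-axis
diameter — coincides with the MEC for the circles and ellipses used in
validation but differs for, e.g., triangles; it is flagged, not
implemented.) The MEC is computed by Welzl's algorithm on the convex
hull of boundary pixel centers and its radius is inflated by half a
pixel diagonal (√2/2) so the circle covers whole pixel squares; this
makes F ≥ 0 provable (disjoint unit squares with centers inside radius R
fit inside radius R + √2/2) at the cost of a small positive bias for
discs (~1.4/r, i.e. 0.026 at r = 50). Analytic anchors used by the
tests: a disc has F ≈ 0, an a:b ellipse F = 1 − b/a, a square
F = 1 − 2/π ≈ 0.363.

Masks must be a single 4-connected component; holes are filled before
measurement (gross tumor outlines are analyzed). The long axis is the
maximum Feret diameter, computed over convex-hull vertices and verified
against an all-pairs oracle. The perimeter is the traced 8-connected
outer contour length with diagonal steps weighted √2 (reported, but not
used by F). F is scale-free and computed in pixels; caliper volume
V = w²·L/2 uses physical mm only and is never inferred from images.
Because the relative discretization error of F is largest where F ≈ 0,
scale-invariance is asserted on ellipse families (±0.02 for semi-axes
≥ 30 px) rather than on discs.

## Invasion depth

Depth is measured along a declared axis from a declared capsule edge —
the surface where the tumor-cell hydrogel drop was adhered, from which
invasion proceeds inward. The total liver depth is the maximal per-line
extent of the liver mask along that axis; the invaded depth is the
*maximum* lesion extent from the capsule (the front's deepest point,
matching the reading of "depth of the intrahepatic lesions"; averaging
over the width is the plausible alternative and is documented, not
implemented). RI = invaded/total ∈ [0, 1]. The synthetic section
generator pins the deepest lesion pixel exactly at the requested depth,
so generator round-trips are exact and used as the primary correctness
check; thresholding of grayscale sections keeps the largest component
for the liver and all components for lesions.

## Cohort model and statistics

`simulate_cohort()` draws, per group, methylation rates from a Gaussian
truncated to [0, 1] and expression from linear links with additive
Gaussian noise (only means ± SD are ever reported for such cohorts, so
Gaussians are the minimal assumption). Defaults
(`default_cohort_params()`): group sizes 35/42/38/21 for the
intraosseous, blood, bone-tumor and extraosseous stages plus 20 B-cell
controls; the published per-stage regression coefficients as generating
links; stage methylation means 0.20/0.70/0.70/0.85 (SD 0.10) and B cells
0.08 (SD 0.04). The means were chosen once so that the qualitative stage
structure holds — methylation and uPA lowest in the intraosseous group
and highest in the extraosseous group, miR-23 reversed, B cells at the
extremes. Notably, the published stage-wise intercepts are mutually
inconsistent with *all* reported group equalities (no methylation means
make blood and bone-tumor uPA both ≈ equal given intercepts 1.879 vs
0.5024), so that particular equality is not asserted anywhere. Link
noise defaults to |slope|·SD(methylation), a within-group
signal-to-noise ratio of 1 (per-link R² ≈ 0.5), which reproduces the
strongly significant but scattered per-stage fits typical of such data.
B cells have no methylation–expression link (slope 0 with fixed means):
n = 20 primary B-cell lines act as a control, not a regression stratum.

The statistical layer uses `stats::lm` for OLS (slope p from the t
statistic on n−2 df, verified against a closed-form normal-equations
oracle to 1e-10), one-way ANOVA plus pairwise *Welch* t-tests for group
comparisons (group sizes differ, so pooled variance is not assumed; the
single-factor design is what the comparisons actually are, even where
wet-lab reports loosely say "two-way ANOVA"), Bonferroni adjustment
min(1, m·p) with m the pairwise family within one analysis (the smallest
defensible family; the multiplier is configurable), and the
normal-approximation sample size n = 2(z~1−α/2~ + z~1−β~)²/Δ² (16 per
group at Δ = 1, α = 0.05, power 0.8). Expression units are treated as
arbitrary continuous qPCR-relative units throughout.

## Reproducibility and problem sizes

Every generator is a pure function of its parameters and a seed
(Mersenne-Twister via `withr`, sub-seeds derived deterministically per
stage), so identical configurations give bitwise-identical outputs;
`run_end_to_end()` writes its resolved configuration beside its outputs
and skips stages whose configuration digest and outputs are unchanged.
The validation suite runs at deliberately modest sizes chosen to make
sampling error negligible relative to the tolerances: amplicons of
100–240 bp at depths 50–1000, masks up to 128 px, 200-replicate cohort
simulations, and a 2000-replicate null calibration of the slope test.
What passing tests show — and do not show — about real data: the
generators emulate sampling noise, incomplete conversion and sequencing
errors, but not PCR amplification bias, cell-population heterogeneity
(methylation is i.i.d. per molecule, not clonal), staining artifacts, or
segmentation error in masks; results on real images and libraries depend
on those upstream steps.

## Known limitations

* Plus-strand CpG context only; no CHH/CHG, no duplicate-read removal,
  no basecalling, no primer trimming beyond a fixed-length clip.
* The global aligner is designed for amplicon reads; shotgun bisulfite
  data would need local alignment and a mapping-quality model.
* The "selected area" definition (minimum enclosing circle) is one
  defensible reading of an under-specified manual procedure; F-values
  for strongly concave shapes depend on it.
* The invasion statistic reduces a 2-D lesion field to one depth ratio;
  nodule counts and area fractions are deliberately out of scope.
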