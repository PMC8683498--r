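---
title: "Models and methods: subclonal reconstruction, survival and synergy scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonevolve)
```

This vignette documents the models behind each stage of the package, the
tunable parameters and their defaults, what the synthetic-data generator does
and does not emulate, and the numerical choices made where the design was
genuinely open.

## From read counts to cancer cell fractions

A somatic variant observed with `alt` of `total` reads has allele fraction
$\mathrm{VAF} = alt/total$. In a biopsy of tumor purity $\rho$ where the
locus has total copy number $CN_t$ in tumor cells (and 2 in admixed normal
cells), a mutation present on $m$ copies in a fraction $\mathrm{CCF}$ of
tumor cells is expected at

$$\mathrm{VAF} = \frac{m\,\rho\,\mathrm{CCF}}{\rho\,CN_t + (1-\rho)\,2},$$

which the CCF engine inverts:

$$\mathrm{CCF}_{raw} = \mathrm{VAF}\cdot\frac{\rho\,CN_t + (1-\rho)\,2}{\rho\, m}.$$

Multiplicity is estimated by the nearest-integer rule
$\hat m = \mathrm{round}(\mathrm{VAF}(\rho CN_t + (1-\rho)2)/\rho)$ clamped
to $[1, CN_t]$, with ties at .5 rounded half-up so results do not depend on
the platform's rounding mode. The reported CCF is clamped at 1; the raw
value is kept because the clamp is informative QC (systematic raw values
well above 1 indicate a purity or copy-number error). The variance is
first-order propagation of the binomial VAF variance
$\mathrm{VAF}(1-\mathrm{VAF})/total$ through the linear correction. Normal
copy number is fixed at 2; sex chromosomes are outside the model's scope.

Assumptions worth stating: purity and per-segment copy number are inputs,
not estimates; subclonal copy-number change at a mutated locus is not
modeled; multiplicity is integral.

**Covered-absent versus missing.** When mutation tables from several
biopsies are merged, a mutation not observed in a sample is CCF 0 only if
the site is adequately covered there (`min_depth`, default 20x, mirroring
the coverage level at which exome calls are commonly trusted); otherwise it
is missing and excluded from density estimation rather than imputed. Rows
missing everywhere are dropped with a message.

## Subclone deconvolution

The CCF distribution of a biopsy is a noisy mixture: each subclone
contributes a peak whose width is set by binomial counting noise. The
deconvolution is nonparametric mode seeking:

1. per sample, a weighted Gaussian KDE over the non-missing CCFs (weights =
   inverse mean variance of the mutation, so deep sites count more);
2. each mutation is snapped to its nearest density mode per coordinate, and
   distinct snapped vectors seed clusters (hard assignment — equivalent to
   nearest-seed Gaussian responsibility under a shared isotropic bandwidth);
3. clusters whose centers differ by less than `merge_tol` in *every* sample
   merge (smallest-distance pair first, deterministically);
4. clusters below `min_cluster_size` dissolve into their nearest neighbor.

Parameters, with defaults and rationale:

| parameter | default | role |
|---|---|---|
| bandwidth | median binomial SD of the CCFs, floor 0.05 | adapts smoothing to depth; the floor prevents over-segmentation of very deep data |
| `merge_tol` | 0.10 CCF | two clusters closer than typical noise (~1 SD at 150x) in every sample are one population |
| `min_cluster_size` | 5 mutations | a subclone supported by fewer mutations is not distinguishable from noise |
| `clonal_threshold` | 0.85 | center at/above this in a sample counts as clonal there |
| `absent_threshold` | 0.10 | center at/below this counts as absent |

Cluster centers are means of the **unclamped** CCFs, clamped to $[0,1]$ only
for reporting. Averaging already-clamped values would bias a truly clonal
cluster's center to about $1 - \sigma\phi(0) \approx 0.96$ at 150x depth,
and that bias would propagate into every downstream composition; averaging
raw values is unbiased.

Classification: `clonal_all` if the center reaches `clonal_threshold` in
every sample; `private:<sample>` if it exceeds `absent_threshold` in exactly
one sample (flagged `(subclonal)` when below the clonal threshold there);
`absent` when below `absent_threshold` everywhere (this occurs in pairwise
views when a third biopsy's private cluster collapses onto the origin);
otherwise `shared_subclonal`. The private rule is deliberately based on
presence/absence rather than on clonality, so a single-biopsy subclone is
reported as private-subclonal rather than as "shared".

The suite validates the deconvolution against an independent EM
binomial-mixture oracle with BIC model selection on 1-D instances with
well-separated components; cluster counts must agree and centers match
within 0.05.

## Clone-tree reconstruction

Two constraints order clusters into a lineage: **containment** (a child's
CCF cannot exceed its parent's in any sample) and the **sum rule** (a
clone's children cannot jointly exceed it in any sample), both applied with
an absolute tolerance `sum_rule_tol` (default 0.10, sized to absorb binomial
CCF noise at ~150x depth). The root must be the unique cluster clonal in all
samples — zero or several such clusters mean ancestry is unresolvable and
the reconstruction stops with an error.

Attachment is greedy in descending total-CCF order, preferring the deepest
feasible parent (ties broken by cluster id). Greedy depth preference can
paint itself into a corner — an early cluster occupies room that a later one
needs — so when any cluster ends up without a feasible parent, an exhaustive
depth-first search over parent assignments runs (practical for the cluster
counts this analysis produces); a fully feasible tree is therefore found
whenever one exists, and on identifiable noiseless instances it equals the
unique sum-rule-feasible tree, which the suite confirms by brute-force
enumeration. Only genuinely infeasible clusters are force-attached to the
root and flagged, a deliberate graceful-degradation choice: FFPE-derived
data violate the rules often enough that aborting would make the pipeline
unusable, and a flagged node is visible in every downstream artifact.

**Composition.** In a sample $s$, clone $v$'s cellular fraction is
$\mathrm{ccf}_s(v) - \sum_{c \in \mathrm{children}(v)} \mathrm{ccf}_s(c)$,
floored at 0; clones below `absent_threshold` in $s$ are omitted.

**Inter-lesion distance.** The mean absolute per-mutation CCF difference
between two biopsies. The exact distance behind published lesion-similarity
maps is typically a supplementary detail of each study's own pipeline; the
mean-L1 form was chosen here because it is a true metric (symmetry, identity
of indiscernibles, triangle inequality), admits an all-zero "normal"
baseline naturally, and is on the interpretable CCF scale — 0.22 between the
two liver biopsies of the worked example versus ≥ 0.48 to the peritoneum.
No claim is made that it numerically matches any specific study's
supplementary formula.

Newick export uses cluster-private mutation counts as branch lengths,
canonical sibling order, and round-trips through standard tree parsers.

## The synthetic-data generator

The generator inverts the CCF model: a scenario fixes a clone tree, the
per-sample CCF of every clone (validated against the sum rule at
construction), the number of private mutations per clone, and per-sample
purity, mean depth and copy-number segments. Each biopsy draws depth
$\sim$ Poisson(mean depth) and variant reads $\sim$ Binomial(depth,
expected VAF) per mutation; multiplicity is 1 throughout (no multiplicity
model is claimed) and copy number is read from the covering segment
(default 2). Mutations of absent clones are emitted with zero variant reads
rather than omitted, so the covered-absent path is exercised exactly as with
real joint calling.

The packaged `p04_like` scenario encodes the worked example's study
conditions: three biopsies, five clones with CCFs
C0 (1,1,1), C1 (1,0,0), C3 (0.4,0,0), C2 (0,1,1), C4 (0,0,1), 150 private
mutations per clone (the per-clone mutation count is an artifact choice —
within the range of exome studies and large enough for stable cluster
centers at 150x), purity 0.7, depth 150x.

What the generator does **not** emulate: sequencing error and strand bias,
germline contamination, FFPE artifacts, subclonal copy number, overlapping
mutation spectra, or purity misestimation. Tests passing on this generator
therefore demonstrate correctness of the estimators under the stated noise
model — binomial counting noise at realistic depth — not robustness to the
full messiness of archival tumor material.

Dose–response plates are generated as two monotherapy log-logistic
inhibition curves combined by Bliss independence
($y_a + y_b - y_a y_b$), an optional constant synergy offset on
double-dosed wells, Gaussian noise on the inhibition scale, clipped to
$[0,1]$. The axes are five 3-fold dilutions plus vehicle (the screen layout
this emulates fixes the starting concentrations, 300 nM and 100 nM, but not
the dilution ratio; 3-fold is a common choice that spans ~2 orders of
magnitude), and the default EC50s equal the starting concentrations —
moderate maximal monotherapy effect, which keeps the Bliss surface away
from the clip boundary.

## Survival and response scoring

Kaplan–Meier estimation is the product-limit estimator (computed via the
survival package; tied censored and event times are handled events-first,
the standard convention), with the median defined as the first event time
where $S(t) \le 0.5$ and reported as undefined — not an error — when the
curve never reaches 0.5. Days convert to months at $365.25/12$.
Greenwood-based log-log confidence intervals are reported but the package
makes no claim about matching any published CI computed from exact calendar
dates. Co-occurrence proportions round half-up to one decimal. PET
metabolic response is an SUVmax reduction of at least 30% — the boundary is
inclusive by definition, and the classifier applies a $10^{-12}$ guard so
that an exactly-30% reduction is not lost to floating point. Xenograft
volume is $0.5 \cdot \mathrm{length} \cdot \mathrm{width}^2$ with
auto-correction (and a warning) when the caliper dimensions arrive swapped.

## Relative AUC and ZIP synergy

The relative AUC resistance score is the trapezoid area under normalized
viability over $\log_{10}$ dose, divided by the area of a hypothetical
non-responder at viability 1 over the same axis, times 100 — the only
reading under which 100% is the no-effect ceiling. Zero-dose points are
excluded from the log axis (they are used for normalization only).

ZIP scoring converts viability to inhibition $y = 1 - v$ (clipped to
$[0,1]$), fits a 4-parameter log-logistic to each monotherapy axis, and
takes $y_a + y_b - y_a y_b$ of the fitted effects as the zero-interaction
expectation. The observed surface is smoothed by the canonical
potency-shifted refits: along each row (fixed dose of drug B) the
combination responses are refitted with the floor pinned at drug B's fitted
effect and the ceiling at 1, and symmetrically along columns; the delta
surface is the mean of the two directional refits minus the expectation,
and the summary is the mean of the 9 largest deltas (a contiguous-3×3-window
variant is available via `top_mode = "window"`; the 9-largest-cells form is
the default because the windowed "most synergistic area" is a tool-specific
convention). In the 3-D extension each layer at a fixed third-drug dose
folds that drug's observed effect (the layer's double-vehicle well) into
both the floors and a three-way independence baseline, so an inert third
drug reduces each layer exactly to the 2-D analysis.

Curve fitting is deterministic multi-start (slopes 0.5–4, EC50s on dose
quantiles) L-BFGS-B on log-EC50/log-slope scale with box constraints,
followed by a Levenberg–Marquardt polish; the polish is skipped when its
gradient turns singular, which happens precisely on noiseless data where
the multi-start solution is already at machine precision. Degenerate
(constant) responses return a flat fit with a flag, and refits falling back
to observed values are flagged in the result.

**A measured limitation.** The potency-shifted refit cannot represent a
surface that is "Bliss plus a constant offset": the refit is anchored at the
monotherapy floor while the offset surface is not. On generator plates with
a uniform injected synergy of 0.2, the refitted surface overshoots mid-grid
and the top-9 summary lands near 0.23, while the full-grid mean delta — the
unbiased estimator of a uniform offset — recovers 0.194. Users comparing
summary scores across matrices should treat the top-9 summary as a ranking
score for the most synergistic region, not as an unbiased estimate of a
global interaction strength. Under the Bliss null the summary is centered
within 0.02 of zero (mean over 20 seeded plates at noise SD 0.02), with the
residual positive offset being the unavoidable selection bias of averaging
the 9 largest of 25 noisy cells.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit seed; identical configuration and
seed give byte-identical output bundles, and every output table carries an
MD5 hash of the analytic configuration (inputs, thresholds, seed — not the
output path) in a header comment. The test suite exercises the full
pipeline at the packaged study conditions (750 mutations × 3 biopsies at
150x), topology-recovery sweeps over 50 seeds, and ZIP calibration over 20
seeded plates — sizes chosen so the estimators' behavior is measured
stably while the whole suite stays fast enough to run routinely.

## Known limitations

- No intra-biopsy phylogeny beyond the cluster level; no mutation-level
  (character-based) phylogeny, timing or rate estimation.
- Purity/ploidy and copy-number calling are upstream of this package.
- The deconvolution is mode-seeking, not a Dirichlet-process mixture; very
  close subclones (centers within ~1 bandwidth) merge by design.
- Whether a nested subclone descends from its sibling or its parent can be
  genuinely unidentifiable from CCFs alone when both placements satisfy the
  sum rule; the worked example's scenario encodes the nested reading, and
  on such instances the reconstruction reports the unique feasible tree
  only when it is in fact unique.
- The ZIP summary's top-9 selection bias and refit overshoot, quantified
  above.
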