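---
title: "Methods: simulating and analyzing odorant-receptor panel vapor assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing odorant-receptor panel vapor assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorpanel)
```

## The experiment this package models

A panel of odorant receptors (ORs) — 31 receptors plus one empty-vector
control group in the default layout — is expressed in reporter cells, one
receptor per well group, in triplicate on a 96-well plate. A live-cell cAMP
reporter converts receptor activation into luminescence, read once every
90 s for 20 cycles. Odorant is delivered either dissolved in the medium
(liquid phase, mol/L) or as equilibrated vapor (vol/vol dilution in mineral
oil) that must dissolve into the medium before reaching the receptors — the
arrangement that mimics how odorants traverse nasal mucus. The per-odorant
pattern of activation strengths across the panel (the combinatorial code)
is what detects and discriminates odors.

The package provides (i) a generative simulator producing plate runs with
the statistical structure such experiments exhibit, and (ii) the complete
analysis chain: normalization, quantification, screening, inference and
classification. Everything is exercisable on synthetic data; no external
data are required.

## Generative model

### Kinetics

Each well's luminescence is a single-exponential saturating rise over a
positive baseline (see `simulate_trace()`):

\[
L(t_i) = g\, B\, d^{\,i-1}\bigl[1 + E\,(1 - e^{-k \max(0,\,t_i - t_0)})\bigr]\,\varepsilon_i,
\qquad t_i = (i-1)\,\Delta t .
\]

A monotone rise to plateau is the qualitative shape of odor-evoked cAMP
reporter traces over a 30-minute read; no biphasic or decay term is
included (response loss at cytotoxic doses is handled by a scalar
attenuation, below, not by the kinetics). Cycle indices are 1-based and
cycle 1 is read at \(t = 0\), i.e. before any rise has occurred — the first
read always sits at baseline.

Defaults: baseline \(B = 100\) (arbitrary units), rate \(k = 0.002\,
\mathrm{s^{-1}}\) (so the rise reaches ~97% of plateau by the final cycle of
a 20 × 90 s read), onset delay \(t_0 = 0\), drift \(d = 1\).

### Dose response and mixtures

The driving term \(E\) is Hill occupancy weighted by efficacy and summed
over the components of the dissolved mixture, capped at the largest single
efficacy so that superposition cannot exceed the strongest full agonist:

\[
E = v \cdot \min\Bigl(\textstyle\sum_j e_j\,\frac{c_j^{n}}{c_j^{n}+EC50_j^{n}},\ \max_j e_j\Bigr).
\]

The cap is a generator convention: without it, an enzyme that splits one
agonist into two would let responses grow without bound. Receptors with no
affinity entry, and the vector control always, have \(E = 0\).

Vapor delivery uses a linear partition map, `vapor_to_dissolved()`:
dissolved mol/L = coefficient × dilution. The coefficient (default
\(10^{-2}\) mol/L at dilution 1, per odorant) is a free generator
parameter, not an estimate — the experiment itself never quantifies the
dissolved concentration under vapor stimulation, so the simulator makes the
simplest monotone assumption and exposes it. At the standard \(10^{-2}\)
dilution this yields \(10^{-4}\) mol/L (100 µM), commensurate with typical
liquid-phase doses.

### Noise

Three multiplicative log-normal sources (`noise_params()`), all unit-mean:

| source | CV default | role |
|---|---|---|
| per-well gain | 0.10 | transfection-efficiency surrogate |
| per-read noise | 0.03 | photon-counting / pipetting jitter |
| per-run gain | 0.05 | day-to-day global scale |

Placement matters more than magnitude: the per-well gain and the per-run
gain are removed almost entirely by the initial-value normalization (each
trace is divided by its own first read), so the residual well-to-well
scatter is dominated by the read noise entering through the cycle-1
denominator. This is what makes replicate response vectors highly
reproducible while leaving realistic scatter in individual traces. With
these defaults the acceptance script's reproducibility measurement (mean
squared Pearson \(R^2\) between per-receptor mean AUC vectors of
independent runs) lands far above the 0.91 floor expected of such assays.

Randomness is organized as counter-based substreams: one root seed, one
derived seed per well (`derive_seed()`), so appending conditions to a
design never perturbs the traces of existing wells and every run is a pure
function of (design, models, seed).

### Toxicity and enzymatic conversion

Undiluted odorant vapor is cytotoxic to different degrees; the simulator
models this as a scalar response attenuation (`toxicity_model()`) applied
only above a dilution threshold of \(10^{-1}\) — effectively at the
undiluted \(10^0\) condition. Presets retain 0.25 (harsh, eugenol-like) or
0.8 (mild, methyl-benzoate-like) of the response. The generator
deliberately conflates viability loss with any receptor-level saturation
loss: the experiment only supports the attenuation's existence and rough
size, not its mechanism.

Carboxyl-esterase co-expression (`ces1d_model()`, `apply_ces1d()`) converts
a fixed fraction of an ester substrate's molarity into its product before
occupancy is computed, conserving total molarity to floating precision. A
receptor with affinity only for the product gains response; one with
affinity only for the substrate loses it — the sign structure the enzyme
co-expression analysis (`ces1d_compare()`) is designed to detect.

### The default affinity code

`default_affinity()` fixes a deterministic 31 × 7 efficacy table for seven
structural analogs of acetophenone. Each entry is the sum of a
receptor-intrinsic *scaffold* component (fixed arithmetic pattern, up to
6.4 — all analogs present the same core scaffold, so scaffold-binding
receptors respond broadly) and an odorant-specific Gaussian *tuning bump*
(amplitude 5.8, width 3.3, odorant-specific centers 3, 4.8, 8.5, 12.5,
16.5, 20.5, 24.5 along the receptor index), capped at 8. EC50 co-varies
with efficacy, from \(10^{-6.5}\) mol/L for the strongest pairs to
\(10^{-4}\) for the weakest, so receptors recruited at low concentration
are a subset of those recruited at high concentration (nested activation
sets across a dilution series — a property the test suite checks at zero
noise). The closest pair of centers (3 and 4.8) makes two analogs nearly
twins, giving the cross-analog correlation spectrum a high end near 0.9
while distant analogs correlate weakly — the spread that makes
discrimination non-trivial but solvable.

## Analysis conventions

### Normalization and quantification

`normalize_trace()` divides each trace by its own cycle-1 value, then by
the per-cycle mean of the (equally initial-normalized) vector-control
wells of the same condition. Cycle 1 is exactly 1 afterwards; normalizing
any control well against the control set gives all ones; and multiplying a
trace and its controls by a common constant changes nothing (both are
tested as properties). Control aggregation is the arithmetic mean per
cycle.

The response scalar (`auc()`) is the plain, unweighted sum of normalized
values over cycles — no trapezoid rule, no time units — because that is
what "sum of normalized luminescence" means operationally for an
evenly-sampled read. Whether the resting level of 1 per cycle is
subtracted is genuinely ambiguous in how such quantities are reported, so
both modes exist: `auc_raw` (the sum) and `auc_baseline` (the sum minus
the cycle count), related by the exact identity
`auc_baseline = auc_raw − n_cycles`. The default is `auc_baseline`,
because it makes the vector-control row of a response matrix quantify to
≈ 0, matching how panel heat maps display the control. `peak()` (maximum
normalized value) is the alternative quantification; the acceptance script
measures the squared-Pearson concordance of the two on the same runs.

`build_response_matrix()` keeps every replicate value and reports per-cell
mean and s.e.m. = sd/√n with the sample (n − 1) standard deviation.

### Screening cascade

The dual-luciferase screen (`reporter_activity()`, `primary_rank()`,
`secondary_confirm()`, `screen_summary()`) normalizes firefly by Renilla
luminescence per well, ranks receptor–odorant pairs by fold change of mean
activity over the no-odor control, and confirms candidates by triplicate
two-sided t-tests (odor vs medium alone) at a small dose series,
uncorrected, with a direction filter so suppressions are not counted as
hits. Two open choices are made explicit and configurable: the primary
selection rule (top-k or fold ≥ threshold, default 2.0 — the underlying
screen reports ranking by fold change but no cutoff), and the t-test
flavor (Welch by default throughout the package, switchable to pooled;
only "two-sided t-test" is ever specified for such screens). Real screen
tallies of the form 813 tested → 279 candidates → 176 confirmed are
dataset-bound facts, reproducible here only structurally (a top-279 rule
marks exactly 279 candidates).

### Inference

- `one_way_anova()` / `f_critical()`: classical fixed-effects
  decomposition; seven odorants in triplicate give df (6, 14), whose 0.95
  F-quantile is 2.85 — the significance threshold quoted for such panels.
  The all-constant degenerate case reports F = 0, p = 1; zero residual
  variance with real separation reports F = ∞, p = 0.
- `tukey_hsd()`: studentized-range adjustment
  (`stats::TukeyHSD`), verified in the test suite against a Monte-Carlo
  studentized-range null and against the exact two-group identity
  q = t√2. `differential_activation_counts()` gates the per-receptor Tukey
  comparisons on a significant ANOVA, then counts receptors separating
  each odorant pair — the panel-level discriminability summary.
- `dunnett_onset()`: many-to-one comparisons of each cycle against the
  baseline cycle via the equicorrelated multivariate-t (correlation 1/2
  under the balanced design), computed by `multcomp`'s quasi-Monte-Carlo
  integration with a fixed seed for reproducibility. The earliest cycle
  with adjusted p < α and positive mean difference is the onset. The
  reported degrees of freedom are always the true ones for the data at
  hand.
- `bh_fdr()`: Benjamini–Hochberg step-up (`stats::p.adjust`), with the FDR
  family defined per odorant across the receptor panel in
  `ces1d_compare()` — matching how per-odorant "n receptors changed"
  counts are formed — rather than jointly across odorants.
- `regression_r2()`: ordinary least squares with \(R^2\) defined as the
  squared Pearson correlation throughout the package (including
  `auc_peak_concordance()` and `replicate_reproducibility()`). Constant y
  returns \(R^2 = 0\) with a warning; constant x is an error.

### Discrimination

Trials are the replicate-level 32-dimensional response vectors (3 per odor
per day); replicates are never averaged before classification, and
features are not rescaled (random forests are scale-free; LDA standardizes
internally through the pooled covariance). The random forest uses 500
trees and mtry = ⌊√32⌋ = 5; LDA uses `MASS::lda` with a small tolerance.
These hyperparameters are exposed, not claimed — only the algorithm
families are part of the modeled analysis. t-SNE (exact, perplexity 10,
Euclidean distances on raw response values) serves visualization only and
is run on train and test days combined, which also satisfies its
requirement of roughly 3 × perplexity + 1 points.

`evaluate_classifier()` enforces the cross-day protocol: test trials must
carry day labels disjoint from the training days, an empty test set is an
error, and accuracy is 100 · trace(confusion)/n. One error among 7 odors ×
3 test replicates is 20/21 = 95.2%, the benchmark figure for this design.

## What the generator does and does not emulate

Emulated: plate geometry (32 groups × 3 replicates = 96 wells per
condition), read schedule, monotone odor-evoked rises, vapor dilution
series \(10^0\)–\(10^{-8}\), replicate and day-to-day noise structure,
concentration-nested activation, toxicity attenuation at undiluted
exposure, esterase substrate→product conversion, and the
high-same-odor / lower-cross-analog correlation contrast.

Not emulated: the physical chemistry of vapor equilibration (Henry
constants, chamber dynamics, plasticware absorption), mechanistic cAMP
cascade dynamics, plate-position/edge effects, receptor expression
differences beyond a scalar gain, and any structure–activity relationship
(odorants are labels, not molecules). Passing tests therefore demonstrate
that the analysis chain is correct and well-calibrated on data with this
statistical structure — not that real plates meet these assumptions; in
particular, real day effects can be non-multiplicative and real noise can
be heteroscedastic in ways the generator does not produce.

## Numerical conventions and problem sizes

- Plate CSVs serialize numerics with 17 significant digits, so
  write→read→write round-trips are byte-identical and doubles survive
  exactly. Response-matrix condition keys render concentrations with
  `%.6g` to keep decade dilutions stable as strings.
- Hierarchical clustering (`hierarchical_cluster()`) is average linkage on
  Euclidean distances with rows pre-sorted by receptor label so ties
  resolve deterministically; the heat-map exporter falls back to a [0, 1]
  color scale for constant matrices and always writes the ordered matrix
  as a CSV sidecar.
- Degenerate statistical inputs are mapped to their limiting answers
  rather than NaN: identical ANOVA/Tukey groups give p = 1, numerically
  constant t-test groups give p = 1 (equal means) or 0 (separated means).
- Test and acceptance problem sizes are chosen to keep a full run in
  minutes on one core while leaving no asymptotic regime untested: 10 run
  pairs for reproducibility, 20 seeds × two simulated days for cross-day
  accuracy, a 2 × 10⁵-draw Monte-Carlo studentized-range oracle, 2 × 10³
  null ANOVAs for the type-I-error check, and 540 null t-tests for the
  screen's level. The EC50-recovery check uses a six-decade liquid dose
  series in triplicate and requires recovery within two-fold at default
  noise.

## Known limitations

- The Hill parameters of the affinity presets are generative conveniences;
  the package makes no claim that fitted EC50s from real vapor data are
  interpretable as dissolved-phase affinities (the partition coefficient
  is not identified by the assay).
- The toxicity model is a single scalar per odorant; it cannot produce the
  partial, receptor-dependent attenuation real cytotoxicity might cause.
- `dunnett_onset()` assumes a balanced design when it relies on the
  equal-correlation form; strongly unbalanced cycle replication should use
  smaller claims.
- The screening cascade models no plate-layout effects, so its
  false-positive calibration (≈ α per dose) is optimistic for real plates
  with edge effects.
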