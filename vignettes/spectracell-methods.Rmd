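---
title: "Multispectral autofluorescence cell classification: models and methods"
author: "spectracell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral autofluorescence cell classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Label-free multispectral autofluorescence microscopy images cells across many
excitation/emission band combinations ("spectral channels"). Native
fluorophores — NAD(P)H, flavins, collagen, tryptophan — glow differently
depending on a cell's metabolic and structural state, so the per-cell spectral
signature can discriminate biological conditions. spectracell implements the
full quantitative chain for such data, developed around urinary exfoliated
proximal tubule cells (PTCs) from kidney transplant recipients, where the goal
is to distinguish three histopathological causes of graft dysfunction — acute
tubular necrosis (ATN), graft rejection, and interstitial fibrosis with
tubular atrophy (IFTA) — without a biopsy:

1. acquisition data model and IO (`data_block`, TIFF + JSON manifests),
2. a synthetic multispectral image generator with known ground truth,
3. image preparation and reference-fluid calibration,
4. per-cell spectral feature extraction,
5. entropy-based feature selection,
6. cross-validated binary classification with ROC/AUC summaries.

Because raw patient images are not publicly available, the synthetic generator
is a first-class component: every downstream stage is validated against
generated data whose true abundances, illumination field and informative
channels are known exactly.

## Channel model

A channel is an excitation band center (narrowband LED, ±5 nm) plus an
emission window. The instrument class this package targets acquires 34
channels spanning excitation 340–510 nm and emission 420–650 nm. The exact
band list of the original instrument is not published, so
`default_channel_table()` constructs a documented stand-in: eight excitation
centers {340, 365, 390, 415, 440, 465, 490, 510} nm crossed with five
contiguous emission windows ([420,465], [466,511], [512,557], [558,603],
[604,650]), keeping pairs whose emission window lies strictly above the
excitation center. Exactly 34 pairs survive, honoring the published count and
ranges. A user-supplied table (CSV/JSON, via `read_channel_table()`) replaces
the default everywhere.

## Synthetic data generator

The generator emulates everything upstream of feature extraction. Its
defaults are the study conditions the package was built around: 3 groups × 10
patients × 5–7 cells (≈160 cells), 34 channels.

**Spectral model.** Each fluorophore has Gaussian excitation and emission
profiles; the response of fluorophore $f$ in channel $c$ is separable:

$$ r_{fc} \;=\; B_f \exp\!\Big(-\frac{(x_c-\mu^x_f)^2}{2(\sigma^x_f)^2}\Big)\;
   \big[\Phi(e^{hi}_c;\mu^m_f,\sigma^m_f)-\Phi(e^{lo}_c;\mu^m_f,\sigma^m_f)\big], $$

with $x_c$ the excitation center and $[e^{lo}_c,e^{hi}_c]$ the emission
window. This is deliberately minimal — no vibronic structure — but it is
sufficient to create channel-correlated, group-separable signals, which is
what the pipeline consumes. The default panel is an NADH-like (ex 350/σ25,
em 460/σ35) and a FAD-like (ex 450/σ25, em 530/σ30) species; group
differences are multiplicative abundance shifts of these two (rejection-like
groups raised in NADH-like, fibrosis-like groups raised in FAD-like).

**Image model.** Cells are non-overlapping ellipses (semi-axes 8–16 px,
rejection-sampled placement) with a smooth multiplicative intra-cell texture
(SD 10%) so SD and skewness features are non-degenerate. The expected pixel
value in channel $c$ is

$$ \lambda_c(x,y) \;=\; I(x,y)\,\Big[\,t(x,y)\,G \textstyle\sum_f A_{kf}\,
   r_{fc} + b\Big], $$

where $I$ is a radial quadratic illumination field (default 30% corner
falloff, identical across channels), $t$ the texture, $G$ the photon gain,
$A_{kf}$ the cell's abundances and $b$ the background level (default 20
counts). The background sits inside the illumination factor: background
fluorescence is excited by the same uneven illumination as the cells, and the
water reference frame used for subtraction carries that same field. Observed
counts are Poisson($\lambda$), clipped to the full well (65535), after which
dead pixels are set to 0 and saturated pixels to the full well (defaults
5×10⁻⁴ each). Per-cell abundances are log-normal around the group mean
(CV 20%) times a per-patient log-normal multiplier (σ = 0.15 on the log
scale), which creates the within-patient correlation real cohorts have — the
ingredient that makes leakage measurable. All randomness is fixed by the
config seed.

**Reference frames.** Water frames are Poisson(background × illumination);
calibration-fluid frames add `gain × R_c` where $R_c$ is the simulated
spectrofluorometer spectrum of the fixed NADH+FAD mixture (molar ratio
30:18). $R_c$ carries a broadband pedestal of 5% of its peak: the real fluid
fluoresces measurably in every channel, and a pure two-Gaussian model would
leave far-off-resonance channels uncalibratable. Reference frames are bright
(default 500 counts per reference unit) because real reference acquisitions
are long-exposure, high-SNR images.

**What the generator does not model** (and hence what passing tests do not
show about real data): optical PSF and channel-dependent blur, photobleaching
kinetics, cell-shape irregularity and occlusion, channel-dependent
illumination fields, segmentation error (masks are exact by construction),
and any real biochemical relationship between diagnosis groups and
fluorophore abundances — the group shifts are plausible but invented.
Synthetic fields default to 256×256 px (the tests use 96–128 px): per-cell
statistics depend on pixels per cell, not field area, so the camera's native
1024×1024 frame adds nothing but runtime for cohort-level validation.

## Image preparation and calibration

Raw frames are prepared as: 3×3 median filter (restores isolated dead and
saturated pixels) → Gaussian smoothing (σ = 1 px) → background subtraction →
flat-field division → scaling to reference units. The composition order
treats sensor defects first and keeps the scale factor last; it is
configurable. From the reference frames, `fit_calibration()` derives per
channel:

* **background** $b_c(x,y)$: the smoothed water frame, kept per-pixel so the
  background's own illumination pattern is subtracted along with it;
* **flat field** $F_c(x,y)$: smoothed (calibration − water) excess divided by
  its spatial mean — a unit-mean image of the illumination pattern;
* **scale** $k_c$: spectrofluorometer reference value divided by the mean
  excess, anchoring corrected intensities to reference units. A channel whose
  calibration frame does not exceed its background is reported as
  uncalibratable by name.

Calibrated intensity is $\max(0, s_c - b_c)/F_c \times k_c$ with $s_c$ the
smoothed cell frame. Numerical choices: the clamp to zero happens after
background subtraction (fluorescence is physically nonnegative; the clamp
breaks strict linearity only at the noise floor, and the linearity test
therefore works above background); the flat field is floored at 10⁻³ so
division stays defined in photon-starved corners; reference frames are
smoothed much more strongly (σ = 8 px) than cell frames — the fields they
estimate vary over tens of pixels, so heavy smoothing suppresses reference
shot noise without biasing cell intensities. Smoothing uses replicate-edge
padding; the few border pixels are the least accurate part of the flat field.
Calibrating an already-calibrated block is an error, not a no-op.

On synthetic cohorts the fitted flat field correlates > 0.99 with the true
illumination field and calibrated cell-mean spectra have cosine similarity
> 0.98 with the true mixed fluorophore spectra (both recomputed by
`scripts/acceptance.R`).

## Per-cell features

For each cell (mask) and channel: the pixel mean, the population SD
(divisor n), and the Fisher–Pearson skewness $g_1 = m_3/m_2^{3/2}$ (population
central moments; defined as 0 when $m_2 = 0$), plus every ordered pair ratio
of channel means, regularized as $(\bar x_i + \varepsilon)/(\bar x_j +
\varepsilon)$ with $\varepsilon$ = 10⁻⁶ × the block's global mean intensity
(recorded in the table's metadata). Population rather than sample moments
match the plain "pixel SD" reading; the convention is documented so deposited
tables can be compared under either. Ratios are directional (both i/j and
j/i) since selection may prefer either orientation. For $C$ channels the
catalog holds $3C + C(C-1)$ features — 1224 for 34 channels. The catalog is
explicit and configurable (`feature_catalog()`); the four stated families are
the default and no attempt is made to reverse-engineer any larger published
feature count from an unpublished composition.

## Entropy-based feature selection

"Entropy-based" is implemented as threshold information gain, the standard
entropy criterion for continuous features: for feature $x$ and binary labels
$Y$,

$$ IG(x) = \max_{t}\; H(Y) - \tfrac{n_{\le t}}{n} H(Y \mid x \le t)
   - \tfrac{n_{> t}}{n} H(Y \mid x > t), $$

maximized exhaustively over midpoints between consecutive distinct sorted
values. This criterion is invariant to strictly increasing transforms of the
feature and bounded by $H(Y)$; both properties are asserted in the tests, and
the implementation is checked exactly against a brute-force enumeration
oracle. An equal-frequency multi-bin discretization is available as an
alternative (`discretization = "equalfreq"`).

`rank_and_select()` ranks by gain (ties broken lexicographically by name, so
runs are reproducible) and then greedily admits features whose absolute
Spearman correlation with every already-admitted feature is ≤ 0.95, stopping
at k = 8 — a compact set guarding against overfitting at ~100-cell sample
sizes. Note that when one fluorophore drives several channels, those channel
means are near-perfectly correlated and the redundancy filter will admit only
one of them; recovery of *channels* is therefore a property of the ranking,
not of the filtered set, and that is how the planted-effect test reads it.

**Placement matters.** By default selection is re-run inside each training
fold (`selection_mode = "fold"`), so held-out cells never influence the
feature set. A `"global"` mode selects once on all cells before
cross-validation — this reproduces the common practice of publishing one
fixed feature set per comparison, but it lets test cells leak into selection
and its AUCs are optimistically biased; results carry an explicit
`selection_bias_note`.

## Cross-validated classification

Binary comparisons only (all three pairwise comparisons for a three-group
cohort). Folds are stratified by class at the cell level (default, mirroring
per-cell splitting) or grouped by patient (`grouping = "PATIENT"`, every cell
of a patient shares a fold). Cells from one patient are correlated, so
cell-level splitting overstates patient-level generalization; the package
reproduces the cell-level design and recommends the patient-grouped one — the
leakage acceptance test demonstrates the inflation directly (cell-level CV
with global selection beats patient-grouped CV on a null cohort with strong
patient effects in ≥ 8/10 seeds).

Method 1 is a random forest (500 trees, √p candidates per split, unlimited
depth, seeded). Method 2 — exploring alternative classifiers with an
automated model-selection framework — is a pluggable score-backend interface
(`register_backend()`); the package ships a logistic baseline and degrades
gracefully ("backend unavailable") when a requested backend is not
registered, so no heavyweight third-party framework is a dependency.

AUC is the rank (Mann–Whitney) statistic with ties counted ½, identical to
the trapezoidal area under the step ROC; it is verified against explicit
pair counting and against an established ROC implementation. Per-fold AUCs
are summarized as mean, variance, and a 95% CI of mean ± t₀.₉₇₅,₄·√(var/5);
the t form is the documented default (a normal-approximation alternative
exists) since published ±-style intervals rarely state their formula. Pooled
ROC curves are emitted for plotting only; all metrics use per-fold AUCs.

## Validation design

The test suite and `scripts/acceptance.R` validate the pipeline end-to-end at
deliberately chosen problem sizes (96–128 px fields, 2–10 patients per group,
fixed seeds; the acceptance script derives every seed from `--seed`):

* exact-oracle checks: information gain vs exhaustive enumeration, AUC vs
  pair counting, entropy closed forms, the feature-count law;
* calibration recovery: flat-field correlation > 0.99, cell-spectrum cosine
  similarity > 0.98 on synthetic cohorts;
* planted-effect recovery: a narrow marker fluorophore doubled between
  groups makes exactly three channels informative (>10% relative spread);
  their MEAN features must reach the top-8 of the gain ranking in ≥ 9/10
  seeds;
* the analytic benchmark: one feature shifted by δ = 2 gives a closed-form
  AUC of Φ(δ/√2) ≈ 0.921; five replicate 60+60 cohorts are pooled and the
  cross-validated mean AUC (logistic backend, whose scores are monotone in
  the feature) must lie inside the fold-derived 95% CI;
* null calibration: identically-parameterized groups with no patient effect
  (cells exchangeable — with patient effects, cell-level CV is *not* a null,
  which is exactly what the leakage test shows) classify within [0.35, 0.65],
  and label permutation gives mean AUC 0.5 ± 0.1 over 20 seeds;
* byte-level determinism of the full pipeline under a fixed seed.

## Known limitations

* The default channel table is a stand-in with the published count and
  ranges, not the instrument's actual band list.
* Calibration implements per-channel background/flat-field/scale alignment
  only; no spectral-response correction across channels, no registration
  (channels are assumed co-registered), no denoising beyond median+Gaussian.
* Spectral unmixing of calibrated spectra into fluorophore abundances is out
  of scope (a natural next step the feature tables would support).
* The generator's group effects, variance components, and defect rates are
  stated defaults, not values fitted to real cohorts; the real
  between-patient vs within-patient variance ratio is unknown.
* Multi-class classification is not implemented; the pipeline performs
  binary comparisons only.
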