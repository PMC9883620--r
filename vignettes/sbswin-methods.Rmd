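---
title: "Methods: speech tracking, behavior, and directed connectivity in sbswin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speech tracking, behavior, and directed connectivity in sbswin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the synthetic data it validates
itself on, and the numerical and design choices behind both.

## 1. The measurement model

### Linguistic rate bands

Speech is treated as a hierarchy of quasi-rhythmic units. For each story, a
tier's unit rate is its interval count divided by the tier span (last offset
minus first onset); the pass band of a linguistic timescale is the minimum
and maximum of these per-story rates across the corpus (`unit_rates()`,
`derive_bands()`). This makes the bands exact, permutation-invariant
statistics of the annotations. Whether "rate" should instead exclude pauses
is an open question of the source procedure; the package uses total tier
span, which is the simpler and reproducible reading (the alternative only
shifts band edges slightly and can be emulated by supplying pause-free
annotations). The reference corpus values used as defaults elsewhere are
phrase 0.2–2 Hz, word 2.4–4.9 Hz, syllable 3.4–6.5 Hz, phoneme 8.4–14.1 Hz
(`default_rate_bands()`); note that word and syllable bands genuinely
overlap.

### Envelope and filtering

The amplitude envelope is the magnitude of the analytic signal of the
broadband waveform, low-passed at 30 Hz with a 4th-order zero-phase
Butterworth and decimated to the neural sampling rate (`extract_envelope()`).
The envelope method is a design choice (the upstream description is silent);
analytic-magnitude extraction is the standard in envelope-tracking work, and
the per-band filtering downstream dominates the result anyway.

All band-pass filtering uses the squared magnitude response of the digital
4th-order Butterworth applied in the frequency domain after odd reflective
padding (`bandpass_zero_phase()`). This realizes exactly the transfer
function of forward–backward time-domain filtering — zero net phase, squared
magnitude — while operating on whole voxel matrices at once; agreement with
a sample-domain forward–backward implementation is ~1e-7 away from the
edges. The analytic representation (`analytic_bandpass()`) is obtained in
the same FFT pass.

### Speech-brain synchrony as Gaussian-copula MI

Cortical responses trail the stimulus; the package shifts the brain signal
by a base delay of 120 ms (24 samples at 200 Hz, integer shift;
`analytic_delay()`). Residual delay and phase variation are absorbed by
modeling the brain signal as two series — the real and imaginary parts of
the analytic band signal — so that, e.g., at 4 Hz a quarter cycle around the
base delay is covered.

Synchrony is mutual information between the 1-D band-passed envelope and the
2-D analytic brain signal. Each margin is rank-transformed to standard
normal quantiles, $\Phi^{-1}((r - 0.5)/n)$ (`copula_gauss()`; ties broken by
stable first-occurrence order — deterministic, unlike random tie jitter),
and the Gaussian closed form is evaluated on the joint correlation matrix:

$$ I = \tfrac{1}{2}\log_2\frac{\det R_{xx}\,\det R_{yy}}{\det R}. $$

The analytic small-sample bias of the plug-in Gaussian estimator (a digamma
expansion over the marginal and joint dimensions) is subtracted by default
(`mi_gaussian_bits(..., bias_correct = TRUE)`); the real-vs-surrogate
contrast cancels residual bias anyway, but correction keeps absolute values
interpretable. Stories are filtered independently (avoiding cross-story
filter transients), concatenated after alignment, and copula-transformed as
one sample (`sbs_map()`).

One caution the tests encode: band-limited series are strongly
autocorrelated, so the *effective* sample size is roughly the sample count
times the relative bandwidth. Voxelwise null MI therefore fluctuates beyond
the iid-sample bound even after bias correction; inference must come from
the surrogate contrast, never from absolute MI.

### Surrogates and cluster inference

Chance-level synchrony is estimated by pairing each recording with
mismatched stories. Each of the (default 50) randomizations is a
*derangement* of the story labels — no pairing is even partially matched —
with the longer member of a mismatched pair trimmed head-aligned
(`surrogate_sbs()`). The 50 maps are averaged into one surrogate map per
subject/voxel/band.

Real vs surrogate maps are compared by voxelwise paired t-tests
(`paired_t_map()`), thresholded at one-tailed P ≤ 0.001 (the direction is
real > surrogate; excess MI is one-sided by construction), and surviving
voxels are grouped by 6-connectivity (faces only; 18/26 available) with
summed t per cluster (`find_clusters()`). The permutation null sign-flips
each subject's difference map, with flips constant within family blocks —
the exchangeable null for paired designs with related subjects (the
"subject label swapping" of the source procedure reduces to exactly this for
a paired contrast). Each permutation records its top-3 cluster sums and the
observed k-th largest cluster is compared with the null distribution of
k-th largest sums (`cluster_perm_test()`), the step-down max-statistic
convention.

### Behavior

Word-in-noise raw scores convert to a 50% SNR threshold as
`26 dB − 0.8 × raw` (`win_threshold()`); lower is better. Thresholds are
rank-inverse-normal transformed and standardized (`rank_int()`), with
missing values imputed by the median of observed scores *before* the
transform (so the transform sees a complete vector; median because it is
robust and the reference cohort had a single missing value). Age is
regressed out of the transformed score and of every voxel's SBS value
(`deconfound()`), in that order: impute → transform → deconfound.

Voxelwise Pearson correlations between deconfounded SBS and WiN′ are
computed over the SBS-significant voxels only; the null permutes subject
labels of WiN′, and a voxel is significant when its |ρ| exceeds the 95th
percentile of that voxel's null |ρ| (`sbs_win_corr_map()`). The null is
voxelwise, not pooled (the pooled alternative changes little on synthetic
data but the voxelwise reading is the conservative interpretation of the
procedure); two-sided by default with a one-sided-negative option, since all
reference effects are negative. Significant components smaller than 5
contiguous voxels are discarded (`prune_clusters()`, boundary: 4 removed,
5 kept).

### Directed connectivity

Parcel series are first principal components of parcel voxels, sign-fixed
(dominant loading positive — a convention independent of the SVD solver's
internal sign choice) and unit-scaled (`first_pc_series()`). Collinear
parcels are merged by k-means on the rows of the parcel correlation matrix
(default k = 30), with voxel-union re-extraction (`merge_collinear()`); the
feature space for "most strongly correlated neighbors" is the correlation
profile, the natural reading of the under-specified source step. Source
leakage is removed by symmetric orthogonalization: the closest (Frobenius)
set of mutually orthogonal, zero-mean series to the input, found by
iterating the closest-orthonormal-matrix (Procrustes) step with per-series
scaling (`symmetric_orthogonalize()`); rank-deficient input is an explicit
failure — that is precisely why parcels are merged first.

Directed influence is bivariate spectral Granger causality per registered
edge: a VAR fit by least squares with BIC order selection (cap 20 at 200 Hz,
covering delays up to 100 ms), then the Geweke decomposition on the integer
1–100 Hz grid,

$$ F_{x\to y}(f) = \ln\frac{S_{yy}(f)}{S_{yy}(f) - (\Sigma_{xx} -
\Sigma_{xy}^2/\Sigma_{yy})\,|H_{yx}(f)|^2}, $$

clamped at zero against numerical negatives (`spectral_gc()`, `edge_gc()`).
Bivariate rather than conditional GC is used because edges are modeled
pairwise; parametric VAR rather than nonparametric factorization because it
is deterministic and closed-form checkable (the frequency average of the
spectral measure equals the time-domain innovation-variance ratio on stable
VARs, e.g. ln 1.25 for a unit-innovation VAR(1) with coupling 0.5). The
registered network (`default_edge_set()`) has 24 edges: 5 frontal parcels
per hemisphere × top-down and bottom-up × 2 hemispheres, plus 4
auditory–temporal edges.

### Linkage and mediation

Per edge, the 100-bin connectivity spectrum is reduced by PCA over
frequency to 3 subject-level scores (warning, not failure, below 98%
variance explained; `reduce_spectra()`). Each edge's features are
canonically correlated with the standardized pair (SBS score, WiN′)
(`cca_fit()`, built on the QR-based canonical decomposition); mode
significance is the permutation rank of the first canonical correlation
under outcome-row permutation, Benjamini–Hochberg corrected across the
registered tests (`cca_perm_fdr()`). Post-hoc, canonical scores are
correlated with SBS, WiN′ and the fully resolved spectrum with Fisher-z 95%
CIs (`posthoc_profile()`).

Mediation (`mediate()`) is the OLS decomposition: a (predictor→mediator),
b and c′ (outcome on predictor + mediator), c (total). The mediator is
operationalized as the CCA-weighted sum of the top-down edge's features,
recomputed per subject. Sobel's z uses
$ab/\sqrt{a^2 SE_b^2 + b^2 SE_a^2}$; the complementary percentile bootstrap
(default 1,000 replicates; BCa deliberately not used, matching common
bootstrap-CI practice) resamples subjects. For a single mediator on complete
data the product (a·b) and difference (c − c′) indirect effects coincide to
machine precision — the package asserts this identity; any printed
discrepancy between the two in rounded reports is rounding, not method.

## 2. The synthetic ground truth

The synthetic module exists so every stage can be validated with known
answers and no data downloads; it emulates the *structure* of the real
problem, not its biology.

* **Envelopes** (`gen_envelope()`): renewal event trains with
  gamma-distributed inter-event intervals (mean 1/rate, CV `jitter_cv`)
  convolved with a unit-area Hann kernel. Gamma intervals give tunable
  regularity between periodic (CV 0) and Poisson-like (CV 1). The default
  CV of 0.2 is chosen so the generator's contract — a modulation spectrum
  reliably peaking at the syllable rate, mirroring the single broad theta
  peak of natural speech — holds with margin at story durations of tens of
  seconds.
* **Annotations** (`gen_annotations()`): four nested tiers built from the
  event train by deterministic (or Poisson-jittered) grouping.
* **Recordings** (`gen_subject_recording()`): a 10×10×10 grid with an
  ellipsoidal in-brain mask (~500 voxels — a desk-scale stand-in for a
  beamformed source grid of several thousand). Coupled voxels carry
  `trait × rho_c` times the band-limited, 120 ms-delayed envelope plus 1/f
  background noise (spectral exponent 1: flat noise would make detection
  unrealistically easy); uncoupled voxels are pure 1/f noise. The delay is a
  circular shift, so cross-correlation recovers it exactly. Subject traits
  are uniform on [0, 1] — the simplest model producing inter-subject SBS
  variance, whose real-data counterpart is not characterized numerically
  anywhere we could calibrate to.
* **Behavior** (`gen_behavior()`): raw scores rise linearly with the trait
  plus Gaussian noise, are rounded and clamped to the instrument range
  (0–40), and converted to thresholds. Defaults (baseline 20.75, slope 12,
  noise SD 6) center the cohort near the reference mean threshold of 4.6 dB
  and plant a trait–threshold correlation of about −0.5.
* **Family blocks** (`make_family_blocks()`): 20% of subjects in 2-member
  blocks, the rest singletons — a minimal stand-in for twin structure whose
  exact real composition is unpublished.
* **Networks** (`var_network_spec()`, `gen_var_parcels()`): stable VARs
  (companion spectral radius < 1 enforced) with known coefficients and
  innovation covariance; the analytic spectral matrix (`var_spectrum()`) is
  the ground truth for the GC estimators.

What the generator does **not** emulate: acoustics (no formants or phones —
envelopes only), sensor-space MEG and leadfields, volume conduction between
voxels (noise is voxelwise independent; leakage correction is therefore
validated on constructed collinear inputs, not on the grid simulation), and
nonstationarity. Passing tests demonstrate that the estimators recover what
was planted under these idealized conditions; they do not certify
performance on real MEG.

## 3. The end-to-end reference study

`pipeline_config()` defines a deliberately small, fully seeded study that
the integration tests rerun across seeds: 48 subjects, 4 stories × 15 s at
200 Hz, an 8×8×8 grid (~125 masked voxels) with an 18-voxel coupled patch at
`rho_c = 0.6`, 10 surrogate randomizations, 200 cluster permutations, 500
correlation/CCA permutations, 500 bootstrap replicates, and a five-node
directed network whose left premotor→temporal edge coefficient is
`0.08 + 0.35 × trait + N(0, 0.15)`.

These sizes and effects were fixed by an a priori power analysis of the
planted-effect submodels, not by the upstream study's (unknown) effect
sizes: at roughly half the reference cohort, recovering a behavioral
correlation with the same reliability as −0.4 at n = 53 requires planting
about −0.6, and a mediated path only becomes recoverable when the mediator
carries substantial trait-independent variance (hence the wide top-down
coefficient noise and a behavioral drive weighted 0.7 toward the top-down
phenotype, 0.3 toward the raw trait). With these conditions the full chain —
significant SBS cluster, surviving negative correlation voxels,
FDR-significant canonical mode on the planted edge, bootstrap CI excluding
zero — is jointly recovered in essentially every seeded run; sub-pieces of
the chain are additionally validated at their own scales (oracle identities
at n = 10⁴, FWER calibration on 200 null simulations of a 12³ grid, CCA and
mediation recovery at n = 500).

Per-stage sub-seeds are derived deterministically from the master seed and
the stage name (`derive_seed()`), so reruns of an identical configuration
are byte-identical (manifest hashes are compared in the tests).

## 4. Numerical choices, degenerate inputs, limitations

* Copula ties: stable first-occurrence order; quantized synthetic scores can
  tie, and reproducibility was preferred over randomized tie-breaking.
* Surrogate trimming: head-aligned, first `min(len)` samples.
* Zero-variance voxels in the paired contrast: t = 0 when the differences
  are identically zero, flagged `NA` when variance is zero with nonzero
  mean.
* `find_clusters` with no suprathreshold voxels returns an empty set (not an
  error); empty correlation masks warn and no-op.
* Sign conventions: PC scores fix the dominant loading positive; globally
  negated data negates the score (no deterministic linear score can be
  invariant to a global sign flip).
* Orthogonalization iterates to a relative Frobenius tolerance of 1e-12 and
  refuses rank-deficient input rather than regularizing it.
* VAR stability is enforced both when specifying networks and after fitting;
  spectral GC clamps small negative numerical values at zero.
* The permutation p-value convention is (1 + exceedances)/(n_perm + 1),
  guaranteeing validity at finite permutation counts.
* Bootstrap CIs are percentile, not BCa; with heavily skewed indirect-effect
  distributions at small n they can under-cover slightly.
* The base delay is a single integer shift; sub-sample residuals and
  frequency-dependent delays are absorbed by the bivariate analytic
  representation, not modeled.
* HDF5 and WAV containers are not used; stage outputs persist as
  TSV/CSV/JSON (plus a plain-text config format with an exact round trip).
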