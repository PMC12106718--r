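---
title: "Physiological coupling topographies and family-aware CCA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physiological coupling topographies and family-aware CCA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physiocca)
```

# The scientific problem

Slow respiratory dynamics — breath-to-breath changes in depth and rate,
paced at roughly 0.03 Hz by end-tidal CO~2~ fluctuations — modulate
cerebral blood flow and leave a strong imprint on the resting-state fMRI
global signal (GS), the mean BOLD time series across the brain. The
conventional view treats this imprint as nuisance. physiocca implements
the opposing analysis: quantify *where* in the brain respiratory (and
cardiac) measures couple to BOLD, ask how consistent that coupling
topography is with the GS topography across people, and test whether the
individual differences it carries predict behavior — with inference that
respects the twin/family structure typical of large cohorts.

The pipeline is organized as: physiological trace preprocessing →
frame-grid measures (RVT, ENV, RV, HR) → lag-optimized Fisher-z coupling
topographies (GSCORR, RVTCORR, HRCORR, …) → per-ROI intraclass
correlation between topography pairs → behavioral screening and
component reduction → canonical correlation analysis (CCA) with
family-blocked permutation, max-statistic back-projection, and
family-aware 10-fold cross-validation. A synthetic-cohort generator with
complete ground truth makes every stage testable end to end.

# Physiological preprocessing

**Respiratory belt.** The fixed cleaning order is: z-score → linear
detrend → local outlier replacement → zero-phase low-pass → z-score.
Outliers are samples more than 3 scaled median absolute deviations
(scale 1.4826, the Gaussian-consistent convention of MATLAB's
`filloutliers`) from the local median in a centered 0.3 s window — 120
samples at the 400 Hz recording rate — and are replaced by linear
interpolation. The low-pass is a second-order Butterworth at 5 Hz
applied forward-backward. Zero-phase filtering is a deliberate choice:
any phase shift here would bias the lag search downstream. To keep
boundary transients from ringing into the trace (and leaking into the
global z-score), the signal is padded by odd reflection (about 3 s)
before `filtfilt` and trimmed afterwards; this keeps re-cleaning an
already-clean trace a no-op on the interior to well below 1e-6.

**Respiration measures.** RVT (respiration volume per time) is the
difference between the upper and lower signal envelopes: inspiratory
peaks and expiratory troughs are detected with a minimum spacing of 1 s
(breathing stays below 1 Hz) and the constraint that, on the zero-mean
cleaned trace, peaks lie above zero and troughs below — which rejects
ripple extrema on the wrong side of the baseline — then linearly
interpolated with edges clamped to the nearest extremum. RVT is
non-negative by construction (clamped at 0 where interpolation crosses).
ENV is the sliding-window maximum of the rectified trace over 10 s; the
phrase "envelope over a window" is ambiguous, so a Hilbert-magnitude
variant sits behind `envelope_method = "hilbert"`. RV is the
sliding-window standard deviation over 6 s. All sliding windows shrink
at the boundaries rather than padding, so no data are fabricated.

**Pulse oximetry.** Cardiac traces are z-scored and band-pass filtered
0.3–10 Hz (second-order Butterworth, zero-phase). Pulse peaks are
detected with a minimum spacing of 0.3 s and a height floor (30% of the
99th percentile) so filter ringing between beats is ignored;
instantaneous heart rate is 60/IBI in bpm, assigned to interval
midpoints, cleaned of beat-level outliers (3 scaled MADs from the local
30 s median, plus a configurable 30–180 bpm physiological range) and
interpolated to the sample grid. The outlier pass operates on the
per-beat rate sequence *before* gridding — equivalent to, and better
conditioned than, filtering the interpolated series.

**Frame gridding.** Measures are brought to the fMRI grid by block
averaging within each TR window (288 samples per frame at 400 Hz and
TR = 0.72 s), matching the temporal-averaging convention of the
acquisition.

# Topographies and the lag search

The global signal is the unweighted ROI mean per frame. All series are
truncated by 10 frames at each end before correlation to discard
equilibration and filter transients.

Physiological measures couple to BOLD with a hemodynamic delay, so each
measure is aligned to the GS by cross-correlation over integer-frame
lags spanning ±72 s. "Shifted backward by lag τ" means the physiological
sample at `t − τ` is paired with BOLD at `t`. Correlations are computed
on the overlapping segment only — zero-padding would bias the estimate
toward small lags — averaged across runs within participant and then
across participants, and the lag with the largest absolute mean
correlation wins; ties break toward the smaller |lag|. A negative mean
correlation at the winning lag sets `flip = TRUE`: the measure couples
inverted, as RVT does (deeper breathing → lower CO~2~ → constriction →
BOLD decrease). With TR = 0.72 s the canonical respiratory delay of 16
frames corresponds to 11.5 s. Individually optimized lags use the same
machinery restricted to one participant.

A topography is then the per-ROI Pearson correlation with the (flipped,
lag-shifted) reference, Fisher z-transformed with |r| clipped at
1 − 1e-7 (an exact r = ±1 would otherwise produce an infinite z and
break run averaging), averaged across runs. Zero-variance ROIs become
`NA` with a warning rather than poisoning the average.

One caveat the synthetic experiments expose: when breathing-depth
modulation is close to sinusoidal, the cross-correlation profile has a
mirror peak at the true lag minus half the modulation period with
opposite sign. Group averaging over participants with heterogeneous
modulation frequencies suppresses it, but in small cohorts the mirror
can occasionally win; the lag-plus-flip pair it returns is almost
equivalent in practice, and downstream code accepts signed lags.

# Spatial consistency: two-way random-effects ICC

For each ROI, the two topography values across n participants form an
n × 2 table (rows = participants, columns = measures). From the two-way
ANOVA mean squares, the intraclass correlation is
σ~r~² / (σ~r~² + σ~e~²) with σ~r~² = MSR − MSE and σ~e~² = MSE. This
row-variance estimate omits the conventional division of MSR − MSE by
the number of measures; the package implements this form verbatim as the
default (`variant = "paper"`) — algebraically (MSR − MSE)/MSR — and
offers the standard Shrout–Fleiss ICC(C,1) and ICC(A,1) alongside, so
the discrepancy is visible rather than silently resolved. Negative
σ~r~² estimates are floored at zero; zero-total-variance ROIs come back
`NA` with a warning. With multiple sessions, ICC is computed per session
pairing and averaged. Network comparison Fisher-transforms the per-ROI
ICC (same clipping as topographies), groups by atlas label, excludes
networks with fewer than two ROIs, and applies a Kruskal–Wallis rank
test.

# Behavioral preparation

**Screening.** A measure is dropped when any value lies more than 100
standard deviations above its median, when fewer than half its values
are valid, or when its modal value accounts for more than 95% of the
non-missing entries; listed confounds and unwanted measures are removed
with their own reason codes, and the exclusion report is exhaustive
(kept + dropped = input). The SD rule is implemented above-only, as
worded, with a symmetric option behind a flag. Note that with the
full-sample SD a single outlier among n values is bounded near √n SDs,
so the rule only bites in large samples or with several extreme values —
a property of the rule as printed, which we preserve.

**Deconfounding.** Per variable: z-score on the non-missing entries,
OLS residual against an intercept plus the confounds fitted on those
rows, then rescaling of the residual to unit variance — which makes the
operation exactly idempotent. Missing cells stay missing. Confound
removal happens *before* covariance completion, following the stated
order ("after normalizing and removing the confounds"). A rank-deficient
confound matrix is an error that names the collinear columns.

**Covariance completion and reduction.** Missing behavioral cells are
handled without imputation at the reduction step: the participants ×
participants covariance of the normalized, deconfounded measures is
estimated pairwise — entry (i, j) from the measures both participants
have — and projected onto the nearest positive semidefinite matrix by
symmetrizing, eigendecomposing, and clipping eigenvalues below
1e-10 × the largest (the fixed point of the symmetric-polar nearest-SPD
construction for symmetric input; idempotent). The top k eigenvectors
scaled by √eigenvalue are the component scores. With complete data this
reproduces the span of ordinary PCA scores exactly, which is the test
oracle. Topographies, which have no missing entries after validation,
are column-standardized and reduced by SVD, keeping the right-singular
basis for out-of-sample projection. For behavioral components —
eigenvectors of a participant-space matrix, which have no natural
projector for new participants — the package retains a regression basis
(pseudo-inverse of the zero-imputed training data onto the training
scores); held-out participants are standardized with training
parameters, zero-imputed, and pushed through it.

The study-scale default is k = 100 components per block; tests and the
acceptance script use k = 10 on cohorts of a few hundred participants,
where 100 components would be rank-degenerate.

# CCA and inference

The canonical decomposition is computed by SVD whitening: each centered
block X is factored X = UDVᵀ (rank-checked; a deficient block is an
error advising smaller k), and the canonical correlations are the
singular values of U~x~ᵀU~y~, clipped into [0, 1]. Canonical scores have
unit variance and their pairwise correlation equals the canonical
correlation — an invariant the tests assert. `stats::cancor` serves as
an independent cross-check in the test suite, never as the
implementation, which needs the whitened form for the permutation fast
path and out-of-sample scoring.

**Family-blocked permutation.** One block's participant order is
shuffled under exchangeability blocks: whole families exchange only with
families of identical size, member order within a family fixed.
Singleton-only rosters reduce exactly to unrestricted permutation; if no
two families share a size the test falls back to unrestricted with a
loud warning. Because a row permutation changes neither a block's
column means nor its covariance, whitening is computed once and each of
the 5000 permutations costs one small cross-product and SVD. Every
permutation records the *first* canonical correlation, so each observed
mode is compared against a null of maxima; p-values carry the add-one
correction (1 + #{null ≥ r}) / (1 + n~perm~), which prevents exact
zeros, and significance additionally requires exceeding the null's 95th
percentile.

**Back-projection.** Full-length weights are the correlations of one
mode's participant scores with every original variable or ROI.
Family-wise error across the hundreds of variables is controlled by a
max-statistic null: each permutation shuffles the scores under the same
family blocks (permuting the score vector or the variable block yields
the same null; the former costs one matrix-vector product) and records
the maximum |r| across variables; observed weights beyond the
1 − α quantile (α = 0.001) are significant. Missing cells are
mean-imputed after standardization so the observed statistic and its
null are computed by the identical formula; at the sub-percent
missingness the pipeline targets, the difference from pairwise deletion
is negligible. Constant variables are excluded with a report.

**Sign convention.** Eigen decompositions are sign-indeterminate, so
modes are aligned to an interpretive positive–negative axis by
anchoring a named variable (e.g., a substance-use measure held
negative): if its back-projected weight disagrees, all weights and both
score vectors of the mode are negated jointly — an involution that
changes no correlation magnitude. Mode comparisons report the standard
four correlations: behavioral scores, topographic scores, behavioral
weights, topographic weights.

**Regress-out controls.** Map-space: per participant, the target
topography is replaced by its residual against an intercept plus the
regressor topography. Time-domain: a frame series is residualized
against one or more (optionally flipped, integer-lagged) regressors on
the overlapping frames, with the dropped head/tail recorded so callers
can align the BOLD matrix.

# Cross-validated CCA

Folds are built by shuffling families (seeded), ordering by decreasing
size and greedily assigning each whole family to the currently smallest
fold — so fold sizes differ by at most the largest family. The stated
requirement is that monozygotic twins never straddle a train/test split;
keeping *all* family members together is the stronger constraint we
apply deliberately.

Per fold, both reductions and the CCA are fitted on training rows only;
test participants are standardized and deconfounded with training
parameters, projected through the training bases and canonical weights,
and the out-of-sample canonical correlation is the Pearson correlation
of the test-side mode-1 score pair. A bitwise leakage test verifies that
shuffling a test fold never changes any training artifact.

Weight stability is the mean pairwise correlation of training weights
across splits. Raw canonical weights live in fold-specific component
bases and are not comparable, so stability is computed on the
full-length representation (training scores correlated with the
original variables), sign-aligned to the first split before averaging —
the representation the best-split back-projection uses anyway.

Permutation significance of the CV re-runs the scoring with the
behavioral component rows of each fold's training set permuted under
family blocks (families are whole within folds by construction) and the
canonical weights refit, holding the component reductions fixed;
refitting the reductions inside each of the 5000 permutations is
exposed as a cost switch but is not the default. Per-fold and
mean-level p-values use the add-one rule; the decision rule rejects
when any fold's p falls below 0.005 (a Bonferroni-style allowance for
10 folds), with the mean-level p reported separately.

# The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the
study conditions, not dials:

* **BOLD model.** `BOLD_j(t) = loading_j·g(t) + gain_i·map_j·(−RVT(t−16
  frames)) + noise`, with TR 0.72 s, 1200-frame runs, and g(t) an AR(1)
  (φ = 0.9) process band-limited below 0.1 Hz — resting-state spectral
  content without a hemodynamic model. Regional loadings are N(1, 0.3).
  The respiratory map is proportional to the loadings
  (`coupling = "matched"`, scale 0.5) to reproduce the observed strong
  GS–respiration spatial consistency; an `independent` mean-zero map
  and a `none` option provide the contrast conditions.
* **Respiration.** Each run gets a modulated breathing trace (carrier
  ≈ 0.3 Hz, modulation ≈ 0.03 Hz, depth 0.3–0.6, random phases) emitted
  at 400 Hz; the *analytic* amplitude envelope, sampled on the frame
  grid, is the RVT that drives BOLD, so the trace pipeline's RVT should
  (and does) recover it. The coupling is flipped and lagged 16 frames,
  exercising the pipeline's flip convention; cardiac traces are Gaussian
  pulse trains from a sampled IBI sequence (65 ± 5 bpm mean, 3 bpm
  beat-to-beat).
* **Individual differences and the planted mode.** A participant-level
  coupling gain (1 + 0.35·latent) scales the respiratory map; the
  topographic latent correlates with a behavioral latent at
  `true_canonical_r` (default 0.7), and behavior measures load on that
  latent (|loading| 0.4–1, noise SD 0.8, 40 measures). This is the
  mechanism that makes ICC across participants, the canonical mode, and
  the back-projected loadings all recoverable quantities.
* **Families.** 30% of participants sit in MZ pairs and 20% in DZ
  pairs; both latents carry a family random effect explaining 30% of
  latent variance. That fraction is a free parameter chosen as a
  plausible within-family behavioral similarity, not an estimate —
  nothing in the sources pins it — and it is what makes family-blocked
  permutation consequential. Missing behavioral cells are injected
  completely at random at 0.93%.
* All randomness flows through one explicit seed; identical seed and
  configuration reproduce the cohort bit for bit.

What the generator does *not* emulate: hemodynamic response functions,
head motion, scanner drift, non-Gaussian behavioral distributions,
heritability differences between MZ and DZ pairs, and spatial
autocorrelation among ROIs. Passing tests therefore demonstrate that
the machinery recovers known structure under a fair idealization of the
data — not that real acquisitions meet these assumptions.

# Problem sizes and numerical choices

The test suite and acceptance script run the study's frame grid (1200
frames, TR 0.72 s) but desk-scale cohorts — 30 participants × 100 ROIs
for lag/ICC checks, 500 × 60 for the planted canonical mode with k = 10
components, 1000 null simulations × 500 permutations (n = 120, k = 5)
for type-I calibration, and 50 paired simulations for the regress-out
control — sizes chosen so the full suite completes in a few minutes
while every estimate stays comfortably inside its tolerance band.

Numerical conventions collected in one place: Fisher clipping at
1 − 1e-7; eigenvalue flooring at 1e-10 × the largest; lag ties toward
smaller |lag|; add-one permutation p-values; negative σ~r~² floored at
zero; sliding windows shrink at boundaries; filters are zero-phase with
odd-reflection padding; frame indexing is 0-based in serialized output
with lags reported in both frames and seconds.

# Interfaces

The package is a library: tibble-returning functions with `tidy()`,
`glance()` and `autoplot()` methods are the interface, and
`run_pipeline()` chains the seven stages (simulate → physio → topo →
icc → prep → cca → cv) into a results directory with a manifest of
seeds, configuration and per-file checksums. Serialization is plain TSV
and JSON throughout: the analysis consumes ROI-level matrices, so no
imaging formats are needed. `scripts/acceptance.R` recomputes the
headline quantities from scratch against the installed package.

# Known limitations

* RVT is envelope-based and inherits peak detection's failure mode on
  breath-hold-like segments (fewer than three detected cycles is an
  error, not a guess).
* The covariance-completion projector assumes missingness is sparse and
  unstructured; at tens of percent missing it degrades and is refused
  above 20%.
* The CV permutation default holds component reductions fixed under
  permutation; with very small folds and large k this is slightly
  liberal relative to full refitting (the exposed `refit` switch exists
  for that reason).
* The mirror-peak ambiguity of near-sinusoidal modulation (above) means
  small-cohort lag estimates should be inspected via the stored
  cross-correlation profile (`tidy()` on a lag estimate, or
  `autoplot()`).
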