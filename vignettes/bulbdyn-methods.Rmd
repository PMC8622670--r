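---
title: "Methods: olfactory-bulb network dynamics from LFP and calcium imaging"
author: "bulbdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: olfactory-bulb network dynamics from LFP and calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bulbdyn` implements the analysis chain used to compare olfactory-bulb
network dynamics between wild-type (WT) and LRRK2-knockout (KO) mice:
behavior-state-conditioned spectral analysis of local field potentials
(LFP), detection of spontaneous calcium events in mitral/tufted-cell ROI
traces, kernel-regression quantification of odor-evoked responses,
distance-resolved pairwise correlation, Ward clustering of field-of-view
(FOV) activity, and habituation–dishabituation scoring. This vignette
documents the models, parameter choices, and numerical decisions; the
worked analysis lives in the numbered scripts under `analysis/`.

## LFP spectral analysis

A raw recording (nominally digitized at 10 kHz) is band-pass filtered
1–150 Hz with a zero-phase 5th-order Butterworth response and resampled to
250 Hz (`preprocess_lfp()`). Four bands are analyzed: theta 4–12 Hz, beta
15–30 Hz, low gamma 40–70 Hz, high gamma 70–100 Hz.

Power spectral densities use Welch's method with a periodic Hann window of
0.5 s and 0.25 s overlap (`welch_psd()`; the spectrogram variant returns
the per-window matrix with the same parameters). For each behavioral state
(resting vs exploring–sniffing), `state_band_power()` takes that state's
labeled intervals in temporal order up to an aggregation cap of 15 min,
trims 2 s from each interval edge to suppress residual filter transients
(reduced automatically for intervals too short to retain one window),
computes the PSD per interval, averages PSDs across intervals weighted by
interval length, and then averages power over each band's frequency range.

Three decisions deserve explanation:

* **Zero-phase filtering.** Forward–backward (zero-phase) filtering is used
  everywhere so that state-boundary timing is not distorted by filter group
  delay. The filters are applied in the frequency domain as the analytic
  Butterworth band-pass magnitude response (`butter_bandpass_gain()`); this
  has exactly the amplitude response of forward–backward recursive
  filtering but remains numerically exact at very small normalized cutoffs
  (a recursive 10th-order transfer function with a 1 Hz edge at a 10 kHz
  rate, or a 0.005 Hz edge at 30 fps, is unstable in double precision).
  Resampling is spectral (Fourier truncation), which applies an ideal
  anti-alias cut at the new Nyquist and introduces no delay.
* **Band edges are half-open** (`[lo, hi)`) when averaging PSD bins into a
  band: low and high gamma share the 70 Hz edge, and a closed interval
  would count the shared bin in both bands.
* **Normalized power.** Reported state powers are normalized per
  (subject, band) by the mean of the rest and sniff values, so the two
  normalized values always average to 1. This reconstruction matches the
  reported WT value pairs, which consistently sum to approximately 2; the
  underlying study does not define its normalization explicitly.

`sniff_rest_ratio()` reports the raw (unnormalized) power ratio
sniff/rest per band; a rest power of exactly zero is flagged as undefined
rather than propagated. Both normalized powers and ratios are invariant
under uniform gain applied to the recording.

## Spontaneous calcium events

ROI traces (cells × frames, 30 fps) are band-pass filtered 0.005–0.8 Hz
(zero-phase, 5th order) and z-scored per cell (`preprocess_traces()`).
Constant traces have undefined z-scores; they are flagged and excluded
downstream rather than patched.

Events are detected by binarizing each cell's *filtered* trace at

    threshold_c = 2.5 * (sigma_FOV + median_c)

where `sigma_FOV` is the population standard deviation pooled over every
sample of every filtered trace in the FOV and `median_c` is the cell's
median filtered intensity. The population (rather than sample) SD is used;
at realistic sizes the difference is far below 1%. Binarization uses the
filtered trace because the threshold references the intensity
distribution, while event *amplitudes* are reported in z-score units (the
peak of the z-scored trace within the event). Each maximal run of
supra-threshold frames is one event; the minimum event length is one frame
(no debouncing). Doubling all trace values doubles `sigma_FOV`, the
medians, and hence all thresholds — threshold homogeneity of degree 1.

The amplitude–duration relationship is summarized by fitting per-cell mean
amplitude `a` and mean duration `S` to the logistic

    S(a) = D / (1 + exp(-k (a - a0)))

with `D` the duration plateau, `k` the slew rate, and `a0` the amplitude
at half-maximal duration (the defining property `S(a0) = D/2` fixes this
functional form). The fit is bounded (`D, k > 0`) nonlinear least squares
(Levenberg–Marquardt) multi-started from data quantiles; convergence
failure is reported explicitly, and a constant-duration input degenerates
to an exact flat fit (`D` = the common duration, R² = 1 by convention,
flagged `degenerate`). Density maps over (amplitude, duration) use a
top-hat (uniform disk) kernel of radius 0.75, which has compact support
and integrates to 1 by construction.

## Odor-evoked responses

The GCaMP6s impulse response is modeled as

    h(t) = (1 - exp(-t / tau_on)) * exp(-t / tau_off)

with `tau_on = 0.11 s`, `tau_off = 0.52 s`, truncated after the peak at
1e-4 of the maximum and normalized to unit peak. Its peak time is
`tau_on * log(1 + tau_off/tau_on)` (about 0.192 s). Each stimulus trial
contributes one regressor: a boxcar of the trial duration placed at
`onset + 5.6 s` (the cell response delay; shifting the boxcar or the
kernel is equivalent — the boxcar shift is used for clarity), convolved
with `h`, and normalized to unit peak so that regression coefficients read
as response peak amplitudes.

`fit_responses()` performs ordinary least squares of each cell's z-scored
trace on all trial regressors plus an intercept (kept for robustness even
though filtered traces are near zero-mean). Two methodological points:

* **The design matrix is filtered like the data.** When traces have been
  band-passed, the same filter is applied to the regressors (then
  re-normalized to unit peak). Fitting unfiltered regressors to filtered
  traces leaves a systematic model mismatch that biases oil-trial
  coefficients away from zero.
* **Standard errors use a Newey–West sandwich** (Bartlett-tapered residual
  autocovariance up to 2 s of lags). After the 0.005–0.8 Hz band-pass the
  residuals are strongly autocorrelated at 30 fps, and the plain OLS
  variance understates coefficient uncertainty roughly fourfold.

A trial is *responsive* when its coefficient exceeds `kappa = 3` standard
errors (one-sided, positive). With the sandwich errors this calibrates the
per-trial false-positive rate on white-noise traces below 1%; `kappa` is
exposed. The *effective duration* of a response is the time the trace
stays above half the fitted peak within the trial window (response onset
to the next trial's response onset), taking the contiguous run containing
the window's maximum; an "above detection threshold" definition would be a
straightforward alternative, but the half-max width is less sensitive to
the FOV-wide threshold level. Reliability classes count responsive odor
trials per cell: `all`, `none`, `one`, or `few` (2 to n-1); per-FOV class
fractions partition to 1.

The regression is per-trial (one coefficient per stimulation event), not
per-stimulus-type; odor/oil aggregation happens afterwards.

## Population structure

Pairwise Pearson correlations are computed between z-scored traces
(spontaneous) or between traces restricted to concatenated
stimulus-response windows (evoked). Pairs are binned by Euclidean
inter-soma distance into half-open 56 µm bins (`[k·56, (k+1)·56)`; ties at
an edge go deterministically to the upper bin). The exponential decay
length of a profile is estimated by nonlinear least squares of
`r = A * exp(-d / lambda)` on the pair-level data, seeded from a
log-linear fit to the binned means.

FOV activity vectors: in spontaneous mode, the mean z-scored activity over
cells and frames in consecutive 33.3 s windows — fixed at exactly 1000
frames at 30 fps, otherwise `round(33.3 * frame_hz)` frames, with a
trailing partial window dropped. In evoked mode, the mean fitted response
amplitude over cells, per trial ("average response per stimulus" is read
as the mean regression amplitude, since the regression is what yields
per-stimulus responses; a rate-based variant would need a separate event
count). Note that because z-scoring centers every trace, spontaneous
vectors fluctuate around zero and clustering on them reflects temporal
patterning rather than absolute activity level.

Clustering uses Ward linkage on Euclidean distances (`hclust`,
`ward.D2`), cut into 4 clusters for spontaneous vectors and 2 for evoked
vectors — the cluster counts the study design targets; the full dendrogram
is always retained so other cuts can be taken. Per cluster, the genotype
composition (percentages summing to 100), mean vector amplitude, and mean
per-FOV correlation are reported. **Cross-FOV evoked clustering is only
meaningful when all FOVs received the same stimulus sequence**: vector
entry *t* must refer to the same stimulus in every FOV, otherwise the
odor/oil placement dominates the distances. The analysis scripts therefore
deliver one shared pseudo-random 7-odor/3-oil sequence to every simulated
FOV.

## Behavior and statistics

The habituation–dishabituation task yields four investigation times per
mouse (three water trials, then a novel odorant). `habituation_summary()`
reports per-genotype, per-trial mean ± SD; `dishabituation_test()` runs a
paired two-sided Wilcoxon signed-rank test of trial 4 vs trial 3 per
genotype, exact whenever the sample permits. Fewer than 3 mice is reported
as insufficient; all-zero differences make the statistic degenerate and
are reported as such rather than given a p-value.

`compare_groups()` wraps the rank tests used throughout (Mann–Whitney U,
paired Wilcoxon, Kruskal–Wallis) with two-sided p-values, exact
small-sample distributions where ties/zeros permit, and the normal
approximation with tie correction otherwise. Zero paired differences
follow the standard Wilcoxon convention (dropped), as implemented by
`stats::wilcox.test`. Pairwise tests after a Kruskal–Wallis are reported
unadjusted, matching the individual-p reporting style of the field; a
Holm adjustment can be applied by the caller.

## The synthetic-data generator

Every analysis is exercised against generated data with known ground
truth.

**LFP** (`gen_lfp()`): each band is white noise band-passed with the same
zero-phase Butterworth response the analysis uses, scaled to unit SD and
multiplied by the state-dependent amplitude from the schedule; broadband
white noise is added on top. A state amplitude ratio `r` therefore appears
as a measured power ratio `r²`. Band noise is synthesized at 250 Hz —
where all band filters are well conditioned — and spectrally upsampled to
the target rate, which is exact for the sub-125 Hz content involved.

**Calcium** (`gen_calcium_session()`): cells are placed uniformly in a
512 px FOV (1 µm/px by default; the pixel calibration is a free parameter
because the study geometry does not pin it down). Each cell receives a
Poisson event train (1.8 events/min by default, matching the reported
spontaneous rates) with truncated-normal amplitudes (non-negative, as
fluorescence transients are), convolved with the GCaMP6s kernel.
Distance-dependent correlation is imposed by mixing the per-cell source
signals with the Cholesky factor of `C_ij = exp(-d_ij / lambda)`
(exponential covariance, valid in the plane; sources are standardized
before mixing and rescaled after), so pairwise correlations realize
`exp(-d/lambda)` directly — a single shared latent train with
distance-weighted mixing would instead produce correlations depending on
each cell's distance to the latent's anchor rather than on the inter-soma
distance, and would not carry the advertised decay length. `lambda = 0`
disables mixing (needed when event-level ground truth must stay exact);
`lambda = Inf` collapses all cells onto one source. Slow sinusoidal drift
(100 s period, random phase) and white noise are added last.

If a protocol is present, a random responder fraction of cells responds at
odor onsets with per-trial probability `reliability` and truncated-normal
amplitude, injected through the same delayed-boxcar/kernel regressor model
the analysis fits — so recovered coefficients can be compared to the
injected amplitudes exactly. Oil trials evoke nothing. The default
inter-trial interval is 40 s: because responses contribute to the very
variance that z-scoring divides by, the achievable z-scored amplitude is
capped at `1/sqrt(duty cycle)`, and a duty cycle low enough to reach the
z-amplitudes reported for strong responders (about 5) requires roughly
this spacing.

**Behavior** (`gen_behavior_trials()`): per mouse, `t1 = base`,
`t_{k} = t_{k-1} * decay + noise` for the remaining habituation trials,
and `t4 = t3 * (1 + gain) + noise`, clipped at zero. Defaults (base 2.8 s,
decay 0.55, gain 1.8, noise 0.5 s) approximate the reported WT trial
means.

**What the generator does not emulate** — and hence what passing tests do
not establish about real recordings: neuropil contamination and imperfect
ROI segmentation, motion artifacts, photobleaching trends beyond a
sinusoidal drift, bursty (non-Poisson) firing, indicator nonlinearity and
saturation, breathing-locked temporal structure in the calcium signal, and
non-stationary LFP noise. Recovery results certify the estimators under
the stated statistical model, not robustness to these effects.

## Problem sizes and numerical details

The test suite and the acceptance script run at deliberately compact
sizes chosen to keep sampling error well inside the stated tolerances:
126 s LFP recordings (≥ 60 s per state) at the full 10 kHz rate, 100-seed
Welch/white-noise checks at 30 s × 250 Hz, 1000-trace event-segmentation
oracles, 100-replicate sigmoid recoveries at 200 cells, 50-cell / 8-min
evoked sessions at SNR 5, 110-cell spontaneous sessions for decay-length
recovery, 100 random sets for the Ward linkage oracle, 16-FOV clustering
cohorts, and 200-replicate behavior power checks.

Other numerical choices: nonlinear fits use Levenberg–Marquardt with
`ftol = 1e-10` and multi-start; the sigmoid fit treats zero
duration-variance inputs as exact flat fits; KDE grids extend one
bandwidth beyond the data; regressor values below 1e-10 after FFT
convolution are snapped to exactly zero so regressors vanish outside the
stimulation period; Welch segments are demeaned per segment; distance and
band bins are half-open with deterministic edge assignment; sampling rates
are coerced to double before frequency-grid arithmetic (32-bit integer
rates overflow otherwise).

## Known limitations

* The normalization behind the reported "normalized power values" is a
  reconstruction (pair-mean = 1); other conventions would rescale Figure-G
  style panels but leave ratios untouched.
* The responsiveness criterion (`kappa = 3` sandwich SEs) and the
  effective-duration definition are package decisions; the study does not
  define either operationally.
* Spontaneous FOV vectors are means of z-scored activity and hence carry
  no absolute-rate information; clustering them is structurally weaker
  than the evoked case.
* The Newey–West lag window (2 s) slightly underestimates residual
  autocorrelation beyond it; the white-noise calibration of `kappa`
  absorbs most of the residual bias.
* `fit_correlation_decay()` assumes a single exponential; layered or
  anisotropic spatial structure is not modeled.
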