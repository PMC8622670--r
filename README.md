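# bulbdyn

Analysis pipeline for olfactory-bulb network dynamics in mice, built for
studies comparing wild-type (WT) and LRRK2-knockout (KO) animals across
three levels of observation:

* **Circuit rhythms** — local field potentials (LFP) recorded in freely
  behaving animals, analyzed by behavioral state (resting vs
  exploring–sniffing): zero-phase Butterworth filtering 1–150 Hz,
  down-sampling to 250 Hz, Welch power spectral densities (Hann window
  0.5 s, 0.25 s overlap), band power in theta (4–12 Hz), beta (15–30 Hz),
  low gamma (40–70 Hz) and high gamma (70–100 Hz), normalized state powers
  and sniff/rest power ratios.
* **Single cells** — two-photon GCaMP6s ROI traces of mitral/tufted cells
  (30 fps, 512 px fields of view): band-pass 0.005–0.8 Hz, z-scoring,
  event detection at the threshold `2.5 × (σ_FOV + median_cell)`, event
  rate/amplitude/duration, the logistic amplitude–duration relationship
  `S(a) = D / (1 + e^{−k(a−a0)})`, and top-hat kernel density maps.
  Odor-evoked responses are quantified by per-trial linear regression on
  regressors built from the GCaMP6s impulse response
  `h(t) = (1 − e^{−t/0.11}) e^{−t/0.52}` delayed by 5.6 s, with
  autocorrelation-robust standard errors, responsiveness flags, and
  reliability classes (responds to all / few / one / no odor trials).
* **Populations** — pairwise Pearson correlation vs inter-soma distance in
  56 µm bins with exponential decay-length fits, field-of-view activity
  vectors (33.3 s windows for spontaneous activity, per-trial amplitudes
  for evoked activity), and Ward hierarchical clustering with per-cluster
  genotype composition. Behavioral discrimination is scored with the
  4-trial habituation–dishabituation task and paired Wilcoxon tests;
  group comparisons use Mann–Whitney and Kruskal–Wallis tests.

Because raw recordings of this kind are rarely deposited, the package
ships a synthetic-data generator (`gen_lfp()`, `gen_calcium_session()`,
`gen_behavior_trials()`) that emulates the statistical structure every
stage assumes — state-dependent band-limited LFP noise, Poisson calcium
events with GCaMP6s kinetics and `exp(−d/λ)` spatial correlation,
kernel-shaped evoked responses, and habituating investigation times — with
full ground truth, so every estimator is tested by recovery.

## Worked example

```r
library(bulbdyn)

# 2 min of LFP with a doubled high-gamma amplitude during sniffing
sched <- data.frame(state = rep(c("rest", "sniff"), 3), duration_s = rep(21, 6))
amps <- list(rest  = c(theta = 1, beta = 1, low_gamma = 1, high_gamma = 1),
             sniff = c(theta = 1, beta = 1, low_gamma = 1, high_gamma = 2))
rec <- gen_lfp(synth_lfp_params(126, fs_hz = 10000, band_amplitudes = amps,
                                state_schedule = sched, noise_sd = 0.2, seed = 1))
ratios <- sniff_rest_ratio(state_band_power(preprocess_lfp(rec)))
print(ratios[, c("band", "ratio")], row.names = FALSE)

# spontaneous calcium session: detect events against the FOV threshold
g <- gen_calcium_session(synth_calcium_params(n_cells = 60, seed = 1))
sess <- preprocess_traces(g$session)
events <- detect_events(sess)
summ <- event_summary(events, sess)
cat(sprintf("detected %d events; %.2f events/min/cell (generated: 1.8)\n",
            nrow(events), mean(summ$rate_per_min)))

prof <- correlation_vs_distance(pairwise_correlation(sess), sess$centroids)
dec <- fit_correlation_decay(prof)
cat(sprintf("correlation decay length: %.0f um (generated: 100)\n", dec$lambda_um))
```

```
       band     ratio
       beta 0.9612660
 high_gamma 4.2452923
  low_gamma 1.0719833
      theta 0.9624479
detected 837 events; 2.79 events/min/cell (generated: 1.8)
correlation decay length: 96 um (generated: 100)
```

The doubled high-gamma *amplitude* during sniffing comes back as a ×4
power ratio (power scales with amplitude squared) while the other bands
stay at 1. The detected event rate exceeds each cell's own source rate
because spatial mixing shares events between nearby cells — neighbors'
events above threshold are genuine events of the mixed trace. The
`exp(−d/λ)` correlation structure is recovered with `λ̂ = 96 µm` against a
generated 100 µm.

The full study-style analysis — 13 LFP subjects, 12 spontaneous and 16
stimulated FOVs, 16 behavior mice, through spectral comparison, event
statistics, evoked amplitudes and reliability, correlation profiles, and
genotype-composition clustering — is scripted in order under `analysis/`
(`01_simulate_data.R` … `06_behavior.R`); each script prints what it finds
and writes compact tables under `results/`.

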