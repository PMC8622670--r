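#!/usr/bin/env Rscript
# Generates the synthetic study cohorts used by the downstream analysis
# scripts: state-labeled LFP recordings, spontaneous and odor-stimulated
# calcium imaging sessions, and habituation-dishabituation trial tables.
#
# Cohort parameters mirror the study design: 7 WT / 6 KO LFP subjects with
# sniffing-state band amplitudes set so the generated power ratios match the
# group medians the LFP analysis reports; 6 + 6 spontaneous FOVs; 8 + 8
# stimulated FOVs with a shared pseudo-random 7-odor / 3-oil sequence and a
# weaker, less reliable KO response; 8 + 8 behavior mice with a blunted KO
# dishabituation gain.
#
# Traces and the matching ground-truth tables (suffixed _truth) go to
# scratch/synthetic_data/; they are large and regenerable. The behavior
# trial table (small) goes to results/.

library(bulbdyn)

data_dir <- "scratch/synthetic_data"
truth_dir <- file.path(data_dir, "truth")  # alongside the data
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(truth_dir, recursive = TRUE, showWarnings = FALSE)

## LFP cohort ---------------------------------------------------------------
# sniff-state amplitudes are the square roots of the target power ratios
sniff_amp <- list(
  WT = c(theta = sqrt(2.94), beta = sqrt(2.02), low_gamma = sqrt(2.85),
         high_gamma = sqrt(3.79)),
  KO = c(theta = sqrt(2.07), beta = sqrt(1.17), low_gamma = sqrt(2.01),
         high_gamma = sqrt(2.22)))
sched <- data.frame(state = rep(c("rest", "sniff"), 3),
                    duration_s = rep(21, 6))
n_lfp <- c(WT = 7, KO = 6)
truth_rows <- list()
for (gt in c("WT", "KO")) {
  for (i in seq_len(n_lfp[[gt]])) {
    amps <- list(rest = c(theta = 1, beta = 1, low_gamma = 1,
                          high_gamma = 1),
                 sniff = sniff_amp[[gt]])
    p <- synth_lfp_params(126, fs_hz = 10000, band_amplitudes = amps,
                          state_schedule = sched, noise_sd = 0.2,
                          seed = 1000 + i + 100 * (gt == "KO"))
    rec <- gen_lfp(p, subject_id = sprintf("%s_lfp_%02d", gt, i),
                   genotype = gt)
    write_lfp_recording(rec, file.path(data_dir, rec$subject_id))
    truth_rows[[rec$subject_id]] <-
      data.frame(subject_id = rec$subject_id, genotype = gt,
                 band = names(sniff_amp[[gt]]),
                 true_power_ratio = unname(sniff_amp[[gt]])^2)
  }
}
write.table(do.call(rbind, truth_rows),
            file.path(truth_dir, "lfp_band_ratio_truth.tsv"),
            sep = "\t", row.names = FALSE)
cat("wrote", sum(n_lfp), "LFP recordings (126 s each, 10 kHz)\n")

## Spontaneous imaging cohort ------------------------------------------------
ev_truth <- list()
for (gt in c("WT", "KO")) {
  for (i in 1:6) {
    p <- synth_calcium_params(n_cells = 60, duration_s = 300,
                              corr_length_um = 100,
                              seed = 2000 + i + 100 * (gt == "KO"))
    g <- gen_calcium_session(p, genotype = gt,
                             fov_id = sprintf("%s_spont_%02d", gt, i))
    write_calcium_session(g$session, file.path(data_dir, g$session$fov_id))
    ev <- g$truth$events
    ev$fov_id <- g$session$fov_id
    ev_truth[[g$session$fov_id]] <- ev
  }
}
write.table(do.call(rbind, ev_truth),
            file.path(truth_dir, "spontaneous_events_truth.tsv"),
            sep = "\t", row.names = FALSE)
cat("wrote 12 spontaneous FOVs (60 cells, 5 min, lambda = 100 um)\n")

## Stimulated imaging cohort -------------------------------------------------
# one pseudo-random stimulus sequence shared by every FOV
resp <- list(WT = list(amp = 5.5, rel = 0.95),
             KO = list(amp = 3.5, rel = 0.90))
amp_truth <- list()
for (gt in c("WT", "KO")) {
  for (i in 1:8) {
    pp <- synth_protocol_params(response_amp_mean = resp[[gt]]$amp,
                                reliability = resp[[gt]]$rel, seed = 777)
    p <- synth_calcium_params(n_cells = 25, duration_s = 480,
                              corr_length_um = 100, noise_sd = 0.6,
                              seed = 3000 + i + 100 * (gt == "KO"))
    g <- gen_calcium_session(p, pp, genotype = gt,
                             fov_id = sprintf("%s_evoked_%02d", gt, i))
    write_calcium_session(g$session, file.path(data_dir, g$session$fov_id))
    amp <- as.data.frame(g$truth$response_amp)
    names(amp) <- paste0("trial_", seq_len(ncol(amp)))
    amp <- cbind(fov_id = g$session$fov_id,
                 cell_id = g$session$centroids$cell_id, amp)
    amp_truth[[g$session$fov_id]] <- amp
  }
}
write.table(do.call(rbind, amp_truth),
            file.path(truth_dir, "evoked_amplitude_truth.tsv"),
            sep = "\t", row.names = FALSE)
cat("wrote 16 stimulated FOVs (25 cells, 8 min, shared 7+3 sequence)\n")

## Behavior cohort ------------------------------------------------------------
beh <- rbind(
  gen_behavior_trials(synth_behavior_params(8, habituation_decay = 0.55,
                                            dishabituation_gain = 1.8,
                                            base_time_s = 2.8,
                                            noise_sd_s = 0.5, seed = 41),
                      genotype = "WT"),
  gen_behavior_trials(synth_behavior_params(8, habituation_decay = 0.55,
                                            dishabituation_gain = 0.5,
                                            base_time_s = 1.9,
                                            noise_sd_s = 0.5, seed = 42),
                      genotype = "KO"))
dir.create("results", showWarnings = FALSE)
write.table(beh, "results/behavior_trials.tsv",
            sep = "\t", row.names = FALSE)
cat("wrote behavior table:", nrow(beh), "rows (8 WT + 8 KO mice)\n")
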