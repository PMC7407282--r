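#!/usr/bin/env Rscript
# Cine-MRI-style haustral analysis on synthetic recordings: event
# detection, occlusion metrics, wave linking, timing ratio, motility index
# and baseline-vs-stimulated fold changes.
# Writes results/motility_events.csv, results/motility_waves.csv,
# results/motility_summary.csv.

suppressPackageStartupMessages(library(dcmflow))
dir.create("results", showWarnings = FALSE)
seed <- 42L

# a "stimulated"-like recording: one strong antegrade wave
stim <- simulate_haustral_series(
  data.frame(direction = "antegrade", velocity_cm_s = 2,
             occlusion_pct = 55, onset = 10),
  t_c = 6, hold = 2, t_r = 22, seed = seed)
ev_s <- detect_contraction_events(stim)
lw_s <- link_waves(ev_s, stim)

# a "baseline"-like recording: one weak, slow wave
base <- simulate_haustral_series(
  data.frame(direction = "antegrade", velocity_cm_s = 1,
             occlusion_pct = 20, onset = 20),
  t_c = 8, hold = 2, t_r = 9, noise_sigma = 0.05, seed = seed + 1L)
ev_b <- detect_contraction_events(base)
lw_b <- link_waves(ev_b, base)

write_motility_table(ev_s, "results/motility_events.csv")
write_motility_table(rbind(cbind(condition = "stimulated", lw_s$waves),
                           cbind(condition = "baseline", lw_b$waves)),
                     "results/motility_waves.csv")

fc <- fold_change_summary(
  c(travel_velocity = mean(lw_b$waves$travel_velocity)),
  c(travel_velocity = mean(lw_s$waves$travel_velocity)))

summary <- data.frame(
  condition = c("baseline", "stimulated"),
  n_events = c(nrow(ev_b), nrow(ev_s)),
  mean_occlusion_pct = c(mean(ev_b$occlusion_degree),
                         mean(ev_s$occlusion_degree)),
  timing_ratio = c(relaxation_contraction_ratio(ev_b),
                   relaxation_contraction_ratio(ev_s)),
  motility_index = c(in_vivo_motility_index(ev_b, base),
                     in_vivo_motility_index(ev_s, stim)))
write.csv(summary, "results/motility_summary.csv", row.names = FALSE)

cat("Detected", nrow(ev_s), "stimulated and", nrow(ev_b),
    "baseline contraction events.\n")
print(summary, digits = 3)
cat(sprintf("\nStimulated/baseline travel-velocity fold change: %.1f\n",
            fc[["travel_velocity"]]))
cat(sprintf("Recovered wave: %s at %.2f cm/s (truth: antegrade, 2 cm/s)\n",
            lw_s$waves$direction[1], lw_s$waves$travel_velocity[1]))
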