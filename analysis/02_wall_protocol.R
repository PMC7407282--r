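#!/usr/bin/env Rscript
# The programmed DCM wall motion: one antegrade wave of haustral
# contractions (40 % occlusion, 1.6 cm/s inflation, 1 s hold, 0.35 cm/s
# deflation, 2 cm/s travel) and its motility-index accounting.
# Writes results/occlusion_field.csv and results/wall_protocol_summary.csv.

suppressPackageStartupMessages(library(dcmflow))
dir.create("results", showWarnings = FALSE)

geo <- tube_geometry()
kin <- unit_kinematics()
proto <- wave_protocol(n_waves = 4)        # four waves in ~2 min
field <- propagate_wave(proto, kin, geo, t_end = 120)
write_occlusion_field(field, "results/occlusion_field.csv")

traversal <- wave_traversal_time(field)
activity <- field_to_segment_activity(field)
rec_len <- max(field$time)
mi <- motility_index(activity, recording_length = rec_len)

summary <- data.frame(
  wave_traversal_s = traversal,
  n_waves = proto$n_waves,
  recording_s = rec_len,
  motility_index_segment_s = mi)
write.csv(summary, "results/wall_protocol_summary.csv", row.names = FALSE)

cat(sprintf("Wave front traverses the %.0f cm tube in %.0f s.\n",
            100 * geo$total_length, traversal))
cat(sprintf("%d waves over %.0f s give a motility index of %.0f segment*s\n",
            proto$n_waves, rec_len, mi))
cat("(each wave sweeps all five segments; the score is set by the\n",
    "per-bin contraction durations of the programmed schedule).\n")
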