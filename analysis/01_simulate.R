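#!/usr/bin/env Rscript
# Generate one seeded synthetic dataset per analysis stage and write it under
# results/data/ as multi-page TIFFs (or CSV) with JSON ground-truth sidecars.
# Later drivers re-read these files, so the whole workflow runs off disk the
# way a real imaging study would.

library(gliaquant)

seed <- 20260927L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

arbor <- generate_arbor(6, seq(10, 30, 5), pixel_size = 1, seed = seed)
save_synthetic(arbor, file.path(out, "arbor"))
cat("arbor: ", sum(arbor$mask), "foreground px,",
    nrow(arbor$ground_truth_crossings), "ground-truth radii\n")

movie <- generate_timelapse(arbor, T = 12, extension_fraction = 0.1,
                            retraction_fraction = 0.1, frame_interval = 4,
                            noise_sd = 12, seed = seed + 1L)
save_synthetic(movie, file.path(out, "timelapse"))
cat("timelapse: 12 frames at 4-min cadence, planted fractions 0.1/0.1,",
    "noise sd 12\n")

for (rate in c(1, 4)) {
  abl <- generate_ablation_movie(T = 8, converge_rate = rate,
                                 seed = seed + 10L + rate)
  save_synthetic(abl, file.path(out, sprintf("ablation_rate%d", rate)))
}
cat("ablation: two 8-frame movies (converge 1 and 4 px/frame)\n")

puncta_spec <- list(nd = 3L, md = 6L)
for (nm in names(puncta_spec)) {
  pn <- generate_puncta_image(puncta_spec[[nm]], 3, puncta_size_px = 4,
                              seed = seed + 20L + puncta_spec[[nm]])
  save_synthetic(pn, file.path(out, paste0("puncta_", nm)))
}
cat("puncta: two two-channel images (3 and 6 internal puncta planted)\n")

table <- generate_event_table(
  list(ND = c(cleft_contacts = 0.25, inclusions = 0.05),
       MD = c(cleft_contacts = 0.5, inclusions = 0.1)),
  n_animals = 4, n_processes = 70, area_range = c(0.5, 4), seed = seed + 30L)
save_synthetic(table, file.path(out, "em_events"))
cat("EM table:", nrow(table$table), "processes across",
    length(unique(table$table$animal)), "animals\n")

cat("done; files under", out, "\n")
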