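#!/usr/bin/env Rscript
# Laser-ablation chemotaxis: R(t) curves for a fast- and a slow-converging
# movie, plus the exactness check against planted pixel counts.

library(gliaquant)

curves <- list(); labels <- character(0)
for (rate in c(1, 4)) {
  truth <- jsonlite::read_json(
    sprintf("results/data/ablation_rate%d_truth.json", rate),
    simplifyVector = TRUE)
  stack <- read_stack(sprintf("results/data/ablation_rate%d.tif", rate),
                      pixel_size = truth$pixel_size, frame_interval = 5)
  geom <- ablation_geometry(unlist(truth$center), truth$inner_radius_um,
                            truth$outer_radius_um, truth$core_exclusion_um)
  rc <- ablation_response(stack$data, geom, pixel_size = truth$pixel_size,
                          frame_interval = 5)
  planted <- (truth$planted_Rx_counts - truth$planted_Rx_counts[1L]) /
    truth$planted_Ry0
  cat(sprintf("rate %d px/frame: final R = %.3f (planted %.3f), max |err| = %g\n",
              rate, rc$R[nrow(rc)], planted[length(planted)],
              max(abs(rc$R - planted))))
  curves[[length(curves) + 1L]] <- rc
  labels <- c(labels, sprintf("rate%d", rate))
}

summary <- compare_response_curves(curves, labels)
write.csv(summary, "results/ablation_response.csv", row.names = FALSE)
cat("wrote results/ablation_response.csv\n")
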