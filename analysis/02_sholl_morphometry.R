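#!/usr/bin/env Rscript
# Sholl ramification profile of the simulated arbor: binarize the grayscale
# image, count circle crossings every 5 um, and check the profile against
# the generator's analytic ground truth.

library(gliaquant)

truth <- jsonlite::read_json("results/data/arbor_truth.json",
                             simplifyVector = TRUE)
stack <- read_stack("results/data/arbor.tif", pixel_size = truth$pixel_size)
img <- stack$data[1L, , ]

mask <- binarize(img, method = "triangle", min_size = 4,
                 pixel_size = truth$pixel_size)
prof <- sholl(mask, soma_center = unlist(truth$soma_center),
              radius_step = 5, max_radius = 30)

cmp <- merge(prof, truth$ground_truth_crossings, by = "radius_um",
             suffixes = c("_measured", "_truth"))
write.csv(cmp, "results/sholl_profile.csv", row.names = FALSE)
print(cmp)
cat(sprintf("agreement with analytic truth: %d / %d radii\n",
            sum(cmp$crossings_measured == cmp$crossings_truth), nrow(cmp)))
cat(sprintf("peak ramification: %d crossings at %g um\n",
            max(prof$crossings), prof$radius_um[which.max(prof$crossings)]))
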