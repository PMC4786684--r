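#!/usr/bin/env Rscript
# Two-channel engulfment scoring: triangle-threshold both channels, multiply
# the binary stacks, count internalized puncta (> 1 px) and normalize by
# microglial area; compare the two simulated conditions.

library(gliaquant)

score <- function(nm) {
  truth <- jsonlite::read_json(sprintf("results/data/puncta_%s_truth.json", nm),
                               simplifyVector = TRUE)
  cell <- read_stack(sprintf("results/data/puncta_%s_cell.tif", nm), 1)
  pun <- read_stack(sprintf("results/data/puncta_%s_puncta.tif", nm), 1)
  res <- colocalize(cell$data[1L, , ], pun$data[1L, , ])
  cat(sprintf("%s: %d internalized puncta (planted %d), %.1f um2 microglia, density %.5f /um2\n",
              nm, res$n_internal_puncta, truth$planted_internal,
              res$microglia_area_um2, res$density_per_um2))
  res
}

nd <- score("nd")
md <- score("md")
cmp <- compare_density(list(md), list(nd))
cat(sprintf("density ratio md/nd: %.2f\n", cmp$ratio))
write.csv(data.frame(condition = c("nd", "md"),
                     n_internal = c(nd$n_internal_puncta, md$n_internal_puncta),
                     area_um2 = c(nd$microglia_area_um2, md$microglia_area_um2),
                     density_per_um2 = c(nd$density_per_um2, md$density_per_um2)),
          "results/engulfment.csv", row.names = FALSE)
cat("wrote results/engulfment.csv\n")
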