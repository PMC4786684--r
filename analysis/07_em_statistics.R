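#!/usr/bin/env Rscript
# EM event statistics: per-process densities (events / um2), one-pass Grubbs
# outlier screen, per-animal means and group summaries with the animal as
# the unit of replication.

library(gliaquant)

tab <- read.csv("results/data/em_events.csv")
truth <- jsonlite::read_json("results/data/em_events_truth.json",
                             simplifyVector = TRUE)

res <- summarize_groups(tab, grubbs = TRUE, alpha = 0.05)
print(res$summary)

for (cat_nm in names(res$grubbs)) {
  g <- res$grubbs[[cat_nm]]
  if (is.null(g$removed)) {
    cat(sprintf("%s: no outlying density (G = %.2f, crit = %.2f)\n",
                cat_nm, g$G, g$critical))
  } else {
    cat(sprintf("%s: removed one density %.2f /um2 (G = %.2f > crit %.2f)\n",
                cat_nm, g$removed, g$G, g$critical))
  }
}

ratio <- with(res$summary[res$summary$category == "cleft_contacts", ],
              mean_density[group == "MD"] / mean_density[group == "ND"])
cat(sprintf("cleft-contact density ratio MD/ND: %.2f (planted %.2f)\n", ratio,
            truth$planted_densities$MD[["cleft_contacts"]] /
              truth$planted_densities$ND[["cleft_contacts"]]))
write.csv(res$summary, "results/em_group_summary.csv", row.names = FALSE)
write.csv(res$per_animal, "results/em_per_animal.csv", row.names = FALSE)
cat("wrote results/em_group_summary.csv and results/em_per_animal.csv\n")
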