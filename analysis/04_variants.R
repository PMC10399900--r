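#!/usr/bin/env Rscript
# Variant comparison under identical seeded-start conditions:
#   W8A      - the eight WR tryptophans mutated to alanine; the micelle core
#              should dissolve while the wild-type core persists.
#   OnlyCTD  - NTD and DBD deleted; the condensate should become markedly
#              denser (no charged shell keeping it loose).
#   PhosphoNTD - four NTD serines at charge -1; condensate slightly looser.
# Writes results/variants.tsv.  Takes ~15 minutes.

library(nanogmicelle)
dir.create("results", showWarnings = FALSE)
seed <- 1

peak_density <- function(tr) {
  nf <- n_frames(tr)
  dp <- density_profile_z(tr, z_bin = 10, frames = seq(ceiling(2 * nf / 3), nf),
                          center = TRUE)
  max(dp$counts)
}

rows <- list()
for (v in c("WT", "W8A", "OnlyCTD", "PhosphoNTD")) {
  run <- desk_condensate(v, n_chains = 8, seed = seed, n_steps = 60000)
  ret <- wr_retention(run$trajectory)
  rows[[v]] <- data.frame(variant = v,
                          retention = ret$retention,
                          final_max_wr = tail(ret$max_sizes, 1),
                          peak_density = peak_density(run$trajectory))
  cat(sprintf("%-10s retention %.2f, peak density %.0f\n", v,
              ret$retention, rows[[v]]$peak_density))
}
tab <- do.call(rbind, rows)
write.table(tab, "results/variants.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

cat("\nW8A core dissolves while WT persists:",
    tab["W8A", "retention"] < tab["WT", "retention"] - 0.3, "\n")
cat("OnlyCTD condensate denser than WT:",
    tab["OnlyCTD", "peak_density"] > tab["WT", "peak_density"], "\n")
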