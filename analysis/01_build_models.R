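#!/usr/bin/env Rscript
# Builds every molecular model used in the study and tabulates their basic
# bookkeeping: bead counts, net charges, WR spans, DNA composition, crowder
# counts, and the average slab concentration.  Writes results/models.tsv and
# exports the wild-type topology as PDB + JSON sidecar.

library(nanogmicelle)
dir.create("results", showWarnings = FALSE)

variants <- c("WT", "W8A", "OnlyCTD", "DeltaDBD", "PhosphoNTD")
rows <- lapply(variants, function(v) {
  ch <- build_nanog(v)
  data.frame(model = v, beads = nrow(ch$beads), net_charge = net_charge(ch),
             wr_spans = nrow(ch$wr_spans),
             trp_in_wr = sum(ch$beads$code[ch$beads$wr] == "W"))
})
dna <- build_dna_duplex(50)
rows[[length(rows) + 1]] <- data.frame(
  model = "polyCG_50bp", beads = nrow(dna$beads), net_charge = net_charge(dna),
  wr_spans = 0, trp_in_wr = 0)
tab <- do.call(rbind, rows)
write.table(tab, "results/models.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
print(tab)

cr <- build_crowders(10, 8000, c(300, 300, 3000), rg = 15)
cat(sprintf("crowders for 10 wt%% PEG8000: %d spheres of radius %d A\n",
            cr$count, cr$radius))
cat(sprintf("average concentration of 200 chains in the slab box: %.2f mM\n",
            1000 * average_concentration(200)))

wt <- build_nanog("WT")
sys <- build_system(list(list(topology = wt, count = 1)),
                    box = c(300, 300, 300))
write_topology_pdb(sys, random_placement(sys, seed = 1), "results/nanog_wt")
cat("wrote results/nanog_wt.pdb (+ .json sidecar)\n")
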