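#!/usr/bin/env Rscript
# Hydrogen-bond, water-bridge and hydrophobic occupancy analysis of the
# planted complex: the occupancy table must recover exactly the planted
# interactions at their planted occupancies (1.0, 0.5, ...).

suppressPackageStartupMessages(library(alchemtraj))
dir.create("results", showWarnings = FALSE)

tr <- read_trajectory("results/inputs/complex.xyz",
                      top = read_topology("results/inputs/complex_topology.json"))
tab <- occupancy_table(tr$trajectory, tr$topology)
write_occupancy_tsv(tab, "results/occupancy.tsv")

cat("interaction occupancy (ligand-protein):\n")
print(as.data.frame(tab[, c("kind", "partner_a", "partner_b", "occupancy",
                            "conserved")]))
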