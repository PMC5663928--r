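#!/usr/bin/env Rscript
# Fixed-radius (1.6 A) k-means conformational clustering of the free and
# bound ligand ensembles: the flexible free ligand should shatter into
# many more clusters than the rigid bound one at equal sample size.

suppressPackageStartupMessages(library(alchemtraj))
dir.create("results", showWarnings = FALSE)
top <- read_topology("results/inputs/ligand_topology.json")

counts <- sapply(c(free = "free", bound = "bound"), function(state) {
  tr <- read_trajectory(sprintf("results/inputs/ligand_%s_rep1.xyz", state),
                        top = top)$trajectory
  mod <- suppressWarnings(kmeans_rmsd(tr, radius_threshold = 1.6))
  stopifnot(mod$max_radius <= 1.6)
  tab <- population_report(mod)
  write.table(tab, sprintf("results/cluster_populations_%s.tsv", state),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s ligand: %d clusters, top population %.2f\n",
              state, nrow(mod$centroids), tab$population[1]))
  nrow(mod$centroids)
})
cat(sprintf("flexibility contrast: free %d vs bound %d clusters\n",
            counts["free"], counts["bound"]))
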