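#!/usr/bin/env Rscript
# Quasi-harmonic configurational entropy of the ligand, free vs bound,
# triplicate: dS_conf = S(bound) - S(free) with replicate SEM and the
# -T*dS_conf report value at 298.15 K, plus split-window convergence.

suppressPackageStartupMessages(library(alchemtraj))
dir.create("results", showWarnings = FALSE)
top <- read_topology("results/inputs/ligand_topology.json")

reps <- lapply(1:3, function(r) {
  free <- read_trajectory(sprintf("results/inputs/ligand_free_rep%d.xyz", r),
                          top = top)$trajectory
  bound <- read_trajectory(sprintf("results/inputs/ligand_bound_rep%d.xyz", r),
                           top = top)$trajectory
  list(free = qh_entropy(mass_weighted_covariance(free, top)),
       bound = qh_entropy(mass_weighted_covariance(bound, top)))
})
dS <- delta_entropy(lapply(reps, `[[`, "bound"), lapply(reps, `[[`, "free"))
print(dS)

write.table(data.frame(replicate = 1:3, dS_conf = dS$per_replicate),
            "results/entropy_replicates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(
  list(dS_conf = dS$delta_S, sem = dS$sem,
       minus_T_dS_conf = dS$minus_T_delta_S, minus_T_sem = dS$minus_T_sem),
  "results/entropy.json", auto_unbox = TRUE, digits = NA)

# convergence check on replicate 1 (full span vs halves)
fr <- read_trajectory("results/inputs/ligand_free_rep1.xyz", top = top)$trajectory
span_ns <- max(fr$time_ps) / 1000
cw <- convergence_windows(fr, list(c(0, span_ns), c(0, span_ns / 2),
                                   c(span_ns / 2, span_ns)), top)
cat(sprintf("free-ligand convergence: |S1 - S2| / S_full = %.3f\n",
            attr(cw, "split_relative")))
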