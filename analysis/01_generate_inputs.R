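#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume:
# Gaussian ligand trajectories (free and bound), a planted
# protein-ligand-water complex, and per-window FEP sample tables.
# All files land under results/inputs/.

suppressPackageStartupMessages(library(alchemtraj))
seed <- 1L
out <- "results/inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# free (flexible) and bound (rigid) ligand trajectories, triplicate
for (r in 1:3) {
  free <- gen_gaussian_trajectory(gaussian_trajectory_spec(
    10, 2000, 1.0^2, seed = seed + 100L + r))
  bound <- gen_gaussian_trajectory(gaussian_trajectory_spec(
    10, 2000, 0.25^2, seed = seed + 200L + r))
  write_trajectory_xyz(free$trajectory, free$topology,
                       file.path(out, sprintf("ligand_free_rep%d.xyz", r)))
  write_trajectory_xyz(bound$trajectory, bound$topology,
                       file.path(out, sprintf("ligand_bound_rep%d.xyz", r)))
  if (r == 1) write_topology(free$topology,
                             file.path(out, "ligand_topology.json"))
}

# planted complex with known interactions, 100 frames
px <- gen_planted_complex(planted_complex_spec(
  hbonds = data.frame(dist = c(2.8, 2.7), angle = c(160, 150),
                      occupancy = c(1, 0.5)),
  hydrophobics = data.frame(dist = c(3.5, 3.9)),
  bridges = 1, n_frames = 100L, seed = seed + 21L))
write_trajectory_xyz(px$trajectory, px$topology,
                     file.path(out, "complex.xyz"))
write_topology(px$topology, file.path(out, "complex_topology.json"))
write_structure(get_frame(px$trajectory, 1), px$topology,
                file.path(out, "complex_frame1.pdb"))

# per-window FEP sample tables for one transformation at two temperatures
lam <- seq(0, 1, by = 0.05)
for (Tsim in c(288.15, 298.15)) {
  sigma <- 0.3; shift <- if (Tsim > 290) -1.7 else -1.1
  wins <- lapply(1:20, function(i)
    gen_fep_samples(fep_sample_spec(
      lam[i], lam[i + 1],
      mu = shift / 20 + sigma^2 / (2 * PHYS_CONST$kB * Tsim),
      sigma = sigma, n_samples = 5000, temperature = Tsim,
      seed = seed + 1000L + round(Tsim) + i)))
  write_fep_samples(wins, file.path(out, sprintf("fep_2to4_%dK.tsv",
                                                 round(Tsim))))
}

cat("inputs written to", out, ":\n ",
    paste(list.files(out), collapse = "\n  "), "\n")
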