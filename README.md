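# alchemtraj

Post-simulation analysis of relative ligand-binding thermodynamics from
molecular dynamics and alchemical free-energy perturbation (FEP) output,
written for the common drug-design question: *does replacing one linker
group in a ligand by an isostere preserve binding, and is the answer driven
by enthalpy or entropy?* The package is aimed at computational chemists who
already have trajectories and per-window energy differences from an MD
engine and need the downstream estimation, decomposition and diagnostics —
plus fully synthetic inputs with analytic ground truth for validating that
chain without any engine.

## What it computes

* **FEP estimation** — per-window Zwanzig exponential averaging,
  ΔΔG<sub>ex,i</sub> = −k<sub>B</sub>T ln ⟨exp(−ΔH/k<sub>B</sub>T)⟩, with
  overflow-safe log-sum-exp arithmetic, block (per-ns-segment) standard
  errors, bidirectional midpoint-outward window combination over a 21-point
  λ schedule, and a soft-core Lennard-Jones toy system whose exact coupling
  free energy comes from quadrature, as an end-to-end oracle.
* **Thermodynamic cycles** — closure of the three transformations between
  three ligand variants (ΔΔG<sub>b</sub> = ΔG<sub>b</sub><sup>C</sup> −
  ΔG<sub>b</sub><sup>P</sup>), with propagated SEMs.
* **Enthalpy–entropy decomposition** — finite difference between two
  simulation temperatures: ΔΔS = −(ΔΔG(T₂) − ΔΔG(T₁))/(T₂ − T₁),
  ΔΔH = ΔΔG(T₂) + T₂ΔΔS, with linear error propagation and coverage-tested
  SEMs.
* **Quasi-harmonic configurational entropy** — eigen-spectrum of the
  mass-weighted covariance of aligned ligand coordinates, quantum-oscillator
  entropy per mode, ΔS<sub>conf</sub> = S(complex) − S(free) over
  replicates, −TΔS<sub>conf</sub> reporting, split-window convergence.
* **Interaction occupancy** — geometric hydrogen bonds (≥ 120°, D···A
  ≤ 3 Å), single-water bridges, hydrophobic contacts (≤ 4 Å), per-frame
  bitmaps and occupancy tables.
* **Structural metrics** — Kabsch superposition, RMSD series (align on one
  selection, report on another), per-atom RMSF.
* **Conformational clustering** — radius-driven k-means under heavy-atom
  RMSD with a 1.6 Å cluster-radius guarantee and population reports.
* **Synthetic data** — Gaussian trajectories with prescribed covariance,
  Gaussian FEP windows with closed-form ΔG, linear-in-T free-energy series,
  planted protein–ligand–water complexes, and the 10-ps triplicate sampling
  bookkeeping (27,000 complexed / 6,000 free-ligand structures).
* **I/O** — PDB and CHARMM DCD (via bio3d) plus multi-frame XYZ, a
  JSON/YAML topology sidecar with explicit donor/acceptor/hydrophobic
  flags, and a TSV dialect for per-window FEP samples.

## Worked example

```r
library(alchemtraj)

# a 20-window transformation with planted total -1.7 kcal/mol at 298.15 K
lam <- seq(0, 1, by = 0.05); sigma <- 0.3; kBT <- PHYS_CONST$kB * 298.15
wins <- lapply(1:20, function(i)
  gen_fep_samples(fep_sample_spec(lam[i], lam[i + 1],
    mu = -1.7 / 20 + sigma^2 / (2 * kBT), sigma = sigma,
    n_samples = 5000, block_size = 1000, seed = i)))
tot <- combine_windows(lapply(wins, zwanzig_window))
print(tot)
#> transformation ddG = -1.7036 +/- 0.0164 kcal/mol (20 windows, bidirectional-midpoint, 298.15 K)

# cycle closure of the three reported linker transformations at 298 K
cc <- cycle_closure(cycle_spec(c("2->4", "4->3", "2->3"),
                               ddG = c(-1.7, -0.5, -1.4),
                               orientation = c(1, 1, -1)))
print(cc)
#> cycle closure = -0.8 +/- 0 kcal/mol over 3 legs

# two-temperature decomposition of the 2->4 leg
d <- vant_hoff_decompose(-1.1, -1.7, 288.15, 298.15, 0.8, 0.4, label = "2->4")
print(d)
#> 2->4: ddG(298.15 K) = -1.7 +/- 0.4; ddH = 16.19 +/- 27; -T ddS(298.15 K) = -17.89 +/- 27 kcal/mol
```

The decomposition output shows the enthalpy–entropy compensation pattern:
a large unfavourable ΔΔH offset by a favourable −TΔΔS, leaving ΔΔG small —
and error propagation inflating the component uncertainties far beyond the
free-energy SEMs.

The numbered scripts under `analysis/` run the whole chain on generated
inputs (`01_generate_inputs.R` … `07_clustering.R`), writing tables under
`results/`. `run_pipeline()` does the same in one call with a validated
configuration whose defaults encode all the analysis constants (120°/3 Å/
4 Å criteria, 1.6 Å cluster radius, 288.15/298.15 K, 21-point λ list,
10-ps sampling).

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the estimators,
their assumptions, the numerical choices and the limits of what the
synthetic-data validation demonstrates.
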