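---
title: "Methods: alchemical free energies and trajectory thermodynamics with alchemtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alchemical free energies and trajectory thermodynamics with alchemtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alchemtraj)
```

# Scope and model

`alchemtraj` implements the post-simulation analysis chain used to compare
ligands that differ in a single linker group: free-energy perturbation (FEP)
estimation with thermodynamic-cycle closure, a two-temperature
enthalpy--entropy decomposition, quasi-harmonic configurational entropy,
geometric interaction-occupancy analysis, and fixed-radius conformational
clustering. It deliberately does *not* run molecular dynamics: every stage
consumes trajectories or per-window energy-difference samples, and a
synthetic-data module generates those inputs with analytically known ground
truth so each stage can be validated end to end.

# Free-energy estimation

## Window estimator

Each $\lambda$ subinterval is estimated by Zwanzig exponential averaging,

$$\Delta\Delta G_{ex,i} = -k_B T \,\ln\left\langle
  e^{-(H(\lambda_{i+1}) - H(\lambda_i))/k_B T}\right\rangle_{\lambda_i},$$

implemented with a log-sum-exp contract so that adding a constant $c$ to all
samples shifts the estimate by exactly $c$ regardless of magnitude
(`zwanzig_window()` tests this with shifts of $\pm 800$ kcal/mol). The
default schedule is the 21-point list $0, 0.05, \dots, 0.95, 1$, giving 20
windows; `validate_lambda_schedule()` rejects gapped or unordered lists.
Reverse-direction windows (sampled midpoint-outward, e.g.
$0.0 \leftarrow 0.05 \rightarrow 0.1$) are mapped onto the forward axis with
negated sign by `combine_windows()`, which validates that the mapped
subintervals tile $[0,1]$ exactly before summing. We chose sign-mapped
summation rather than averaging forward/reverse estimates of the same
subinterval because the midpoint-outward scheme produces each subinterval
exactly once; an averaging mode (`duplicates = "average"`) exists for
schedules that do sample both directions of one subinterval. BAR/MBAR are
intentionally out of scope: the analysis mirrors plain exponential
averaging, and a BAR implementation would change the estimator being
validated.

## Uncertainty

The SEM of a window is the block standard error over consecutive sample
blocks (the analogue of per-nanosecond simulation segments):
block estimates are full Zwanzig estimates on each block, and
$\mathrm{SEM} = \mathrm{sd}(\text{blocks})/\sqrt{n_\text{blocks}}$.
Transformation totals add window variances in quadrature, i.e. windows are
treated as independent — a documented simplification that matches the
per-segment error analysis it reproduces. Without a block size a
first-order delta-method SEM is used.

## Validation oracles

Two oracles validate the chain. (1) Gaussian windows: for
$\Delta H \sim \mathcal N(\mu, \sigma^2)$ the estimator must converge to
$\mu - \sigma^2/2k_BT$ (second-cumulant identity). (2) A toy alchemical
system: one soft-core Lennard-Jones particle coupled to a fixed particle
inside a sphere of radius $R$. The separation-shifted soft-core form

$$U(r, \lambda) = 4\epsilon\lambda\left[
 \left(\tfrac{\sigma^2}{\alpha(1-\lambda)+r^2}\right)^{6} -
 \left(\tfrac{\sigma^2}{\alpha(1-\lambda)+r^2}\right)^{3}\right],
 \qquad \alpha = 4.0\ \text{\AA}^2,$$

is finite at $r = 0$ for $\lambda < 1$ and reduces to standard LJ at
$\lambda = 1$. The exact coupling free energy follows from 1-D radial
quadrature of $Z(\lambda) = \int_0^R 4\pi r^2 e^{-U/k_BT}\,dr$
(`toy_alchemical_reference()`), fully independent of sampling; Monte-Carlo
samples are drawn from the exact radial Boltzmann density by inverse-CDF
sampling on a 4096-point grid (`sample_toy_fep()`). A sphere (rather than a
cubic box) was chosen as the confinement volume because it makes both the
quadrature and the sampler exact one-dimensional operations; nothing
downstream depends on the shape.

# Cycle closure and enthalpy–entropy decomposition

Three transformations between three ligands form a closed cycle; the signed
sum of the legs (`cycle_closure()`) measures convergence, with SEMs added
in quadrature. The decomposition uses the finite-temperature difference of
totals measured at $T_1 = 288.15$ K and $T_2 = 298.15$ K:

$$\Delta\Delta S = -\frac{\Delta\Delta G(T_2)-\Delta\Delta G(T_1)}{T_2-T_1},
\qquad \Delta\Delta H = \Delta\Delta G(T_2) + T_2\,\Delta\Delta S,$$

anchored at $T_2$ so that $\Delta\Delta H - T_2\Delta\Delta S$ reproduces
$\Delta\Delta G(T_2)$ to machine precision. Errors propagate linearly
treating the two temperatures as independent; a coverage experiment (1,000
seeded repeats of planted linear $\Delta G(T)$ plus Gaussian noise) checks
that the 1-SEM interval covers the true slope at the nominal 68%. Inputs
are transformation totals, not per-window values. Report tables carry
unrounded values plus display columns rounded to 1 decimal (free energies)
and the nearest 10 (components), reflecting the much larger propagated
errors of the components.

# Quasi-harmonic configurational entropy

Frames are superposed onto a reference over the ligand heavy atoms (Kabsch,
mass-unweighted) to remove overall rotation and translation; the
mass-weighted covariance $\sigma = M^{1/2} C M^{1/2}$ is accumulated and
eigen-decomposed. Each eigenvalue $\lambda$ (amu Å$^2$) defines a mode of
frequency $\omega = \sqrt{k_B T/\lambda}$ and the entropy defaults to the
quantum-oscillator form

$$S = k_B \sum_i \left[\frac{\alpha_i}{e^{\alpha_i}-1} -
  \ln(1 - e^{-\alpha_i})\right], \qquad \alpha_i = \hbar\omega_i/k_BT,$$

with the classical form $k_B\sum_i(1-\ln\alpha_i)$ available by flag; the
quantum form is the default because it is what the standard quasi-harmonic
module of the CHARMM lineage reports, and the two agree within 1% in the
high-temperature limit (tested). Superposition drives six rigid-body modes
to numerical zero ($\sim 10^{-16}$ amu Å$^2$ empirically); the eigenvalue
floor of $10^{-8}$ amu Å$^2$ discards them and the discarded count is
reported. Hydrogens are excluded by the default heavy-atom selection; both
the floor and the selection are configuration options because different
upstream tools make different choices here. $\Delta S_{conf} =
S_{bound} - S_{free}$ is computed per replicate (paired by index), and the
reported error is the SEM over replicates — not within-trajectory error
propagation — matching how triplicate simulation tables report it.
Convergence is monitored by recomputing the entropy on sub-windows (full
span vs halves).

All physical constants ($k_B = 1.987204\times10^{-3}$ kcal/mol/K, $\hbar$,
unit conversions) live in the single `PHYS_CONST` table so the identity
tests across modules see bit-identical constants.

# Interaction occupancy

A hydrogen bond requires a donor–hydrogen–acceptor angle $\ge 120^\circ$
and a donor-to-acceptor heavy-atom distance $\le 3$ Å — the distance is
read literally as heavy-atom (D···A) separation, with the H···A alternative
available by configuring the cutoff, since upstream tools differ. A
hydrophobic contact requires two hydrophobic-flagged atoms of different
molecules within 4 Å; because "hydrophobic atom" is rarely defined
precisely, the default derivation (C or S bonded only to C, S or H) is
explicit in the topology sidecar and overridable. A water bridge is a
single water hydrogen-bonded (either role) to a ligand atom and a protein
atom in the same frame; two-water chains are excluded by definition.
Occupancy is the fraction of frames a record is present; tables impose no
"conserved" threshold but annotate occupancy $\ge 0.5$. Detection is
rotation/translation invariant and monotone under cutoff tightening, both
property-tested.

# Conformational clustering

`kmeans_rmsd()` is a radius-driven k-means over ligand heavy-atom RMSD in
the style of MMTSB's kclust: structures are globally superposed onto the
first structure so RMSD becomes a Euclidean distance on flattened
coordinates; k grows until every member lies within the radius threshold
(default 1.6 Å) of its centroid, which is asserted on every model. Growth
is deterministic — the first structure seeds $k=1$, and each pass seeds a
new centroid at the farthest member of every cluster still violating the
radius. Splitting all violating clusters per pass (rather than only the
widest) was adopted because it reaches the same radius guarantee in
$O(\log k)$ passes instead of $O(k)$, which matters when a flexible ligand
shatters into hundreds of clusters; assignments between splits iterate
mean-update/reassign to a fixpoint (ties to the lowest cluster index,
100-iteration cap with best-so-far warning). A pairwise-superposition
distance mode exists for small sets; global alignment is the default
because the clustered structures are already aligned ligand conformers.

# Synthetic data as study conditions

The generator reproduces the bookkeeping of the study it mirrors: frames
every 10 ps over ns segments 11–100 (bound complex, triplicate, 27,000
structures) and 1–20 (free ligand, triplicate, 6,000 structures). Window
labels count whole nanosecond segments, so segment 11 begins at $t = 10$ ns
exclusive: `segment_schedule(11, 100, 10, 3)` is the only frame-placement
convention consistent with both printed counts. Trajectories are i.i.d.
Gaussian per frame (optional AR(1) correlation for SEM experiments) — this
gives exact first/second moments at the cost of realism in kinetics, so
passing tests validate estimator arithmetic and convergence, not force-field
physics. Ligand fluctuation scales default to 0.25 Å per coordinate
(bound/rigid) and 1.0 Å (free/flexible): at the 1.6 Å cluster radius these
produce one cluster and hundreds of clusters respectively, a deliberate
qualitative mirror of a rigid linker versus a flexible one. Planted
complexes place every interaction with a margin of at least 0.1 Å / 5°
on the relevant criterion (positive or negative), 30 Å apart so nothing
unplanned can fire; waters are ideal 3-site. FEP sample specs are Gaussian
with the exact free energy $\mu - \sigma^2/2k_BT$; pipeline demos offset
$\mu$ by $\sigma^2/2k_BT$ so the planted per-leg totals are exact.

# Numerical choices and edge cases

* Kabsch superposition uses base `svd()` with the reflection-corrected
  branch; under-determined selections (< 3 non-collinear atoms) warn rather
  than error, because the optimal RMSD is still well defined even when the
  rotation is not unique (`strict = TRUE` upgrades to an error).
* Covariances are symmetrised before eigen-decomposition; generator
  covariances are validated PSD via their spectrum (tolerance
  $10^{-8}$ relative).
* The soft-core energy is computed in the factored form
  $4\epsilon\lambda\,q^3(q^3-1)$ so the $r\to 0,\ \lambda\to 1$ corner
  yields $+\infty$ rather than NaN.
* Degenerate inputs error early with named diagnostics: empty selections,
  non-dividing sampling intervals, open thermodynamic cycles (unmatched
  states listed), gapped $\lambda$ schedules (missing interval printed),
  donors without hydrogens (atom named).
* Problem sizes in the validation suite (e.g. $10^5$ frames for entropy
  convergence, $2\times10^5$ samples per Gaussian window, 5,000 structures
  for clustering, 1,000 repeats for SEM coverage) were chosen so each check
  resolves its tolerance comfortably at interactive runtimes.

# Known limitations

Window independence in the transformation SEM ignores correlation between
adjacent windows sharing configurations. The quasi-harmonic model captures
only ligand configurational entropy — no solvent or protein terms, no
anharmonic/multimodal corrections, so its $\Delta S_{conf}$ is a diagnostic
of conformational restriction, not a full binding entropy. Gaussian
synthetic trajectories cannot probe sampling pathologies (metastability,
hysteresis) that real alchemical simulations exhibit; the toy system probes
the estimator, not the sampler. The PDB/DCD readers cover the common
fixed-column and CHARMM dialects only.
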