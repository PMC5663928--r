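#' Mass-weighted coordinate covariance of an aligned trajectory
#'
#' Each frame is superposed onto the reference over the selection (removing
#' overall translation and rotation), then the covariance C of the flattened
#' selection coordinates is accumulated and mass-weighted as
#' \eqn{\sigma = M^{1/2} C M^{1/2}} with M the diagonal matrix of atomic
#' masses (each repeated for x, y, z). Eigenvalues of \eqn{\sigma} are in
#' amu A^2.
#'
#' @param traj a [trajectory()].
#' @param top a [topology()] supplying masses.
#' @param selection atom indices (default: heavy atoms).
#' @param reference `n x 3` reference coordinates (default: first frame).
#' @param align superpose frames first (disable for pre-aligned input or
#'   closed-form checks on free atoms).
#' @param mass_weight apply the mass weighting (default TRUE).
#' @return symmetric `3*n_sel x 3*n_sel` matrix with attributes `masses`,
#'   `selection` and `n_frames_used`.
#' @export
mass_weighted_covariance <- function(traj, top, selection = NULL,
                                     reference = NULL, align = TRUE,
                                     mass_weight = TRUE) {
  if (is.null(selection)) selection <- which(top$atoms$is_heavy)
  if (!length(selection)) stop("empty selection")
  nf <- n_frames(traj)
  if (nf < 2) stop("covariance requires at least 2 frames")
  if (nf < 3 * length(selection) + 1)
    warning("only ", nf, " frames for ", 3 * length(selection),
            " degrees of freedom; covariance will be rank-deficient")
  X <- aligned_coordinate_matrix(traj, reference, selection,
                                 align_selection = selection, align = align)
  C <- stats::cov(X)
  if (mass_weight) {
    sq <- sqrt(rep(top$atoms$mass[selection], each = 3L))
    C <- sq * t(sq * C)              # M^{1/2} C M^{1/2}
  }
  C <- (C + t(C)) / 2
  attr(C, "masses") <- top$atoms$mass[selection]
  attr(C, "selection") <- selection
  attr(C, "n_frames_used") <- nf
  C
}

#' Quasi-harmonic configurational entropy from a covariance matrix
#'
#' Eigen-decomposes the mass-weighted covariance; each retained eigenvalue
#' \eqn{\lambda} defines a quasi-harmonic mode of angular frequency
#' \eqn{\omega = \sqrt{k_B T / \lambda}}. The default entropy is the
#' quantum-oscillator form,
#' \deqn{S = k_B \sum_i \left[ \frac{\alpha_i}{e^{\alpha_i} - 1} -
#'   \ln(1 - e^{-\alpha_i}) \right], \quad \alpha_i = \hbar\omega_i / k_B T,}
#' with the classical-oscillator form \eqn{k_B \sum_i (1 - \ln \alpha_i)}
#' available by flag. Modes with eigenvalue below `eigen_floor` — including
#' the six rigid-body modes left by alignment — are discarded and counted.
#'
#' @param covariance matrix from [mass_weighted_covariance()] (amu A^2).
#' @param temperature Kelvin.
#' @param classical use the classical high-temperature form.
#' @param eigen_floor eigenvalue cutoff (amu A^2, default 1e-8).
#' @param window_label free-text label carried into the result.
#' @return list of class `qh_entropy`: `eigenvalues` (amu A^2, descending),
#'   `mode_frequencies` (rad/s, for retained modes), `entropy` (kcal/mol/K),
#'   `temperature`, `n_modes_retained`, `n_modes_discarded`,
#'   `n_frames_used`, `window_label`, `classical`.
#' @export
qh_entropy <- function(covariance, temperature = 298.15, classical = FALSE,
                       eigen_floor = 1e-8, window_label = "") {
  stopifnot(temperature > 0)
  if (max(abs(covariance - t(covariance))) >
      1e-6 * max(1, max(abs(covariance))))
    stop("covariance matrix is not symmetric")
  ev <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  keep <- ev > eigen_floor
  n_disc <- sum(!keep)
  lam <- ev[keep]
  if (!length(lam)) {
    warning("all modes below the eigenvalue floor; entropy = 0")
    omega <- numeric(0); S <- 0
  } else {
    kBT_J <- .kBT_joule(temperature)
    lam_SI <- lam * PHYS_CONST$kg_per_amu * PHYS_CONST$m2_per_A2
    omega <- sqrt(kBT_J / lam_SI)
    alpha <- PHYS_CONST$hbar * omega / kBT_J
    per_mode <- if (classical) 1 - log(alpha)
      else alpha / expm1(alpha) - log1p(-exp(-alpha))
    S <- PHYS_CONST$kB * sum(per_mode)
  }
  structure(list(eigenvalues = ev, mode_frequencies = omega, entropy = S,
                 temperature = temperature,
                 n_modes_retained = length(lam), n_modes_discarded = n_disc,
                 n_frames_used = attr(covariance, "n_frames_used"),
                 window_label = window_label, classical = classical),
            class = "qh_entropy")
}

#' @export
print.qh_entropy <- function(x, ...) {
  cat(sprintf(
    "quasi-harmonic entropy%s: S = %.6g kcal/mol/K at %g K (%d modes, %d discarded)\n",
    if (nzchar(x$window_label)) paste0(" [", x$window_label, "]") else "",
    x$entropy, x$temperature, x$n_modes_retained, x$n_modes_discarded))
  invisible(x)
}

#' Closed-form entropy of a specified harmonic system
#'
#' Independent oracle for [qh_entropy()]: the exact oscillator entropy for
#' the eigenvalues of a covariance specified analytically (no sampling).
#'
#' @param eigenvalues mass-weighted covariance eigenvalues (amu A^2).
#' @param temperature Kelvin.
#' @param classical classical form instead of quantum.
#' @return entropy in kcal/mol/K.
#' @export
harmonic_entropy_exact <- function(eigenvalues, temperature = 298.15,
                                   classical = FALSE) {
  qh_entropy(diag(eigenvalues, nrow = length(eigenvalues)),
             temperature = temperature, classical = classical,
             eigen_floor = 0)$entropy
}

#' Configurational entropy change on binding, with replicate SEM
#'
#' Per-replicate \eqn{\Delta S_{conf} = S_{complex} - S_{free}} (replicates
#' paired by index), the arithmetic mean with its standard error over
#' replicates, and \eqn{-T \Delta S_{conf}} at the stated temperature.
#'
#' @param complex_results list of [qh_entropy()] results (one per replicate)
#'   for the bound ligand.
#' @param free_results matching list for the free ligand.
#' @param temperature report temperature (K, default 298.15).
#' @return list of class `delta_entropy`: `per_replicate` (kcal/mol/K),
#'   `delta_S` (mean), `sem`, `minus_T_delta_S`, `minus_T_sem`,
#'   `temperature`.
#' @export
delta_entropy <- function(complex_results, free_results,
                          temperature = 298.15) {
  if (inherits(complex_results, "qh_entropy")) complex_results <- list(complex_results)
  if (inherits(free_results, "qh_entropy")) free_results <- list(free_results)
  if (length(complex_results) != length(free_results))
    stop("mismatched replicate counts: ", length(complex_results), " vs ",
         length(free_results))
  if (!length(complex_results)) stop("need at least 1 replicate")
  dS <- vapply(seq_along(complex_results), function(i)
    complex_results[[i]]$entropy - free_results[[i]]$entropy, numeric(1))
  m <- mean(dS)
  sem <- if (length(dS) > 1) stats::sd(dS) / sqrt(length(dS)) else 0
  structure(list(per_replicate = dS, delta_S = m, sem = sem,
                 minus_T_delta_S = -temperature * m,
                 minus_T_sem = temperature * sem,
                 temperature = temperature),
            class = "delta_entropy")
}

#' @export
print.delta_entropy <- function(x, ...) {
  cat(sprintf(
    "dS_conf = %.4g +/- %.2g kcal/mol/K; -T dS_conf = %.4g +/- %.2g kcal/mol at %g K (n = %d)\n",
    x$delta_S, x$sem, x$minus_T_delta_S, x$minus_T_sem, x$temperature,
    length(x$per_replicate)))
  invisible(x)
}

#' Windowed entropy for convergence monitoring
#'
#' Computes the quasi-harmonic entropy over time windows of a trajectory
#' (e.g. the full span and its two halves) to monitor convergence. Window
#' bounds are in ns with the start exclusive and end inclusive, matching
#' [sampling_schedule()]; a window labelled by first/last included ns
#' segment can be formed with `c(first - 1, last)`.
#'
#' @param traj a [trajectory()] with timestamps in ps.
#' @param windows list of `c(start_ns, end_ns)` pairs.
#' @param top,selection,reference,align passed to
#'   [mass_weighted_covariance()].
#' @param temperature,classical,eigen_floor passed to [qh_entropy()].
#' @return list of [qh_entropy()] results, one per window, labelled
#'   "start-end ns"; attribute `split_relative` holds
#'   |S_first - S_second| / S_full when >= 3 windows are given (full span
#'   first).
#' @export
convergence_windows <- function(traj, windows, top, selection = NULL,
                                reference = NULL, align = TRUE,
                                temperature = 298.15, classical = FALSE,
                                eigen_floor = 1e-8) {
  res <- lapply(windows, function(w) {
    stopifnot(length(w) == 2, w[2] > w[1])
    idx <- which(traj$time_ps > w[1] * 1000 & traj$time_ps <= w[2] * 1000)
    if (!length(idx))
      stop("window ", w[1], "-", w[2], " ns contains no frames")
    sub <- subset_frames(traj, idx)
    C <- mass_weighted_covariance(sub, top, selection, reference, align)
    qh_entropy(C, temperature, classical, eigen_floor,
               window_label = paste0(w[1], "-", w[2], " ns"))
  })
  if (length(res) >= 3 && res[[1]]$entropy > 0)
    attr(res, "split_relative") <-
      abs(res[[2]]$entropy - res[[3]]$entropy) / res[[1]]$entropy
  res
}
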