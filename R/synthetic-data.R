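#' Specify a Gaussian-fluctuation trajectory
#'
#' Defines a multivariate-normal surrogate for an MD trajectory: frames are
#' drawn about `mean_structure` with a prescribed covariance over the
#' 3*n_atoms Cartesian coordinates (atom-major flattening x1,y1,z1,x2,...).
#' The covariance is the analytic ground truth that downstream fluctuation,
#' entropy and clustering stages must recover.
#'
#' @param n_atoms number of atoms.
#' @param n_frames number of frames to draw.
#' @param covariance either a full symmetric PSD `3n x 3n` matrix (A^2), a
#'   length-`3n` vector of per-coordinate variances, or a single scalar
#'   isotropic variance.
#' @param mean_structure `n_atoms x 3` matrix (A); default atoms spaced 5 A
#'   along x.
#' @param masses atomic masses (amu); default 12 (carbon-like).
#' @param rigid_motion logical; superimpose a random rigid rotation +
#'   translation on every frame (exercises alignment-removal code paths).
#' @param ar1 lag-1 autocorrelation of the latent noise in (0,1); 0 = i.i.d.
#'   frames. The stationary marginal covariance is unchanged.
#' @param seed integer RNG seed.
#' @return list of class `gaussian_trajectory_spec`.
#' @export
gaussian_trajectory_spec <- function(n_atoms, n_frames, covariance,
                                     mean_structure = NULL, masses = NULL,
                                     rigid_motion = FALSE, ar1 = 0,
                                     seed = 1L) {
  d <- 3L * n_atoms
  if (length(covariance) == 1L) covariance <- rep(covariance, d)
  if (is.vector(covariance)) {
    stopifnot(length(covariance) == d)
    covariance <- diag(covariance, nrow = d)
  }
  stopifnot(nrow(covariance) == d, ncol(covariance) == d)
  if (max(abs(covariance - t(covariance))) > 1e-8 * max(1, max(abs(covariance))))
    stop("covariance matrix is not symmetric")
  if (is.null(mean_structure))
    mean_structure <- cbind(5 * (seq_len(n_atoms) - 1), 0, 0)
  if (is.null(masses)) masses <- rep(12.011, n_atoms)
  stopifnot(length(masses) == n_atoms, all(masses > 0),
            n_frames >= 1, ar1 >= 0, ar1 < 1)
  structure(list(n_atoms = as.integer(n_atoms), n_frames = as.integer(n_frames),
                 covariance = covariance, mean_structure = mean_structure,
                 masses = masses, rigid_motion = rigid_motion, ar1 = ar1,
                 seed = as.integer(seed)),
            class = "gaussian_trajectory_spec")
}

# symmetric PSD square root; rejects matrices with meaningfully negative spectrum
.psd_sqrt <- function(sigma, tol = 1e-8) {
  es <- eigen(sigma, symmetric = TRUE)
  lo <- min(es$values)
  if (lo < -tol * max(1, max(abs(es$values))))
    stop("covariance is not positive semi-definite (min eigenvalue ",
         format(lo), ")")
  es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
}

.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Generate a Gaussian trajectory with known covariance
#'
#' @param spec a [gaussian_trajectory_spec()].
#' @return list with elements `trajectory` and `topology`. Same spec + seed
#'   gives bit-identical output.
#' @export
gen_gaussian_trajectory <- function(spec) {
  stopifnot(inherits(spec, "gaussian_trajectory_spec"))
  S <- .psd_sqrt(spec$covariance)
  d <- 3L * spec$n_atoms
  set.seed(spec$seed)
  Z <- matrix(stats::rnorm(spec$n_frames * d), spec$n_frames, d)
  if (spec$ar1 > 0 && spec$n_frames > 1L) {
    rho <- spec$ar1
    for (f in 2:spec$n_frames)
      Z[f, ] <- rho * Z[f - 1, ] + sqrt(1 - rho^2) * Z[f, ]
  }
  X <- Z %*% S
  mu <- as.vector(t(spec$mean_structure))       # atom-major flatten
  coords <- array(0, dim = c(spec$n_frames, spec$n_atoms, 3L))
  for (f in seq_len(spec$n_frames)) {
    fr <- matrix(mu + X[f, ], ncol = 3L, byrow = TRUE)
    if (isTRUE(spec$rigid_motion)) {
      R <- .random_rotation()
      tr <- stats::rnorm(3, sd = 5)
      fr <- fr %*% t(R) + matrix(tr, nrow(fr), 3, byrow = TRUE)
    }
    coords[f, , ] <- fr
  }
  atoms <- data.frame(
    name = paste0("C", seq_len(spec$n_atoms)), element = "C",
    mass = spec$masses, resno = 1L, resname = "LIG", segid = "LIG",
    molclass = "ligand", stringsAsFactors = FALSE)
  list(trajectory = trajectory(coords),
       topology = topology(atoms))
}

#' Specify per-window FEP energy-difference samples
#'
#' Gaussian surrogate for one lambda-window's forward energy differences
#' H(lambda_to) - H(lambda_from). For Gaussian samples the exact free energy
#' is available in closed form (second-cumulant identity),
#' \eqn{\Delta G = \mu - \sigma^2 / (2 k_B T)}, exposed by
#' [fep_analytic_ddG()].
#'
#' @param lambda_from,lambda_to window endpoints in `[0,1]`.
#' @param mu,sigma mean and standard deviation of the samples (kcal/mol).
#' @param n_samples number of draws (>= 1).
#' @param temperature Kelvin.
#' @param block_size samples per block for block-SEM analysis (optional).
#' @param seed integer RNG seed.
#' @return list of class `fep_sample_spec`.
#' @export
fep_sample_spec <- function(lambda_from, lambda_to, mu, sigma, n_samples,
                            temperature = 298.15, block_size = NULL,
                            seed = 1L) {
  stopifnot(sigma >= 0, n_samples >= 1,
            lambda_from >= 0, lambda_from <= 1,
            lambda_to >= 0, lambda_to <= 1,
            lambda_from != lambda_to, temperature > 0)
  structure(list(lambda_from = lambda_from, lambda_to = lambda_to, mu = mu,
                 sigma = sigma, n_samples = as.integer(n_samples),
                 temperature = temperature, block_size = block_size,
                 seed = as.integer(seed)),
            class = "fep_sample_spec")
}

#' @rdname fep_sample_spec
#' @param spec a `fep_sample_spec`.
#' @return `fep_analytic_ddG`: the exact Zwanzig free energy (kcal/mol) of
#'   the Gaussian window.
#' @export
fep_analytic_ddG <- function(spec) {
  spec$mu - spec$sigma^2 / (2 * .kBT(spec$temperature))
}

#' Generate FEP window samples from a spec
#'
#' @param spec a [fep_sample_spec()].
#' @return a [fep_window_samples()] object.
#' @export
gen_fep_samples <- function(spec) {
  stopifnot(inherits(spec, "fep_sample_spec"))
  set.seed(spec$seed)
  s <- stats::rnorm(spec$n_samples, spec$mu, spec$sigma)
  fep_window_samples(spec$lambda_from, spec$lambda_to, spec$temperature, s,
                     block_size = spec$block_size)
}

#' Linear-in-temperature free-energy series
#'
#' Evaluates \eqn{\Delta G(T) = \Delta H - T \Delta S} exactly at the given
#' temperatures; the two-temperature decomposition stage must recover
#' `(dH, dS)` from any such series to machine precision.
#'
#' @param dH enthalpy (kcal/mol).
#' @param dS entropy (kcal/mol/K).
#' @param temperatures >= 2 distinct temperatures (K).
#' @return numeric vector of free energies (kcal/mol), named by temperature.
#' @export
gen_vant_hoff_series <- function(dH, dS, temperatures) {
  if (length(temperatures) < 2) stop("need at least 2 temperatures")
  if (anyDuplicated(temperatures)) stop("duplicate temperatures")
  stats::setNames(dH - temperatures * dS, as.character(temperatures))
}

#' Frame-sampling schedule over a simulation span
#'
#' Frames are placed at `t = span_start + k * interval` for `k = 1..N`: the
#' span-start instant is excluded and the span end included, so a span of
#' (10, 100] ns at 10 ps holds exactly 9,000 frames per replicate. The
#' companion [segment_schedule()] accepts the common "first ns - last ns"
#' labelling of analysis windows (segments 11..100 cover the time span
#' (10, 100] ns).
#'
#' @param span_start_ns,span_end_ns span bounds (ns); start exclusive, end
#'   inclusive.
#' @param interval_ps sampling interval (ps); must divide the span evenly.
#' @param replicates number of independent replicate simulations combined.
#' @return list of class `sampling_schedule`.
#' @export
sampling_schedule <- function(span_start_ns, span_end_ns, interval_ps = 10,
                              replicates = 1L) {
  stopifnot(span_end_ns > span_start_ns, interval_ps > 0, replicates >= 1)
  span_ps <- (span_end_ns - span_start_ns) * 1000
  n <- span_ps / interval_ps
  if (abs(n - round(n)) > 1e-9)
    stop("interval ", interval_ps, " ps does not divide the span ",
         span_ps, " ps evenly")
  structure(list(span_start_ns = span_start_ns, span_end_ns = span_end_ns,
                 interval_ps = interval_ps, replicates = as.integer(replicates),
                 frames_per_replicate = as.integer(round(n))),
            class = "sampling_schedule")
}

#' @rdname sampling_schedule
#' @param first_ns,last_ns first and last nanosecond segments included
#'   (e.g. 11 and 100).
#' @export
segment_schedule <- function(first_ns, last_ns, interval_ps = 10,
                             replicates = 1L) {
  sampling_schedule(first_ns - 1, last_ns, interval_ps, replicates)
}

#' Expand a schedule into frame counts and timestamps
#'
#' @param schedule a [sampling_schedule()].
#' @return list with `count` (total frames over all replicates),
#'   `frames_per_replicate`, and `time_ps` (per-replicate timestamps).
#' @export
gen_schedule_frames <- function(schedule) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  n <- schedule$frames_per_replicate
  t_ps <- schedule$span_start_ns * 1000 +
    seq_len(n) * schedule$interval_ps
  list(count = n * schedule$replicates,
       frames_per_replicate = n,
       time_ps = t_ps)
}
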