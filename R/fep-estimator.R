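#' Per-window FEP energy-difference samples
#'
#' Container for one lambda subinterval's samples of
#' H(lambda_to) - H(lambda_from) (kcal/mol) collected in the
#' lambda_from ensemble at a stated temperature.
#'
#' @param lambda_from,lambda_to window endpoints in `[0,1]`,
#'   `lambda_from != lambda_to`. `lambda_from > lambda_to` denotes a
#'   reverse-direction window.
#' @param temperature Kelvin.
#' @param samples numeric vector of energy differences (kcal/mol),
#'   non-empty, all finite.
#' @param block_size samples per block for block-SEM analysis (optional).
#' @return list of class `fep_window_samples`.
#' @export
fep_window_samples <- function(lambda_from, lambda_to, temperature, samples,
                               block_size = NULL) {
  stopifnot(length(samples) >= 1,
    lambda_from >= 0, lambda_from <= 1, lambda_to >= 0, lambda_to <= 1,
    lambda_from != lambda_to, temperature > 0)
  if (any(!is.finite(samples))) stop("non-finite samples")
  structure(list(lambda_from = lambda_from, lambda_to = lambda_to,
                 temperature = temperature, samples = as.numeric(samples),
                 block_size = block_size),
            class = "fep_window_samples")
}

# overflow-safe log(mean(exp(x)))
.log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Zwanzig exponential-average window estimator
#'
#' Free energy of one lambda window from exponential averaging,
#' \deqn{\Delta\Delta G_{ex,i} = -k_B T \ln \langle
#'   \exp[-(H(\lambda_{i+1}) - H(\lambda_i)) / k_B T] \rangle_{\lambda_i},}
#' computed with a log-sum-exp contract so the result is unchanged (to
#' machine precision) by subtracting any constant from all samples and
#' adding it back. The SEM is the block standard error when a block size is
#' available (see [block_sem()]), otherwise a first-order delta-method
#' estimate from the sample variance of the exponential weights.
#'
#' @param w a [fep_window_samples()].
#' @param block_size overrides the block size stored in `w`.
#' @return list of class `window_estimate`: `lambda_from`, `lambda_to`,
#'   `ddG` (kcal/mol), `sem`, `n_samples`, `block_estimates` (NULL without
#'   blocks), `temperature`.
#' @export
zwanzig_window <- function(w, block_size = NULL) {
  stopifnot(inherits(w, "fep_window_samples"))
  if (is.null(block_size)) block_size <- w$block_size
  kBT <- .kBT(w$temperature)
  ddG_of <- function(s) -kBT * .log_mean_exp(-s / kBT)
  ddG <- ddG_of(w$samples)
  n <- length(w$samples)
  blocks <- NULL
  if (!is.null(block_size) && n >= 2 * block_size) {
    bs <- block_sem(w, block_size)
    sem <- bs$sem
    blocks <- bs$block_estimates
  } else {
    # delta method on m = mean(exp(-s/kBT)): sd(ddG) ~ kBT * sd(e)/ (m sqrt(n))
    e <- exp(-(w$samples - min(w$samples)) / kBT)
    sem <- if (n > 1) kBT * stats::sd(e) / (mean(e) * sqrt(n)) else 0
  }
  structure(list(lambda_from = w$lambda_from, lambda_to = w$lambda_to,
                 ddG = ddG, sem = sem, n_samples = n,
                 block_estimates = blocks, temperature = w$temperature),
            class = "window_estimate")
}

#' Block standard error of a window estimate
#'
#' Splits the samples, in order, into consecutive blocks of `block_size`
#' (the analogue of per-nanosecond simulation segments), estimates the
#' window free energy on each block, and reports
#' `sd(block estimates) / sqrt(n_blocks)`. An incomplete trailing block is
#' dropped with a warning.
#'
#' @param w a [fep_window_samples()].
#' @param block_size samples per block.
#' @return list with `block_estimates`, `sem`, `n_blocks`.
#' @export
block_sem <- function(w, block_size = NULL) {
  stopifnot(inherits(w, "fep_window_samples"))
  if (is.null(block_size)) block_size <- w$block_size
  stopifnot(!is.null(block_size), block_size >= 1)
  n <- length(w$samples)
  nb <- as.integer(n %/% block_size)
  if (nb < 2)
    stop("need at least 2 complete blocks (", n, " samples, block size ",
         block_size, ")")
  if (n %% block_size != 0)
    warning("dropping incomplete trailing block of ", n %% block_size,
            " samples")
  kBT <- .kBT(w$temperature)
  est <- vapply(seq_len(nb), function(b) {
    s <- w$samples[((b - 1) * block_size + 1):(b * block_size)]
    -kBT * .log_mean_exp(-s / kBT)
  }, numeric(1))
  list(block_estimates = est, sem = stats::sd(est) / sqrt(nb), n_blocks = nb)
}

#' Combine window estimates into a transformation estimate
#'
#' Maps every window onto the forward lambda axis (reverse-direction
#' windows enter with negated sign), validates that the mapped subintervals
#' tile `[0, 1]` exactly — the midpoint-outward bidirectional scheme
#' (e.g. 0.0 <- 0.05 -> 0.1) produces exactly such a tiling — and sums. The
#' transformation SEM treats windows as independent
#' (\eqn{\sqrt{\sum sem_i^2}}).
#'
#' @param estimates list of [zwanzig_window()] results.
#' @param scheme "bidirectional-midpoint" (the default; reverse windows
#'   expected) or "unidirectional" (label only; validation is identical).
#' @param duplicates "error" (default) to reject two estimates of the same
#'   subinterval, or "average" to average their mapped values (combined SEM
#'   halved in quadrature).
#' @return list of class `transformation_estimate`: `legs` (mapped,
#'   ordered), `total_ddG`, `total_sem`, `temperature`, `direction_scheme`.
#' @export
combine_windows <- function(estimates,
                            scheme = c("bidirectional-midpoint",
                                       "unidirectional"),
                            duplicates = c("error", "average")) {
  scheme <- match.arg(scheme)
  duplicates <- match.arg(duplicates)
  stopifnot(length(estimates) >= 1)
  mapped <- lapply(estimates, function(e) {
    stopifnot(inherits(e, "window_estimate"))
    if (e$lambda_from <= e$lambda_to)
      data.frame(lo = e$lambda_from, hi = e$lambda_to, ddG = e$ddG,
                 sem = e$sem, temperature = e$temperature)
    else
      data.frame(lo = e$lambda_to, hi = e$lambda_from, ddG = -e$ddG,
                 sem = e$sem, temperature = e$temperature)
  })
  legs <- do.call(rbind, mapped)
  if (length(unique(legs$temperature)) > 1)
    stop("windows at different temperatures cannot be combined")
  key <- paste(legs$lo, legs$hi)
  if (anyDuplicated(key)) {
    if (duplicates == "error")
      stop("duplicate estimates for subinterval(s) ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    agg <- lapply(split(legs, key), function(g)
      data.frame(lo = g$lo[1], hi = g$hi[1], ddG = mean(g$ddG),
                 sem = sqrt(sum(g$sem^2)) / nrow(g),
                 temperature = g$temperature[1]))
    legs <- do.call(rbind, agg)
  }
  legs <- legs[order(legs$lo), , drop = FALSE]
  rownames(legs) <- NULL
  eps <- 1e-9
  if (abs(legs$lo[1]) > eps)
    stop("lambda coverage gap: missing interval [0, ", legs$lo[1], "]")
  for (i in seq_len(nrow(legs) - 1)) {
    if (legs$hi[i] < legs$lo[i + 1] - eps)
      stop("lambda coverage gap: missing interval [", legs$hi[i], ", ",
           legs$lo[i + 1], "]")
    if (legs$hi[i] > legs$lo[i + 1] + eps)
      stop("lambda coverage overlap on [", legs$lo[i + 1], ", ",
           min(legs$hi[i], legs$hi[i + 1]), "]")
  }
  if (abs(legs$hi[nrow(legs)] - 1) > eps)
    stop("lambda coverage gap: missing interval [", legs$hi[nrow(legs)],
         ", 1]")
  structure(list(legs = legs, total_ddG = sum(legs$ddG),
                 total_sem = sqrt(sum(legs$sem^2)),
                 temperature = legs$temperature[1],
                 direction_scheme = scheme),
            class = "transformation_estimate")
}

#' @export
print.transformation_estimate <- function(x, ...) {
  cat(sprintf("transformation ddG = %.4f +/- %.4f kcal/mol (%d windows, %s, %g K)\n",
              x$total_ddG, x$total_sem, nrow(x$legs), x$direction_scheme,
              x$temperature))
  invisible(x)
}

#' Validate a lambda schedule
#'
#' Checks that a vector of lambda points starts at 0, ends at 1 and is
#' strictly increasing, and reports the subinterval count. The canonical
#' 21-point schedule `seq(0, 1, 0.05)` yields 20 windows.
#'
#' @param lambdas numeric vector of lambda points.
#' @return list with `lambdas` and `n_windows`; errors name the offending
#'   interval.
#' @export
validate_lambda_schedule <- function(lambdas) {
  if (length(lambdas) < 2) stop("lambda schedule needs at least 2 points")
  if (any(lambdas < 0 | lambdas > 1)) stop("lambda points outside [0, 1]")
  if (any(diff(lambdas) <= 0)) stop("lambda schedule not strictly increasing")
  if (abs(lambdas[1]) > 1e-12)
    stop("lambda schedule gap: missing interval [0, ", lambdas[1], "]")
  if (abs(lambdas[length(lambdas)] - 1) > 1e-12)
    stop("lambda schedule gap: missing interval [",
         lambdas[length(lambdas)], ", 1]")
  list(lambdas = lambdas, n_windows = length(lambdas) - 1L)
}

#' Soft-core Lennard-Jones parameters
#'
#' @param epsilon well depth (kcal/mol).
#' @param sigma LJ diameter (A).
#' @param alpha soft-core shift (A^2, default 4.0).
#' @param direction "appearing" (interaction scales with lambda) or
#'   "disappearing" (scales with 1 - lambda).
#' @param repulsive_only drop the attractive r^-6 term (purely repulsive
#'   reference system; its coupling free energy is strictly positive).
#' @return list of class `softcore_params`.
#' @export
softcore_params <- function(epsilon = 0.2, sigma = 3.5, alpha = 4,
                            direction = c("appearing", "disappearing"),
                            repulsive_only = FALSE) {
  direction <- match.arg(direction)
  stopifnot(alpha >= 0, epsilon >= 0, sigma > 0)
  structure(list(epsilon = epsilon, sigma = sigma, alpha = alpha,
                 direction = direction, repulsive_only = repulsive_only),
            class = "softcore_params")
}

#' Separation-shifted soft-core Lennard-Jones energy
#'
#' \deqn{U(r, \lambda) = 4 \epsilon \lambda \left[
#'   \left(\frac{\sigma^2}{\alpha (1-\lambda) + r^2}\right)^6 -
#'   \left(\frac{\sigma^2}{\alpha (1-\lambda) + r^2}\right)^3 \right]}
#' for an appearing particle (mirror in lambda for disappearing). The shift
#' removes the r -> 0 singularity whenever the coupling is incomplete; at
#' lambda = 1 (appearing) the standard LJ potential is recovered exactly.
#'
#' @param r distance (A), vectorised.
#' @param lambda coupling in `[0,1]`.
#' @param params a [softcore_params()].
#' @return energy in kcal/mol.
#' @export
softcore_lj_energy <- function(r, lambda, params) {
  stopifnot(inherits(params, "softcore_params"),
            all(r >= 0), lambda >= 0, lambda <= 1)
  lam <- if (params$direction == "appearing") lambda else 1 - lambda
  if (params$epsilon == 0 || lam == 0) return(rep(0, length(r)))
  q3 <- (params$sigma^2 / (params$alpha * (1 - lam) + r^2))^3
  # factored so the r -> 0, lam -> 1 corner yields +Inf rather than Inf - Inf
  att <- if (isTRUE(params$repulsive_only)) 0 else 1
  4 * params$epsilon * lam * q3 * (q3 - att)
}

#' Quadrature reference for the toy alchemical system
#'
#' Exact (to quadrature tolerance) free energy of coupling one soft-core LJ
#' particle to a particle fixed at the centre of a spherical volume of
#' radius R, independent of any sampling:
#' \deqn{\Delta G = -k_B T \ln \frac{Z(1)}{Z(0)}, \quad
#'   Z(\lambda) = \int_0^R 4 \pi r^2 e^{-U(r,\lambda)/k_B T}\, dr.}
#'
#' @param params a [softcore_params()].
#' @param temperature Kelvin.
#' @param radius confinement radius R (A).
#' @param rel_tol relative quadrature tolerance.
#' @return list with `ddG` (kcal/mol) and `logZ` at the endpoints.
#' @export
toy_alchemical_reference <- function(params, temperature = 298.15,
                                     radius = 8, rel_tol = 1e-9) {
  kBT <- .kBT(temperature)
  logZ <- function(lambda) {
    # factor exp(+u_min) under the integral for stability, restored in log
    u <- function(r) softcore_lj_energy(r, lambda, params)
    u_min <- min(u(seq(0, radius, length.out = 2048)))
    it <- stats::integrate(function(r)
      4 * pi * r^2 * exp(-(u(r) - u_min) / kBT),
      0, radius, rel.tol = rel_tol, subdivisions = 500L)
    if (it$message != "OK" || it$abs.error > 1e-4 * abs(it$value))
      stop("quadrature did not converge: ", it$message)
    log(it$value) - u_min / kBT
  }
  lz0 <- logZ(0); lz1 <- logZ(1)
  list(ddG = -kBT * (lz1 - lz0), logZ0 = lz0, logZ1 = lz1)
}

#' Monte-Carlo FEP samples for the toy alchemical system
#'
#' Draws exact Boltzmann samples of the radial coordinate at each lambda
#' point by inverse-CDF sampling of \eqn{p(r) \propto r^2 e^{-U(r,\lambda)/k_B T}}
#' on a fine grid, and returns forward windows of
#' \eqn{\Delta H = U(r, \lambda_{i+1}) - U(r, \lambda_i)} ready for
#' [zwanzig_window()] / [combine_windows()]. The end-to-end estimate can be
#' compared against [toy_alchemical_reference()].
#'
#' @param params a [softcore_params()].
#' @param lambdas lambda schedule (validated; default `seq(0, 1, 0.05)`).
#' @param n_per_window samples per window.
#' @param temperature Kelvin.
#' @param radius confinement radius (A).
#' @param seed integer RNG seed.
#' @param grid_n radial grid size for the inverse CDF.
#' @return list of [fep_window_samples()], one per subinterval.
#' @export
sample_toy_fep <- function(params, lambdas = seq(0, 1, by = 0.05),
                           n_per_window = 1e4, temperature = 298.15,
                           radius = 8, seed = 1L, grid_n = 4096L) {
  validate_lambda_schedule(lambdas)
  kBT <- .kBT(temperature)
  set.seed(seed)
  r_grid <- seq(0, radius, length.out = grid_n)
  lapply(seq_len(length(lambdas) - 1L), function(i) {
    li <- lambdas[i]; lj <- lambdas[i + 1]
    u <- softcore_lj_energy(r_grid, li, params)
    w <- r_grid^2 * exp(-(u - min(u)) / kBT)
    cdf <- cumsum(w); cdf <- cdf / cdf[length(cdf)]
    r <- stats::approx(cdf, r_grid, xout = stats::runif(n_per_window),
                       ties = "ordered", rule = 2)$y
    dH <- softcore_lj_energy(r, lj, params) - softcore_lj_energy(r, li, params)
    fep_window_samples(li, lj, temperature, dH)
  })
}
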