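test_that("mass-weighted covariance matches closed forms on degenerate systems", {
  # rigid trajectory: zero matrix
  coords <- array(0, dim = c(10, 3, 3))
  for (f in 1:10) coords[f, , ] <- line_frame(3)
  C <- mass_weighted_covariance(trajectory(coords), carbon_topology(3),
                                selection = 1:3, align = FALSE)
  expect_lt(max(abs(C)), 1e-12)
  expect_error(mass_weighted_covariance(
    trajectory(coords[1, , , drop = FALSE]), carbon_topology(3)), "2 frames")

  # one free atom, mass m, isotropic variance v: eigenvalues {mv, mv, mv}
  m <- 15.999; v <- 0.2
  g <- gen_gaussian_trajectory(gaussian_trajectory_spec(
    1, 5e4, v, masses = m, seed = 20))
  g$topology$atoms$mass <- m
  C1 <- suppressWarnings(mass_weighted_covariance(
    g$trajectory, g$topology, selection = 1L, align = FALSE))
  ev <- eigen(C1, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev, rep(m * v, 3), tolerance = 0.05)
})

test_that("alignment recovers internal fluctuations under composed rigid motions", {
  v <- c(0.30, 0.22, 0.15, 0.40, 0.18, 0.25, 0.12, 0.35, 0.20,
         0.28, 0.16, 0.24)                      # 4 atoms, diagonal truth
  mu <- chain_frame(4)
  spec_still <- gaussian_trajectory_spec(4, 3e4, v, mean_structure = mu,
                                         seed = 21)
  spec_moved <- gaussian_trajectory_spec(4, 3e4, v, mean_structure = mu,
                                         rigid_motion = TRUE, seed = 21)
  top <- gen_gaussian_trajectory(spec_still)$topology
  g <- gen_gaussian_trajectory(spec_moved)
  ref <- gen_gaussian_trajectory(spec_still)$trajectory
  C_aligned <- mass_weighted_covariance(g$trajectory, top, reference = mu)
  C_truth <- mass_weighted_covariance(ref, top, reference = mu)
  # same internal fluctuations, one copy wrapped in random rigid motions:
  # after alignment the covariances agree within sampling error
  expect_lt(max(abs(C_aligned - C_truth)), 0.1)
  expect_lt(abs(qh_entropy(C_aligned)$entropy - qh_entropy(C_truth)$entropy) /
              qh_entropy(C_truth)$entropy, 0.02)
})

test_that("oscillator entropy matches its per-mode closed forms", {
  # zero covariance: entropy 0 with warning
  expect_warning(r0 <- qh_entropy(matrix(0, 3, 3)), "below the eigenvalue")
  expect_identical(r0$entropy, 0)

  # single mode at hbar*omega = kB*T: frozen direct evaluation of
  # 1/(e-1) - ln(1 - 1/e) = 1.040653 (in units of kB)
  T <- 298.15
  kBT_J <- alchemtraj:::.kBT_joule(T)
  lam_amuA2 <- (PHYS_CONST$hbar^2 / kBT_J) /
    (PHYS_CONST$kg_per_amu * PHYS_CONST$m2_per_A2)
  S1 <- harmonic_entropy_exact(lam_amuA2, T)
  expect_equal(S1 / PHYS_CONST$kB, 1.040653, tolerance = 1e-5)

  # high-temperature limit: quantum and classical forms agree within 1%
  lam_soft <- lam_amuA2 * 400          # alpha = 1/20
  Sq <- harmonic_entropy_exact(lam_soft, T)
  Sc <- harmonic_entropy_exact(lam_soft, T, classical = TRUE)
  expect_lt(abs(Sq - Sc) / Sq, 0.01)

  # monotone non-decreasing under covariance scaling c >= 1
  lams <- c(0.5, 0.2, 0.1)
  S_base <- harmonic_entropy_exact(lams)
  for (c_ in c(1, 1.5, 2, 5))
    expect_gte(harmonic_entropy_exact(c_ * lams), S_base - 1e-15)

  # rotation invariance: congruent rotation of the covariance leaves S fixed
  set.seed(22)
  A <- matrix(rnorm(36, sd = 0.3), 6, 6); sigma <- crossprod(A) + diag(0.1, 6)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  expect_equal(qh_entropy(sigma)$entropy,
               qh_entropy(Q %*% sigma %*% t(Q))$entropy, tolerance = 1e-9)
})

test_that("alignment leaves six near-zero modes that are discarded", {
  g <- gen_gaussian_trajectory(gaussian_trajectory_spec(
    4, 3000, 0.25^2, rigid_motion = TRUE, seed = 23))
  C <- mass_weighted_covariance(g$trajectory, g$topology)
  res <- qh_entropy(C)
  expect_gte(res$n_modes_discarded, 6L)
  expect_identical(res$n_modes_retained + res$n_modes_discarded, 12L)
  ev <- sort(res$eigenvalues)
  expect_lt(ev[6], 1e-8)
  expect_gt(ev[7], 1e-3)
})

test_that("delta entropy reproduces the replicate-mean arithmetic", {
  same <- list(entropy_result(0.3), entropy_result(0.28))
  d0 <- delta_entropy(same, same)
  expect_identical(d0$delta_S, 0)
  expect_identical(d0$minus_T_delta_S, 0)

  # -T*dS at 298.15 K reproduces the integer-rounded report values
  mk <- function(dS) delta_entropy(list(entropy_result(0.5 + dS)),
                                   list(entropy_result(0.5)))
  expect_identical(round(mk(-0.125)$minus_T_delta_S), 37)
  expect_identical(round(mk(-0.067)$minus_T_delta_S), 20)
  expect_identical(round(mk(-0.09)$minus_T_delta_S), 27)
  # identity -T*dS = -T * dS holds exactly
  d <- mk(-0.125)
  expect_identical(d$minus_T_delta_S, -298.15 * d$delta_S)

  # SEM over replicates
  dr <- delta_entropy(lapply(c(0.31, 0.29, 0.33), entropy_result),
                      lapply(c(0.40, 0.40, 0.40), entropy_result))
  expect_equal(dr$sem, sd(c(-0.09, -0.11, -0.07)) / sqrt(3))
  expect_error(delta_entropy(same, same[1]), "mismatched")
})

test_that("convergence windows tile the span and agree when stationary", {
  g <- gen_gaussian_trajectory(gaussian_trajectory_spec(3, 4000, 0.2,
                                                        seed = 24))
  tr <- trajectory(g$trajectory$coords, time_ps = seq_len(4000) * 10)  # 40 ns
  res <- convergence_windows(tr, list(c(0, 40), c(0, 20), c(20, 40)),
                             g$topology, align = FALSE)
  expect_identical(res[[2]]$n_frames_used + res[[3]]$n_frames_used,
                   res[[1]]$n_frames_used)
  # full-span window equals the single-call result
  C_full <- mass_weighted_covariance(tr, g$topology, align = FALSE)
  expect_equal(res[[1]]$entropy, qh_entropy(C_full)$entropy)
  # stationary trajectory: halves agree within sampling error
  expect_lt(attr(res, "split_relative"), 0.05)
  expect_error(convergence_windows(tr, list(c(50, 60)), g$topology),
               "no frames")
})
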