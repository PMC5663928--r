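test_that("gaussian trajectory generator honours degenerate, moment and determinism contracts", {
  # zero covariance: every frame equals the mean structure
  g0 <- gen_gaussian_trajectory(gaussian_trajectory_spec(3, 10, 0, seed = 1))
  for (f in 1:10)
    expect_equal(get_frame(g0$trajectory, f), line_frame(3),
                 ignore_attr = TRUE)

  # one atom, isotropic per-coordinate variance 0.25 A^2, 50,000 frames:
  # sample variance within 0.01 of the spec
  g1 <- gen_gaussian_trajectory(gaussian_trajectory_spec(1, 5e4, 0.25,
                                                         seed = 2))
  v <- apply(g1$trajectory$coords[, 1, ], 2, var)
  expect_true(all(abs(v - 0.25) < 0.01))

  # same spec + seed is bit-identical; different seed differs
  s <- gaussian_trajectory_spec(4, 25, 0.1, seed = 7)
  expect_identical(gen_gaussian_trajectory(s)$trajectory$coords,
                   gen_gaussian_trajectory(s)$trajectory$coords)
  s2 <- gaussian_trajectory_spec(4, 25, 0.1, seed = 8)
  expect_false(identical(gen_gaussian_trajectory(s)$trajectory$coords,
                         gen_gaussian_trajectory(s2)$trajectory$coords))

  # non-PSD covariance rejected with a diagnostic
  bad <- diag(c(1, 1, -0.5))
  expect_error(gen_gaussian_trajectory(
    gaussian_trajectory_spec(1, 5, bad, seed = 1)), "positive semi-definite")
})

test_that("full-covariance sampling reproduces off-diagonal structure", {
  d <- 6
  A <- matrix(rnorm(d * d, sd = 0.3), d, d)
  sigma <- crossprod(A) + diag(0.05, d)
  g <- gen_gaussian_trajectory(gaussian_trajectory_spec(
    2, 2e4, sigma, seed = 3))
  X <- aligned_coordinate_matrix(g$trajectory, align = FALSE)
  C <- cov(X)
  expect_lt(max(abs(C - sigma)) / max(diag(sigma)), 0.1)
})

test_that("AR(1) frame correlation preserves the marginal variance", {
  g <- gen_gaussian_trajectory(gaussian_trajectory_spec(
    1, 4e4, 0.25, ar1 = 0.8, seed = 4))
  x <- g$trajectory$coords[, 1, 1]
  expect_lt(abs(var(x) - 0.25), 0.03)
  expect_gt(cor(x[-1], x[-length(x)]), 0.7)
})

test_that("FEP sample generator matches its spec moments and analytic free energy", {
  # sigma = 0: every sample equals mu
  w0 <- gen_fep_samples(fep_sample_spec(0, 0.05, mu = 1.5, sigma = 0,
                                        n_samples = 100, seed = 1))
  expect_true(all(w0$samples == 1.5))

  # two specs differing only in seed: different samples, same analytic ddG
  sA <- fep_sample_spec(0, 0.05, 1, 1, 1000, seed = 1)
  sB <- fep_sample_spec(0, 0.05, 1, 1, 1000, seed = 2)
  expect_false(identical(gen_fep_samples(sA)$samples,
                         gen_fep_samples(sB)$samples))
  expect_identical(fep_analytic_ddG(sA), fep_analytic_ddG(sB))
  expect_equal(fep_analytic_ddG(sA), 1 - 1 / (2 * kB * 298.15))

  expect_error(fep_sample_spec(0, 0.05, 1, 1, 0), "n_samples")
  expect_error(fep_sample_spec(0, 0, 1, 1, 10))
})

test_that("van't Hoff series generator is exact and invertible", {
  expect_equal(unname(gen_vant_hoff_series(0, 0, c(280, 300))), c(0, 0))
  expect_equal(unname(gen_vant_hoff_series(16.2, 0.06, c(288.15, 298.15))),
               c(-1.089, -1.689))
  expect_error(gen_vant_hoff_series(1, 0.1, c(300, 300)), "duplicate")
  expect_error(gen_vant_hoff_series(1, 0.1, 300), "2 temperatures")

  # decomposition recovers the planted pair to machine precision
  for (pars in list(c(16.2, 0.06), c(-3.4, -0.012), c(0.7, 0.002))) {
    g <- gen_vant_hoff_series(pars[1], pars[2], c(288.15, 298.15))
    d <- vant_hoff_decompose(g[1], g[2], 288.15, 298.15)
    expect_equal(d$ddH, pars[1], tolerance = 1e-12)
    expect_equal(d$ddS, pars[2], tolerance = 1e-12)
  }
})

test_that("sampling schedules reproduce the triplicate structure counts", {
  # complexed: ns segments 11-100 at 10 ps, triplicate
  expect_identical(
    gen_schedule_frames(segment_schedule(11, 100, 10, 3))$count, 27000L)
  # free ligand: ns segments 1-20 at 10 ps, triplicate
  expect_identical(
    gen_schedule_frames(segment_schedule(1, 20, 10, 3))$count, 6000L)
  # degenerate single frame: span (0, 1] ns at 1000 ps
  one <- gen_schedule_frames(sampling_schedule(0, 1, 1000, 1))
  expect_identical(one$count, 1L)
  expect_equal(one$time_ps, 1000)
  # span-start excluded, span-end included
  t20 <- gen_schedule_frames(segment_schedule(1, 20, 10, 1))$time_ps
  expect_equal(min(t20), 10)       # first frame strictly after t = 0
  expect_equal(max(t20), 20000)
  expect_error(sampling_schedule(0, 1, 300, 1), "does not divide")
})

test_that("planted complexes satisfy their margins and are rejected otherwise", {
  # margin violations are rejected at spec construction
  expect_error(planted_complex_spec(
    hbonds = data.frame(dist = 2.95, angle = 160)), "margin")
  expect_error(planted_complex_spec(
    hbonds = data.frame(dist = 3.0, angle = 122, positive = FALSE)), "margin")
  expect_error(planted_complex_spec(
    hydrophobics = data.frame(dist = 3.95)), "margin")
  # geometrically unrealisable plant (distance unreachable at that angle)
  expect_error(gen_planted_complex(planted_complex_spec(
    hbonds = data.frame(dist = 0.5, angle = 90, positive = FALSE))),
    "unrealisable")

  px <- gen_planted_complex(planted_complex_spec(
    hbonds = data.frame(dist = 2.8, angle = 160),
    hydrophobics = data.frame(dist = c(3.5, 3.9, 4.1),
                              positive = c(TRUE, TRUE, FALSE)),
    bridges = 1))
  fr <- get_frame(px$trajectory, 1)
  expect_identical(nrow(detect_hydrophobic(fr, px$topology)), 2L)
  expect_identical(nrow(detect_water_bridges(fr, px$topology)), 1L)
  # planted H-bond geometry is reproduced exactly
  hb <- detect_hbonds(fr, px$topology)
  planted <- px$truth[px$truth$kind == "hbond", ]
  row <- hb[hb$donor == planted$i & hb$acceptor == planted$j, ]
  expect_equal(row$dist, 2.8, tolerance = 1e-9)
  expect_equal(row$angle, 160, tolerance = 1e-9)
})
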