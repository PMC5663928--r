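test_that("Zwanzig window estimator obeys its exact identities", {
  # constant samples: ddG equals the constant
  w <- fep_window_samples(0, 0.05, 298.15, rep(1.3, 50))
  expect_equal(zwanzig_window(w)$ddG, 1.3, tolerance = 1e-12)

  # two-sample closed form
  dH <- 2.0; kBT <- kB * 298.15
  w2 <- fep_window_samples(0, 0.05, 298.15, c(0, dH))
  expect_equal(zwanzig_window(w2)$ddG,
               -kBT * log((1 + exp(-dH / kBT)) / 2), tolerance = 1e-12)

  # translation covariance: adding c to all samples adds exactly c,
  # even when the shift is overflow-hostile
  set.seed(30)
  s <- rnorm(200)
  base <- zwanzig_window(fep_window_samples(0, 0.05, 298.15, s))$ddG
  for (c_ in c(-500, -3, 7, 800)) {
    shifted <- zwanzig_window(fep_window_samples(0, 0.05, 298.15, s + c_))$ddG
    expect_equal(shifted, base + c_, tolerance = 1e-9)
  }

  # Jensen bound: exponential average never exceeds the arithmetic mean
  for (seed in 1:20) {
    set.seed(seed)
    s <- rnorm(500, mean = runif(1, -2, 2), sd = runif(1, 0, 2))
    est <- zwanzig_window(fep_window_samples(0, 0.05, 298.15, s))$ddG
    expect_lte(est, mean(s) + 1e-12)
  }
  expect_error(fep_window_samples(0, 0.05, 298.15, c(1, NaN)), "non-finite")
})

test_that("Gaussian windows recover the cumulant identity within Monte-Carlo error", {
  spec <- fep_sample_spec(0, 0.05, mu = 1, sigma = 1, n_samples = 5e4,
                          temperature = 298.15, seed = 31)
  est <- zwanzig_window(gen_fep_samples(spec))
  expect_lt(abs(est$ddG - fep_analytic_ddG(spec)), 3 * est$sem)
  expect_gt(est$sem, 0)
})

test_that("block SEM partitions samples in order and scales as 1/sqrt(blocks)", {
  # identical blocks: sem = 0
  w <- fep_window_samples(0, 0.05, 298.15, rep(c(1, 2, 3, 4), 5),
                          block_size = 4)
  bs <- block_sem(w)
  expect_identical(bs$n_blocks, 5L)
  expect_equal(bs$sem, 0, tolerance = 1e-12)

  # single block rejected; incomplete trailing block dropped with warning
  expect_error(block_sem(fep_window_samples(0, 0.05, 298.15, 1:10), 10),
               "2 complete blocks")
  expect_warning(block_sem(fep_window_samples(0, 0.05, 298.15, rnorm(25)), 10),
                 "incomplete trailing")

  # i.i.d. samples: sem(block_size b) ~ sem(b/4) / 2 on average
  rat <- vapply(1:12, function(seed) {
    set.seed(seed)
    s <- rnorm(8000, 0, 0.5)
    w <- fep_window_samples(0, 0.05, 298.15, s)
    block_sem(w, 500)$sem / block_sem(w, 2000)$sem
  }, numeric(1))
  expect_lt(abs(mean(rat) - 1), 0.35)
})

test_that("window combination validates the lambda chain and maps directions", {
  lam <- seq(0, 1, by = 0.05)
  sched <- validate_lambda_schedule(lam)
  expect_identical(sched$n_windows, 20L)
  expect_error(validate_lambda_schedule(c(0, 0.5, 0.9)), "missing interval")
  expect_error(validate_lambda_schedule(c(0.1, 0.5, 1)), "missing interval")

  mk <- function(from, to, ddG) structure(
    list(lambda_from = from, lambda_to = to, ddG = ddG, sem = 0.01,
         n_samples = 10L, block_estimates = NULL, temperature = 298.15),
    class = "window_estimate")

  # additivity: 20 forward windows of 0.1 total 2.0
  fw <- lapply(1:20, function(i) mk(lam[i], lam[i + 1], 0.1))
  tot <- combine_windows(fw)
  expect_equal(tot$total_ddG, 2.0, tolerance = 1e-12)
  expect_equal(tot$total_sem, sqrt(20) * 0.01, tolerance = 1e-12)

  # single window [0, 1]
  expect_equal(combine_windows(list(mk(0, 1, -0.7)))$total_ddG, -0.7)

  # midpoint-outward pairs: reverse windows sign-map onto the forward axis
  bi <- list(mk(0.05, 0, 0.2), mk(0.05, 0.1, 0.3),
             lapply(seq(0.1, 0.95, by = 0.05), function(l)
               mk(l, l + 0.05, 0.1)))
  bi <- c(bi[1:2], bi[[3]])
  tot_bi <- combine_windows(bi)
  expect_equal(tot_bi$total_ddG, -0.2 + 0.3 + 18 * 0.1, tolerance = 1e-10)

  # gaps and overlaps are rejected with the offending interval
  expect_error(combine_windows(list(mk(0, 0.4, 1), mk(0.6, 1, 1))),
               "missing interval")
  expect_error(combine_windows(list(mk(0, 0.6, 1), mk(0.4, 1, 1))),
               "overlap")
  expect_error(combine_windows(list(mk(0, 0.5, 1), mk(0.5, 1, 1),
                                    mk(0.5, 1, 1.1))), "duplicate")
  # duplicate subintervals may be averaged on request
  avg <- combine_windows(list(mk(0, 0.5, 1), mk(0.5, 1, 1), mk(0.5, 1, 1.1)),
                         duplicates = "average")
  expect_equal(avg$total_ddG, 1 + 1.05, tolerance = 1e-12)
})

test_that("forward and reverse sampling of one subinterval agree after mapping", {
  # same physical subinterval sampled in both directions from matched
  # Gaussian ensembles: hysteresis compatible with zero
  mu <- 0.4; sigma <- 0.5; kBT <- kB * 298.15
  fwd <- zwanzig_window(gen_fep_samples(fep_sample_spec(
    0.5, 0.55, mu, sigma, 4e4, seed = 32)))
  # reverse samples are -dH drawn in the target ensemble: for Gaussians the
  # matched reverse distribution has mean -(mu - sigma^2/kBT)
  rev <- zwanzig_window(gen_fep_samples(fep_sample_spec(
    0.55, 0.5, -(mu - sigma^2 / kBT), sigma, 4e4, seed = 33)))
  hysteresis <- fwd$ddG - (-rev$ddG)
  expect_lt(abs(hysteresis), 3 * sqrt(fwd$sem^2 + rev$sem^2))
})

test_that("soft-core potential reduces to standard LJ at the endpoints", {
  p <- softcore_params(epsilon = 0.5, sigma = 3.0, alpha = 4)
  r <- seq(0.5, 8, by = 0.25)
  lj <- function(r) 4 * 0.5 * ((3 / r)^12 - (3 / r)^6)
  expect_equal(softcore_lj_energy(r, 1, p), lj(r), tolerance = 1e-12)
  expect_identical(softcore_lj_energy(r, 0, p), rep(0, length(r)))
  # finite at r = 0 for partial coupling; plug-in evaluation
  u0 <- softcore_lj_energy(0, 0.5, p)
  q <- 9 / (4 * 0.5)
  expect_equal(u0, 4 * 0.5 * 0.5 * (q^6 - q^3), tolerance = 1e-12)
  expect_true(is.finite(u0))
  # disappearing direction mirrors the coupling
  pd <- softcore_params(epsilon = 0.5, sigma = 3.0, alpha = 4,
                        direction = "disappearing")
  expect_equal(softcore_lj_energy(r, 0, pd), lj(r), tolerance = 1e-12)
})

test_that("the sampled FEP pipeline matches the quadrature oracle on the toy system", {
  p <- softcore_params(epsilon = 0.5, sigma = 3.0, alpha = 4)
  ref <- toy_alchemical_reference(p, radius = 8)
  wins <- sample_toy_fep(p, n_per_window = 2e4, radius = 8, seed = 34)
  tot <- combine_windows(lapply(wins, zwanzig_window))
  expect_lt(abs(tot$total_ddG - ref$ddG), 3 * tot$total_sem)

  # no interaction: exactly zero
  p0 <- softcore_params(epsilon = 0, sigma = 3.0)
  expect_equal(toy_alchemical_reference(p0, radius = 8)$ddG, 0,
               tolerance = 1e-9)
  # purely repulsive coupling costs free energy
  pr <- softcore_params(epsilon = 0.5, sigma = 3.0, repulsive_only = TRUE)
  expect_gt(toy_alchemical_reference(pr, radius = 8)$ddG, 0)
})
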