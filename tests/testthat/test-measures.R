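test_that("grid-point classification separates fixed points from cycles", {
  t <- seq(0, 200, by = 0.5)
  expect_equal(classify_gridpoint(cbind(rep(0.8, length(t)))), "fixed_point")
  expect_equal(
    classify_gridpoint(cbind(1 + 0.5 * sin(t)), rel_tol = 0.01),
    "oscillation")
  # logistic relaxation, transient discarded: residual decay is sub-tolerance
  late <- logistic_solution(seq(30, 60, by = 0.5), 0.01)
  expect_equal(classify_gridpoint(cbind(late)), "fixed_point")
  # everything extinct: the zero fixed point, flagged
  cl <- classify_gridpoint(cbind(rep(1e-6, 50)))
  expect_equal(as.character(cl), "fixed_point")
  expect_true(attr(cl, "all_extinct"))
})

test_that("amplitude estimator recovers planted amplitudes", {
  t <- seq(0, 400, by = 0.25)
  expect_equal(oscillation_amplitude(rep(3.2, 100)), 0)
  expect_equal(oscillation_amplitude(1 + 0.5 * sin(t)), 0.5, tolerance = 1e-3)
  two <- 0.3 * sin(2 * pi * 0.11 * t) + 0.2 * sin(2 * pi * 0.11 * sqrt(2) * t)
  expect_equal(oscillation_amplitude(two), 0.5, tolerance = 0.02)
})

test_that("dominant frequency lands in the right Fourier bin", {
  dt <- 0.5
  t <- seq(0, 400 - dt, by = dt)
  bin <- 1 / (length(t) * dt)
  f <- dominant_frequency(sin(2 * pi * 0.05 * t), dt)
  expect_lt(abs(f - 0.05), bin + 1e-12)
  expect_equal(dominant_frequency(rep(1, 100), dt), 0)
  two_tone <- sin(2 * pi * 0.05 * t) + 0.3 * sin(2 * pi * 0.125 * t)
  expect_lt(abs(dominant_frequency(two_tone, dt) - 0.05), bin + 1e-12)
  expect_error(dominant_frequency(1, dt), "at least 2")
})

test_that("pairwise phase shifts recover planted lags", {
  dt <- 0.5
  t <- seq(0, 400 - dt, by = dt)
  W <- length(t)
  f0 <- 0.05
  a <- sin(2 * pi * f0 * t)
  expect_equal(phase_shift_pair(a, a, f0, dt), 0, tolerance = 1e-10)
  for (lag in c(0, pi / 4, pi / 2, 3 * pi / 4, pi)) {
    b <- sin(2 * pi * f0 * t - lag)
    expect_lt(abs(phase_shift_pair(a, b, f0, dt) - lag), 2 * pi / W)
  }
  # anti-phase is the completely unsynchronised extreme
  expect_equal(phase_shift_pair(a, -a, f0, dt), pi, tolerance = 1e-6)
  expect_error(phase_shift_pair(a, a, 2, dt), "resolvable")
})

test_that("sync index: planted lags match the exhaustive-pair oracle", {
  lags <- c(0, 0.3, 0.7, 1.2, 2.9)
  tr <- sinusoid_trajectory(lags)
  W <- sum(tr$times >= max(tr$times) / 2)
  wrap <- function(d) pmin(abs(d), 2 * pi - abs(d))
  oracle <- max(wrap(outer(lags, lags, "-")))
  expect_lt(abs(sync_index(tr) - oracle), 2 * pi / W + 1e-6)

  # identical series across the grid: synchronised
  expect_lt(sync_index(sinusoid_trajectory(rep(0, 5))), 1e-6)
  # two-point anti-phase grid: completely unsynchronised
  expect_equal(sync_index(sinusoid_trajectory(c(0, pi))), pi,
               tolerance = 1e-6)
  # no oscillating species: undefined, reported as missing
  flat <- make_trajectory(seq(0, 100, 0.5),
                          array(0.7, dim = c(201, 4, 2)))
  expect_true(is.na(sync_index(flat)))
})

test_that("sync index is invariant to global time shift and ring rotation", {
  lags <- c(0.2, 0.5, 1.1, 1.9, 2.4)
  tr <- sinusoid_trajectory(lags)
  s0 <- sync_index(tr)
  # global time shift = same constant added to every lag
  s_shift <- sync_index(sinusoid_trajectory(lags + 0.8))
  W <- sum(tr$times >= max(tr$times) / 2)
  expect_lt(abs(s0 - s_shift), 4 * pi / W)
  # rotation of the ring relabels grid-points
  tr_rot <- tr
  tr_rot$phi <- tr$phi[, c(3, 4, 5, 1, 2), , drop = FALSE]
  expect_equal(sync_index(tr_rot), s0)
})

test_that("diversity uses extant-anywhere semantics", {
  times <- seq(0, 100, 0.5)
  Tn <- length(times)
  phi <- array(0.5, dim = c(Tn, 4, 3))
  tr <- make_trajectory(times, phi)
  expect_equal(diversity_count(tr)$n, 3L)

  phi2 <- phi; phi2[, , 2] <- 1e-6          # species 2 gone everywhere
  expect_equal(diversity_count(make_trajectory(times, phi2))$n, 2L)
  expect_equal(diversity_count(make_trajectory(times, phi2))$extant,
               c(TRUE, FALSE, TRUE))

  phi3 <- phi; phi3[, 1:2, 3] <- 0          # extinct at half the grid only
  expect_equal(diversity_count(make_trajectory(times, phi3))$n, 3L)
})

test_that("diversity is monotone non-increasing in the threshold", {
  set.seed(13)
  times <- seq(0, 100, 0.5)
  phi <- array(rexp(length(times) * 3 * 6, rate = 20),
               dim = c(length(times), 3, 6))
  tr <- make_trajectory(times, phi)
  thresholds <- c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1)
  n <- sapply(thresholds, function(th) diversity_count(tr, th)$n)
  expect_true(all(diff(n) <= 0))
})

test_that("global mean abundance averages the grid", {
  lags <- c(0, pi)
  tr <- sinusoid_trajectory(lags, m = 0.8)
  gm <- global_mean_abundance(tr)
  # perfect anti-phase pair cancels to the constant baseline
  expect_lt(max(abs(gm - 0.8)), 1e-12)

  tr_sync <- sinusoid_trajectory(c(0.4, 0.4, 0.4))
  gm_sync <- global_mean_abundance(tr_sync)
  expect_equal(gm_sync[, 1], tr_sync$phi[, 1, 1])
})

test_that("summarise_run assembles the measurement record", {
  # anti-phase fixture: every point oscillates, index pi, constant global mean
  tr <- sinusoid_trajectory(c(0, pi), a = 0.4, m = 1)
  sm <- summarise_run(tr)
  expect_s3_class(sm, "glv_run_summary")
  expect_equal(sm$n_osc_points, 2L)
  expect_equal(sm$sync_index, pi, tolerance = 1e-6)
  expect_equal(sm$mean_amplitude, 0.4, tolerance = 0.01)
  expect_equal(sm$diversity, 1L)
  expect_equal(unname(sm$global_mean_abundance), 1, tolerance = 1e-6)
  expect_equal(sm$per_point_class, c("oscillation", "oscillation"))

  # deep-feasible system relaxes to the all-species fixed point
  sys <- build_system(N = 8, sigma = 0.02, mu_D = 1e-2,
                      geometry = grid_geometry(1, 6), seed = 3)
  sm2 <- summarise_run(integrate_system(sys, t_end = 200))
  expect_equal(sm2$n_osc_points, 0L)
  expect_equal(sm2$diversity, 8L)
  expect_true(is.na(sm2$sync_index))
  expect_equal(sm2$mean_amplitude, 0)

  # diverged runs yield a flagged record with missing measures
  bad <- tr; bad$diverged <- TRUE
  smb <- summarise_run(bad)
  expect_true(smb$diverged_flag)
  expect_true(is.na(smb$diversity))
})

test_that("window doubling leaves converged measures nearly unchanged", {
  lags <- c(0.1, 0.9, 1.7, 2.5)
  tr1 <- sinusoid_trajectory(lags, t_end = 400)
  tr2 <- sinusoid_trajectory(lags, t_end = 800)
  s1 <- summarise_run(tr1); s2 <- summarise_run(tr2)
  expect_lt(abs(s1$sync_index - s2$sync_index) / s1$sync_index, 0.05)
  expect_lt(abs(s1$mean_amplitude - s2$mean_amplitude) / s1$mean_amplitude,
            0.05)
})
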