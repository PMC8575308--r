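# predicate used by the bisection, reproduced here as an independent check
interior_ok <- function(comm, sigma) {
  comm$sigma <- sigma
  fp <- solve_feasible_fixed_point(comm)
  !fp$singular && fp$feasible && is_linearly_stable(fp$phi_star, comm)
}

test_that("feasibility boundary matches the two-species closed form", {
  # mutual competition A = -(1 - I): phi* = 1/(1+sigma) stays positive for
  # every sigma, and the Jacobian eigenvalues -phi*(1 +/- sigma) lose
  # stability exactly at sigma = 1
  A <- matrix(c(0, -1, -1, 0), 2, 2)
  comm <- community(A, sigma = 0, c = 1, mu = -1)
  sf <- feasibility_boundary(comm, sigma_max = 2, tol = 1e-5)
  expect_equal(as.numeric(sf), 1, tolerance = 1e-4)
  expect_null(attr(sf, "not_bracketed"))

  # bisection contract around the returned boundary
  expect_true(interior_ok(comm, as.numeric(sf) - 2e-5))
  expect_false(interior_ok(comm, as.numeric(sf) + 2e-5))

  # bracket-width independence
  sf2 <- feasibility_boundary(comm, sigma_max = 1.5, tol = 1e-5)
  expect_lt(abs(as.numeric(sf) - as.numeric(sf2)), 2e-5)
})

test_that("unbracketed boundaries are flagged, not silently capped", {
  comm <- community(matrix(0, 2, 2), sigma = 0)  # no interactions at all
  sf <- feasibility_boundary(comm, sigma_max = 2, tol = 1e-4)
  expect_equal(as.numeric(sf), 2)
  expect_true(attr(sf, "not_bracketed"))
})

test_that("boundary estimates are positive, finite, seeded-reproducible", {
  sfs <- sapply(1:6, function(s) {
    comm <- tiny_community(N = 10, sigma = 0, seed = 200 + s)
    as.numeric(feasibility_boundary(comm, sigma_max = 3, tol = 1e-4))
  })
  expect_true(all(sfs > 0 & is.finite(sfs)))
  comm <- tiny_community(N = 10, sigma = 0, seed = 201)
  expect_identical(feasibility_boundary(comm), feasibility_boundary(comm))
})

test_that("larger pools do not raise the ensemble-median boundary", {
  sf_at <- function(N, seeds) {
    sapply(seeds, function(s) {
      comm <- tiny_community(N = N, sigma = 0, seed = 1000 * N + s)
      as.numeric(feasibility_boundary(comm, sigma_max = 3, tol = 1e-3))
    })
  }
  seeds <- 1:20
  expect_lte(median(sf_at(16, seeds)), median(sf_at(8, seeds)))
})

test_that("sigma scan labels the three regimes in order", {
  comm <- tiny_community(N = 10, sigma = 0, seed = 301)
  sf <- as.numeric(feasibility_boundary(comm, sigma_max = 3))
  grid <- sf * c(0.5, 0.9, 1.6, 2.6)
  rep <- stability_scan(comm, grid, n_restarts = 3, seed = 5, t_end = 500)
  expect_equal(rep$labels[1], "feasible")
  expect_equal(rep$diversity[1], 10)
  rank <- c(feasible = 1, structurally_unstable = 2, collapsed = 3)
  expect_true(all(diff(rank[rep$labels]) >= 0))
  # above the boundary the best stable fixed point loses species
  above <- rep$labels[rep$sigma_grid > sf]
  if (any(above == "structurally_unstable")) {
    expect_lt(max(rep$diversity[rep$labels == "structurally_unstable"]), 10)
  }
  # per-restart details are retained for triage
  expect_equal(nrow(rep$details), length(grid) * 3)
})

test_that("scan is deterministic given its seed", {
  comm <- tiny_community(N = 8, sigma = 0, seed = 305)
  g <- c(0.05, 0.3)
  r1 <- stability_scan(comm, g, n_restarts = 2, seed = 9, t_end = 200)
  r2 <- stability_scan(comm, g, n_restarts = 2, seed = 9, t_end = 200)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$details, r2$details)
  expect_error(stability_scan(comm, c(0.3, 0.1), seed = 1), "increasing")
})

test_that("spatial regime rule covers its five labels", {
  base <- structure(
    list(n_osc_points = 0L, sync_index = NA_real_, mean_amplitude = 0,
         diversity = 10L, extant = rep(TRUE, 10),
         global_mean_abundance = rep(1, 10),
         per_point_class = rep("fixed_point", 20),
         amplitude_by_species = rep(0, 10), diverged_flag = FALSE,
         M = 20L, N = 10L),
    class = "glv_run_summary")
  expect_equal(spatial_regime(base), "fixed_point")

  osc <- base; osc$n_osc_points <- 20L; osc$sync_index <- 0.05
  expect_equal(spatial_regime(osc), "synchronised_oscillation")
  osc$sync_index <- 3
  expect_equal(spatial_regime(osc), "unsynchronised_oscillation")

  mix <- base; mix$n_osc_points <- 7L; mix$sync_index <- 1
  expect_equal(spatial_regime(mix), "mixed")

  dead <- base; dead$diversity <- 4L
  expect_equal(spatial_regime(dead), "collapsed")
  div <- base; div$diverged_flag <- TRUE
  expect_equal(spatial_regime(div), "collapsed")

  # anti-phase fixture realises the unsynchronised extreme end-to-end
  sm <- summarise_run(sinusoid_trajectory(c(0, pi)))
  sm$diversity <- 1L; sm$N <- 1L
  expect_equal(spatial_regime(sm), "unsynchronised_oscillation")
})
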