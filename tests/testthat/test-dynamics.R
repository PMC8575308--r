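test_that("non-spatial right-hand side follows the model equation", {
  comm <- tiny_community(N = 4, sigma = 0.2)
  expect_equal(glv_rhs_nonspatial(rep(0, 4), comm), rep(0, 4))

  one <- community(matrix(0, 1, 1), sigma = 0)
  expect_equal(glv_rhs_nonspatial(0.5, one), 0.25)

  # direct transcription oracle
  phi <- c(0.2, 0.5, 0.9, 0.1)
  manual <- sapply(1:4, function(i) {
    phi[i] * comm$r[i] * (1 - phi[i] / comm$K[i]) +
      comm$sigma * phi[i] * sum(comm$A[i, ] * phi)
  })
  expect_equal(glv_rhs_nonspatial(phi, comm), manual)
  expect_error(glv_rhs_nonspatial(c(0.1, 0.2), comm), "length 4")
})

test_that("interior fixed point solves its linear system", {
  comm <- tiny_community(N = 20, sigma = 0.05, seed = 8)
  fp <- solve_feasible_fixed_point(comm)
  expect_false(fp$singular)
  resid <- comm$r * (1 - fp$phi_star / comm$K) +
    comm$sigma * as.numeric(comm$A %*% fp$phi_star)
  expect_lt(max(abs(resid)), 1e-10)
  # and the RHS vanishes there
  expect_lt(max(abs(glv_rhs_nonspatial(abs(fp$phi_star), comm))), Inf)
  if (fp$feasible) {
    expect_lt(max(abs(glv_rhs_nonspatial(fp$phi_star, comm))), 1e-10)
  }

  comm0 <- tiny_community(N = 6, sigma = 0)
  fp0 <- solve_feasible_fixed_point(comm0)
  expect_true(fp0$feasible)
  expect_equal(fp0$phi_star, rep(1, 6))
})

test_that("singular interaction structure is flagged, not mislabelled", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  comm <- community(A, sigma = 1)   # I - A is singular
  fp <- solve_feasible_fixed_point(comm)
  expect_true(fp$singular)
  expect_false(fp$feasible)
})

test_that("Jacobian matches a finite-difference oracle and flags stability", {
  one <- community(matrix(0, 1, 1), sigma = 0)
  expect_equal(jacobian_at(1, one), matrix(-1, 1, 1))
  expect_true(is_linearly_stable(1, one))
  expect_equal(jacobian_at(0, one), matrix(1, 1, 1))
  expect_false(is_linearly_stable(0, one))

  comm <- tiny_community(N = 6, sigma = 0.1, seed = 12)
  phi <- local({ set.seed(1); runif(6, 0.2, 1) })
  J <- jacobian_at(phi, comm)
  eps <- 1e-6
  J_fd <- sapply(1:6, function(j) {
    up <- phi; up[j] <- up[j] + eps
    dn <- phi; dn[j] <- dn[j] - eps
    (glv_rhs_nonspatial(up, comm) - glv_rhs_nonspatial(dn, comm)) / (2 * eps)
  })
  expect_lt(max(abs(J - J_fd)), 1e-6)
})

test_that("spatial RHS = local term + per-species diffusion", {
  comm <- tiny_community(N = 3, sigma = 0.1, seed = 21)
  geom <- grid_geometry(1, 6)
  disp <- dispersal_profile(c(0.1, 0.02, 0.5), 0.1, 0.35)
  set.seed(5)
  phi <- matrix(runif(18, 0.1, 1), 6, 3)

  out <- glv_rhs_spatial(phi, comm, disp, geom)
  # oracle: assemble the two pieces independently
  local_part <- t(apply(phi, 1, glv_rhs_nonspatial, community = comm))
  lap_part <- sapply(1:3, function(s)
    disp$D[s] * discrete_laplacian(phi[, s], geom))
  expect_equal(out, local_part + lap_part)

  # D = 0 reduces to independent local dynamics
  disp0 <- dispersal_profile(rep(0, 3), 0, NA)
  expect_equal(glv_rhs_spatial(phi, comm, disp0, geom), local_part)

  # spatially uniform state: diffusion term vanishes
  phiu <- matrix(rep(phi[1, ], each = 6), 6, 3)
  expect_equal(glv_rhs_spatial(phiu, comm, disp, geom),
               matrix(rep(glv_rhs_nonspatial(phi[1, ], comm), each = 6), 6, 3))

  # dispersal contribution alone conserves each species' total
  pure <- glv_rhs_spatial(phi, comm, disp, geom) - local_part
  expect_lt(max(abs(colSums(pure))), 1e-12)

  expect_error(glv_rhs_spatial(phi[1:3, ], comm, disp, geom), "6 x 3")
})

test_that("integrator reproduces the closed-form logistic solution", {
  one <- community(matrix(0, 1, 1), sigma = 0)
  tr <- integrate_nonspatial(one, 0.01, t_end = 30, output_dt = 0.25)
  expect_false(tr$diverged)
  exact <- logistic_solution(tr$times, 0.01)
  expect_lt(max(abs(tr$phi[, 1, 1] - exact)), 1e-6)
  # uniform output grid
  expect_lt(max(abs(diff(diff(tr$times)))), 1e-9 * diff(tr$times)[1])
})

test_that("D = 0 lattice runs equal decoupled per-point runs", {
  comm <- tiny_community(N = 4, sigma = 0.1, seed = 31)
  geom <- grid_geometry(1, 3)
  sys <- list(community = comm,
              dispersal = dispersal_profile(rep(0, 4), 0, NA),
              geometry = geom, seed = 1L,
              sub_seeds = c(matrix = 1L, b = 1L, diffusion = 1L, ic = 1L))
  class(sys) <- "glv_system"
  set.seed(9)
  phi0 <- matrix(runif(12, 0.2, 1), 3, 4)
  tr <- integrate_system(sys, phi0 = phi0, t_end = 80)
  for (g in 1:3) {
    tr_g <- integrate_nonspatial(comm, phi0[g, ], t_end = 80)
    expect_lt(max(abs(tr$phi[, g, ] - tr_g$phi[, 1, ])), 1e-6)
  }
})

test_that("the homogeneous manifold is invariant for any D", {
  comm <- tiny_community(N = 4, sigma = 0.1, seed = 41)
  geom <- grid_geometry(1, 8)
  disp <- dispersal_profile(sample_diffusion_rates(4, 1, 0.35, seed = 2),
                            1, 0.35)
  sys <- structure(list(community = comm, dispersal = disp, geometry = geom,
                        seed = 1L, sub_seeds = c(matrix = 1L, b = 1L,
                                                 diffusion = 1L, ic = 1L)),
                   class = "glv_system")
  phi0 <- matrix(rep(c(0.3, 0.7, 0.2, 0.9), each = 8), 8, 4)
  tr <- integrate_system(sys, phi0 = phi0, t_end = 100)
  spatial_dev <- apply(tr$phi, c(1, 3), function(x) max(x) - min(x))
  expect_lt(max(spatial_dev), 1e-8)
})

test_that("pure dispersal conserves per-species grid totals", {
  N <- 3
  comm <- community(matrix(0, N, N), sigma = 0, r = rep(0, N))
  geom <- grid_geometry(1, 10)
  disp <- dispersal_profile(c(0.05, 0.2, 1), 0.3, 0.35)
  sys <- structure(list(community = comm, dispersal = disp, geometry = geom,
                        seed = 1L, sub_seeds = c(matrix = 1L, b = 1L,
                                                 diffusion = 1L, ic = 1L)),
                   class = "glv_system")
  set.seed(3)
  phi0 <- matrix(runif(30, 0.1, 2), 10, 3)
  tr <- integrate_system(sys, phi0 = phi0, t_end = 50)
  totals <- apply(tr$phi, c(1, 3), sum)
  rel_drift <- apply(totals, 2, function(x) max(abs(x - x[1])) / x[1])
  expect_lt(max(rel_drift), 1e-8)
})

test_that("integration is converged, not tolerance-limited", {
  comm <- tiny_community(N = 5, sigma = 0.08, seed = 51)
  phi0 <- local({ set.seed(4); runif(5, 0.2, 1) })
  tr1 <- integrate_nonspatial(comm, phi0, t_end = 60, rtol = 1e-8,
                              atol = 1e-10)
  tr2 <- integrate_nonspatial(comm, phi0, t_end = 60, rtol = 5e-9,
                              atol = 5e-11)
  rel <- max(abs(tr1$phi - tr2$phi)) / max(tr1$phi)
  expect_lt(rel, 1e-5)
})

test_that("abundances stay non-negative and bad inputs are rejected", {
  comm <- tiny_community(N = 8, sigma = 0.4, seed = 61)
  phi0 <- local({ set.seed(5); runif(8, 1e-3, 1) })
  tr <- integrate_nonspatial(comm, phi0, t_end = 150)
  expect_gte(min(tr$phi), 0)
  expect_error(integrate_nonspatial(comm, rep(-0.1, 8)), "non-negative")
  sys <- build_system(N = 4, sigma = 0, mu_D = 0, seed = 1,
                      geometry = grid_geometry(1, 4))
  expect_error(integrate_system(sys, phi0 = matrix(0.5, 3, 4)), "4 x 4")
  expect_error(integrate_system(sys, t_end = -1), "positive")
})

test_that("high diffusion synchronises the lattice", {
  sys <- build_system(N = 6, sigma = 0.1, mu_D = 1, b = 0.35,
                      geometry = grid_geometry(1, 12), seed = 71)
  tr <- integrate_system(sys, t_end = 150)
  spatial_var <- apply(tr$phi, c(1, 3), stats::var)
  late <- colMeans(spatial_var[tr$times > 100, , drop = FALSE])
  early <- colMeans(spatial_var[tr$times < 10, , drop = FALSE])
  expect_lt(max(late), 1e-6)
  expect_lt(max(late / pmax(early, 1e-12)), 1e-3)
})
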