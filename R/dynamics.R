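# GLV right-hand sides, the interior fixed point, linear stability, and the
# adaptive time integrator (compiled Dormand-Prince 5(4), see src/).

#' Non-spatial GLV right-hand side
#'
#' Evaluates, for each species,
#' `phi_i r_i (1 - phi_i / K_i) + sigma phi_i sum_j A_ij phi_j`.
#'
#' @param phi non-negative abundance vector of length `N`.
#' @param community a [community()].
#' @return numeric vector of length `N` of time derivatives.
#' @export
glv_rhs_nonspatial <- function(phi, community) {
  stopifnot(inherits(community, "glv_community"))
  phi <- as.numeric(phi)
  if (length(phi) != community$N) {
    stop(sprintf("`phi` must have length %d", community$N), call. = FALSE)
  }
  if (any(!is.finite(phi))) stop("`phi` must be finite", call. = FALSE)
  phi * community$r * (1 - phi / community$K) +
    community$sigma * phi * as.numeric(community$A %*% phi)
}

#' Spatial GLV right-hand side
#'
#' The local GLV term applied independently at each grid-point, plus
#' per-species nearest-neighbour diffusion `D_i * lap(phi_i) / h^2` with
#' periodic wrap.
#'
#' @param phi `M` x `N` matrix of abundances (grid-points x species).
#' @param community a [community()].
#' @param dispersal a [dispersal_profile()].
#' @param geometry a [grid_geometry()].
#' @return `M` x `N` matrix of time derivatives.
#' @export
glv_rhs_spatial <- function(phi, community, dispersal, geometry) {
  stopifnot(inherits(community, "glv_community"),
            inherits(dispersal, "glv_dispersal"),
            inherits(geometry, "grid_geometry"))
  M <- n_points(geometry)
  N <- community$N
  phi <- as.matrix(phi)
  if (nrow(phi) != M || ncol(phi) != N) {
    stop(sprintf("`phi` must be %d x %d (grid-points x species)", M, N),
         call. = FALSE)
  }
  if (length(dispersal$D) != N) {
    stop("dispersal profile does not match the community size", call. = FALSE)
  }
  local <- phi * matrix(community$r, M, N, byrow = TRUE) *
    (1 - sweep(phi, 2, community$K, "/")) +
    community$sigma * phi * (phi %*% t(community$A))
  lap <- apply(phi, 2, discrete_laplacian, geometry = geometry)
  lap <- matrix(lap, M, N)
  local + sweep(lap, 2, dispersal$D, "*")
}

#' Interior (all-species) fixed point of the non-spatial GLV
#'
#' Solves the linear system `r_i (1 - phi_i / K_i) + sigma sum_j A_ij phi_j
#' = 0`, i.e. `(diag(r / K) - sigma A) phi = r`.  With the default
#' `r = K = 1` this is `(I - sigma A) phi = 1`.  The fixed point is feasible
#' when every component is strictly positive.
#'
#' @param community a [community()].
#' @return a list with `phi_star` (numeric, `NA` if the system is singular),
#'   `feasible` (logical), and `singular` (logical: no unique interior
#'   equilibrium exists).
#' @export
solve_feasible_fixed_point <- function(community) {
  stopifnot(inherits(community, "glv_community"))
  Mmat <- diag(community$r / community$K, community$N) -
    community$sigma * community$A
  phi <- tryCatch(solve(Mmat, community$r), error = function(e) NULL)
  if (is.null(phi) || any(!is.finite(phi)) ||
      rcond(Mmat) < .Machine$double.eps * 1e2) {
    return(list(phi_star = rep(NA_real_, community$N), feasible = FALSE,
                singular = TRUE))
  }
  list(phi_star = as.numeric(phi), feasible = all(phi > 0), singular = FALSE)
}

#' Jacobian of the non-spatial GLV at a state
#'
#' `J_ij = d(dphi_i/dt)/dphi_j` evaluated at `phi`:
#' the diagonal carries `r_i (1 - 2 phi_i / K_i) + sigma sum_k A_ik phi_k`
#' and off-diagonals `sigma phi_i A_ij`.
#'
#' @param phi abundance vector (typically a fixed-point candidate).
#' @param community a [community()].
#' @return numeric `N` x `N` matrix.
#' @export
jacobian_at <- function(phi, community) {
  stopifnot(inherits(community, "glv_community"))
  phi <- as.numeric(phi)
  if (length(phi) != community$N) {
    stop(sprintf("`phi` must have length %d", community$N), call. = FALSE)
  }
  interact <- as.numeric(community$A %*% phi)
  J <- community$sigma * phi * community$A
  diag(J) <- community$r * (1 - 2 * phi / community$K) +
    community$sigma * interact
  J
}

#' Linear stability of a fixed-point candidate
#'
#' @param phi fixed-point candidate.
#' @param community a [community()].
#' @param tol eigenvalues must have real part below `-tol` (default 1e-9).
#' @return logical.
#' @export
is_linearly_stable <- function(phi, community, tol = 1e-9) {
  ev <- eigen(jacobian_at(phi, community), only.values = TRUE)$values
  all(Re(ev) < -tol)
}

#' Default initial conditions for a spatial run
#'
#' The feasible fixed point (component-wise absolute value if infeasible)
#' perturbed multiplicatively, per grid-point and species, by i.i.d.
#' lognormal noise with `sdlog = ic_sd`.  Per-point perturbation is essential:
#' the spatially homogeneous manifold is invariant under the dynamics, so an
#' unperturbed start could never desynchronise.
#'
#' @param system a [build_system()] result.
#' @param ic_sd lognormal perturbation scale (default 0.2).
#' @param seed integer seed; defaults to the system's `ic` sub-seed.
#' @param preset `"perturbed_fixed_point"` (default) or `"uniform"`
#'   (i.i.d. uniform on (0, 1\]).
#' @return `M` x `N` matrix of non-negative abundances.
#' @export
initial_state <- function(system, ic_sd = 0.2, seed = NULL,
                          preset = c("perturbed_fixed_point", "uniform")) {
  stopifnot(inherits(system, "glv_system"))
  preset <- match.arg(preset)
  M <- n_points(system$geometry)
  N <- system$community$N
  if (is.null(seed)) seed <- system$sub_seeds[["ic"]]
  if (preset == "uniform") {
    return(local_seed(seed, matrix(runif(M * N), M, N)))
  }
  fp <- solve_feasible_fixed_point(system$community)
  base <- if (fp$singular) rep(1, N) else abs(fp$phi_star)
  base <- pmax(base, 1e-6)
  local_seed(seed, {
    noise <- matrix(exp(rnorm(M * N, sd = ic_sd)), M, N)
    sweep(noise, 2, base, "*")
  })
}

#' Integrate a spatial (or non-spatial) GLV system
#'
#' Adaptive Dormand-Prince 5(4) integration of the lattice ODEs, sampled onto
#' a uniform output grid.  With one grid-point (or `mu_D = 0`) this is the
#' plain non-spatial model run as `M` decoupled copies.  Trajectories are
#' reported with abundances clipped at zero; a solver undershoot beyond
#' `-1e-9`, a non-finite state, or exhaustion of the step budget marks the
#' run as diverged and the partial trajectory is retained for diagnosis.
#'
#' @param system a [build_system()] result.
#' @param phi0 optional `M` x `N` initial state; default [initial_state()].
#' @param t_end integration horizon (default 2000 time units; `r = 1` sets
#'   the time scale).
#' @param output_dt uniform output sampling step (default 0.5).
#' @param rtol,atol solver relative/absolute tolerances (defaults 1e-8,
#'   1e-10).
#' @param max_step optional cap on the internal step (0 = none).
#' @param max_steps step budget before the run is flagged diverged.
#' @return an object of class `glv_trajectory`: list with `times` (length
#'   `T`), `phi` (`T` x `M` x `N` array), `geometry`, `system`, `diverged`.
#' @export
integrate_system <- function(system, phi0 = NULL, t_end = 2000,
                             output_dt = 0.5, rtol = 1e-8, atol = 1e-10,
                             max_step = 0, max_steps = 5e6) {
  stopifnot(inherits(system, "glv_system"))
  if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  M <- n_points(system$geometry)
  N <- system$community$N
  if (is.null(phi0)) phi0 <- initial_state(system)
  phi0 <- as.matrix(phi0)
  if (nrow(phi0) != M || ncol(phi0) != N) {
    stop(sprintf("`phi0` must be %d x %d", M, N), call. = FALSE)
  }
  if (any(phi0 < 0) || any(!is.finite(phi0))) {
    stop("`phi0` must be finite and non-negative", call. = FALSE)
  }
  res <- .glv_integrate_cpp(
    phi0, system$community$A, system$community$r, system$community$K,
    system$community$sigma, system$dispersal$D, system$geometry$ndim,
    system$geometry$extent, system$geometry$h, t_end, output_dt, rtol, atol,
    max_step, as.integer(max_steps)
  )
  keep <- seq_len(res$n_recorded)
  structure(
    list(times = res$times[keep],
         phi = res$phi[keep, , , drop = FALSE],
         geometry = system$geometry,
         system = system,
         diverged = res$diverged,
         solver = list(rtol = rtol, atol = atol, output_dt = output_dt,
                       n_accept = res$n_accept, n_reject = res$n_reject)),
    class = "glv_trajectory"
  )
}

#' Integrate a community without space
#'
#' Convenience wrapper: runs [integrate_system()] on a single grid-point.
#'
#' @param community a [community()].
#' @param phi0 initial abundance vector (length `N`).
#' @param ... passed to [integrate_system()].
#' @return a `glv_trajectory` with `M = 1`.
#' @export
integrate_nonspatial <- function(community, phi0, ...) {
  stopifnot(inherits(community, "glv_community"))
  sys <- structure(
    list(community = community,
         dispersal = dispersal_profile(numeric(community$N), 0, NA_real_),
         geometry = grid_geometry(1L, 1L),
         seed = NA_integer_,
         sub_seeds = c(matrix = NA_integer_, b = NA_integer_,
                       diffusion = NA_integer_, ic = NA_integer_)),
    class = "glv_system"
  )
  integrate_system(sys, phi0 = matrix(phi0, nrow = 1), ...)
}

#' @export
print.glv_trajectory <- function(x, ...) {
  d <- dim(x$phi)
  cat(sprintf(
    "GLV trajectory: %d samples x %d grid-points x %d species (t in [%g, %g])%s\n",
    d[1], d[2], d[3], x$times[1], x$times[length(x$times)],
    if (isTRUE(x$diverged)) " [DIVERGED]" else ""))
  invisible(x)
}
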