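# Sigma-regime structure of the non-spatial model: with growing interaction
# strength a random community passes from a feasible, stable all-species
# equilibrium, through a structurally unstable region where extinctions trim
# the community, to collapse (no stable many-species fixed point; persistent
# oscillations or a drop to a much smaller community).

# feasible *and* linearly stable interior equilibrium at this sigma?
.interior_ok <- function(community, sigma) {
  comm <- community
  comm$sigma <- sigma
  fp <- solve_feasible_fixed_point(comm)
  if (fp$singular || !fp$feasible) return(FALSE)
  is_linearly_stable(fp$phi_star, comm)
}

#' Feasibility boundary of a community
#'
#' Bisection in `sigma` of the predicate "the interior fixed point has all
#' components positive and is linearly stable".  Returns the largest such
#' `sigma`, to absolute tolerance `tol`.  If the predicate still holds at
#' `sigma_max` the value `sigma_max` is returned with attribute
#' `not_bracketed = TRUE`.
#'
#' @param community a [community()] (its own `sigma` is ignored).
#' @param sigma_max upper end of the search bracket (default 2).
#' @param tol absolute tolerance on the boundary (default 1e-4).
#' @return the boundary `sigma_f` (numeric scalar, possibly with attribute
#'   `not_bracketed`).
#' @export
feasibility_boundary <- function(community, sigma_max = 2, tol = 1e-4) {
  stopifnot(inherits(community, "glv_community"), sigma_max > 0, tol > 0)
  if (!.interior_ok(community, 0)) {
    stop("community must be feasible at sigma = 0 (requires r, K > 0)",
         call. = FALSE)
  }
  if (.interior_ok(community, sigma_max)) {
    return(structure(sigma_max, not_bracketed = TRUE))
  }
  lo <- 0; hi <- sigma_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.interior_ok(community, mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# exact interior equilibrium of the subcommunity S embedded in the full
# state (zeros elsewhere); NULL if it does not exist or is not positive
.subcommunity_equilibrium <- function(community, S) {
  Msub <- diag(community$r[S] / community$K[S], length(S)) -
    community$sigma * community$A[S, S, drop = FALSE]
  phiS <- tryCatch(solve(Msub, community$r[S]), error = function(e) NULL)
  if (is.null(phiS) || any(!is.finite(phiS)) || any(phiS <= 0)) return(NULL)
  phi <- numeric(community$N)
  phi[S] <- phiS
  phi
}

# Classify one non-spatial restart: integrate, test convergence to a fixed
# point, and verify the candidate against the exact subcommunity equilibrium
# (linear solve on the extant set, full-system Jacobian including invasion
# rates of the extinct species).
.classify_restart <- function(community, seed, t_end, extinct_threshold,
                              rel_tol, rtol = 1e-8, atol = 1e-10) {
  phi0 <- local_seed(seed, runif(community$N, min = 1e-3, max = 1))
  tr <- integrate_nonspatial(community, phi0, t_end = t_end, output_dt = 0.5,
                             rtol = rtol, atol = atol, max_steps = 5e5)
  if (isTRUE(tr$diverged)) {
    return(list(kind = "diverged", n = NA_integer_))
  }
  tail <- tr$phi[tr$times >= 0.75 * t_end, 1, , drop = TRUE]
  tail <- matrix(tail, ncol = community$N)
  prev <- tr$phi[tr$times >= 0.5 * t_end & tr$times < 0.75 * t_end, 1, ,
                 drop = TRUE]
  prev <- matrix(prev, ncol = community$N)
  mt <- colMeans(tail)
  mp <- colMeans(prev)
  extant <- mt > extinct_threshold
  # species above the floor but on a clear downward trend are prospective
  # extinctions; their relative fluctuation is meaningless (range ~ mean
  # while decaying), so the settledness assessment uses the core set only
  dying <- extant & (mt < 0.5 * mp)
  core <- extant & !dying
  rel_fluct_over <- function(m, idx) {
    if (!any(idx)) return(0)
    rng <- apply(m[, idx, drop = FALSE], 2, function(x) max(x) - min(x))
    max(rng / pmax(colMeans(m[, idx, drop = FALSE]), extinct_threshold))
  }
  fluct <- rel_fluct_over(tail, core)
  if (!any(extant)) {
    return(list(kind = "fixed_point", n = 0L, stable = TRUE))
  }
  settled <- fluct < rel_tol
  # a weakly damped tail still identifies its attractor before settling: the
  # fluctuation must not be sustained (amplitude shrinking between windows,
  # and moderate), and the exact subcommunity equilibrium plus full-system
  # Jacobian (including invasion rates of the excluded species) then settles
  # "is there a stable fixed point" rigorously -- a genuine limit cycle
  # keeps its amplitude and its extant-set equilibrium is not stable
  contracting <- fluct < 0.95 * rel_fluct_over(prev, core) && fluct < 0.5
  if (settled || contracting) {
    for (S in unique(list(which(core), which(extant)))) {
      if (length(S) == 0) next
      fp <- .subcommunity_equilibrium(community, S)
      if (!is.null(fp) && is_linearly_stable(fp, community, tol = 1e-8)) {
        return(list(kind = "fixed_point", n = length(S), stable = TRUE,
                    phi = fp))
      }
    }
    if (settled) {
      # fully settled state whose exact equilibrium eluded the linear solve:
      # judge the simulated state itself
      phi_full <- numeric(community$N)
      phi_full[core] <- mt[core]
      stable <- is_linearly_stable(phi_full, community, tol = 1e-8)
      return(list(kind = "fixed_point", n = sum(core), stable = stable,
                  phi = phi_full))
    }
  }
  list(kind = "oscillatory", n = sum(extant))
}

#' Scan sigma regimes of the non-spatial system
#'
#' For each `sigma` in `sigma_grid` the community is integrated from
#' `n_restarts` seeded random initial conditions.  Each restart either
#' converges to a fixed point (verified by an exact subcommunity equilibrium
#' solve plus a full-system Jacobian check, so invasion by the extinct
#' species is also ruled out) or keeps fluctuating.  The `sigma` is labelled
#'
#' * `feasible` - some restart reaches a stable fixed point with all `N`
#'   species extant;
#' * `structurally_unstable` - best stable fixed point retains at least
#'   `collapse_fraction * N` species but fewer than `N`;
#' * `collapsed` - no stable fixed point found, or only fixed points that
#'   lost more than `1 - collapse_fraction` of the pool (oscillations count
#'   here too).
#'
#' @param community a [community()] (its own `sigma` is ignored).
#' @param sigma_grid increasing positive sigma values.
#' @param n_restarts random restarts per sigma (default 5; the structurally
#'   unstable region can hold several alternative equilibria).
#' @param seed integer seed for the restart initial conditions.
#' @param t_end horizon per restart (default 600).
#' @param extinct_threshold,rel_tol measurement cut-offs.
#' @param collapse_fraction diversity fraction separating trimmed fixed
#'   points from collapse (default 0.5).
#' @return an object of class `glv_regime_report`: list with `sigma_grid`,
#'   `labels`, `diversity` (best stable-fixed-point diversity per sigma, NA
#'   if none), `sigma_feasibility`, `sigma_stability`, and the per-restart
#'   `details` data frame.
#' @export
stability_scan <- function(community, sigma_grid, n_restarts = 5, seed = 1,
                           t_end = 600, extinct_threshold = 1e-4,
                           rel_tol = 1e-3, collapse_fraction = 0.5,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(community, "glv_community"))
  if (is.unsorted(sigma_grid, strictly = TRUE)) {
    stop("`sigma_grid` must be strictly increasing", call. = FALSE)
  }
  restart_seeds <- derive_seeds(seed, paste0("restart", seq_len(
    length(sigma_grid) * n_restarts)))
  labels <- character(length(sigma_grid))
  best_div <- rep(NA_integer_, length(sigma_grid))
  rows <- list()
  for (i in seq_along(sigma_grid)) {
    comm <- community
    comm$sigma <- sigma_grid[i]
    kinds <- character(n_restarts)
    divs <- rep(NA_integer_, n_restarts)
    stable_div <- integer(0)
    for (k in seq_len(n_restarts)) {
      res <- .classify_restart(comm,
                               restart_seeds[(i - 1) * n_restarts + k],
                               t_end, extinct_threshold, rel_tol,
                               rtol = rtol, atol = atol)
      kinds[k] <- res$kind
      divs[k] <- res$n
      if (res$kind == "fixed_point" && isTRUE(res$stable)) {
        stable_div <- c(stable_div, res$n)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sigma = sigma_grid[i], restart = k, kind = res$kind,
        diversity = res$n,
        stable = if (res$kind == "fixed_point") isTRUE(res$stable) else NA)
    }
    if (length(stable_div) > 0 && max(stable_div) == community$N) {
      labels[i] <- "feasible"
      best_div[i] <- community$N
    } else if (length(stable_div) > 0 &&
               max(stable_div) >= collapse_fraction * community$N) {
      labels[i] <- "structurally_unstable"
      best_div[i] <- max(stable_div)
    } else {
      labels[i] <- "collapsed"
      if (length(stable_div) > 0) best_div[i] <- max(stable_div)
    }
  }
  feas <- sigma_grid[labels == "feasible"]
  stab <- sigma_grid[labels %in% c("feasible", "structurally_unstable")]
  structure(
    list(sigma_grid = sigma_grid, labels = labels, diversity = best_div,
         sigma_feasibility = if (length(feas)) max(feas) else NA_real_,
         sigma_stability = if (length(stab)) max(stab) else NA_real_,
         details = do.call(rbind, rows), N = community$N),
    class = "glv_regime_report"
  )
}

#' @export
print.glv_regime_report <- function(x, ...) {
  cat("Non-spatial sigma-regime scan:\n")
  for (i in seq_along(x$sigma_grid)) {
    cat(sprintf("  sigma = %-8.4g %-22s diversity %s\n", x$sigma_grid[i],
                x$labels[i],
                if (is.na(x$diversity[i])) "-" else x$diversity[i]))
  }
  cat(sprintf("  sigma_feasibility <= %s, sigma_stability <= %s\n",
              format(x$sigma_feasibility), format(x$sigma_stability)))
  invisible(x)
}

#' Classify the spatial regime of a run
#'
#' Deterministic rule applied to a [summarise_run()] record: a diverged run,
#' or one whose diversity fell below `collapse_fraction` of the reference
#' all-species diversity, is `collapsed`; otherwise all grid-points at fixed
#' points gives `fixed_point`; a mix of fixed and oscillating points gives
#' `mixed`; a fully oscillating grid is `synchronised_oscillation` when the
#' synchronisation index is below `sync_threshold` and
#' `unsynchronised_oscillation` otherwise.
#'
#' @param run_summary a `glv_run_summary`.
#' @param nonspatial_report optional `glv_regime_report` supplying the
#'   reference diversity (defaults to the species pool size `N`).
#' @param sync_threshold radians separating synchronised from unsynchronised
#'   oscillation (default `pi / 8`).
#' @param collapse_fraction diversity fraction below which the run counts as
#'   collapsed (default 0.5).
#' @return one of `"fixed_point"`, `"synchronised_oscillation"`,
#'   `"unsynchronised_oscillation"`, `"mixed"`, `"collapsed"`.
#' @export
spatial_regime <- function(run_summary, nonspatial_report = NULL,
                           sync_threshold = pi / 8, collapse_fraction = 0.5) {
  stopifnot(inherits(run_summary, "glv_run_summary"))
  if (isTRUE(run_summary$diverged_flag)) return("collapsed")
  n_ref <- if (!is.null(nonspatial_report)) nonspatial_report$N else
    run_summary$N
  if (run_summary$diversity < collapse_fraction * n_ref) return("collapsed")
  if (run_summary$n_osc_points == 0) return("fixed_point")
  if (run_summary$n_osc_points < run_summary$M) return("mixed")
  if (!is.na(run_summary$sync_index) &&
      run_summary$sync_index < sync_threshold) {
    "synchronised_oscillation"
  } else {
    "unsynchronised_oscillation"
  }
}
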