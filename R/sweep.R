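# Experiment runner: single-system presets and the (diffusion magnitude x
# interaction-strength s.d.) parameter-space sweep, with seeded
# reproducibility, crash-safe record files and panel aggregation.

#' Sweep configuration
#'
#' One community per system index is shared across every (sigma, diffusion)
#' cell of that system, isolating the diffusion effect; diffusion-rate
#' vectors are redrawn per diffusion level from that level's decade.
#'
#' @param N species-pool size (default 20).
#' @param c,mu interaction density and mean (defaults 0.5, -0.5).
#' @param r,K growth rates / carrying capacities (default 1).
#' @param sigma_grid increasing positive interaction-strength values.
#' @param diffusion_levels non-negative mean diffusion rates; 0 is the
#'   disconnected (non-spatial) row.  Default `c(0, 10^(-5:1))`.
#' @param n_systems number of independent communities (default 10).
#' @param geometry lattice (default ring of 50 patches).
#' @param b relative diffusion spread; `NULL` draws per dispersal sample.
#' @param t_end,output_dt integration horizon and sampling (defaults 2000,
#'   0.5; the leading `transient_frac` of the horizon is discarded when
#'   measuring).
#' @param rtol,atol solver tolerances.
#' @param measure a [measure_config()].
#' @param master_seed integer master seed for the whole sweep.
#' @return a list of class `glv_sweep_config`.
#' @export
sweep_config <- function(N = 20, c = 0.5, mu = -0.5, r = 1, K = 1,
                         sigma_grid, diffusion_levels = c(0, 10^(-5:1)),
                         n_systems = 10, geometry = grid_geometry(1L, 50L),
                         b = NULL, t_end = 2000, output_dt = 0.5,
                         rtol = 1e-8, atol = 1e-10,
                         measure = measure_config(), master_seed = 1) {
  if (missing(sigma_grid) || length(sigma_grid) == 0) {
    stop("`sigma_grid` must be a non-empty increasing vector", call. = FALSE)
  }
  if (is.unsorted(sigma_grid, strictly = TRUE) || any(sigma_grid < 0)) {
    stop("`sigma_grid` must be non-negative and strictly increasing",
         call. = FALSE)
  }
  if (any(diffusion_levels < 0)) {
    stop("`diffusion_levels` must be non-negative", call. = FALSE)
  }
  if (n_systems < 1) stop("`n_systems` must be >= 1", call. = FALSE)
  structure(
    list(N = N, c = c, mu = mu, r = r, K = K, sigma_grid = sigma_grid,
         diffusion_levels = diffusion_levels, n_systems = n_systems,
         geometry = geometry, b = b, t_end = t_end, output_dt = output_dt,
         rtol = rtol, atol = atol, measure = measure,
         master_seed = as.integer(master_seed)),
    class = "glv_sweep_config"
  )
}

# deterministic seed tree: master -> system -> {community, dispersal x level,
# ic x cell}
.system_seeds <- function(config, system_index) {
  sys_seed <- derive_seeds(config$master_seed,
                           paste0("sys", seq_len(config$n_systems)))[system_index]
  sub <- derive_seeds(sys_seed, c("community", "b", "dispersal", "ic"))
  n_lv <- length(config$diffusion_levels)
  n_cell <- n_lv * length(config$sigma_grid)
  list(
    community = sub[["community"]],
    b = sub[["b"]],
    dispersal = derive_seeds(sub[["dispersal"]], paste0("lv", seq_len(n_lv))),
    ic = derive_seeds(sub[["ic"]], paste0("cell", seq_len(n_cell)))
  )
}

#' Run one sweep cell
#'
#' Builds the cell's system from the deterministic seed tree (community
#' shared across all cells of `system_index`; dispersal redrawn per diffusion
#' level; initial conditions per cell), integrates and summarises.  Re-running
#' the same cell reproduces the identical record.
#'
#' @param config a [sweep_config()].
#' @param system_index which community (1-based).
#' @param sigma interaction strength (must be in `config$sigma_grid`).
#' @param mu_D diffusion level (must be in `config$diffusion_levels`).
#' @return one-row data frame record.
#' @export
run_cell <- function(config, system_index, sigma, mu_D) {
  stopifnot(inherits(config, "glv_sweep_config"))
  i_sig <- match(sigma, config$sigma_grid)
  i_lv <- match(mu_D, config$diffusion_levels)
  if (is.na(i_sig) || is.na(i_lv)) {
    stop("cell (sigma, mu_D) not in the configured grid", call. = FALSE)
  }
  seeds <- .system_seeds(config, system_index)
  A <- sample_interaction_matrix(config$N, c = config$c, mu = config$mu,
                                 seed = seeds$community)
  comm <- community(A, sigma = sigma, r = config$r, K = config$K,
                    c = config$c, mu = config$mu)
  b <- config$b
  if (is.null(b)) b <- local_seed(seeds$b, runif(1, 0.3, 0.4))
  D <- sample_diffusion_rates(config$N, mu_D = mu_D, b = b,
                              seed = seeds$dispersal[i_lv])
  sys <- structure(
    list(community = comm,
         dispersal = dispersal_profile(D, mu_D = mu_D, b = b),
         geometry = config$geometry,
         seed = seeds$community,
         sub_seeds = c(matrix = seeds$community, b = seeds$b,
                       diffusion = seeds$dispersal[[i_lv]],
                       ic = seeds$ic[[(i_sig - 1) * length(config$diffusion_levels) + i_lv]])),
    class = "glv_system"
  )
  t0 <- proc.time()[["elapsed"]]
  tr <- integrate_system(sys, t_end = config$t_end,
                         output_dt = config$output_dt,
                         rtol = config$rtol, atol = config$atol)
  sm <- summarise_run(tr, config$measure)
  data.frame(
    system = system_index, sigma = sigma, mu_D = mu_D,
    n_osc_points = sm$n_osc_points,
    sync_index = sm$sync_index,
    mean_amplitude = sm$mean_amplitude,
    diversity = sm$diversity,
    diverged = sm$diverged_flag,
    M = sm$M, N = sm$N,
    elapsed = proc.time()[["elapsed"]] - t0
  )
}

#' Aggregate sweep records into panel tables
#'
#' Per (sigma, mu_D) cell: mean oscillatory-grid-point count, mean
#' synchronisation index (over runs where it is defined), mean oscillation
#' amplitude (over runs with oscillations), mean diversity, plus run and
#' divergence counts.  Purely a function of the records, so aggregates can
#' always be recomputed.
#'
#' @param records data frame of [run_cell()] rows.
#' @return data frame, one row per (sigma, mu_D).
#' @export
aggregate_records <- function(records) {
  key <- interaction(records$sigma, records$mu_D, drop = TRUE)
  rows <- lapply(split(records, key), function(df) {
    ok <- !df$diverged
    osc <- ok & !is.na(df$n_osc_points) & df$n_osc_points > 0
    data.frame(
      sigma = df$sigma[1], mu_D = df$mu_D[1],
      mean_n_osc_points = mean(df$n_osc_points[ok]),
      mean_sync_index = if (any(osc & !is.na(df$sync_index)))
        mean(df$sync_index[osc], na.rm = TRUE) else NA_real_,
      mean_amplitude = if (any(osc)) mean(df$mean_amplitude[osc]) else
        NA_real_,
      mean_diversity = mean(df$diversity[ok]),
      n_runs = nrow(df), n_diverged = sum(df$diverged)
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mu_D, out$sigma), ]
  rownames(out) <- NULL
  out
}

#' Run the full parameter-space sweep
#'
#' Executes every (system, sigma, diffusion level) cell.  When
#' `records_path` is given, finished records are appended to that CSV as they
#' complete and a restarted sweep skips cells already on disk, so an
#' interrupted sweep resumes to the identical result (each cell is seeded
#' independently).
#'
#' @param config a [sweep_config()].
#' @param records_path optional CSV path for incremental records.
#' @param verbose print one line per cell (default FALSE).
#' @return an object of class `glv_sweep_result`: list with `records`,
#'   `aggregates` and `config`.
#' @export
run_sweep <- function(config, records_path = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "glv_sweep_config"))
  done <- NULL
  if (!is.null(records_path) && file.exists(records_path)) {
    done <- read.csv(records_path)
  }
  records <- if (is.null(done)) list() else list(done)
  for (i in seq_len(config$n_systems)) {
    for (sigma in config$sigma_grid) {
      for (mu_D in config$diffusion_levels) {
        if (!is.null(done) &&
            any(done$system == i & done$sigma == sigma & done$mu_D == mu_D)) {
          next
        }
        rec <- run_cell(config, i, sigma, mu_D)
        if (verbose) {
          message(sprintf(
            "cell system=%d sigma=%.4g mu_D=%.3g: div=%s osc=%s (%.1fs)",
            i, sigma, mu_D, rec$diversity, rec$n_osc_points, rec$elapsed))
        }
        records[[length(records) + 1L]] <- rec
        if (!is.null(records_path)) {
          write.table(rec, records_path, sep = ",", append = file.exists(records_path),
                      col.names = !file.exists(records_path),
                      row.names = FALSE, qmethod = "double")
        }
      }
    }
  }
  records <- do.call(rbind, records)
  structure(list(records = records, aggregates = aggregate_records(records),
                 config = config),
            class = "glv_sweep_result")
}

#' @export
print.glv_sweep_result <- function(x, ...) {
  cat(sprintf("Sweep result: %d records over %d sigma x %d diffusion cells\n",
              nrow(x$records), length(x$config$sigma_grid),
              length(x$config$diffusion_levels)))
  print(x$aggregates)
  invisible(x)
}

#' Search for an unsynchronised-oscillation stabilisation example
#'
#' Scans seeded N-species communities for one where, at an interaction
#' strength beyond the non-spatial fixed-point range, low dispersal
#' (`mu_D = 1e-2`, `sd = 0.4 mu_D`) produces unsynchronised local
#' oscillations whose spatial averages are nearly constant: every extant
#' species' global-mean abundance has coefficient of variation below
#' `cv_max`, the local relative oscillation amplitudes exceed `amp_factor`
#' times those CVs (local swings at least an order of magnitude above the
#' global fluctuation level), and spatial diversity is at least the
#' non-spatial diversity at the same sigma.
#'
#' @param seed integer seed selecting the candidate stream.
#' @param search_budget maximum candidate communities (default 50).
#' @param N pool size (default 20).
#' @param mu_D,b dispersal level of the spatial run (defaults 1e-2, 0.4).
#' @param geometry lattice (default ring of 50).
#' @param t_end horizon per run (default 1000).
#' @param cv_max global-mean CV threshold (default 0.05).
#' @param amp_factor required ratio of mean relative local amplitude to mean
#'   global CV among oscillating extant species (default 10).
#' @param sigma_factors candidate multiples of the feasibility boundary at
#'   which collapse of the non-spatial model is probed.
#' @param verbose print one progress line per candidate (default FALSE).
#' @return on success, a list of class `glv_stabilisation_example` with the
#'   qualifying `system`, `sigma`, spatial and non-spatial summaries,
#'   trajectories and per-candidate `diagnostics`; on failure an error is
#'   thrown carrying the diagnostics table.
#' @export
preset_stabilisation_example <- function(seed, search_budget = 50, N = 20,
                                         mu_D = 1e-2, b = 0.4,
                                         geometry = grid_geometry(1L, 50L),
                                         t_end = 1000, cv_max = 0.05,
                                         amp_factor = 10,
                                         sigma_factors = c(1.5, 2, 2.5, 3,
                                                           3.5, 4, 5, 6),
                                         verbose = FALSE) {
  cand_seeds <- derive_seeds(seed, paste0("cand", seq_len(search_budget)))
  diagnostics <- list()
  diag_row <- function(candidate, status, sigma = NA_real_, max_cv = NA_real_,
                       amp_ratio = NA_real_, spatial_diversity = NA_integer_,
                       nonspatial_diversity = NA_integer_, pass = NA) {
    data.frame(candidate = candidate, status = status, sigma = sigma,
               max_cv = max_cv, amp_ratio = amp_ratio,
               spatial_diversity = spatial_diversity,
               nonspatial_diversity = nonspatial_diversity, pass = pass)
  }
  cfg <- measure_config()
  for (k in seq_len(search_budget)) {
    sys <- build_system(N = N, sigma = 0, mu_D = mu_D, b = b,
                        geometry = geometry, seed = cand_seeds[k])
    sf <- feasibility_boundary(sys$community, sigma_max = 2, tol = 1e-3)
    if (isTRUE(attr(sf, "not_bracketed"))) {
      diagnostics[[k]] <- diag_row(k, "no_boundary")
      next
    }
    # walk sigma upward until the non-spatial model first has no stable
    # fixed point (collapse/oscillation onset), then stop
    sigma <- NA_real_
    nonspatial_div <- NA_integer_
    scan <- NULL
    for (fac in sigma_factors) {
      sg <- fac * as.numeric(sf)
      scan_f <- stability_scan(sys$community, sigma_grid = sg,
                               n_restarts = 2, seed = cand_seeds[k],
                               t_end = 800, rtol = 1e-6, atol = 1e-8)
      if (scan_f$labels[1] == "collapsed") {
        sigma <- sg
        scan <- scan_f
        nonspatial_div <- max(0, scan_f$details$diversity[
          !is.na(scan_f$details$diversity)])
        break
      }
    }
    if (is.na(sigma)) {
      diagnostics[[k]] <- diag_row(k, "no_collapse")
      if (verbose) message(sprintf("candidate %d: no collapse found", k))
      next
    }

    sys$community$sigma <- sigma
    tr <- integrate_system(sys, t_end = t_end, output_dt = 1,
                           rtol = 1e-6, atol = 1e-8, max_steps = 3e5)
    sm <- summarise_run(tr, cfg)
    if (sm$diverged_flag || sm$n_osc_points == 0) {
      diagnostics[[k]] <- diag_row(k, "no_oscillation", sigma)
      next
    }
    gm <- global_mean_abundance(tr)
    keep <- tr$times >= t_end * cfg$transient_frac
    gm <- gm[keep, , drop = FALSE]
    ext <- which(sm$extant)
    # per extant species: CV of the global-mean series, and the mean local
    # oscillation amplitude relative to the species' global mean abundance
    cv <- apply(gm[, ext, drop = FALSE], 2,
                function(x) sd(x) / max(mean(x), 1e-12))
    rel_amp <- sm$amplitude_by_species[ext] /
      pmax(colMeans(gm[, ext, drop = FALSE]), 1e-12)
    osc_sp <- rel_amp > 0
    amp_ratio <- if (any(osc_sp)) {
      mean(rel_amp[osc_sp]) / max(mean(cv[osc_sp]), 1e-12)
    } else {
      0
    }
    ok_cv <- max(cv) < cv_max
    ok_amp <- amp_ratio > amp_factor
    ok_div <- sm$diversity >= nonspatial_div
    diagnostics[[k]] <- diag_row(
      k, "tested", sigma, max_cv = max(cv), amp_ratio = amp_ratio,
      spatial_diversity = sm$diversity, nonspatial_diversity = nonspatial_div,
      pass = ok_cv && ok_amp && ok_div)
    if (verbose) {
      message(sprintf(
        "candidate %d: sigma=%.3f maxCV=%.3g amp_ratio=%.2f div %d vs %d %s",
        k, sigma, max(cv), amp_ratio, sm$diversity, nonspatial_div,
        if (ok_cv && ok_amp && ok_div) "PASS" else "fail"))
    }
    if (ok_cv && ok_amp && ok_div) {
      return(structure(
        list(system = sys, sigma = sigma, seed = cand_seeds[[k]],
             candidate = k,
             spatial_summary = sm, spatial_trajectory = tr,
             nonspatial_report = scan, nonspatial_diversity = nonspatial_div,
             max_global_cv = max(cv), amp_ratio = amp_ratio,
             diagnostics = do.call(rbind, diagnostics[!sapply(diagnostics, is.null)])),
        class = "glv_stabilisation_example"))
    }
  }
  diag_df <- do.call(rbind, diagnostics[!sapply(diagnostics, is.null)])
  cond <- simpleError("no qualifying community found within the search budget")
  cond$diagnostics <- diag_df
  stop(cond)
}

#' One community across four diffusion magnitudes
#'
#' Runs a single seeded community at diffusion means `10^-5, 10^-3, 10^-1, 1`
#' with `sd = 0.4 * mean` (so the mean is 2.5 times the s.d.), at an
#' interaction strength beyond the feasibility boundary, and returns the
#' per-level trajectories, summaries and global-mean series.  Typical
#' behaviour: unsynchronised low-amplitude oscillations with near-constant
#' global means at the low end, synchronised high-amplitude global
#' oscillations at the high end.
#'
#' @param seed integer seed.
#' @param levels diffusion means (default `c(1e-5, 1e-3, 1e-1, 1)`).
#' @param sigma interaction strength; `NULL` (default) uses 1.3 times the
#'   community's feasibility boundary.
#' @param N pool size (default 20).
#' @param b relative spread (default 0.4).
#' @param geometry lattice (default ring of 50).
#' @param t_end horizon (default 1000).
#' @return a list of class `glv_diffusion_scan`: `system`, `sigma`, `levels`,
#'   `summaries` (one per level), `trajectories`, `global_means`.
#' @export
preset_diffusion_scan <- function(seed, levels = c(1e-5, 1e-3, 1e-1, 1),
                                  sigma = NULL, N = 20, b = 0.4,
                                  geometry = grid_geometry(1L, 50L),
                                  t_end = 1000) {
  seeds <- derive_seeds(seed, c("system", paste0("lv", seq_along(levels))))
  sys0 <- build_system(N = N, sigma = 0, mu_D = levels[1], b = b,
                       geometry = geometry, seed = seeds[["system"]])
  if (is.null(sigma)) {
    sf <- feasibility_boundary(sys0$community, sigma_max = 2, tol = 1e-3)
    sigma <- 1.3 * as.numeric(sf)
  }
  summaries <- list()
  trajectories <- list()
  global_means <- list()
  for (j in seq_along(levels)) {
    sys <- sys0
    sys$community$sigma <- sigma
    D <- sample_diffusion_rates(N, mu_D = levels[j], b = b,
                                seed = seeds[[paste0("lv", j)]])
    sys$dispersal <- dispersal_profile(D, mu_D = levels[j], b = b)
    tr <- integrate_system(sys, t_end = t_end)
    summaries[[j]] <- summarise_run(tr)
    trajectories[[j]] <- tr
    global_means[[j]] <- global_mean_abundance(tr)
  }
  structure(list(system = sys0, sigma = sigma, levels = levels,
                 summaries = summaries, trajectories = trajectories,
                 global_means = global_means, seed = seed),
            class = "glv_diffusion_scan")
}
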