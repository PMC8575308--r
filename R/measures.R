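# Measurement suite: per-grid-point dynamics classification, oscillation
# amplitudes, dominant frequencies, Fourier phase-shift synchronisation,
# diversity and global (spatial-mean) abundances.
#
# Spectral estimates remove the mean and apply a Hann window before the
# transform to limit leakage; phases are read off at the dominant bin.

#' Measurement configuration
#'
#' @param rel_tol relative fluctuation below which a series counts as a fixed
#'   point (default 1e-3).
#' @param extinct_threshold time-averaged abundance below which a species is
#'   locally extinct, in units of `K = 1` (default 1e-4).
#' @param transient_frac leading fraction of a trajectory discarded before
#'   measuring (default 0.5).
#' @return a list of class `measure_config`.
#' @export
measure_config <- function(rel_tol = 1e-3, extinct_threshold = 1e-4,
                           transient_frac = 0.5) {
  stopifnot(rel_tol > 0, extinct_threshold > 0,
            transient_frac >= 0, transient_frac < 1)
  structure(list(rel_tol = rel_tol, extinct_threshold = extinct_threshold,
                 transient_frac = transient_frac),
            class = "measure_config")
}

# drop the transient: rows of the trajectory before transient_frac * t_end
post_transient <- function(trajectory, transient_frac) {
  t_cut <- trajectory$times[length(trajectory$times)] * transient_frac
  keep <- trajectory$times >= t_cut
  list(times = trajectory$times[keep],
       phi = trajectory$phi[keep, , , drop = FALSE])
}

#' Classify one grid-point as fixed point or oscillation
#'
#' A grid-point is a fixed point when every locally extant species has a
#' relative fluctuation range `(max - min) / max(mean, floor)` below
#' `rel_tol` over the (post-transient) window; otherwise it oscillates.  A
#' grid-point where everything is extinct is the zero fixed point and is
#' flagged via the `"all_extinct"` attribute.
#'
#' @param slice numeric `T` x `N` matrix: the post-transient time series of
#'   one grid-point.
#' @param rel_tol relative fluctuation tolerance.
#' @param extinct_threshold local-extinction floor.
#' @return `"fixed_point"` or `"oscillation"`.
#' @export
classify_gridpoint <- function(slice, rel_tol = 1e-3,
                               extinct_threshold = 1e-4) {
  slice <- as.matrix(slice)
  means <- colMeans(slice)
  extant <- means > extinct_threshold
  if (!any(extant)) {
    return(structure("fixed_point", all_extinct = TRUE))
  }
  rng <- apply(slice[, extant, drop = FALSE], 2, function(x) max(x) - min(x))
  rel <- rng / pmax(means[extant], extinct_threshold)
  if (all(rel < rel_tol)) "fixed_point" else "oscillation"
}

#' Oscillation amplitude of a series
#'
#' Half the peak-to-peak range over the analysis window; 0 for a constant
#' series.
#'
#' @param series numeric vector (uniformly sampled, post-transient).
#' @return non-negative number.
#' @export
oscillation_amplitude <- function(series) {
  (max(series) - min(series)) / 2
}

# Hann-windowed, mean-removed discrete Fourier transform
windowed_fft <- function(series) {
  n <- length(series)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / n))
  fft((series - mean(series)) * w)
}

#' Dominant oscillation frequency
#'
#' Frequency (cycles per unit time) of the non-zero bin with maximal
#' Hann-windowed Fourier amplitude.  Series whose relative fluctuation falls
#' below `rel_tol` are treated as fixed points and return 0.
#'
#' @param series numeric vector, uniformly sampled.
#' @param dt sampling interval.
#' @param rel_tol sub-tolerance fluctuation cut-off (default 1e-3).
#' @return non-negative frequency, 0 for a fixed point.
#' @export
dominant_frequency <- function(series, dt, rel_tol = 1e-3) {
  n <- length(series)
  if (n < 2) stop("series must have at least 2 samples", call. = FALSE)
  m <- mean(series)
  if ((max(series) - min(series)) / max(abs(m), 1e-12) < rel_tol) {
    return(0)
  }
  amp <- Mod(windowed_fft(series))
  half <- seq(2, floor(n / 2) + 1)  # positive frequencies, DC excluded
  k <- half[which.max(amp[half])]
  (k - 1) / (n * dt)
}

#' Phase shift between two series at a given frequency
#'
#' Absolute difference of the discrete-Fourier arguments of the two series at
#' the bin nearest `freq`, wrapped into `[0, pi]` (lags `delta` and
#' `2 pi - delta` are the same physical offset).
#'
#' @param series_a,series_b numeric vectors on a common uniform time grid.
#' @param freq positive frequency in cycles per unit time.
#' @param dt sampling interval.
#' @return phase difference in `[0, pi]` radians.
#' @export
phase_shift_pair <- function(series_a, series_b, freq, dt) {
  n <- length(series_a)
  if (length(series_b) != n) {
    stop("series must share one time grid", call. = FALSE)
  }
  if (freq <= 0 || freq > 1 / (2 * dt)) {
    stop("`freq` must lie in the resolvable band (0, Nyquist]", call. = FALSE)
  }
  k <- round(freq * n * dt) + 1
  k <- max(2, min(k, floor(n / 2) + 1))
  d <- Arg(windowed_fft(series_a)[k]) - Arg(windowed_fft(series_b)[k])
  d <- abs(((d + pi) %% (2 * pi)) - pi)
  d
}

# phases of every grid-point's series for one species at one bin
.phases_at_bin <- function(mat, k) {
  apply(mat, 2, function(x) Arg(windowed_fft(x)[k]))
}

#' Synchronisation index of a trajectory
#'
#' For each globally extant species, take its dominant oscillation frequency
#' (the positive bin with greatest summed power across the grid-points where
#' it is locally extant), compute the Fourier phase at that bin in every such
#' grid-point, and record the maximum pairwise phase difference wrapped into
#' `[0, pi]`.  The index is the mean of these per-species maxima: 0 means the
#' grid is synchronised, `pi` completely unsynchronised.  Returns `NA` when
#' no extant species oscillates (the index is undefined at a fixed point).
#'
#' @param trajectory a `glv_trajectory` (transient not yet removed).
#' @param config a [measure_config()].
#' @return scalar in `[0, pi]`, or `NA_real_`.
#' @export
sync_index <- function(trajectory, config = measure_config()) {
  pt <- post_transient(trajectory, config$transient_frac)
  dt <- pt$times[2] - pt$times[1]
  d <- dim(pt$phi)
  Tn <- d[1]; M <- d[2]; N <- d[3]
  shifts <- rep(NA_real_, N)
  for (s in seq_len(N)) {
    mat <- matrix(pt$phi[, , s], Tn, M)
    means <- colMeans(mat)
    loc <- means > config$extinct_threshold
    if (sum(loc) < 2) next
    sub <- mat[, loc, drop = FALSE]
    rel <- apply(sub, 2, function(x) (max(x) - min(x)) / max(mean(x), config$extinct_threshold))
    if (max(rel) < config$rel_tol) next  # species at a spatial fixed point
    # dominant bin: greatest total windowed power over included grid-points
    pw <- rowSums(sapply(seq_len(ncol(sub)),
                         function(j) Mod(windowed_fft(sub[, j]))^2))
    half <- seq(2, floor(Tn / 2) + 1)
    k <- half[which.max(pw[half])]
    ph <- .phases_at_bin(sub, k)
    dmat <- abs(outer(ph, ph, "-"))
    dmat <- pmin(dmat, 2 * pi - dmat)
    shifts[s] <- max(dmat)
  }
  if (all(is.na(shifts))) NA_real_ else mean(shifts, na.rm = TRUE)
}

#' Global diversity of a trajectory
#'
#' A species is extant when its post-transient time-averaged abundance
#' exceeds `extinct_threshold` in at least one grid-point ("extant anywhere"
#' semantics: a species rescued by any patch counts).
#'
#' @param trajectory a `glv_trajectory`.
#' @param extinct_threshold extinction floor (default 1e-4).
#' @param transient_frac leading fraction discarded (default 0.5).
#' @return list with `n` (integer count) and `extant` (logical length-`N`
#'   mask).
#' @export
diversity_count <- function(trajectory, extinct_threshold = 1e-4,
                            transient_frac = 0.5) {
  pt <- post_transient(trajectory, transient_frac)
  avg <- apply(pt$phi, c(2, 3), mean)           # M x N time means
  extant <- apply(avg, 2, function(x) any(x > extinct_threshold))
  list(n = sum(extant), extant = extant)
}

#' Global (spatial-mean) abundances
#'
#' Unweighted mean over grid-points at each output time.
#'
#' @param trajectory a `glv_trajectory`.
#' @return numeric `T` x `N` matrix.
#' @export
global_mean_abundance <- function(trajectory) {
  apply(trajectory$phi, c(1, 3), mean)
}

#' Summarise one run
#'
#' Discards the transient and assembles the full measurement record: the
#' per-grid-point dynamics class, the count of oscillatory grid-points, the
#' synchronisation index, the mean oscillation amplitude (over species x
#' oscillating grid-points, locally extant only; per-species and
#' per-grid-point marginals are also kept), global diversity, and the
#' time-averaged spatial-mean abundance per species.
#'
#' @param trajectory a `glv_trajectory`.
#' @param config a [measure_config()].
#' @return an object of class `glv_run_summary`.
#' @export
summarise_run <- function(trajectory, config = measure_config()) {
  stopifnot(inherits(trajectory, "glv_trajectory"))
  d <- dim(trajectory$phi)
  M <- d[2]; N <- d[3]
  if (isTRUE(trajectory$diverged)) {
    return(structure(
      list(n_osc_points = NA_integer_, sync_index = NA_real_,
           mean_amplitude = NA_real_, diversity = NA_integer_,
           extant = rep(NA, N), global_mean_abundance = rep(NA_real_, N),
           per_point_class = rep(NA_character_, M),
           amplitude_by_species = rep(NA_real_, N),
           diverged_flag = TRUE, M = M, N = N),
      class = "glv_run_summary"))
  }
  pt <- post_transient(trajectory, config$transient_frac)
  Tn <- dim(pt$phi)[1]

  classes <- character(M)
  amp_sum <- 0; amp_n <- 0
  amp_sp_sum <- numeric(N); amp_sp_n <- numeric(N)
  for (g in seq_len(M)) {
    slice <- matrix(pt$phi[, g, ], Tn, N)
    classes[g] <- classify_gridpoint(slice, config$rel_tol,
                                     config$extinct_threshold)
    if (classes[g] == "oscillation") {
      means <- colMeans(slice)
      for (s in which(means > config$extinct_threshold)) {
        a <- oscillation_amplitude(slice[, s])
        amp_sum <- amp_sum + a; amp_n <- amp_n + 1
        amp_sp_sum[s] <- amp_sp_sum[s] + a; amp_sp_n[s] <- amp_sp_n[s] + 1
      }
    }
  }
  div <- diversity_count(trajectory, config$extinct_threshold,
                         config$transient_frac)
  gm <- global_mean_abundance(trajectory)
  keep <- trajectory$times >= trajectory$times[length(trajectory$times)] *
    config$transient_frac
  structure(
    list(
      n_osc_points = sum(classes == "oscillation"),
      sync_index = sync_index(trajectory, config),
      mean_amplitude = if (amp_n > 0) amp_sum / amp_n else 0,
      diversity = div$n,
      extant = div$extant,
      global_mean_abundance = colMeans(gm[keep, , drop = FALSE]),
      per_point_class = classes,
      amplitude_by_species = ifelse(amp_sp_n > 0, amp_sp_sum / pmax(amp_sp_n, 1),
                                    0),
      diverged_flag = FALSE, M = M, N = N
    ),
    class = "glv_run_summary"
  )
}

#' @export
print.glv_run_summary <- function(x, ...) {
  if (isTRUE(x$diverged_flag)) {
    cat("Run summary: DIVERGED\n")
    return(invisible(x))
  }
  cat(sprintf(
    paste0("Run summary: %d/%d grid-points oscillating, diversity %d/%d,\n",
           "  sync index = %s rad, mean amplitude = %.4g\n"),
    x$n_osc_points, x$M, x$diversity, x$N,
    if (is.na(x$sync_index)) "NA" else sprintf("%.3f", x$sync_index),
    x$mean_amplitude))
  invisible(x)
}
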