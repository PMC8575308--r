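# Shared fixtures, all built in code.

# a small deterministic community
tiny_community <- function(N = 5, sigma = 0.05, seed = 101, c = 0.5,
                           mu = -0.5) {
  community(sample_interaction_matrix(N, c = c, mu = mu, seed = seed),
            sigma = sigma, c = c, mu = mu)
}

# wrap a [time x grid-point x species] array as a trajectory object
make_trajectory <- function(times, phi, geometry = NULL) {
  if (is.null(geometry)) geometry <- grid_geometry(1L, dim(phi)[2])
  structure(list(times = times, phi = phi, geometry = geometry,
                 system = NULL, diverged = FALSE,
                 solver = list(rtol = NA, atol = NA,
                               output_dt = times[2] - times[1])),
            class = "glv_trajectory")
}

# planted-sinusoid trajectory: one species, per-grid-point phase lags.
# `lags` in radians; amplitude a around baseline m.
sinusoid_trajectory <- function(lags, freq = 0.05, dt = 0.5, t_end = 400,
                                a = 0.5, m = 1) {
  times <- seq(0, t_end, by = dt)
  M <- length(lags)
  phi <- array(0, dim = c(length(times), M, 1))
  for (g in seq_len(M)) {
    phi[, g, 1] <- m + a * sin(2 * pi * freq * times - lags[g])
  }
  make_trajectory(times, phi)
}

# closed-form logistic solution phi' = r phi (1 - phi / K)
logistic_solution <- function(t, phi0, r = 1, K = 1) {
  K * phi0 * exp(r * t) / (K + phi0 * (exp(r * t) - 1))
}
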