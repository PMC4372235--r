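# Shared fixture builders. Everything is generated in code; no binary
# fixtures.

# A frozen single-particle trajectory at a prescribed surface position,
# for closed-form rendering oracles.
frozen_trajectory <- function(s, theta, n_frames = 10L,
                              geometry = cell_geometry(),
                              dt = 0.1) {
  cfg <- sim_config(D_free = 0, D_bound = 0, n_particles = length(s),
                    n_sites = 0, dt = dt, n_steps = n_frames - 1L, seed = 1L,
                    geometry = geometry)
  structure(list(
    s = matrix(rep(s, each = n_frames), n_frames, length(s)),
    theta = matrix(rep(theta, each = n_frames), n_frames, length(theta)),
    bound_site = matrix(0L, n_frames, length(s)),
    bleached = matrix(FALSE, n_frames, length(s)),
    site_s = numeric(0), site_theta = numeric(0),
    config = cfg), class = "tirf_trajectory")
}

# Rectangular label mask: cell `id` spanning the given rows/cols.
rect_mask <- function(H, W, rows, cols, id = 1L, base = NULL) {
  m <- base %||% matrix(0L, H, W)
  m[rows, cols] <- id
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noise-free optics for oracle tests.
oracle_optics <- function(mode = "tirf", ...) {
  optics_config(mode = mode, read_noise_sd = 0, camera_offset = 0,
                expected_photons = TRUE, ...)
}

# Synthetic two-phase decay curves as bleach_trace objects.
synth_traces <- function(times, pars, condition, n_cells = 1L,
                         noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_cells), function(j) {
    y <- pars$A * exp(-pars$k_fast * times) +
      (100 - pars$A) * exp(-pars$K * times)
    if (noise_sd > 0) {
      y <- y + rnorm(length(y), 0, noise_sd)
      y[1L] <- 100
    }
    structure(list(cell_id = j, condition = condition, times = times,
                   normalized_intensity = y), class = "bleach_trace")
  })
}

# Independent two-state Gillespie oracle: long-run bound fraction of a
# free<->bound chain with hazards k_on, k_off, from time-averaging one
# long exact realization.
gillespie_bound_fraction <- function(k_on, k_off, t_end = 5000, seed = 99) {
  set.seed(seed)
  t <- 0; bound <- FALSE
  t_bound <- 0
  while (t < t_end) {
    rate <- if (bound) k_off else k_on
    dt <- rexp(1, rate)
    if (bound) t_bound <- t_bound + min(dt, t_end - t)
    t <- t + dt
    bound <- !bound
  }
  t_bound / t_end
}
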