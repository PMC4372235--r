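#' Geometry of an idealized rod-shaped cell
#'
#' The cell is modelled as the cylindrical section of a spherocylinder
#' resting on the coverslip. Surface positions are parameterized by the
#' axial coordinate \code{s} (\eqn{0 \le s \le length}, in micrometres)
#' and the azimuth \code{theta} (radians, \code{theta = 0} at the bottom
#' of the cell, touching the coverslip). The membrane height above the
#' coverslip is \eqn{z = r (1 - \cos\theta)}. Hemispherical end caps are
#' omitted: all analyzed signals (perimeter scans, kymograms, bleach
#' traces) come from the lateral wall.
#'
#' @param length cylinder length, micrometres (> 0).
#' @param radius cylinder radius, micrometres (> 0).
#' @param center_xy position of the cell center in the image plane,
#'   micrometres relative to the image center (length-2 numeric).
#' @param orientation in-plane orientation of the long axis, radians.
#' @return an object of class \code{cell_geometry}.
#' @export
cell_geometry <- function(length = 3, radius = 0.4, center_xy = c(0, 0),
                          orientation = 0) {
  check_scalar(length, "length", min = 0, strict = TRUE)
  check_scalar(radius, "radius", min = 0, strict = TRUE)
  check_scalar(orientation, "orientation")
  if (!is.numeric(center_xy) || length(center_xy) != 2L || !all(is.finite(center_xy)))
    stopf("'center_xy' must be two finite numbers (micrometres)")
  structure(list(length = length, radius = radius,
                 center_xy = as.numeric(center_xy), orientation = orientation),
            class = "cell_geometry")
}

#' Configuration of the membrane dynamics simulation
#'
#' Parameters of the Brownian dynamics of fluorophore-tagged membrane
#' proteins on the cylindrical wall of a rod-shaped cell, with transient
#' binding to immobile substrate sites (the clustering mechanism behind
#' membrane foci). Setting \code{n_sites = 0} removes the clustering
#' mechanism entirely, emulating substrate depletion (the
#' rifampicin-treated condition).
#'
#' @param D_free diffusion coefficient of unbound particles, um^2/s.
#' @param D_bound diffusion coefficient while bound to a site, um^2/s.
#' @param n_particles number of fluorophore-tagged particles.
#' @param n_sites number of substrate sites placed uniformly at random
#'   on the surface at t = 0 (immobile thereafter).
#' @param site_capacity maximum simultaneous occupants per site.
#' @param capture_radius binding reach of a site, micrometres (surface
#'   distance).
#' @param k_on binding hazard (1/s) while a free particle is within
#'   \code{capture_radius} of an unsaturated site.
#' @param k_off unbinding hazard, 1/s.
#' @param dt time step, seconds.
#' @param n_steps number of steps; the trajectory holds
#'   \code{n_steps + 1} snapshots.
#' @param seed integer seed; trajectories are byte-identical across runs
#'   with the same seed.
#' @param geometry a \code{\link{cell_geometry}}.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(D_free = 0.05, D_bound = 0, n_particles = 300,
                       n_sites = 0, site_capacity = 8, capture_radius = 0.2,
                       k_on = 0, k_off = 0, dt = 1 / 30, n_steps = 90,
                       seed = 1L, geometry = cell_geometry()) {
  check_scalar(D_free, "D_free", min = 0)
  check_scalar(D_bound, "D_bound", min = 0)
  n_particles <- check_count(n_particles, "n_particles", min = 0L)
  n_sites <- check_count(n_sites, "n_sites", min = 0L)
  site_capacity <- check_count(site_capacity, "site_capacity", min = 0L)
  check_scalar(capture_radius, "capture_radius", min = 0)
  check_scalar(k_on, "k_on", min = 0)
  check_scalar(k_off, "k_off", min = 0)
  check_scalar(dt, "dt", min = 0, strict = TRUE)
  n_steps <- check_count(n_steps, "n_steps", min = 0L)
  seed <- check_count(seed, "seed")
  if (!inherits(geometry, "cell_geometry"))
    stopf("'geometry' must be a cell_geometry object")
  if (n_sites > 0 && capture_radius > 0 &&
      sqrt(4 * D_free * dt) >= capture_radius)
    warnf("per-step displacement sqrt(4*D_free*dt) = %.3g um is not below capture_radius = %.3g um; binding kinetics will be time-step dependent",
          sqrt(4 * D_free * dt), capture_radius)
  structure(list(D_free = D_free, D_bound = D_bound,
                 n_particles = n_particles, n_sites = n_sites,
                 site_capacity = site_capacity,
                 capture_radius = capture_radius,
                 k_on = k_on, k_off = k_off, dt = dt, n_steps = n_steps,
                 seed = seed, geometry = geometry),
            class = "sim_config")
}

# Surface distance on the unrolled cylinder between particle positions
# (s, theta) and site positions (ss, ts): axial difference plus the
# shorter azimuthal arc. Returns an n_particles x n_sites matrix.
surface_dist2 <- function(s, theta, ss, ts, radius) {
  ds <- outer(s, ss, "-")
  dth <- abs(outer(theta, ts, "-"))
  dth <- pmin(dth, 2 * pi - dth)
  ds^2 + (radius * dth)^2
}

#' Simulate membrane protein diffusion with transient site binding
#'
#' Brownian dynamics on the unrolled cylindrical wall: free particles
#' take Gaussian steps of variance \eqn{2 D_{free} dt} per surface
#' dimension (azimuth periodic, axial ends reflecting), bound particles
#' move with \code{D_bound}. After the diffusion step of each tick,
#' bound particles unbind with probability \eqn{1 - e^{-k_{off} dt}};
#' free particles within \code{capture_radius} of an unsaturated site
#' bind with probability \eqn{1 - e^{-k_{on} dt}} (at most one binding
#' event per particle per tick; the nearest unsaturated site wins, ties
#' broken by lowest site index). Particles that unbind in a tick cannot
#' rebind until the next tick.
#'
#' The flat surface metric is valid for steps much smaller than the cell
#' radius; \code{\link{sim_config}} warns when the step size approaches
#' the capture radius.
#'
#' @param config a \code{\link{sim_config}}.
#' @return an object of class \code{tirf_trajectory}: matrices \code{s},
#'   \code{theta} (frames x particles), integer matrix \code{bound_site}
#'   (0 = unbound), logical matrix \code{bleached} (filled in by
#'   \code{\link{render_stack}}), site positions, and the config.
#' @export
simulate_membrane_dynamics <- function(config) {
  if (!inherits(config, "sim_config"))
    stopf("'config' must be a sim_config object")
  g <- config$geometry
  n <- config$n_particles
  nf <- config$n_steps + 1L
  dt <- config$dt
  r <- g$radius
  L <- g$length

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  # initial state: particles and sites uniform on the surface
  s <- stats::runif(n, 0, L)
  theta <- stats::runif(n, 0, 2 * pi)
  site_s <- if (config$n_sites > 0) stats::runif(config$n_sites, 0, L) else numeric(0)
  site_t <- if (config$n_sites > 0) stats::runif(config$n_sites, 0, 2 * pi) else numeric(0)
  bound <- integer(n)                     # 0 = unbound
  occ <- integer(config$n_sites)

  S <- matrix(NA_real_, nf, n)
  TH <- matrix(NA_real_, nf, n)
  B <- matrix(0L, nf, n)
  S[1L, ] <- s; TH[1L, ] <- theta

  sd_free <- sqrt(2 * config$D_free * dt)
  sd_bound <- sqrt(2 * config$D_bound * dt)
  p_off <- 1 - exp(-config$k_off * dt)
  p_on <- 1 - exp(-config$k_on * dt)
  cap2 <- config$capture_radius^2
  has_sites <- config$n_sites > 0L && config$site_capacity > 0L

  for (step in seq_len(config$n_steps)) {
    sd_step <- ifelse(bound > 0L, sd_bound, sd_free)
    if (n > 0L) {
      ds <- stats::rnorm(n, 0, sd_step)
      darc <- stats::rnorm(n, 0, sd_step)
      s <- reflect_into(s + ds, L)
      theta <- wrap_angle(theta + darc / r)
      # unbinding (drawn every tick for stable RNG consumption)
      u_off <- stats::runif(n)
      unb <- bound > 0L & u_off < p_off
      if (any(unb)) {
        occ <- occ - tabulate(bound[unb], nbins = config$n_sites)
        bound[unb] <- 0L
      }
      # binding: particles free at the start of the tick and still free
      u_on <- stats::runif(n)
      if (has_sites && p_on > 0) {
        free <- which(bound == 0L & !unb & u_on < p_on)
        if (length(free) > 0L) {
          d2 <- surface_dist2(s[free], theta[free], site_s, site_t, r)
          for (j in seq_along(free)) {
            open <- which(occ < config$site_capacity & d2[j, ] <= cap2)
            if (length(open) > 0L) {
              k <- open[which.min(d2[j, open])]   # which.min: lowest index on ties
              bound[free[j]] <- k
              occ[k] <- occ[k] + 1L
            }
          }
        }
      }
    }
    S[step + 1L, ] <- s
    TH[step + 1L, ] <- theta
    B[step + 1L, ] <- bound
  }

  structure(list(s = S, theta = TH, bound_site = B,
                 bleached = matrix(FALSE, nf, n),
                 site_s = site_s, site_theta = site_t,
                 config = config),
            class = "tirf_trajectory")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.tirf_trajectory <- function(x, ...) {
  cat(sprintf("tirf_trajectory: %d particles, %d frames (dt = %.4g s), %d sites\n",
              ncol(x$s), nrow(x$s), x$config$dt, length(x$site_s)))
  cat(sprintf("  cell %.2f x %.2f um, D_free = %.3g um^2/s\n",
              x$config$geometry$length, 2 * x$config$geometry$radius,
              x$config$D_free))
  invisible(x)
}

#' Drop leading frames from a trajectory
#'
#' Discards snapshots before \code{from} (1-based), e.g. a burn-in
#' period that lets site binding reach steady state before imaging.
#'
#' @param traj a \code{tirf_trajectory}.
#' @param from first snapshot to keep.
#' @return the trimmed \code{tirf_trajectory}.
#' @export
trim_trajectory <- function(traj, from) {
  from <- check_count(from, "from", 1L)
  if (from > nrow(traj$s)) stopf("'from' exceeds the number of frames")
  for (f in c("s", "theta", "bound_site", "bleached"))
    traj[[f]] <- traj[[f]][from:nrow(traj[[f]]), , drop = FALSE]
  traj$config$n_steps <- nrow(traj$s) - 1L
  traj
}

#' Fraction of particles bound to a site, per frame
#' @param traj a \code{tirf_trajectory}.
#' @return numeric vector, one value per frame.
#' @export
bound_fraction <- function(traj) {
  if (ncol(traj$bound_site) == 0L) return(rep(0, nrow(traj$bound_site)))
  rowMeans(traj$bound_site > 0L)
}

#' Ensemble mean squared displacement of a trajectory
#'
#' Computed on the unrolled surface: axial displacement plus azimuthal
#' arc length, with the azimuth unwrapped frame to frame (valid while
#' per-step angular displacements stay below pi).
#'
#' @param traj a \code{tirf_trajectory}.
#' @param lags integer frame lags (default: all).
#' @return data.frame with columns \code{lag}, \code{t} (seconds) and
#'   \code{msd} (um^2).
#' @export
trajectory_msd <- function(traj, lags = NULL) {
  r <- traj$config$geometry$radius
  nf <- nrow(traj$s)
  if (is.null(lags)) lags <- seq_len(nf - 1L)
  dth <- diff(traj$theta)
  dth <- ((dth + pi) %% (2 * pi)) - pi      # unwrap steps into (-pi, pi]
  arc <- apply(dth, 2L, cumsum) * r
  arc <- rbind(0, arc)
  # Axial displacement measured from origin; reflections at the ends make
  # axial MSD sub-linear at long times, so callers probing the free-diffusion
  # law should use a geometry much longer than the diffusion length.
  ax <- traj$s
  msd <- vapply(lags, function(l) {
    da <- ax[1L + l, ] - ax[1L, ]
    dc <- arc[1L + l, ] - arc[1L, ]
    mean(da^2 + dc^2)
  }, numeric(1))
  data.frame(lag = lags, t = lags * traj$config$dt, msd = msd)
}
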