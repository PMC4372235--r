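#' Image formation settings for epifluorescence or TIRF rendering
#'
#' In TIRF mode the excitation intensity decays exponentially with
#' height above the coverslip (evanescent field, depth \code{d}); in
#' epifluorescence mode every fluorophore is excited equally. The
#' emission weight equals the excitation weight (no separate collection
#' efficiency), so a fluorophore at azimuth \code{theta} contributes
#' photons in proportion to \eqn{e^{-z/d}}, \eqn{z = r(1-\cos\theta)}.
#'
#' @param mode \code{"tirf"} or \code{"epifluorescence"}.
#' @param evanescent_depth evanescent-field depth d, micrometres
#'   (required > 0 for TIRF).
#' @param photons_per_fluorophore mean emitted photons per fluorophore
#'   per exposure at excitation weight 1.
#' @param bleach_coefficient photobleaching rate at excitation weight 1,
#'   1/s of exposure; per-frame survival is
#'   \eqn{e^{-\beta w \cdot exposure}}.
#' @param psf_sigma Gaussian point-spread-function width, micrometres.
#' @param pixel_size micrometres per pixel.
#' @param exposure exposure time per frame, seconds (<= frame_interval).
#' @param frame_interval time between rendered frames, seconds.
#' @param image_shape c(height, width) in pixels.
#' @param camera_offset constant camera baseline, counts.
#' @param read_noise_sd Gaussian read noise, counts.
#' @param expected_photons if TRUE, disable all stochastic noise:
#'   photon emission uses expected values, bleaching multiplies each
#'   fluorophore's intensity by its survival probability instead of
#'   drawing binary fates, and no read noise or quantization is applied.
#'   Intended for closed-form oracle checks.
#' @param seed integer seed for the rendering noise.
#' @return an object of class \code{optics_config}.
#' @export
optics_config <- function(mode = c("tirf", "epifluorescence"),
                          evanescent_depth = 0.1,
                          photons_per_fluorophore = 100,
                          bleach_coefficient = 0,
                          psf_sigma = 0.1, pixel_size = 0.1,
                          exposure = 0.1, frame_interval = 0.1,
                          image_shape = c(32L, 48L),
                          camera_offset = 100, read_noise_sd = 2,
                          expected_photons = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "tirf") check_scalar(evanescent_depth, "evanescent_depth", min = 0, strict = TRUE)
  check_scalar(photons_per_fluorophore, "photons_per_fluorophore", min = 0)
  check_scalar(bleach_coefficient, "bleach_coefficient", min = 0)
  check_scalar(psf_sigma, "psf_sigma", min = 0, strict = TRUE)
  check_scalar(pixel_size, "pixel_size", min = 0, strict = TRUE)
  check_scalar(exposure, "exposure", min = 0, strict = TRUE)
  check_scalar(frame_interval, "frame_interval", min = 0, strict = TRUE)
  if (exposure > frame_interval + 1e-12)
    stopf("exposure (%g s) must not exceed frame_interval (%g s)", exposure, frame_interval)
  if (length(image_shape) != 2L || any(image_shape < 1))
    stopf("'image_shape' must be c(height, width) in pixels")
  check_scalar(camera_offset, "camera_offset", min = 0)
  check_scalar(read_noise_sd, "read_noise_sd", min = 0)
  seed <- check_count(seed, "seed")
  structure(list(mode = mode, evanescent_depth = evanescent_depth,
                 photons_per_fluorophore = photons_per_fluorophore,
                 bleach_coefficient = bleach_coefficient,
                 psf_sigma = psf_sigma, pixel_size = pixel_size,
                 exposure = exposure, frame_interval = frame_interval,
                 image_shape = as.integer(image_shape),
                 camera_offset = camera_offset,
                 read_noise_sd = read_noise_sd,
                 expected_photons = isTRUE(expected_photons),
                 seed = as.integer(seed)),
            class = "optics_config")
}

#' Excitation weight of a membrane position
#'
#' Epifluorescence excites uniformly (weight 1). TIRF excitation decays
#' as \eqn{e^{-z/d}} with height \eqn{z = r(1 - \cos\theta)} of the
#' membrane above the coverslip, so only a thin stripe at the bottom of
#' the cell is appreciably excited.
#'
#' @param theta azimuth, radians (0 = bottom of the cell).
#' @param geometry a \code{\link{cell_geometry}}.
#' @param optics an \code{\link{optics_config}}.
#' @return excitation weights in [0, 1], same length as \code{theta}.
#' @export
excitation_weight <- function(theta, geometry, optics) {
  if (optics$mode == "epifluorescence") return(rep(1, length(theta)))
  z <- geometry$radius * (1 - cos(theta))
  exp(-z / optics$evanescent_depth)
}

# Deposit per-fluorophore expected photons into the pixel grid through a
# pixel-integrated Gaussian PSF. Returns the photon-mean image
# (stochastic = FALSE) or a Poisson realization of it per pixel-weight.
deposit_photons <- function(row, col, lambda, sigma_px, H, W, stochastic) {
  img <- matrix(0, H, W)
  n <- length(row)
  if (n == 0L) return(img)
  hw <- max(1L, ceiling(4 * sigma_px))
  k <- 2L * hw + 1L
  r0 <- round(row); c0 <- round(col)
  # pixel-integrated Gaussian weights in each dimension
  edges <- seq_len(k + 1L) - (hw + 1.5)            # window pixel edges rel. center px
  wr <- matrix(0, n, k); wc <- matrix(0, n, k)
  for (a in seq_len(k)) {
    lo_r <- r0 + edges[a] - row; hi_r <- r0 + edges[a + 1L] - row
    wr[, a] <- stats::pnorm(hi_r / sigma_px) - stats::pnorm(lo_r / sigma_px)
    lo_c <- c0 + edges[a] - col; hi_c <- c0 + edges[a + 1L] - col
    wc[, a] <- stats::pnorm(hi_c / sigma_px) - stats::pnorm(lo_c / sigma_px)
  }
  # flatten: for each fluorophore a k x k window, index order (f, a, b)
  off <- seq_len(k) - (hw + 1L)
  rr <- rep(r0, times = k * k) + rep(rep(off, each = n), times = k)
  cc <- rep(c0, times = k * k) + rep(off, each = n * k)
  ww <- rep(lambda, times = k * k) *
    rep(as.vector(wr), times = k) *
    as.vector(wc[, rep(seq_len(k), each = k)])
  keep <- rr >= 1L & rr <= H & cc >= 1L & cc <= W & ww > 0
  rr <- rr[keep]; cc <- cc[keep]; ww <- ww[keep]
  if (length(ww) == 0L) return(img)
  if (stochastic) {
    # independent Poisson per pixel-weight == multinomial thinning of a
    # Poisson total; Gaussian approximation above mean 1000 for speed
    big <- ww > 1000
    ww[!big] <- stats::rpois(sum(!big), ww[!big])
    if (any(big)) ww[big] <- pmax(0, round(stats::rnorm(sum(big), ww[big], sqrt(ww[big]))))
  }
  idx <- (cc - 1L) * H + rr
  acc <- rowsum(ww, idx)
  img[as.integer(rownames(acc))] <- acc
  img
}

# Footprint of the cell in pixel coordinates: pixels whose centers fall
# within the projected rectangle (length x diameter) of the lateral wall.
cell_footprint <- function(geometry, optics) {
  H <- optics$image_shape[1L]; W <- optics$image_shape[2L]
  px <- optics$pixel_size
  cy <- (H + 1) / 2 + geometry$center_xy[2] / px
  cx <- (W + 1) / 2 + geometry$center_xy[1] / px
  phi <- geometry$orientation
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  dx <- (cols - cx) * px
  dy <- (rows - cy) * px
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  abs(u) <= geometry$length / 2 & abs(v) <= geometry$radius
}

#' Render a trajectory into a synthetic image stack
#'
#' Per rendered frame, each not-yet-bleached fluorophore first bleaches
#' with probability \eqn{1 - e^{-\beta w \cdot exposure}} (w = excitation
#' weight at its current azimuth); survivors emit Poisson-distributed
#' photons with mean \code{photons_per_fluorophore * w} at their
#' projected image position (axial coordinate along the cell axis,
#' lateral offset \eqn{r \sin\theta}); the photon image is blurred by a
#' pixel-integrated Gaussian PSF and the camera adds a constant offset
#' and Gaussian read noise. Bleach states are written back into the
#' returned trajectory. A label mask marks the cell's projected
#' footprint.
#'
#' Rendered frames are taken from the trajectory every
#' \code{frame_interval / dt} snapshots, which must be a whole number.
#'
#' @param traj a \code{\link{simulate_membrane_dynamics}} trajectory.
#' @param optics an \code{\link{optics_config}}.
#' @return list with components \code{stack} (an \code{image_stack}),
#'   \code{mask} (integer label matrix) and \code{trajectory} (the input
#'   with bleach states filled in).
#' @export
render_stack <- function(traj, optics) {
  if (!inherits(traj, "tirf_trajectory")) stopf("'traj' must be a tirf_trajectory")
  if (!inherits(optics, "optics_config")) stopf("'optics' must be an optics_config")
  g <- traj$config$geometry
  dt <- traj$config$dt
  stride <- optics$frame_interval / dt
  if (abs(stride - round(stride)) > 1e-9)
    stopf("optics frame_interval (%g s) is not a multiple of the trajectory dt (%g s)",
          optics$frame_interval, dt)
  stride <- as.integer(round(stride))
  frame_rows <- seq(1L, nrow(traj$s), by = stride)
  Tn <- length(frame_rows)
  H <- optics$image_shape[1L]; W <- optics$image_shape[2L]
  px <- optics$pixel_size
  sigma_px <- optics$psf_sigma / px
  n <- ncol(traj$s)
  expected <- optics$expected_photons

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(optics$seed)

  cy <- (H + 1) / 2 + g$center_xy[2] / px
  cx <- (W + 1) / 2 + g$center_xy[1] / px
  phi <- g$orientation

  alive <- rep(TRUE, n)            # binary fates (stochastic mode)
  survival <- rep(1, n)            # continuous survival (expected mode)
  frames <- array(0, dim = c(H, W, Tn))
  bleach_beta <- optics$bleach_coefficient * optics$exposure

  for (f in seq_len(Tn)) {
    i <- frame_rows[f]
    th <- traj$theta[i, ]
    w <- excitation_weight(th, g, optics)
    if (n > 0L) {
      p_surv <- exp(-bleach_beta * w)
      if (expected) {
        survival <- survival * p_surv
        lam_scale <- survival
        act <- rep(TRUE, n)
      } else {
        u <- stats::runif(n)
        alive <- alive & (u < p_surv)
        lam_scale <- as.numeric(alive)
        act <- alive
      }
      traj$bleached[i, ] <- if (expected) survival < .Machine$double.eps else !alive
      sel <- which(act & lam_scale > 0 & w > 0)
    } else sel <- integer(0)
    if (length(sel) > 0L) {
      u <- traj$s[i, sel] - g$length / 2
      v <- g$radius * sin(th[sel])
      col <- cx + (u * cos(phi) - v * sin(phi)) / px
      row <- cy + (u * sin(phi) + v * cos(phi)) / px
      lam <- optics$photons_per_fluorophore * w[sel] * lam_scale[sel]
      frames[, , f] <- deposit_photons(row, col, lam, sigma_px, H, W,
                                       stochastic = !expected)
    }
    frames[, , f] <- frames[, , f] + optics$camera_offset
    if (!expected) {
      if (optics$read_noise_sd > 0)
        frames[, , f] <- frames[, , f] +
          stats::rnorm(H * W, 0, optics$read_noise_sd)
      frames[, , f] <- pmin(pmax(round(frames[, , f]), 0), 65535)
    }
    # propagate bleach state to trajectory snapshots up to the next
    # rendered frame (or the end of the trajectory)
    upto <- if (f < Tn) frame_rows[f + 1L] - 1L else nrow(traj$s)
    if (upto > i) for (j in seq(i + 1L, upto))
      traj$bleached[j, ] <- traj$bleached[i, ]
  }

  mask <- matrix(0L, H, W)
  mask[cell_footprint(g, optics)] <- 1L
  stack <- image_stack(frames, pixel_size = px,
                       frame_interval = optics$frame_interval)
  list(stack = stack, mask = mask, trajectory = traj)
}

#' Construct an image stack container
#'
#' @param frames numeric array, height x width x time (counts).
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between frames.
#' @return an object of class \code{image_stack}.
#' @export
image_stack <- function(frames, pixel_size, frame_interval) {
  if (length(dim(frames)) == 2L) frames <- array(frames, dim = c(dim(frames), 1L))
  if (length(dim(frames)) != 3L) stopf("'frames' must be an H x W x T array")
  if (any(frames < 0)) stopf("image intensities must be non-negative")
  check_scalar(pixel_size, "pixel_size", min = 0, strict = TRUE)
  check_scalar(frame_interval, "frame_interval", min = 0, strict = TRUE)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d frames of %d x %d px (%.3g um/px, %.4g s/frame)\n",
              d[3L], d[1L], d[2L], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack an \code{image_stack}.
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3L]
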