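#' Build a kymogram along a cell axis
#'
#' Each frame of the stack is scanned along the chosen principal axis
#' (long or short, determined from the mask's second moments) through
#' the cell centroid, averaging across \code{band_width} perpendicular
#' pixels; the scans are stacked in time order. Directed motion appears
#' as tilted ridges, random motion as uncorrelated speckle.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param mask integer label matrix.
#' @param cell_id which cell to scan.
#' @param axis \code{"long"} or \code{"short"}.
#' @param band_width perpendicular averaging width, pixels (odd).
#' @param trim pixels dropped from each end of the scan. The outermost
#'   columns carry the static intensity ramp of the cell edge (PSF
#'   roll-off of the projected geometry), which swamps the dynamics; the
#'   trim is clamped so at least 8 positions remain.
#' @return a \code{kymogram}: matrix (rows = frames, columns =
#'   positions), with axis, frame_interval (s) and position_step (um).
#' @export
build_kymogram <- function(stack, mask, cell_id, axis = c("long", "short"),
                           band_width = 3L, trim = 3L) {
  axis <- match.arg(axis)
  if (!inherits(stack, "image_stack")) stopf("'stack' must be an image_stack")
  if (!all(dim(stack$frames)[1:2] == dim(mask)))
    stopf("stack frames and mask must have the same shape")
  ax <- mask_axes(mask, cell_id)
  e <- if (axis == "long") ax$long else ax$short
  ep <- if (axis == "long") ax$short else ax$long
  half <- if (axis == "long") ax$half_long else ax$half_short
  trim <- min(check_count(trim, "trim"), max(0, floor((2 * half + 1 - 8) / 2)))
  half <- half - trim
  u <- seq(-half, half, by = 1)
  b <- seq_len(band_width) - (band_width + 1) / 2
  H <- dim(stack$frames)[1L]; W <- dim(stack$frames)[2L]
  pr <- outer(u * e[1L], b * ep[1L], "+") + ax$centroid[1L]
  pc <- outer(u * e[2L], b * ep[2L], "+") + ax$centroid[2L]
  if (any(pr < 1 | pr > H | pc < 1 | pc > W))
    warnf("scan band extends beyond the image; samples clipped to the border")
  Tn <- n_frames(stack)
  mat <- matrix(0, Tn, length(u))
  for (f in seq_len(Tn)) {
    vals <- bilinear(stack$frames[, , f], as.vector(pr), as.vector(pc))
    mat[f, ] <- rowMeans(matrix(vals, length(u), band_width))
  }
  structure(list(matrix = mat, axis = axis,
                 frame_interval = stack$frame_interval,
                 position_step = stack$pixel_size),
            class = "kymogram")
}

#' @export
print.kymogram <- function(x, ...) {
  cat(sprintf("kymogram (%s axis): %d frames x %d positions (%.4g s, %.3g um steps)\n",
              x$axis, nrow(x$matrix), ncol(x$matrix),
              x$frame_interval, x$position_step))
  invisible(x)
}

#' Temporal persistence of a kymogram
#'
#' Mean Pearson correlation between mean-centered kymogram rows at times
#' t and t + lag, over all valid row pairs. A frozen intensity pattern
#' (fixed cells) scores near 1; rapidly redistributing fluorescence
#' (live cells) decorrelates towards 0. Zero-variance rows are excluded.
#'
#' @param kym a \code{kymogram}.
#' @param lag time lag in seconds; must be a multiple of the frame
#'   interval.
#' @return a \code{persistence_result}: lag (s), score (mean Pearson r),
#'   n_pairs, and the per-pair correlations.
#' @export
persistence_score <- function(kym, lag) {
  if (!inherits(kym, "kymogram")) stopf("'kym' must be a kymogram")
  k <- lag / kym$frame_interval
  if (abs(k - round(k)) > 1e-6)
    stopf("lag (%g s) must be a multiple of the frame interval (%g s)",
          lag, kym$frame_interval)
  k <- as.integer(round(k))
  m <- kym$matrix
  Tn <- nrow(m)
  if (Tn - k < 2L) stopf("fewer than 2 usable row pairs at lag %g s", lag)
  sds <- apply(m, 1L, stats::sd)
  usable <- sds > 0
  pairs <- which(usable[seq_len(Tn - k)] & usable[seq_len(Tn - k) + k])
  if (length(pairs) == 0L) stopf("all row pairs have zero variance")
  r <- vapply(pairs, function(t) stats::cor(m[t, ], m[t + k, ]), numeric(1))
  structure(list(lag = lag, score = mean(r), n_pairs = length(r),
                 correlations = r),
            class = "persistence_result")
}

#' Persistence as a function of lag
#'
#' @param kym a \code{kymogram}.
#' @param lags lags in seconds (default: 1..10 frame intervals).
#' @return data.frame with columns \code{lag} and \code{score}.
#' @export
persistence_curve <- function(kym, lags = kym$frame_interval * 1:10) {
  data.frame(lag = lags,
             score = vapply(lags, function(l) persistence_score(kym, l)$score,
                            numeric(1)))
}

#' Ridge slope of a kymogram by column-argmax regression
#'
#' For each time row the position of maximum intensity is found and a
#' line is fitted through (time, argmax position); the slope estimates
#' directed transport velocity in pixels per frame (0 for purely random
#' motion).
#'
#' @param kym a \code{kymogram}.
#' @return slope in pixels per frame.
#' @export
ridge_slope <- function(kym) {
  pos <- apply(kym$matrix, 1L, which.max)
  t <- seq_along(pos)
  unname(stats::coef(stats::lm(pos ~ t))[2L])
}
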