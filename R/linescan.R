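#' Extract membrane-perimeter line scans from a labelled image
#'
#' For each labelled cell the two lateral membrane traces (left and
#' right of the long axis) are sampled at 1-pixel spacing along the
#' membrane midline with bilinear sub-pixel interpolation. The midline
#' is taken at the cell's lateral half-extent minus
#' \code{membrane_halfwidth} pixels (the mask contour eroded by half the
#' expected membrane width). A side is excluded when another cell's mask
#' lies within \code{adjacency_gap} of that side; cells touching the
#' image border are skipped with a warning.
#'
#' @param image numeric matrix (one frame, counts).
#' @param mask integer label matrix, 0 = background, k = cell k.
#' @param pixel_size micrometres per pixel.
#' @param adjacency_gap exclusion distance to neighbouring cells,
#'   micrometres (default 3 pixels).
#' @param membrane_halfwidth half the expected membrane width, pixels.
#' @param background \code{NULL} (raw intensities), a number to
#'   subtract, or \code{"auto"} (median of background pixels).
#' @return list of \code{line_scan} objects (cell_id, side,
#'   arc_positions in micrometres, intensities, background_subtracted).
#' @export
extract_perimeter_scans <- function(image, mask, pixel_size,
                                    adjacency_gap = 3 * pixel_size,
                                    membrane_halfwidth = 1,
                                    background = NULL) {
  if (!all(dim(image) == dim(mask)))
    stopf("image and mask must have the same shape")
  ids <- sort(setdiff(unique(as.vector(mask)), 0L))
  if (length(ids) == 0L) return(list())
  bg <- 0
  bg_flag <- FALSE
  if (!is.null(background)) {
    bg <- if (identical(background, "auto")) {
      stats::median(image[mask == 0L])
    } else {
      check_scalar(background, "background")
      background
    }
    bg_flag <- TRUE
  }
  H <- nrow(mask); W <- ncol(mask)
  gap_px <- adjacency_gap / pixel_size
  scans <- list()
  for (k in ids) {
    idx <- which(mask == k, arr.ind = TRUE)
    if (any(idx[, 1L] == 1L | idx[, 1L] == H | idx[, 2L] == 1L | idx[, 2L] == W)) {
      warnf("cell %d touches the image border; skipped", k)
      next
    }
    ax <- mask_axes(mask, k)
    offset <- ax$half_short - membrane_halfwidth
    if (offset <= 0) {
      warnf("cell %d too thin for a membrane midline; skipped", k)
      next
    }
    u_span <- ax$half_long - 1
    if (u_span < 0) next
    u <- seq(-u_span, u_span, by = 1)
    other <- which(mask != 0L & mask != k, arr.ind = TRUE)
    for (side in c("left", "right")) {
      sgn <- if (side == "left") -1 else 1
      pr <- ax$centroid[1L] + u * ax$long[1L] + sgn * offset * ax$short[1L]
      pc <- ax$centroid[2L] + u * ax$long[2L] + sgn * offset * ax$short[2L]
      if (length(u) < 10L) next
      if (nrow(other) > 0L) {
        # adjacency exclusion, measured from the mask edge of this side
        # (not the eroded midline): min distance from the edge line to
        # any other-cell pixel, with a bounding-box prefilter
        er <- ax$centroid[1L] + u * ax$long[1L] + sgn * ax$half_short * ax$short[1L]
        ec <- ax$centroid[2L] + u * ax$long[2L] + sgn * ax$half_short * ax$short[2L]
        near <- other[, 1L] >= min(er) - gap_px - 1 & other[, 1L] <= max(er) + gap_px + 1 &
                other[, 2L] >= min(ec) - gap_px - 1 & other[, 2L] <= max(ec) + gap_px + 1
        if (any(near)) {
          o <- other[near, , drop = FALSE]
          d2 <- outer(er, o[, 1L], "-")^2 + outer(ec, o[, 2L], "-")^2
          if (min(d2) <= gap_px^2) next
        }
      }
      vals <- bilinear(image, pr, pc) - bg
      scans[[length(scans) + 1L]] <- structure(
        list(cell_id = k, side = side,
             arc_positions = (u - u[1L]) * pixel_size,
             intensities = vals,
             background_subtracted = bg_flag),
        class = "line_scan")
    }
  }
  scans
}

#' Per-scan intensity statistics
#'
#' Mean and sample variance (n - 1 denominator) of the scan's
#' intensities, the quantities plotted per line scan in field-level
#' intensity/variance analyses of membrane foci.
#'
#' @param scan a \code{line_scan}.
#' @return a \code{scan_stats} object: cell_id, side, mean_intensity,
#'   variance, n_pixels.
#' @export
scan_stats <- function(scan) {
  if (!inherits(scan, "line_scan")) stopf("'scan' must be a line_scan")
  x <- scan$intensities
  if (length(x) < 2L) stopf("scan has fewer than 2 samples")
  structure(list(cell_id = scan$cell_id, side = scan$side,
                 mean_intensity = mean(x), variance = stats::var(x),
                 n_pixels = length(x)),
            class = "scan_stats")
}

#' Field-level summary of line-scan statistics
#'
#' Medians (lower-median convention for even n) of the per-scan mean
#' intensity and variance over all scans of a field, with counts.
#'
#' @param stats list of \code{scan_stats}.
#' @return a \code{field_summary}: n_cells, n_scans,
#'   median_mean_intensity, median_variance and the per-scan table.
#' @export
field_summary <- function(stats) {
  if (length(stats) == 0L) stopf("no scan statistics supplied")
  tab <- do.call(rbind, lapply(stats, function(s)
    data.frame(cell_id = s$cell_id, side = s$side,
               mean_intensity = s$mean_intensity, variance = s$variance,
               n_pixels = s$n_pixels)))
  structure(list(n_cells = length(unique(tab$cell_id)),
                 n_scans = nrow(tab),
                 median_mean_intensity = lower_median(tab$mean_intensity),
                 median_variance = lower_median(tab$variance),
                 scans = tab),
            class = "field_summary")
}

#' @export
print.field_summary <- function(x, ...) {
  cat(sprintf("field_summary: %d scans from %d cells\n", x$n_scans, x$n_cells))
  cat(sprintf("  median mean intensity: %.2f counts\n", x$median_mean_intensity))
  cat(sprintf("  median variance:       %.2f counts^2\n", x$median_variance))
  invisible(x)
}
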