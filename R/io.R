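# Plain-text serialization. The imaging stacks this package emulates
# would normally travel as multi-frame 16-bit TIFFs; no TIFF codec is
# available in the supported dependency set, so stacks and masks use a
# TSV-based container with a JSON metadata header line. The schema
# carries the same metadata (pixel size in um, frame interval in s).

#' Write an image stack to a text container
#'
#' Line 1 is a JSON header (\code{dim}, \code{pixel_size},
#' \code{frame_interval}); each frame follows as a tab-separated H x W
#' matrix, frames separated by blank lines.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param path output file.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "image_stack")) stopf("'stack' must be an image_stack")
  d <- dim(stack$frames)
  hdr <- jsonlite::toJSON(list(type = "image_stack", dim = d,
                               pixel_size = stack$pixel_size,
                               frame_interval = stack$frame_interval),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  for (f in seq_len(d[3L])) {
    writeLines(apply(stack$frames[, , f], 1L, paste, collapse = "\t"), con)
    if (f < d[3L]) writeLines("", con)
  }
  invisible(path)
}

#' Read an image stack written by \code{\link{write_stack}}
#' @param path input file.
#' @return an \code{\link{image_stack}}.
#' @export
read_stack <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1L])
  d <- as.integer(hdr$dim)
  body <- lines[-1L]
  body <- body[body != ""]
  vals <- scan(text = body, quiet = TRUE)
  frames <- array(0, dim = d)
  per <- d[1L] * d[2L]
  for (f in seq_len(d[3L])) {
    block <- vals[(f - 1L) * per + seq_len(per)]
    frames[, , f] <- matrix(block, d[1L], d[2L], byrow = TRUE)
  }
  image_stack(frames, pixel_size = hdr$pixel_size,
              frame_interval = hdr$frame_interval)
}

#' Write a label mask as TSV
#' @param mask integer label matrix.
#' @param path output file.
#' @export
write_mask <- function(mask, path) {
  utils::write.table(mask, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a label mask written by \code{\link{write_mask}}
#' @param path input file.
#' @return integer matrix.
#' @export
read_mask <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                              colClasses = "integer"))
}

#' Write a trajectory as TSV with a JSON config sidecar
#'
#' Long-format table (frame, particle, s, theta, bound_site, bleached);
#' the simulation configuration is written next to it as
#' \code{<path>.json}.
#'
#' @param traj a \code{tirf_trajectory}.
#' @param path output TSV file.
#' @export
write_trajectory <- function(traj, path) {
  nf <- nrow(traj$s); np <- ncol(traj$s)
  df <- data.frame(frame = rep(seq_len(nf) - 1L, np),
                   particle = rep(seq_len(np), each = nf),
                   s = as.vector(traj$s),
                   theta = as.vector(traj$theta),
                   bound_site = as.vector(traj$bound_site),
                   bleached = as.integer(as.vector(traj$bleached)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- traj$config
  side <- list(config = unclass_config(cfg),
               site_s = traj$site_s, site_theta = traj$site_theta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

unclass_config <- function(cfg) {
  x <- unclass(cfg)
  x$geometry <- unclass(x$geometry)
  x
}

#' Read a trajectory written by \code{\link{write_trajectory}}
#' @param path TSV file (expects \code{<path>.json} sidecar).
#' @return a \code{tirf_trajectory}.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  cf <- side$config
  cfg <- sim_config(D_free = cf$D_free, D_bound = cf$D_bound,
                    n_particles = cf$n_particles, n_sites = cf$n_sites,
                    site_capacity = cf$site_capacity,
                    capture_radius = cf$capture_radius,
                    k_on = cf$k_on, k_off = cf$k_off, dt = cf$dt,
                    n_steps = cf$n_steps, seed = cf$seed,
                    geometry = cell_geometry(cf$geometry$length,
                                             cf$geometry$radius,
                                             cf$geometry$center_xy,
                                             cf$geometry$orientation))
  nf <- max(df$frame) + 1L; np <- max(df$particle)
  o <- order(df$particle, df$frame)
  df <- df[o, ]
  structure(list(s = matrix(df$s, nf, np),
                 theta = matrix(df$theta, nf, np),
                 bound_site = matrix(as.integer(df$bound_site), nf, np),
                 bleached = matrix(df$bleached != 0L, nf, np),
                 site_s = as.numeric(side$site_s),
                 site_theta = as.numeric(side$site_theta),
                 config = cfg),
            class = "tirf_trajectory")
}

#' Read a simulation config from JSON
#' @param path JSON file with sim_config fields (geometry nested).
#' @return a \code{\link{sim_config}}.
#' @export
read_sim_config <- function(path) {
  cf <- jsonlite::fromJSON(path)
  geo <- if (!is.null(cf$geometry))
    cell_geometry(cf$geometry$length %||% 3, cf$geometry$radius %||% 0.4,
                  cf$geometry$center_xy %||% c(0, 0),
                  cf$geometry$orientation %||% 0)
  else cell_geometry()
  args <- cf[setdiff(names(cf), "geometry")]
  do.call(sim_config, c(args, list(geometry = geo)))
}

#' Read an optics config from JSON
#' @param path JSON file with optics_config fields.
#' @return an \code{\link{optics_config}}.
#' @export
read_optics_config <- function(path) {
  do.call(optics_config, jsonlite::fromJSON(path))
}
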