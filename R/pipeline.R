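#' Canonical condition presets
#'
#' Encodes the condition-to-mechanism mapping of the emulated
#' experiments as simulation parameters (never hard-wired into analysis
#' code):
#' \itemize{
#'   \item \code{untreated}: substrate sites present (clustering on),
#'     transient binding calibrated to a steady-state bound fraction
#'     near 0.5.
#'   \item \code{rifampicin}: substrate depleted, \code{n_sites = 0};
#'     everything else identical to \code{untreated}.
#'   \item \code{fixed}: chemically fixed cell; all dynamics frozen
#'     (D = 0, no binding exchange).
#'   \item \code{control_protein}: uniformly distributed membrane
#'     protein with no clustering and condition-independent diffusion
#'     (specificity control).
#' }
#'
#' @param name preset name.
#' @param D_free free diffusion coefficient, um^2/s.
#' @param n_particles fluorophores per cell (copy numbers of the
#'   emulated proteins are in the thousands).
#' @param geometry a \code{\link{cell_geometry}}.
#' @return a list of \code{\link{sim_config}} arguments (seed, dt and
#'   n_steps are filled in by the experiment driver).
#' @export
condition_preset <- function(name = c("untreated", "rifampicin", "fixed",
                                      "control_protein"),
                             D_free = 0.05, n_particles = 2000,
                             geometry = cell_geometry()) {
  name <- match.arg(name)
  base <- list(D_free = D_free, D_bound = 0, n_particles = n_particles,
               n_sites = 0, site_capacity = 40, capture_radius = 0.15,
               k_on = 0, k_off = 0, geometry = geometry)
  switch(name,
    untreated = utils::modifyList(base, list(n_sites = 40, k_on = 4, k_off = 1)),
    rifampicin = base,
    fixed = utils::modifyList(base, list(D_free = 0)),
    control_protein = base)
}

#' Assemble an experiment configuration
#'
#' @param conditions named list; each element a list of
#'   \code{\link{sim_config}} arguments (see
#'   \code{\link{condition_preset}}).
#' @param n_cells simulated cells per condition.
#' @param analyses subset of \code{c("linescan", "kymo", "bleach")}.
#' @param out_dir output directory (created if needed); \code{NULL} for
#'   in-memory results only.
#' @param seed master seed; every stage seed is derived from it.
#' @param n_bleach_frames frames of the photobleaching acquisition
#'   (0.1 s interval). The default 40-frame (4 s) window ends before the
#'   fastest-diffusing pool is fully depleted, where the
#'   diffusion-to-bleach-rate mapping is monotone.
#' @param burn_in_s simulated seconds discarded before imaging starts,
#'   letting site binding reach steady state.
#' @return an \code{experiment_config}.
#' @export
experiment_config <- function(conditions, n_cells = 6L,
                              analyses = c("linescan", "kymo", "bleach"),
                              out_dir = NULL, seed = 1L,
                              n_bleach_frames = 40L, burn_in_s = 2) {
  if (is.null(names(conditions)) || anyDuplicated(names(conditions)))
    stopf("'conditions' must be a uniquely named list")
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(list(conditions = conditions,
                 n_cells = check_count(n_cells, "n_cells", 1L),
                 analyses = analyses, out_dir = out_dir,
                 seed = check_count(seed, "seed"),
                 n_bleach_frames = check_count(n_bleach_frames,
                                               "n_bleach_frames", 5L),
                 burn_in_s = check_scalar(burn_in_s, "burn_in_s", min = 0)),
            class = "experiment_config")
}

# Default optics for each acquisition the pipeline emulates.
bleach_optics <- function(seed, shape = c(24L, 44L))
  optics_config(mode = "tirf", evanescent_depth = 0.1,
                photons_per_fluorophore = 100, bleach_coefficient = 1,
                psf_sigma = 0.1, pixel_size = 0.1, exposure = 0.1,
                frame_interval = 0.1, image_shape = shape,
                camera_offset = 100, read_noise_sd = 2, seed = seed)

kymo_optics <- function(seed, shape = c(24L, 44L))
  optics_config(mode = "tirf", evanescent_depth = 0.1,
                photons_per_fluorophore = 400, bleach_coefficient = 0.05,
                psf_sigma = 0.1, pixel_size = 0.1, exposure = 1 / 30,
                frame_interval = 1 / 30, image_shape = shape,
                camera_offset = 100, read_noise_sd = 2, seed = seed)

epi_optics <- function(seed, frame_interval, shape = c(24L, 44L))
  optics_config(mode = "epifluorescence",
                photons_per_fluorophore = 30, bleach_coefficient = 0,
                psf_sigma = 0.1, pixel_size = 0.1,
                exposure = min(0.1, frame_interval),
                frame_interval = frame_interval, image_shape = shape,
                camera_offset = 100, read_noise_sd = 2, seed = seed)

#' Simulate a field of cells and render one labelled mosaic image
#'
#' Simulates \code{n_cells} independent cells from a common parameter
#' set (per-cell seeds derived from \code{seed}), renders each cell's
#' snapshot at \code{t_snapshot} in epifluorescence mode, and tiles the
#' renders into one field image with a matching label mask (labels
#' 1..n_cells).
#'
#' @param sim_args list of \code{\link{sim_config}} arguments (without
#'   dt/n_steps/seed).
#' @param n_cells number of cells.
#' @param seed master seed for the field.
#' @param t_snapshot simulated time of the rendered snapshot, seconds
#'   (allows binding to equilibrate first).
#' @param dt simulation step, seconds.
#' @return list: image (matrix), mask, trajectories.
#' @export
simulate_field <- function(sim_args, n_cells = 30L, seed = 1L,
                           t_snapshot = 2, dt = 0.1) {
  tile <- c(24L, 44L)
  n_steps <- as.integer(round(t_snapshot / dt))
  ncol_t <- ceiling(sqrt(n_cells))
  nrow_t <- ceiling(n_cells / ncol_t)
  image <- matrix(0, nrow_t * tile[1L], ncol_t * tile[2L])
  mask <- matrix(0L, nrow_t * tile[1L], ncol_t * tile[2L])
  trajs <- vector("list", n_cells)
  for (j in seq_len(n_cells)) {
    cfg <- do.call(sim_config,
                   c(sim_args, list(dt = dt, n_steps = n_steps,
                                    seed = derive_seed(seed, j))))
    trajs[[j]] <- simulate_membrane_dynamics(cfg)
    opt <- epi_optics(derive_seed(seed, 10000 + j),
                      frame_interval = t_snapshot, shape = tile)
    rd <- render_stack(trajs[[j]], opt)
    last <- n_frames(rd$stack)
    ri <- ((j - 1L) %/% ncol_t) * tile[1L] + seq_len(tile[1L])
    ci <- ((j - 1L) %% ncol_t) * tile[2L] + seq_len(tile[2L])
    image[ri, ci] <- rd$stack$frames[, , last]
    mask[ri, ci] <- ifelse(rd$mask > 0L, j, 0L)
  }
  list(image = image, mask = mask, trajectories = trajs)
}

#' Run an end-to-end simulated imaging experiment
#'
#' For every condition: simulate cells, render TIRF bleaching stacks and
#' an epifluorescence field image, then run the requested analyses
#' (perimeter line scans with field medians, kymogram + persistence for
#' the first cell, global two-phase bleach fit across conditions) and a
#' cross-condition comparison. Fully reproducible from the master seed;
#' when \code{out_dir} is set, all tabular outputs are written as
#' CSV/TSV plus a manifest JSON.
#'
#' @param cfg an \code{\link{experiment_config}}.
#' @return result bundle: per-condition analyses, the global bleach fit,
#'   and the comparison table.
#' @export
run_experiment <- function(cfg) {
  if (!inherits(cfg, "experiment_config"))
    stopf("'cfg' must be an experiment_config")
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  all_traces <- list()
  manifest <- list(seed = cfg$seed, conditions = names(cfg$conditions),
                   analyses = cfg$analyses, files = character(0))
  for (ic in seq_along(cfg$conditions)) {
    cname <- names(cfg$conditions)[ic]
    sim_args <- cfg$conditions[[ic]]
    cres <- list()
    stage <- function(what, expr) {
      t0 <- proc.time()[["elapsed"]]
      r <- tryCatch(expr, error = function(e)
        stopf("stage '%s' failed for condition '%s': %s", what, cname,
              conditionMessage(e)))
      message(sprintf("[%s/%s] %.1fs", cname, what,
                      proc.time()[["elapsed"]] - t0))
      r
    }

    if ("linescan" %in% cfg$analyses) {
      cres$linescan <- stage("linescan", {
        fld <- simulate_field(sim_args, n_cells = cfg$n_cells,
                              seed = derive_seed(cfg$seed, 100 * ic))
        scans <- extract_perimeter_scans(fld$image, fld$mask,
                                         pixel_size = 0.1,
                                         background = "auto")
        field_summary(lapply(scans, scan_stats))
      })
    }

    if ("kymo" %in% cfg$analyses) {
      cres$kymo <- stage("kymo", {
        scfg <- do.call(sim_config,
                        c(sim_args, list(dt = 1 / 30, n_steps = 90L,
                                         seed = derive_seed(cfg$seed, 100 * ic + 1))))
        traj <- simulate_membrane_dynamics(scfg)
        rd <- render_stack(traj, kymo_optics(derive_seed(cfg$seed, 100 * ic + 2)))
        kym <- build_kymogram(rd$stack, rd$mask, 1L, axis = "long")
        list(kymogram = kym, persistence = persistence_score(kym, lag = 1))
      })
    }

    if ("bleach" %in% cfg$analyses) {
      cres$traces <- stage("bleach", {
        burn <- as.integer(round(cfg$burn_in_s / 0.1))
        lapply(seq_len(cfg$n_cells), function(j) {
          scfg <- do.call(sim_config,
                         c(sim_args, list(dt = 0.1,
                                          n_steps = burn + cfg$n_bleach_frames - 1L,
                                          seed = derive_seed(cfg$seed, 100 * ic + 10 + j))))
          traj <- trim_trajectory(simulate_membrane_dynamics(scfg), burn + 1L)
          rd <- render_stack(traj,
                             bleach_optics(derive_seed(cfg$seed, 100 * ic + 50 + j)))
          cell_trace(rd$stack, rd$mask, 1L, condition = cname)
        })
      })
      all_traces <- c(all_traces, cres$traces)
    }
    results[[cname]] <- cres
  }

  fit <- NULL
  comparison <- NULL
  if ("bleach" %in% cfg$analyses) {
    fit <- fit_photobleach_global(all_traces)
    if (length(cfg$conditions) >= 2L) comparison <- compare_conditions(fit)
  }

  if (!is.null(out_dir)) {
    wr <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      manifest$files <<- c(manifest$files, name)
    }
    for (cname in names(results)) {
      r <- results[[cname]]
      if (!is.null(r$linescan))
        wr(r$linescan$scans, sprintf("%s_linescans.csv", cname))
      if (!is.null(r$kymo)) {
        p <- file.path(out_dir, sprintf("%s_kymogram.tsv", cname))
        utils::write.table(r$kymo$kymogram$matrix, p, sep = "\t",
                           row.names = FALSE, col.names = FALSE)
        manifest$files <- c(manifest$files, basename(p))
      }
      if (!is.null(r$traces)) {
        df <- do.call(rbind, lapply(r$traces, function(tr)
          data.frame(condition = tr$condition, cell_id = tr$cell_id,
                     time = tr$times, intensity = tr$normalized_intensity)))
        wr(df, sprintf("%s_traces.csv", cname))
      }
    }
    if (!is.null(fit)) wr(fit$table, "bleach_fits.csv")
    if (!is.null(comparison)) wr(as.data.frame(comparison), "comparison.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(conditions = results, bleach_fit = fit, comparison = comparison,
       manifest = manifest)
}
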