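test_that("excitation weight follows the evanescent-field profile", {
  g <- cell_geometry(radius = 0.4)
  tirf <- optics_config(mode = "tirf", evanescent_depth = 0.1)
  epi <- optics_config(mode = "epifluorescence")
  expect_equal(excitation_weight(0, g, tirf), 1)
  expect_equal(excitation_weight(pi, g, tirf), exp(-8))
  expect_equal(excitation_weight(seq(0, 2 * pi, length.out = 7), g, epi),
               rep(1, 7))
  # symmetric about the bottom of the cell
  expect_equal(excitation_weight(0.7, g, tirf),
               excitation_weight(2 * pi - 0.7, g, tirf))
})

test_that("background-only render stays at the camera offset", {
  cfg <- sim_config(n_particles = 0, n_steps = 9, seed = 1)
  traj <- simulate_membrane_dynamics(cfg)
  opt <- optics_config(camera_offset = 100, read_noise_sd = 2, seed = 3)
  rd <- render_stack(traj, opt)
  m <- mean(rd$stack$frames)
  se <- 2 / sqrt(length(rd$stack$frames))
  expect_lt(abs(m - 100), 3 * se + 0.2)  # rounding adds < 0.2 counts
})

test_that("without bleaching expected-photon intensity is conserved", {
  traj <- frozen_trajectory(s = c(1.2, 1.8, 1.5),
                            theta = c(0.3, 1.0, 5.5), n_frames = 8)
  opt <- oracle_optics(bleach_coefficient = 0)
  rd <- render_stack(traj, opt)
  totals <- apply(rd$stack$frames, 3, sum)
  expect_equal(totals, rep(totals[1], 8), tolerance = 1e-12)
})

test_that("top/bottom fluorophore intensity ratio matches the closed form", {
  g <- cell_geometry(radius = 0.4)
  opt <- oracle_optics(evanescent_depth = 0.1, bleach_coefficient = 0,
                       image_shape = c(32L, 48L))
  bottom <- render_stack(frozen_trajectory(1.5, 0, geometry = g), opt)
  top <- render_stack(frozen_trajectory(1.5, pi, geometry = g), opt)
  ratio <- sum(top$stack$frames[, , 1]) / sum(bottom$stack$frames[, , 1])
  expect_equal(ratio, exp(-2 * 0.4 / 0.1), tolerance = 1e-6)
})

test_that("rendering is deterministic for a fixed seed", {
  cfg <- sim_config(n_particles = 60, n_steps = 5, seed = 2)
  traj <- simulate_membrane_dynamics(cfg)
  opt <- optics_config(bleach_coefficient = 1, seed = 9)
  r1 <- render_stack(traj, opt)
  r2 <- render_stack(traj, opt)
  expect_identical(r1$stack$frames, r2$stack$frames)
})

test_that("bleached count is non-decreasing and intensity decays", {
  cfg <- sim_config(D_free = 0.01, n_particles = 150, n_steps = 29, seed = 5)
  traj <- simulate_membrane_dynamics(cfg)
  opt <- optics_config(bleach_coefficient = 2, seed = 6)
  rd <- render_stack(traj, opt)
  nb <- rowSums(rd$trajectory$bleached)
  expect_true(all(diff(nb) >= 0))
  expect_gt(nb[30], 0)
  # expected-photon decay is strictly decreasing when something bleaches
  rd2 <- render_stack(traj, oracle_optics(bleach_coefficient = 2))
  totals <- apply(rd2$stack$frames, 3, sum)
  expect_true(all(diff(totals) < 0))
})

test_that("TIRF bleach decay slows with diffusion; epifluorescence is blind to it", {
  mk <- function(D, mode) {
    cfg <- sim_config(D_free = D, n_particles = 600, n_sites = 0, dt = 0.1,
                      n_steps = 29, seed = 3)
    traj <- simulate_membrane_dynamics(cfg)
    opt <- oracle_optics(mode = mode, bleach_coefficient = 1,
                         evanescent_depth = 0.1)
    tot <- apply(render_stack(traj, opt)$stack$frames, 3, sum)
    tot / tot[1]
  }
  slow <- mk(0.002, "tirf"); mid <- mk(0.02, "tirf"); fast <- mk(0.2, "tirf")
  expect_gt(fast[30], mid[30])
  expect_gt(mid[30], slow[30])
  # epifluorescence: survival is exp(-beta*t) independent of D (up to
  # PSF-window truncation at the image edge, < 0.1%)
  e1 <- mk(0.002, "epifluorescence"); e2 <- mk(0.2, "epifluorescence")
  expect_equal(e1, e2, tolerance = 1e-3)
  expect_equal(unname(e1[30]), exp(-1 * 0.1 * 29), tolerance = 1e-3)
})

test_that("render validates input consistency", {
  cfg <- sim_config(n_particles = 5, n_steps = 4, dt = 0.07, seed = 1)
  traj <- simulate_membrane_dynamics(cfg)
  expect_error(render_stack(traj, optics_config(frame_interval = 0.1,
                                                exposure = 0.1)),
               "multiple")
  expect_error(optics_config(exposure = 0.2, frame_interval = 0.1),
               "exposure")
})
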