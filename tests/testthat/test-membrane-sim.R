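test_that("config validation rejects bad parameters", {
  expect_error(sim_config(D_free = -1), "D_free")
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(k_on = NaN), "k_on")
  expect_error(sim_config(n_particles = 2.5), "integer")
  expect_warning(
    sim_config(D_free = 1, dt = 0.1, n_sites = 5, capture_radius = 0.05,
               k_on = 1),
    "capture_radius")
})

test_that("frozen dynamics leave every snapshot identical", {
  cfg <- sim_config(D_free = 0, D_bound = 0, k_on = 0, n_particles = 10,
                    n_sites = 3, n_steps = 20, seed = 4)
  traj <- simulate_membrane_dynamics(cfg)
  for (f in 2:21) {
    expect_identical(traj$s[f, ], traj$s[1, ])
    expect_identical(traj$theta[f, ], traj$theta[1, ])
  }
})

test_that("without sites the bound fraction is zero everywhere", {
  cfg <- sim_config(n_sites = 0, k_on = 5, k_off = 1, n_particles = 50,
                    n_steps = 30, seed = 2)
  traj <- simulate_membrane_dynamics(cfg)
  expect_true(all(bound_fraction(traj) == 0))
})

test_that("coordinate and occupancy invariants hold across random configs", {
  for (seed in 1:4) {
    cfg <- sim_config(D_free = 0.1, D_bound = 0.01, n_particles = 40,
                      n_sites = 6, site_capacity = 3, capture_radius = 0.3,
                      k_on = 10, k_off = 2, dt = 0.05, n_steps = 40,
                      seed = seed)
    traj <- simulate_membrane_dynamics(cfg)
    L <- cfg$geometry$length
    expect_true(all(traj$theta >= 0 & traj$theta < 2 * pi))
    expect_true(all(traj$s >= 0 & traj$s <= L))
    expect_identical(dim(traj$s), c(41L, 40L))
    # occupancy never exceeds capacity, in any frame
    for (f in seq_len(nrow(traj$bound_site))) {
      b <- traj$bound_site[f, ]
      occ <- tabulate(b[b > 0], nbins = 6)
      expect_true(all(occ <= 3))
      expect_equal(sum(occ), sum(b > 0))
    }
  }
})

test_that("trajectories are byte-identical for a fixed seed", {
  cfg <- sim_config(n_particles = 30, n_sites = 4, k_on = 3, k_off = 1,
                    n_steps = 25, seed = 11)
  expect_identical(simulate_membrane_dynamics(cfg),
                   simulate_membrane_dynamics(cfg))
  cfg2 <- sim_config(n_particles = 30, n_sites = 4, k_on = 3, k_off = 1,
                     n_steps = 25, seed = 12)
  expect_false(identical(simulate_membrane_dynamics(cfg)$s,
                         simulate_membrane_dynamics(cfg2)$s))
})

test_that("free-diffusion MSD follows the 2-D Brownian law", {
  # scaled-down version of the full-size acceptance check
  cfg <- sim_config(D_free = 0.05, n_particles = 1500, n_sites = 0,
                    dt = 0.01, n_steps = 200, seed = 7,
                    geometry = cell_geometry(length = 100, radius = 0.4))
  traj <- simulate_membrane_dynamics(cfg)
  msd <- trajectory_msd(traj, lags = seq(5, 100, by = 5))
  slope <- unname(coef(lm(msd ~ 0 + t, data = msd))[1])
  expect_equal(slope, 4 * 0.05, tolerance = 0.1)
})

test_that("binding equilibrium matches the two-state Gillespie oracle", {
  # capture everywhere + saturating capacity reduces binding to a
  # two-state chain with p(bound) = k_on / (k_on + k_off)
  k_on <- 2; k_off <- 1
  cfg <- sim_config(D_free = 0.05, D_bound = 0.05, n_particles = 1200,
                    n_sites = 1, site_capacity = 1200, capture_radius = 10,
                    k_on = k_on, k_off = k_off, dt = 0.02, n_steps = 300,
                    seed = 8)
  traj <- simulate_membrane_dynamics(cfg)
  p_sim <- mean(traj$bound_site[301, ] > 0)
  p_oracle <- gillespie_bound_fraction(k_on, k_off)
  se <- sqrt(p_oracle * (1 - p_oracle) / 1200)
  expect_lt(abs(p_sim - p_oracle), 3 * se + 0.01)
})

test_that("trim_trajectory drops leading frames and updates the config", {
  cfg <- sim_config(n_particles = 5, n_steps = 10, seed = 1)
  traj <- simulate_membrane_dynamics(cfg)
  tr <- trim_trajectory(traj, 4)
  expect_identical(nrow(tr$s), 8L)
  expect_identical(tr$config$n_steps, 7L)
  expect_identical(tr$s[1, ], traj$s[4, ])
  expect_error(trim_trajectory(traj, 50), "exceeds")
})
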