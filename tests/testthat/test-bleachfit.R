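test_that("cell traces start at exactly 100 and are scale invariant", {
  H <- 24; W <- 44; Tn <- 6
  mask <- rect_mask(H, W, 9:15, 8:36)
  frames <- array(50, dim = c(H, W, Tn))
  for (f in seq_len(Tn)) frames[9:15, 8:36, f] <- 50 + 40 * 0.8^(f - 1)
  stack <- image_stack(frames, pixel_size = 0.1, frame_interval = 0.1)
  tr <- cell_trace(stack, mask, 1L)
  expect_identical(tr$normalized_intensity[1], 100)
  expect_equal(tr$normalized_intensity, 100 * 0.8^(0:5))
  expect_equal(tr$times, 0.1 * (0:5))
  # scaling the whole stack changes nothing
  stack2 <- image_stack(frames * 3.7, pixel_size = 0.1, frame_interval = 0.1)
  expect_equal(cell_trace(stack2, mask, 1L)$normalized_intensity,
               tr$normalized_intensity)
  # constant stack: flat at 100
  stack3 <- image_stack(array(rep(frames[, , 1], Tn), dim = c(H, W, Tn)),
                        pixel_size = 0.1, frame_interval = 0.1)
  expect_equal(cell_trace(stack3, mask, 1L)$normalized_intensity,
               rep(100, Tn))
})

test_that("cell_trace rejects unnormalizable or inconsistent input", {
  mask <- rect_mask(24, 44, 9:15, 8:36)
  frames <- array(50, dim = c(24, 44, 6))   # cell == background
  stack <- image_stack(frames, pixel_size = 0.1, frame_interval = 0.1)
  expect_error(cell_trace(stack, mask, 1L), "cannot normalize")
  expect_error(cell_trace(stack, mask, 1L, background_region = mask == 1L),
               "overlaps")
})

test_that("noiseless two-phase parameters are recovered to 1e-6", {
  times <- seq(0, 10, by = 0.1)
  pars <- list(A = 40, k_fast = 0.5, K = 0.05)
  fit <- fit_photobleach_global(synth_traces(times, pars, "c1"))
  expect_equal(fit$table$K, pars$K, tolerance = 1e-6)
  expect_equal(fit$k_fast, pars$k_fast, tolerance = 1e-6)
  expect_equal(fit$table$A_fast, pars$A, tolerance = 1e-5)
  expect_gt(fit$table$R2, 1 - 1e-9)
})

test_that("a pure slow exponential gives K = ln2 / half-life", {
  t_half <- 8
  times <- seq(0, 30, by = 0.5)
  y <- 100 * exp(-log(2) / t_half * times)
  tr <- structure(list(cell_id = 1, condition = "slow", times = times,
                       normalized_intensity = y), class = "bleach_trace")
  fit <- fit_photobleach_global(list(tr))
  expect_equal(fit$table$K, log(2) / t_half, tolerance = 1e-6)
})

test_that("shared fast rate is recovered across two noisy conditions", {
  times <- seq(0, 10, by = 0.1)
  tr <- c(synth_traces(times, list(A = 40, k_fast = 0.5, K = 0.08), "ref",
                       n_cells = 4, noise_sd = 1, seed = 21),
          synth_traces(times, list(A = 40, k_fast = 0.5, K = 0.03), "rif",
                       n_cells = 4, noise_sd = 1, seed = 22))
  fit <- fit_photobleach_global(tr)
  expect_equal(fit$k_fast, 0.5, tolerance = 0.05)
  K <- setNames(fit$table$K, fit$table$condition)
  expect_gt(K[["ref"]], K[["rif"]])
  expect_identical(fit$table$n, c(4, 4), ignore_attr = TRUE)
})

test_that("fits are equivariant under time re-units", {
  times <- seq(0, 12, by = 0.2)
  pars <- list(A = 35, k_fast = 0.8, K = 0.06)
  tr_s <- synth_traces(times, pars, "c", n_cells = 2, noise_sd = 0.5,
                       seed = 5)
  tr_min <- lapply(tr_s, function(x) { x$times <- x$times / 60; x })
  f_s <- fit_photobleach_global(tr_s)
  f_min <- fit_photobleach_global(tr_min)
  expect_equal(f_min$table$K, 60 * f_s$table$K, tolerance = 1e-3)
  expect_equal(f_min$table$R2, f_s$table$R2, tolerance = 1e-6)
})

test_that("fit input validation", {
  times <- seq(0, 1, by = 0.5)   # only 3 points
  expect_error(fit_photobleach_global(synth_traces(times,
    list(A = 40, k_fast = 0.5, K = 0.05), "c")), "fewer than 5")
  t1 <- synth_traces(seq(0, 5, 0.1), list(A = 40, k_fast = 0.5, K = 0.05), "c")
  t2 <- synth_traces(seq(0, 5, 0.2), list(A = 40, k_fast = 0.5, K = 0.05), "c")
  expect_error(fit_photobleach_global(c(t1, t2)), "mismatched time grids")
})

test_that("condition comparison reports ratios and diffusion ordering", {
  mk_fit <- function(Ks, conds, times = seq(0, 5, 0.1)) {
    structure(list(
      table = data.frame(condition = conds, K = Ks, SEM_K = 0.01 * Ks,
                         A_fast = 40, k_fast = 0.5, R2 = 0.99,
                         n = 3, K_at_bound = FALSE),
      k_fast = 0.5, SEM_k_fast = 0.01,
      times = rep(list(times), length(conds))), class = "bleach_fit")
  }
  cmp <- compare_conditions(mk_fit(c(0.08, 0.03), c("ref", "rif")))
  expect_equal(cmp$ratio, c(1, 0.375))
  expect_match(cmp$verdict[2], "faster diffusion")
  same <- compare_conditions(mk_fit(c(0.05, 0.05), c("a", "b")))
  expect_identical(same$verdict[2], "no change")
  expect_error(compare_conditions(mk_fit(0.05, "a")), ">= 2")
  expect_error(
    compare_conditions(list(mk_fit(0.05, "a"),
                            mk_fit(0.04, "b", times = seq(0, 5, 0.2)))),
    "mismatched time grids")
})
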