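test_that("constant image yields constant scans, two per isolated cell", {
  mask <- rect_mask(24, 44, 8:16, 6:38)
  img <- matrix(7, 24, 44)
  scans <- extract_perimeter_scans(img, mask, pixel_size = 0.1)
  expect_length(scans, 2L)
  expect_setequal(vapply(scans, `[[`, character(1), "side"),
                  c("left", "right"))
  for (s in scans) {
    expect_true(all(s$intensities == 7))
    expect_gte(length(s$intensities), 10L)
    expect_true(all(diff(s$arc_positions) > 0))
  }
})

test_that("adjacent cell sides are excluded", {
  # two cells whose facing sides are 2 px apart (< 3 px default gap)
  mask <- rect_mask(30, 44, 5:11, 6:38, id = 1L)
  mask <- rect_mask(30, 44, 14:20, 6:38, id = 2L, base = mask)
  img <- matrix(5, 30, 44)
  scans <- extract_perimeter_scans(img, mask, pixel_size = 0.1)
  sides <- vapply(scans, function(s) paste(s$cell_id, s$side), character(1))
  expect_length(scans, 2L)
  # cell 1's facing (bottom, "right" in axis terms) side and cell 2's
  # facing side must both be gone; one scan per cell survives
  expect_setequal(vapply(scans, `[[`, numeric(1), "cell_id"), c(1, 2))
})

test_that("cells touching the border are skipped with a warning", {
  mask <- rect_mask(24, 44, 1:9, 6:38)
  img <- matrix(1, 24, 44)
  expect_warning(scans <- extract_perimeter_scans(img, mask, 0.1), "border")
  expect_length(scans, 0L)
  expect_identical(extract_perimeter_scans(img, matrix(0L, 24, 44), 0.1),
                   list())
})

test_that("scan statistics use the sample variance", {
  sc <- structure(list(cell_id = 1L, side = "left",
                       arc_positions = c(0, 0.1),
                       intensities = c(10, 20),
                       background_subtracted = FALSE),
                  class = "line_scan")
  st <- scan_stats(sc)
  expect_equal(st$mean_intensity, 15)
  expect_equal(st$variance, 50)
  expect_identical(st$n_pixels, 2L)
  sc$intensities <- rep(7, 12); sc$arc_positions <- 0.1 * (0:11)
  expect_equal(scan_stats(sc)$variance, 0)
  sc$intensities <- 3
  expect_error(scan_stats(sc), "fewer than 2")
})

test_that("a focus raises variance at equal mean", {
  flat <- structure(list(cell_id = 1L, side = "left",
                         arc_positions = 0.1 * (0:19),
                         intensities = rep(10, 20),
                         background_subtracted = FALSE),
                    class = "line_scan")
  focal <- flat
  focal$intensities <- c(rep(8, 16), 18, 26, 18, 10)  # same total
  expect_equal(sum(focal$intensities), sum(flat$intensities))
  expect_equal(scan_stats(focal)$mean_intensity,
               scan_stats(flat)$mean_intensity)
  expect_gt(scan_stats(focal)$variance, scan_stats(flat)$variance)
})

test_that("scan statistics are offset-invariant in variance", {
  set.seed(1)
  mask <- rect_mask(24, 44, 8:16, 6:38)
  img <- matrix(rpois(24 * 44, 50), 24, 44)
  s1 <- lapply(extract_perimeter_scans(img, mask, 0.1), scan_stats)
  s2 <- lapply(extract_perimeter_scans(img + 25, mask, 0.1), scan_stats)
  expect_equal(vapply(s1, `[[`, numeric(1), "variance"),
               vapply(s2, `[[`, numeric(1), "variance"))
  expect_equal(vapply(s2, `[[`, numeric(1), "mean_intensity") -
                 vapply(s1, `[[`, numeric(1), "mean_intensity"),
               rep(25, 2))
  # with background subtraction the means match too
  s3 <- lapply(extract_perimeter_scans(img, mask, 0.1, background = "auto"),
               scan_stats)
  s4 <- lapply(extract_perimeter_scans(img + 25, mask, 0.1,
                                       background = "auto"), scan_stats)
  expect_equal(vapply(s3, `[[`, numeric(1), "mean_intensity"),
               vapply(s4, `[[`, numeric(1), "mean_intensity"),
               tolerance = 1e-10)
})

test_that("field summary uses the lower-median convention", {
  mk <- function(m, v, id = 1L)
    structure(list(cell_id = id, side = "left", mean_intensity = m,
                   variance = v, n_pixels = 20L), class = "scan_stats")
  one <- field_summary(list(mk(5, 2)))
  expect_equal(one$median_mean_intensity, 5)
  expect_equal(one$median_variance, 2)
  expect_identical(one$n_scans, 1L)
  three <- field_summary(list(mk(1, 1, 1L), mk(2, 2, 2L), mk(3, 100, 3L)))
  expect_equal(three$median_variance, 2)
  four <- field_summary(lapply(1:4, function(i) mk(i, i, i)))
  expect_equal(four$median_variance, 2)  # lower of {2, 3}
  expect_error(field_summary(list()), "no scan")
})
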