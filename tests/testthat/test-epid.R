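# small image pairs keep the pixel-level tests fast; geometry is fully
# parameterized so nothing depends on the full-size default
small_pair <- function(factors = rep(1, 7), noise_sd = 0, seed = NULL) {
  make_epid_pair(factors = factors, noise_sd = noise_sd, n_rows = 96,
                 n_cols = 256, pixel_spacing = c(1.344, 1.344), seed = seed)
}

test_that("corrected image is the pixelwise strip/open ratio", {
  pair <- small_pair()
  same <- corrected_image(pair$open, pair$open)
  expect_true(all(abs(same - 1) < 1e-12, na.rm = TRUE))

  half <- pair$open
  half$pixels <- half$pixels * 0.5
  half$kind <- "STRIP"
  expect_true(all(abs(corrected_image(half, pair$open) - 0.5) < 1e-12,
                  na.rm = TRUE))

  # planted ROI factors come back exactly before noise
  pert <- small_pair(factors = c(1, 1.05, 0.97, 1, 1.02, 1, 0.99))
  corr <- corrected_image(pert$strip, pert$open)
  rois <- locate_rois(pert$layout, pert$strip)
  for (i in seq_len(nrow(rois))) {
    block <- corr[(rois$row_start[i] + 1):rois$row_end[i],
                  (rois$col_start[i] + 1):rois$col_end[i]]
    expect_true(all(abs(block - pert$factors[i]) < 1e-12))
  }

  wrong <- epid_image(matrix(1, 10, 10), 1, "OPEN")
  expect_error(corrected_image(pert$strip, wrong), "dimensions")
})

test_that("low open-field readings are masked, fully dark pairs error", {
  op <- epid_image(matrix(c(rep(100, 90), rep(0.1, 10)), 10, 10), 1, "OPEN")
  st <- epid_image(matrix(50, 10, 10), 1, "STRIP")
  corr <- corrected_image(st, op)
  expect_equal(sum(is.na(corr)), 10)
  expect_true(all(abs(corr[!is.na(corr)] - 0.5) < 1e-12))

  dark <- epid_image(matrix(0, 4, 4), 1, "OPEN")
  expect_error(corrected_image(epid_image(matrix(1, 4, 4), 1, "STRIP"), dark),
               "fully masked")
})

test_that("locate_rois erodes each strip by the margin fraction", {
  layout <- strip_layout(col_start = seq(0, by = 90, length.out = 7) + 22,
                         col_end = seq(0, by = 90, length.out = 7) + 62,
                         row_start = 100, row_end = 600)
  img <- epid_image(matrix(1, 768, 1024), 0.336, "STRIP")
  rois <- locate_rois(layout, img, margin_fraction = 0.25)
  expect_equal(rois$col_end - rois$col_start, rep(20, 7))  # 40 px -> 20 px
  expect_equal(rois$col_start, layout$strips$col_start + 10)
  expect_equal(rois$roi_index, 1:7)

  full <- locate_rois(layout, img, margin_fraction = 0)
  expect_equal(full$col_start, layout$strips$col_start)
  expect_equal(full$col_end, layout$strips$col_end)

  expect_error(locate_rois(layout, img, margin_fraction = 0.5), "degenerate")
})

test_that("a plan's MLC apertures project to the image strip layout", {
  plan <- make_vendor_replica_plan()
  pair <- small_pair()
  derived <- layout_from_plan(plan, pair$strip)
  expect_equal(nrow(derived$strips), 7)
  expect_equal(derived$strips$col_start, pair$layout$strips$col_start)
  expect_equal(derived$strips$col_end, pair$layout$strips$col_end)
})

test_that("segment deviations follow the ratio-to-grand-mean form", {
  # all equal -> all zero
  corr <- matrix(2.5, 40, 140)
  rois <- locate_rois(strip_layout(seq(0, 120, by = 20),
                                   seq(20, 140, by = 20), 0, 40),
                      epid_image(corr, 1, "STRIP"), margin_fraction = 0.1)
  expect_true(all(abs(segment_deviations(corr, rois)$deviation_pct) < 1e-12))

  # one hot segment among 7: closed form on both hot and cold ROIs
  means <- c(1.07, rep(1, 6))
  dev <- (means / mean(means) - 1) * 100
  expect_equal(round(dev[1], 2), round((1.07 / 1.01 - 1) * 100, 2))
  expect_equal(round(dev[2], 2), round((1 / 1.01 - 1) * 100, 2))

  # published per-ROI means: first ROI sits 1.01% above the grand mean
  tbl <- c(1.01, 1.001, 1.0, 0.996, 0.994, 0.998, 1.0)
  dev_tbl <- (tbl / mean(tbl) - 1) * 100
  expect_equal(round(dev_tbl[1], 2), 1.01)

  expect_error(segment_deviations(corr, rois[1, ]), "at least 2")
})

test_that("deviations have zero mean and are scale invariant", {
  pair <- small_pair(factors = c(1.02, 0.98, 1, 1.01, 0.99, 1.03, 0.97))
  corr <- corrected_image(pair$strip, pair$open)
  rois <- locate_rois(pair$layout, pair$strip)
  dev <- segment_deviations(corr, rois)
  expect_lt(abs(mean(dev$deviation_pct)), 1e-9)

  # multiplying both images by any positive constant changes nothing
  for (c0 in c(0.2, 37)) {
    s2 <- pair$strip; s2$pixels <- s2$pixels * c0
    o2 <- pair$open; o2$pixels <- o2$pixels * c0
    dev2 <- segment_deviations(corrected_image(s2, o2), rois)
    expect_equal(dev2$deviation_pct, dev$deviation_pct, tolerance = 1e-9)
  }
})

test_that("planted single-ROI perturbations are recovered via the closed form", {
  for (delta in c(0.01, 0.03, 0.07)) {
    factors <- rep(1, 7); factors[4] <- 1 + delta
    pair <- small_pair(factors = factors)
    dev <- segment_deviations(corrected_image(pair$strip, pair$open),
                              locate_rois(pair$layout, pair$strip))
    expected <- closed_form_hot(delta, 7)
    expect_equal(dev$deviation_pct[4], expected, tolerance = 1e-4 * expected)
  }
})

test_that("compare_to_baseline reproduces the published per-ROI differences", {
  measured <- c(1.01, 1.001, 1.0, 0.996, 0.994, 0.998, 1.0)
  baseline <- baseline_record("TB1", c(1.012, 1.004, 1.002, 0.992, 0.995,
                                       0.998, 0.997))
  report <- compare_to_baseline(measured, baseline, tolerance_pct = 3)
  expect_equal(round(report$rois$difference_pct, 1),
               c(-0.2, -0.3, -0.2, 0.4, -0.1, 0.0, 0.3))
  expect_equal(round(report$max_abs_difference_pct, 1), 0.4)
  expect_true(report$pass)

  equal <- compare_to_baseline(measured, baseline_record("TB1", measured))
  expect_true(all(equal$rois$difference_pct == 0))
  expect_equal(equal$max_abs_difference_pct, 0)

  expect_error(compare_to_baseline(measured[1:5], baseline), "mismatch")
  expect_error(baseline_record("TB1", c(1, -1)), "positive")
})

test_that("tolerance flagging matches |difference| <= tolerance", {
  base <- baseline_record("TB1", rep(1, 7))
  shifted <- rep(1, 7); shifted[3] <- 1.04
  report <- compare_to_baseline(shifted, base, tolerance_pct = 3)
  expect_false(report$rois$pass[3])
  expect_true(all(report$rois$pass[-3]))
  expect_false(report$pass)
})

test_that("update_baseline averages sessions per ROI", {
  one <- update_baseline(list(c(1.0, 1.02)), machine_id = "TB1")
  expect_equal(one$rois$baseline_mean, c(1.0, 1.02))
  expect_equal(one$n_sessions, 1)

  two <- update_baseline(list(c(1.00, 1.0), c(1.02, 1.0)))
  expect_equal(two$rois$baseline_mean[1], 1.01)

  set.seed(123)
  hist27 <- lapply(1:27, function(i) rnorm(7, 1.005, 0.002))
  agg <- update_baseline(hist27, machine_id = "TB1",
                         date_range = "2020-01..2022-03")
  expect_true(all(abs(agg$rois$baseline_mean - 1.005) < 3 * 0.002 / sqrt(27)))
  expect_equal(agg$n_sessions, 27)

  expect_error(update_baseline(list(1:3, 1:2)), "ragged")
})

test_that("baseline and layout records round-trip through JSON", {
  b <- baseline_record("TB1", c(1.012, 1.004, 1.002), date_range = "27 months",
                       n_sessions = 27)
  path <- withr::local_tempfile(fileext = ".json")
  write_baseline(b, path)
  expect_equal(read_baseline(path), b)

  lay <- strip_layout(c(10, 50), c(30, 70), 5, 90)
  lpath <- withr::local_tempfile(fileext = ".json")
  write_layout(lay, lpath)
  expect_equal(read_layout(lpath), lay)
})

test_that("EPID images round-trip through DICOM RT Image files", {
  set.seed(4)
  img <- epid_image(matrix(sample(0:4000, 48 * 64, replace = TRUE), 48, 64),
                    c(0.336, 0.336), "STRIP", machine_id = "TB-SIM",
                    date = "20260101")
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtimage(img, path)
  back <- read_rtimage(path)
  expect_equal(back$pixels, img$pixels)      # integer readings: exact
  expect_equal(back$pixel_spacing, img$pixel_spacing)
  expect_equal(back$kind, "STRIP")
  expect_equal(back$machine_id, "TB-SIM")

  # non-integer readings: preserved to the 16-bit quantization step
  fimg <- epid_image(matrix(runif(32 * 32, 0, 900), 32, 32), 1, "OPEN")
  fpath <- withr::local_tempfile(fileext = ".dcm")
  write_rtimage(fimg, fpath)
  fback <- read_rtimage(fpath)
  expect_equal(fback$kind, "OPEN")
  expect_lt(max(abs(fback$pixels - fimg$pixels)), 900 / 65535)
})
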