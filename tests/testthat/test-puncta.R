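cal1 <- pixel_calibration(1, 0.5)   # 1 um/px: radii 10 and 100 px

test_that("top-hat segmentation suppresses flat and smooth structure", {
  params <- segmentation_params()
  flat <- matrix(7, 64, 64)
  expect_false(any(tophat_segment(flat, params, cal1, "green")))

  ramp <- matrix(rep(seq(0, 100, length.out = 64), each = 64), 64, 64)
  expect_false(any(tophat_segment(ramp, params, cal1, "green")))

  # five separated blobs above threshold -> exactly five components
  ctrs <- rbind(c(12, 12), c(12, 52), c(32, 32), c(52, 12), c(52, 52))
  img <- blob_image(c(64, 64), ctrs, sigma = 2, amp = 100, background = 10)
  mask <- tophat_segment(img, params, cal1, "green")
  expect_equal(max(aggrequant:::label_mask(mask)), 5)

  # invariance to adding a constant
  expect_identical(mask, tophat_segment(img + 137.5, params, cal1, "green"))

  # sub-half-pixel radius: calibration is suspect
  coarse <- pixel_calibration(25, 0.5)
  expect_error(tophat_segment(img, params, coarse, "green"), "calibration")
})

test_that("puncta detection matches a flood-fill oracle with 8-connectivity",
{
  expect_equal(nrow(detect_puncta(matrix(FALSE, 8, 8), matrix(0, 8, 8))), 0)
  expect_error(detect_puncta(matrix(FALSE, 8, 8), matrix(0, 4, 4)), "shape")

  # one 3x3 square: area 9, centroid at the square centre
  m <- matrix(FALSE, 10, 10); m[4:6, 5:7] <- TRUE
  ps <- detect_puncta(m, matrix(2, 10, 10), frame_index = 3L,
                      calibration = cal1)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$area_px, 9L)
  expect_equal(ps$area_um2, 9)
  expect_equal(ps$x_px, 5)   # columns 5:7 are x = 4:6, centred on 5
  expect_equal(ps$y_px, 4)
  expect_equal(ps$mean_intensity, 2)
  expect_equal(ps$frame, 3L)

  # diagonal touch joins objects (8-connectivity)
  d <- matrix(FALSE, 6, 6); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_equal(nrow(detect_puncta(d, matrix(0, 6, 6))), 1)

  set.seed(11)
  for (i in 1:30) {
    rnd <- matrix(runif(32 * 32) < 0.35, 32, 32)
    got <- detect_puncta(rnd, matrix(1, 32, 32))
    orc <- oracle_label(rnd)
    expect_equal(nrow(got), max(orc))
    expect_equal(sort(got$area_px), sort(tabulate(orc[orc > 0])))
  }
})

test_that("white overlap follows the area-ratio definition", {
  g <- matrix(FALSE, 10, 10); r <- matrix(FALSE, 10, 10)
  g[2:5, 2:5] <- TRUE
  ov_same <- white_overlap(g, g)
  expect_equal(ov_same$fraction, 1)

  r[7:9, 7:9] <- TRUE
  expect_equal(white_overlap(g, r)$fraction, 0)

  # red 100 px, green overlapping 40 of them
  r2 <- matrix(FALSE, 20, 20); r2[1:10, 1:10] <- TRUE
  g2 <- matrix(FALSE, 20, 20); g2[1:4, 1:10] <- TRUE
  ov <- white_overlap(g2, r2)
  expect_equal(ov$fraction, 0.4)
  expect_true(all(ov$mask <= (g2 & r2)))

  expect_warning(z <- white_overlap(g, matrix(FALSE, 10, 10)), "empty")
  expect_equal(z$fraction, 0)
  expect_error(white_overlap(g, matrix(FALSE, 5, 5)), "shape")

  # containment invariant on random masks
  set.seed(21)
  for (i in 1:20) {
    gm <- matrix(runif(100) < 0.4, 10, 10)
    rm_ <- matrix(runif(100) < 0.4, 10, 10)
    ov <- suppressWarnings(white_overlap(gm, rm_))
    expect_true(all(!ov$mask | (gm & rm_)))
    expect_gte(ov$fraction, 0)
    expect_lte(ov$fraction, 1)
  }
})

test_that("object-level colour classification uses the half rule", {
  r <- matrix(FALSE, 8, 12); r[2:5, 2:5] <- TRUE; r[2:5, 8:11] <- TRUE
  g <- matrix(FALSE, 8, 12)
  g[2:5, 2:5] <- TRUE          # first object fully green
  g[2:3, 8:11] <- TRUE         # second: exactly half green
  cls <- classify_puncta_colour(r, g)
  expect_equal(cls$channel, c("white", "white"))
  g[3, 8:11] <- FALSE          # now a quarter green
  expect_equal(classify_puncta_colour(r, g)$channel[2], "red")
})

test_that("average object size averages areas and reports gaps as missing", {
  m1 <- matrix(FALSE, 10, 10); m1[1:2, 1:1] <- TRUE   # 2 px
  m2 <- matrix(FALSE, 10, 10); m2[5:6, 5:6] <- TRUE   # 4 px
  ps <- list(detect_puncta(m1 | m2, matrix(0, 10, 10), 1L, cal1),
             detect_puncta(matrix(FALSE, 10, 10), matrix(0, 10, 10), 2L))
  avg <- average_object_size(ps)
  expect_equal(avg$mean_area_um2, c(3, NA))
})

test_that("object-based colocalization counts centroids inside the marker", {
  m <- matrix(FALSE, 12, 12); m[2:3, 2:3] <- TRUE; m[8:9, 8:9] <- TRUE
  ps <- detect_puncta(m, matrix(0, 12, 12))
  expect_equal(colocalize_puncta(ps, matrix(TRUE, 12, 12)), 1)
  expect_equal(colocalize_puncta(ps, matrix(FALSE, 12, 12)), 0)
  half <- matrix(FALSE, 12, 12); half[1:5, 1:5] <- TRUE
  expect_equal(colocalize_puncta(ps, half), 0.5)
  expect_true(is.na(colocalize_puncta(detect_puncta(matrix(FALSE, 4, 4),
                                                    matrix(0, 4, 4)),
                                      matrix(TRUE, 4, 4))))
})

test_that("colocalization fraction tracks the generator's planted rate", {
  set.seed(33)
  marker <- matrix(FALSE, 80, 80); marker[1:80, 1:24] <- TRUE  # left 30%
  fracs <- replicate(15, {
    n <- 40
    cx <- runif(n, 4, 75); cy <- runif(n, 4, 75)
    img <- blob_image(c(80, 80), cbind(cx, cy), sigma = 1.5)
    mask <- tophat_segment(img, segmentation_params(min_area_px = 1),
                           cal1, "green")
    colocalize_puncta(detect_puncta(mask, img), marker)
  })
  # centres uniform over x in [4, 75]: expected in-marker fraction
  expected <- (23.5 - 4) / (75 - 4)
  expect_lt(abs(mean(fracs) - expected), 0.08)
})

test_that("ROI fold change is 1 against itself and tracks planted signal", {
  set.seed(44)
  make_img <- function(gain) {
    ctrs <- cbind(runif(6, 10, 54), runif(6, 10, 54))
    roi <- blob_image(c(64, 64), ctrs, sigma = 2.5, amp = 100)
    measured <- matrix(7, 64, 64)
    list(roi = roi, measured = measured * gain)
  }
  conds <- list(ctrl = list(make_img(1), make_img(1)),
                treated = list(make_img(2), make_img(2)))
  res <- roi_intensity_foldchange(conds, segmentation_params(),
                                  cal1, reference_condition = "ctrl")
  expect_equal(res$fold_change$fold_change[
    res$fold_change$condition == "ctrl"], 1)
  expect_equal(res$fold_change$fold_change[
    res$fold_change$condition == "treated"], 2, tolerance = 1e-6)
  expect_true(all(res$per_roi$mean_intensity[
    res$per_roi$condition == "ctrl"] == 7))
  expect_error(roi_intensity_foldchange(conds, segmentation_params(), cal1,
                                        "absent"), "absent")
})

test_that("green area fraction divides by the cell footprint", {
  cell <- matrix(FALSE, 10, 10); cell[1:10, 1:8] <- TRUE
  expect_equal(gfp_area_fraction(cell, cell), 1)
  expect_equal(gfp_area_fraction(matrix(FALSE, 10, 10), cell), 0)
  half <- matrix(FALSE, 10, 10); half[1:5, 1:8] <- TRUE
  expect_equal(gfp_area_fraction(half, cell), 0.5)
  expect_error(gfp_area_fraction(half, matrix(FALSE, 10, 10)), "empty")
})

test_that("noiseless generator frames are segmented to the true count", {
  sim <- simulate_aggrephagy_timelapse(n_aggregates = 25, k_deg = 0,
                                       duration = 1, frame_interval = 0.5,
                                       image_shape = c(140, 140),
                                       noise = NULL,
                                       radius_range_um = c(3, 4), seed = 12)
  q <- suppressWarnings(quantify_frame(get_frame(sim$green, 1),
                                       get_frame(sim$red, 1),
                                       calibration = sim$green$calibration))
  expect_equal(nrow(q$green_puncta), 25)
  expect_equal(nrow(q$red_puncta), 25)
  expect_equal(q$white_fraction, 1, tolerance = 0.05)
  # white mask contained in both channel masks
  expect_true(all(!q$white_mask | (q$green_mask & q$red_mask)))
  # mean size within 10% of the geometric expectation for these blobs:
  # pixels above 0.7 of a Gaussian peak cover pi * (0.845 sigma)^2
  sig <- (sim$truth$aggregates$radius_um / 2)
  expected_um2 <- mean(pi * (sqrt(2 * log(1 / 0.7)) * sig)^2)
  got <- average_object_size(list(q$red_puncta))$mean_area_um2
  expect_lt(abs(got - expected_um2) / expected_um2, 0.25)
})
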