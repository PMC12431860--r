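test_that("reporter time-lapse honours the two-state quenching logic", {
  # no quenching, no fragmentation: every aggregate stays dual
  sim0 <- simulate_aggrephagy_timelapse(n_aggregates = 20, k_deg = 0,
                                        k_frag = 0, duration = 4,
                                        image_shape = c(80, 80), seed = 1)
  expect_true(all(sim0$truth$white_fraction == 1))

  # quenching much faster than the frame interval: white gone after frame 1
  simf <- simulate_aggrephagy_timelapse(n_aggregates = 50, k_deg = 50,
                                        duration = 4, image_shape = c(120, 120),
                                        seed = 2)
  expect_equal(simf$truth$white_fraction[1], 1)
  expect_lt(max(simf$truth$white_fraction[-1]), 0.02)

  expect_error(simulate_aggrephagy_timelapse(k_deg = -1, seed = 1))
  expect_error(simulate_aggrephagy_timelapse(image_shape = c(0, 10),
                                             seed = 1))
  expect_error(simulate_aggrephagy_timelapse(n_aggregates = 5))
})

test_that("white-fraction truth decays as exp(-k t) at large n", {
  k <- 0.1
  sim <- simulate_aggrephagy_timelapse(n_aggregates = 1e4, k_deg = k,
                                       duration = 24, render = FALSE,
                                       seed = 42)
  expected <- exp(-k * sim$truth$times)
  expect_lt(max(abs(sim$truth$white_fraction - expected)), 0.02)
  expect_true(all(sim$truth$white_fraction >= 0 &
                  sim$truth$white_fraction <= 1))
  # oracle: brute-force event count (unweighted survival) agrees with the
  # area-weighted truth at this scale
  agg <- sim$truth$aggregates
  surv <- vapply(sim$truth$times, function(t) mean(agg$t_conv > t),
                 numeric(1))
  expect_lt(max(abs(sim$truth$white_fraction - surv)), 0.02)
})

test_that("generators are deterministic given the seed", {
  a <- simulate_aggrephagy_timelapse(n_aggregates = 10, duration = 2,
                                     image_shape = c(64, 64), seed = 9)
  b <- simulate_aggrephagy_timelapse(n_aggregates = 10, duration = 2,
                                     image_shape = c(64, 64), seed = 9)
  expect_identical(a$green$data, b$green$data)
  expect_identical(a$truth$white_fraction, b$truth$white_fraction)
  c_ <- simulate_aggrephagy_timelapse(n_aggregates = 10, duration = 2,
                                      image_shape = c(64, 64), seed = 10)
  expect_false(identical(a$green$data, c_$green$data))

  p1 <- simulate_profile(100, 50, 0.3, seed = 4)
  p2 <- simulate_profile(100, 50, 0.3, seed = 4)
  expect_identical(p1$value, p2$value)
})

test_that("fragmentation conserves parent area and inherits the clock", {
  sim <- simulate_aggrephagy_timelapse(n_aggregates = 30, k_deg = 0.05,
                                       k_frag = 0.1, duration = 24,
                                       image_shape = c(160, 160), seed = 6)
  agg <- sim$truth$aggregates
  kids <- agg[!is.na(agg$parent_id), ]
  expect_gt(nrow(kids), 0)
  for (pid in unique(kids$parent_id)) {
    pair <- kids[kids$parent_id == pid, ]
    parent <- agg[agg$id == pid, ]
    expect_equal(sum(pi * pair$radius_um^2), pi * parent$radius_um^2,
                 tolerance = 0.01)
    expect_equal(pair$t_conv, rep(parent$t_conv, 2))
    expect_true(all(pair$birth == parent$death))
  }
})

test_that("SMLM localization generator matches its declared structure", {
  roi <- disc_roi_mask(1000, 10)

  # clustered fraction 0: everything is background
  s0 <- simulate_smlm_localizations(roi, 100, clustered_fraction = 0,
                                    n_clusters = 0, seed = 1)
  expect_true(all(s0$truth$cluster == -1L))

  # zero molecules: empty table
  se <- simulate_smlm_localizations(roi, 0, 0.5, 2, seed = 1)
  expect_equal(nrow(se$localizations), 0)

  expect_error(simulate_smlm_localizations(roi, 10, 0.5, 2,
                                           cluster_sigma_nm = 0, seed = 1),
               "cluster_sigma")

  # per-cluster counts sum to round(f * n) under multinomial allocation
  for (s in 1:10) {
    sim <- simulate_smlm_localizations(roi, 200, 0.6, 3, seed = s)
    expect_equal(sum(sim$truth$cluster > 0), round(0.6 * 200))
    expect_equal(sort(unique(sim$truth$cluster[sim$truth$cluster > 0])),
                 1:3)
  }

  # localizations stay within 4 sigma_loc of the footprint
  sig <- 10
  for (s in 1:5) {
    sim <- simulate_smlm_localizations(roi, 300, 0.5, 3,
                                       localization_error_nm = sig, seed = s)
    px <- roi$pixel_size_nm
    # distance to nearest mask pixel centre, conservative by half a pixel
    idx <- which(roi$mask > 0, arr.ind = TRUE)
    ctr <- cbind((idx[, 2] - 0.5) * px, (idx[, 1] - 0.5) * px)
    dmax <- max(vapply(seq_len(nrow(sim$localizations)), function(i)
      min(sqrt((ctr[, 1] - sim$localizations$x_nm[i])^2 +
               (ctr[, 2] - sim$localizations$y_nm[i])^2)), numeric(1)))
    expect_lt(dmax, 4 * sig + px)
  }
})

test_that("profile generator hits its target mean and CV", {
  p0 <- simulate_profile(50, 80, 0, seed = 1)
  expect_true(all(p0$value == 80))

  p <- simulate_profile(1e4, 100, 0.5, seed = 2)
  expect_true(all(p$value > 0))
  cv <- sd(p$value) / mean(p$value)
  expect_lt(abs(cv - 0.5) / 0.5, 0.05)
  expect_lt(abs(mean(p$value) - 100) / 100, 0.05)

  expect_error(simulate_profile(5, 100, 0.1, seed = 1))
  expect_error(simulate_profile(100, -1, 0.1, seed = 1))
})

test_that("FRAP generator follows its closed form", {
  flat <- simulate_frap(mobile_fraction = 0, n_frames = 20)
  expect_true(all(flat$value[3:20] == 300))

  tr <- simulate_frap(i_pre = 1000, i_post = 300, mobile_fraction = 0.7,
                      k_rec = 0.02, n_frames = 80, dt = 10, n_prebleach = 2)
  plateau <- 300 + 0.7 * (1000 - 300)
  expect_equal(tail(tr$value, 1), plateau, tolerance = 1e-5)
  expect_true(all(tr$value[1:2] == 1000))
  expect_error(simulate_frap(n_prebleach = 80, n_frames = 80), "n_prebleach")
  expect_error(simulate_frap(i_post = 2000))
})

test_that("raw SMLM frame generator emits spots, background and drift", {
  # no blinking: background only, so no pixel far above the background level
  bg <- simulate_raw_smlm_frames(matrix(c(2000, 2000), 1, 2),
                                 image_shape = c(32, 32), n_frames = 30,
                                 blink_rate = 0, background = 10, seed = 1)
  expect_lt(max(bg$stack$data), 40)
  expect_null(bg$truth$emissions)

  withdrift <- simulate_raw_smlm_frames(matrix(c(2000, 2000), 1, 2),
                                        image_shape = c(32, 32),
                                        n_frames = 30, blink_rate = 0.5,
                                        drift_px = c(3, -2), seed = 2)
  expect_equal(withdrift$truth$drift_px, c(3, -2))
  expect_equal(withdrift$truth$drift_start_frame, 16L)
  expect_gt(nrow(withdrift$truth$emissions), 0)
  expect_error(simulate_raw_smlm_frames(matrix(1, 1, 2), psf_sigma_px = 0,
                                        seed = 1))
})
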