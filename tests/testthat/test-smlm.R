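nm_cal <- pixel_calibration(100, 1, space_unit = "nm", time_unit = "s")

test_that("temporal median filter removes steady background, keeps spikes", {
  arr <- array(50, dim = c(9, 8, 8))
  st <- frame_stack(arr, nm_cal)
  out <- temporal_median_filter(st, 3)
  expect_true(all(out$data == 0))

  arr[5, 4, 4] <- 250   # single-frame transient
  spike <- temporal_median_filter(frame_stack(arr, nm_cal), 5)
  expect_equal(spike$data[5, 4, 4], 200)
  expect_equal(sum(spike$data != 0), 1)

  expect_error(temporal_median_filter(st, 4), "odd")
  expect_error(temporal_median_filter(st, 11), "odd|n_frames")
})

test_that("temporal median filter suppresses a drifting ramp background", {
  sim <- simulate_raw_smlm_frames(matrix(numeric(0), 0, 2),
                                  image_shape = c(32, 32), n_frames = 60,
                                  blink_rate = 0, background = 20,
                                  background_drift = 0.5, seed = 6)
  filt <- temporal_median_filter(sim$stack, 21)
  rms_in <- sqrt(mean(sim$stack$data^2))
  rms_out <- sqrt(mean(filt$data^2))
  expect_gt(rms_in / rms_out, 5)
})

test_that("Gaussian localization recovers sub-pixel spot positions", {
  zero <- frame_stack(array(0, dim = c(2, 16, 16)), nm_cal)
  expect_equal(nrow(gaussian_localize(zero, 10)), 0)

  arr <- array(0, dim = c(1, 32, 32))
  arr[1, , ] <- blob_image(c(32, 32), cbind(20.3, 11.7), sigma = 1.3,
                           amp = 100)
  st <- frame_stack(arr, nm_cal)
  loc <- gaussian_localize(st, 20)
  expect_equal(nrow(loc), 1)
  expect_lt(abs(loc$x_nm / 100 - 20.3), 0.05)
  expect_lt(abs(loc$y_nm / 100 - 11.7), 0.05)
  expect_gt(loc$sigma_nm, 0)

  # two spots 10 sigma apart stay separable
  arr2 <- array(0, dim = c(1, 32, 32))
  arr2[1, , ] <- blob_image(c(32, 32), rbind(c(8, 16), c(21, 16)),
                            sigma = 1.3, amp = 100)
  expect_equal(nrow(gaussian_localize(frame_stack(arr2, nm_cal), 20)), 2)
})

test_that("reconstruction kernels integrate to the localization count", {
  empty <- localization_table(numeric(0), numeric(0), integer(0), numeric(0))
  expect_true(all(render_reconstruction(empty)$image == 0))

  one <- localization_table(500, 400, 1L, 15)
  img <- render_reconstruction(one, render_pixel_nm = 10)
  expect_equal(sum(img$image), 1, tolerance = 1e-3)
  pk <- which(img$image == max(img$image), arr.ind = TRUE)
  pk_x <- img$origin_nm[1] + (pk[2] - 0.5) * 10
  pk_y <- img$origin_nm[2] + (pk[1] - 0.5) * 10
  expect_lte(abs(pk_x - 500), 5)   # within half a render pixel
  expect_lte(abs(pk_y - 400), 5)

  set.seed(13)
  many <- localization_table(runif(50, 0, 2000), runif(50, 0, 2000),
                             1:50, runif(50, 5, 30))
  total <- sum(render_reconstruction(many, 20)$image)
  expect_lt(abs(total - 50) / 50, 0.001)
})

test_that("drift correction recovers injected shifts and is idempotent", {
  roi <- disc_roi_mask(1000, 10)
  sim <- simulate_smlm_localizations(roi, 1000, 0.6, 3, seed = 3)
  locs <- sim$localizations
  half <- locs$frame > nrow(locs) / 2
  px <- 20
  locs$x_nm[half] <- locs$x_nm[half] + 3 * px
  locs$y_nm[half] <- locs$y_nm[half] - 2 * px

  dc <- drift_correct(locs, n_blocks = 2, render_pixel_nm = px)
  expect_lt(abs(dc$drift$dx_nm[2] / px - 3), 0.5)
  expect_lt(abs(dc$drift$dy_nm[2] / px + 2), 0.5)

  # drift-free input: estimated shift below half a render pixel
  d0 <- drift_correct(sim$localizations, 2, px)
  expect_lt(max(abs(c(d0$drift$dx_nm[2], d0$drift$dy_nm[2]))) / px, 0.5)

  # second pass on corrected data finds (almost) nothing
  d2 <- drift_correct(dc$localizations, 2, px)
  expect_lt(max(abs(c(d2$drift$dx_nm[2], d2$drift$dy_nm[2]))) / px, 0.15)
})

test_that("mean NN distance and local density match brute-force oracles", {
  two <- rbind(c(0, 0), c(3, 0))
  expect_equal(mean_nn_distance(two), 3)
  square <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(mean_nn_distance(square), 1)
  expect_error(mean_nn_distance(rbind(c(1, 1))), "2 points")

  expect_equal(local_density(two, radius = 15), c(1L, 1L))
  iso <- rbind(c(0, 0), c(1, 0), c(100, 100))
  expect_equal(local_density(iso, radius = 5), c(1L, 1L, 0L))
  # closed ball: a tie at exactly the radius counts
  expect_equal(local_density(two, radius = 3), c(1L, 1L))

  set.seed(7)
  pts <- cbind(runif(200, 0, 500), runif(200, 0, 500))
  expect_identical(mean_nn_distance(pts), oracle_mean_nn(pts))
  r <- 5 * mean_nn_distance(pts)
  expect_identical(local_density(pts, r), oracle_local_density(pts, r))
})

test_that("density-threshold clustering finds planted clusters only", {
  set.seed(19)
  sparse <- cbind(runif(60, 0, 2000), runif(60, 0, 2000))
  dens <- local_density(sparse, 5 * mean_nn_distance(sparse))
  cl <- cluster_molecules(sparse, dens, density_threshold = 40,
                          link_radius = 5 * mean_nn_distance(sparse))
  expect_equal(nrow(cl$clusters), 0)
  expect_true(all(cl$labels == -1L))

  roi <- disc_roi_mask(1000, 10)
  hits <- vapply(1:25, function(s) {
    sim <- simulate_smlm_localizations(roi, 250, 0.6, 3,
                                       cluster_allocation = "equal",
                                       seed = s)
    pts <- cbind(sim$localizations$x_nm, sim$localizations$y_nm)
    r <- 5 * mean_nn_distance(pts)
    cl <- cluster_molecules(pts, local_density(pts, r), 40, r, 3)
    nrow(cl$clusters)
  }, numeric(1))
  expect_gte(mean(hits == 3), 0.95)
  # cluster members all exceed the density threshold
  sim <- simulate_smlm_localizations(roi, 250, 0.6, 3,
                                     cluster_allocation = "equal", seed = 1)
  pts <- cbind(sim$localizations$x_nm, sim$localizations$y_nm)
  r <- 5 * mean_nn_distance(pts)
  dens <- local_density(pts, r)
  cl <- cluster_molecules(pts, dens, 40, r, 3)
  expect_true(all(dens[cl$labels > 0] > 40))
})

test_that("per-aggregate metrics: density arithmetic and count filters", {
  # square ROI of exactly 1 um^2 (100 x 100 px at 10 nm) with 100 molecules
  mask <- matrix(0L, 120, 120); mask[11:110, 11:110] <- 1L
  set.seed(2)
  n <- 100
  locs <- localization_table(runif(n, 110, 1090), runif(n, 110, 1090),
                             1:n, rep(10, n))
  cfg <- default_config()$smlm
  cfg$min_localizations <- 10
  m <- suppressMessages(aggregate_metrics(locs, list(mask = mask,
                                                     pixel_size_nm = 10),
                                          cfg))
  expect_equal(m$per_aggregate$area_um2, 1)
  expect_equal(m$per_aggregate$density_per_um2, 100)

  # aggregates below the localization floor are skipped with a message
  expect_message(
    m2 <- aggregate_metrics(locs[1:99, ],
                            list(mask = mask, pixel_size_nm = 10)),
    "skipped")
  expect_equal(nrow(m2$per_aggregate), 0)
})

test_that("no clusters are reported when nothing is clustered", {
  roi <- disc_roi_mask(1000, 10)
  zeros <- vapply(1:25, function(s) {
    sim <- simulate_smlm_localizations(roi, 250, 0, 0, seed = s)
    m <- suppressMessages(aggregate_metrics(sim$localizations, roi))
    m$per_aggregate$n_clusters
  }, numeric(1))
  expect_gte(mean(zeros == 0), 0.95)
})

test_that("the analysis is equivariant under coordinate scaling", {
  roi <- disc_roi_mask(1000, 10)
  sim <- simulate_smlm_localizations(roi, 250, 0.6, 3, seed = 23)
  pts <- cbind(sim$localizations$x_nm, sim$localizations$y_nm)
  analyse <- function(p) {
    r <- 5 * mean_nn_distance(p)
    dens <- local_density(p, r)
    list(dens = dens,
         labels = cluster_molecules(p, dens, 40, r, 3)$labels)
  }
  a <- analyse(pts)
  b <- analyse(pts * 2)
  expect_identical(a$dens, b$dens)
  expect_identical(a$labels, b$labels)
  expect_equal(mean_nn_distance(pts * 2), 2 * mean_nn_distance(pts),
               tolerance = 1e-12)
})

test_that("mean local density rises with the planted clustered fraction", {
  roi <- disc_roi_mask(1000, 10)
  mean_d <- vapply(c(0, 0.3, 0.6, 0.9), function(f) {
    mean(vapply(1:10, function(s) {
      sim <- simulate_smlm_localizations(roi, 250, f,
                                         n_clusters = if (f > 0) 3 else 0,
                                         seed = 400 + s)
      pts <- cbind(sim$localizations$x_nm, sim$localizations$y_nm)
      mean(local_density(pts, 5 * mean_nn_distance(pts)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_d) > 0))
})
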