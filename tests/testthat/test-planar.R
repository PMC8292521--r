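# Planar quantification and the hybrid SPECT-anchored calibration.

test_that("conjugate-view geometric mean cancels source depth exactly", {
  # point source at several depths inside a uniform slab: the
  # anterior/posterior attenuation factors multiply to exp(-mu L)
  n <- 21
  mu <- array(0, c(n, n, n))
  mu[11, 4:17, 11] <- 0.15          # 14-voxel slab
  L <- 14
  geom <- acquisition_geometry(n_views = 2, orbit_radius = 30,
                               seconds_per_view = 1)
  geom$angles <- c(0, 180)
  for (depth in c(5, 9, 14)) {
    act <- array(0, c(n, n, n)); act[11, depth, 11] <- 1
    p <- forward_project(act, mu, geom, collimator_response(0, 0), 1)
    gm <- sqrt(sum(p[, , 1]) * sum(p[, , 2]))
    expect_equal(gm * exp(0.15 * L / 2), 1, tolerance = 1e-10)
  }
})

test_that("corrected counts vanish when kidney ROI matches background", {
  # flat planar pair: per-pixel background mean equals the kidney ROI mean,
  # so the background subtraction removes everything
  n <- 24
  flat <- matrix(50, n, n)
  pl <- structure(list(counts = list(anterior = flat, posterior = flat),
                       scatter = list(anterior = flat * 0,
                                      posterior = flat * 0),
                       duration = 100, time_post_injection = 3,
                       voxel_size = 1, T_phys = 6,
                       sensitivity_cpm_per_mbq = 5005),
                  class = "planar_image")
  k <- matrix(FALSE, n, n); k[8:12, 8:14] <- TRUE
  b <- matrix(FALSE, n, n); b[18:22, 4:20] <- TRUE
  rois <- list(kidney = list(anterior = k, posterior = k),
               background = list(anterior = b, posterior = b))
  expect_equal(corrected_kidney_counts(pl, rois, 14), 0)
  # disjointness and empty-background guards
  rois_bad <- rois; rois_bad$background$anterior <- k
  expect_error(corrected_kidney_counts(pl, rois_bad, 14), "disjoint")
  rois_empty <- rois; rois_empty$background$anterior[] <- FALSE
  expect_error(corrected_kidney_counts(pl, rois_empty, 14), "empty")
})

test_that("corrected counts ignore a uniform additive offset", {
  ph <- tiny_phantom()
  rois <- planar_roi_from_phantom(ph)
  pl <- simulate_planar(ph, 5005, 3, noise = FALSE)
  r0 <- corrected_kidney_counts(pl, rois, 14)
  pl2 <- pl
  pl2$counts$anterior <- pl$counts$anterior + 7
  pl2$counts$posterior <- pl$counts$posterior + 7
  r1 <- corrected_kidney_counts(pl2, rois, 14)
  expect_equal(r1, r0, tolerance = 1e-6)
})

test_that("hybrid calibration is a ratio and round-trips at the anchor", {
  cal <- hybrid_calibrate(1000, 25, anchor_time = 3)
  expect_equal(cal$factor, 0.025)
  expect_equal(apply_calibration(cal, 1000), 25)
  expect_error(hybrid_calibrate(0, 25), "positive")
  expect_error(hybrid_calibrate(1000, -2), "positive")
})

test_that("hybrid chain recovers a second time point within 10%", {
  ph <- make_phantom(grid_shape = c(48, 48, 48), voxel_size = 0.75)
  rois <- planar_roi_from_phantom(ph)
  L <- 2 * 8 * sqrt(1 - (3.5 / 10)^2)   # body chord at the kidney centres
  anchor_t <- 3; second_t <- 5
  pl1 <- simulate_planar(ph, 5005, anchor_t, noise = TRUE, seed = 1)
  pl2 <- simulate_planar(ph, 5005, second_t, noise = TRUE, seed = 2)
  r1 <- corrected_kidney_counts(pl1, rois, L)
  r2 <- corrected_kidney_counts(pl2, rois, L)
  cal <- hybrid_calibrate(r1, phantom_kidney_activity(ph, anchor_t), anchor_t)
  est <- apply_calibration(cal, r2)
  truth2 <- phantom_kidney_activity(ph, second_t)
  expect_equal(est, truth2, tolerance = 0.10)
})
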