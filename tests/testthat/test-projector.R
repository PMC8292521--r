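# Forward/adjoint projection model: geometry, attenuation, response.

test_that("a unit voxel projects to a single bin at quarter-turn views", {
  n <- 16
  act <- array(0, c(n, n, n))
  act[5, 7, 9] <- 2.5
  geom <- acquisition_geometry(n_views = 4, orbit_radius = 20,
                               seconds_per_view = 1)
  p <- forward_project(act, NULL, geom, collimator_response(0, 0), 1)
  for (v in 1:4) {
    pv <- p[, , v]
    expect_equal(sum(pv > 1e-9), 1)
    expect_equal(max(pv), 2.5, tolerance = 1e-9)
  }
  # anterior view: u = x, v = z
  expect_equal(p[5, 9, 1], 2.5, tolerance = 1e-12)
})

test_that("attenuation follows Beer-Lambert through a uniform slab", {
  n <- 21
  act <- array(0, c(n, n, n)); mu <- array(0, c(n, n, n))
  act[11, 3, 11] <- 1
  mu[11, 4:13, 11] <- 0.15       # 10 voxels of 1 cm behind the source
  geom <- acquisition_geometry(n_views = 1, orbit_radius = 30,
                               seconds_per_view = 1)
  p <- forward_project(act, mu, geom, collimator_response(0, 0), 1)
  expect_equal(p[11, 11, 1], exp(-1.5), tolerance = 1e-12)
  # half-voxel convention: attenuating from inside the slab counts half of
  # the voxel holding the source
  act2 <- array(0, c(n, n, n)); act2[11, 4, 11] <- 1
  p2 <- forward_project(act2, mu, geom, collimator_response(0, 0), 1)
  expect_equal(p2[11, 11, 1], exp(-0.15 * 9.5), tolerance = 1e-12)
})

test_that("projection is linear in the volume", {
  set.seed(5)
  n <- 16
  x <- array(runif(n^3), c(n, n, n))
  y <- array(runif(n^3), c(n, n, n))
  mu <- array(0.1 * (runif(n^3) > 0.5), c(n, n, n))
  geom <- acquisition_geometry(n_views = 5, orbit_radius = 18,
                               seconds_per_view = 1)
  r <- collimator_response(0.4, 0.03)
  pa <- forward_project(2 * x + 3 * y, mu, geom, r, 1)
  pb <- 2 * forward_project(x, mu, geom, r, 1) +
        3 * forward_project(y, mu, geom, r, 1)
  expect_equal(pa, pb, tolerance = 1e-10)
})

test_that("back projection is the exact adjoint of forward projection", {
  set.seed(9)
  n <- 20
  ph <- tiny_phantom(n = 20, voxel = 1.4)
  geom <- dmsapk:::resolve_geometry(acquisition_geometry(n_views = 7), ph)
  r <- collimator_response(0.3, 0.03)
  for (rep in 1:3) {
    x <- array(runif(n^3), c(n, n, n))
    y <- array(runif(n * n * 7), c(n, n, 7))
    lhs <- sum(forward_project(x, ph$mu, geom, r, 1.4) * y)
    rhs <- sum(x * back_project(y, ph$mu, geom, r, 1.4))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  # zero projections give a zero volume
  z <- back_project(array(0, c(n, n, 3)), NULL,
                    acquisition_geometry(n_views = 3, orbit_radius = 20,
                                         seconds_per_view = 1),
                    collimator_response(0, 0), 1.4)
  expect_true(all(z == 0))
})

test_that("projection conserves counts without attenuation or blur", {
  ph <- tiny_phantom()
  geom <- dmsapk:::resolve_geometry(acquisition_geometry(n_views = 12), ph)
  p <- forward_project(ph$activity, NULL, geom, collimator_response(0, 0),
                       ph$voxel_size)
  sums <- apply(p, 3, sum)
  expect_equal(sums, rep(100, 12), tolerance = 1e-8)
  # blur kernels are normalised, so the response does not change totals
  pb <- forward_project(ph$activity, NULL, geom, collimator_response(0.5, 0.05),
                        ph$voxel_size)
  expect_equal(apply(pb, 3, sum), rep(100, 12), tolerance = 1e-6)
})

test_that("back projection of ones is positive inside the field of view", {
  ph <- tiny_phantom()
  geom <- dmsapk:::resolve_geometry(acquisition_geometry(n_views = 8), ph)
  s <- back_project(array(1, c(24, 24, 8)), NULL, geom,
                    collimator_response(0, 0), ph$voxel_size)
  expect_true(all(s[ph$body_mask] > 0))
  expect_true(all(s >= 0))
})

test_that("collimator response width grows with distance", {
  r <- collimator_response(0.2, 0.02)
  d <- seq(0, 40, by = 5)
  s <- response_sigma(r, d)
  expect_true(all(diff(s) >= 0))
  expect_equal(s[1], 0.2)
  expect_equal(response_sigma(r, 10), sqrt(0.2^2 + 0.2^2))
  expect_error(collimator_response(-1, 0), "sigma0|>= 0")
})
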