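# OS-EM reconstruction: convergence, invariances, subset handling.

test_that("angular striding builds balanced deterministic subsets", {
  s <- dmsapk:::osem_subsets(120, 16)
  expect_length(s, 16)
  sizes <- lengths(s)
  expect_true(all(sizes %in% c(7, 8)))
  expect_equal(sum(sizes), 120)
  expect_equal(sort(unlist(s)), 1:120)
  expect_identical(s, dmsapk:::osem_subsets(120, 16))
  expect_error(dmsapk:::osem_subsets(10, 11), "between")
})

test_that("all-zero projections reconstruct to an all-zero image", {
  ph <- tiny_phantom(n = 16, voxel = 1.6)
  proj <- simulate_acquisition(ph, acquisition_geometry(n_views = 4), 5005, 3,
                               noise = FALSE)
  proj$counts$photopeak[] <- 0
  proj$expected$scatter_in_photopeak[] <- 0
  img <- reconstruct_osem(proj, true_mu_map(ph), n_iterations = 1,
                          n_subsets = 2)
  expect_true(all(img$data == 0))
})

test_that("MLEM on noise-free data converges to the kidney truth", {
  ph <- tiny_phantom()
  r <- collimator_response(0.2, 0.02)
  proj <- simulate_acquisition(ph, acquisition_geometry(n_views = 16), 5005, 3,
                               noise = FALSE, response = r)
  img <- reconstruct_osem(proj, true_mu_map(ph), response = r,
                          n_iterations = 250, n_subsets = 1)
  truth <- phantom_kidney_activity(ph, 3)
  kmask <- ph$left_kidney_mask | ph$right_kidney_mask
  expect_equal(sum(img$data[kmask]), truth, tolerance = 0.03)
  expect_true(all(img$data >= 0))
})

test_that("Poisson log-likelihood is non-decreasing for 1-subset EM", {
  ph <- tiny_phantom(n = 16, voxel = 1.6)
  r <- collimator_response(0.2, 0.02)
  geom <- acquisition_geometry(n_views = 8)
  proj <- simulate_acquisition(ph, geom, 5005, 3, noise = FALSE, response = r)
  lls <- vapply(c(1, 3, 6, 10), function(ni) {
    img <- reconstruct_osem(proj, true_mu_map(ph), response = r,
                            n_iterations = ni, n_subsets = 1)
    fp <- forward_project(img$data, ph$mu, proj$geometry, r,
                          ph$voxel_size) *
      proj$sensitivity_cpm_per_mbq / 60 * geom$seconds_per_view +
      proj$expected$scatter_in_photopeak
    dmsapk:::poisson_loglik(proj$counts$photopeak, fp)
  }, numeric(1))
  expect_true(all(diff(lls) > -1e-6 * abs(lls[1])))
})

test_that("OS-EM with several subsets stays close to the kidney truth", {
  ph <- tiny_phantom()
  r <- collimator_response(0.2, 0.02)
  proj <- simulate_acquisition(ph, acquisition_geometry(n_views = 16), 5005, 3,
                               noise = FALSE, response = r)
  img <- reconstruct_osem(proj, true_mu_map(ph), response = r,
                          n_iterations = 5, n_subsets = 8)
  truth <- phantom_kidney_activity(ph, 3)
  kmask <- ph$left_kidney_mask | ph$right_kidney_mask
  expect_equal(sum(img$data[kmask]), truth, tolerance = 0.06)
})

test_that("scaling the data scales the reconstruction", {
  ph <- tiny_phantom(n = 16, voxel = 1.6)
  proj <- simulate_acquisition(ph, acquisition_geometry(n_views = 8), 5005, 3,
                               noise = TRUE, seed = 3)
  proj2 <- proj
  proj2$counts$photopeak <- proj$counts$photopeak * 5
  proj2$expected$scatter_in_photopeak <-
    proj$expected$scatter_in_photopeak * 5
  i1 <- reconstruct_osem(proj, true_mu_map(ph), n_iterations = 2,
                         n_subsets = 4)
  i2 <- reconstruct_osem(proj2, true_mu_map(ph), n_iterations = 2,
                         n_subsets = 4)
  expect_equal(i2$data, 5 * i1$data, tolerance = 1e-8)
})
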