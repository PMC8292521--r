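# Median regression: exactness, L1 optimality, equivariance, bootstrap.

test_that("noise-free group medians are recovered exactly", {
  d <- data.frame(female = rep(c(0, 1), c(17, 60)))
  d$y <- 0.3 + 0.064 * d$female
  fit <- median_regression(y ~ female, d, n_boot = 0)
  expect_equal(unname(coef(fit)), c(0.3, 0.064), tolerance = 1e-9)
  expect_lt(fit$objective, 1e-9)
})

test_that("solver objective matches the brute-force L1 oracle on small data", {
  set.seed(14)
  for (rep in 1:60) {
    n <- sample(4:8, 1)
    p <- sample(2:3, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
    y <- rnorm(n)
    fit_obj <- dmsapk:::.rho_tau(
      y - X %*% dmsapk:::.rq_solve(X, y), 0.5)
    expect_equal(fit_obj, bruteforce_l1_objective(X, y),
                 tolerance = 1e-8)
  }
})

test_that("L1 objective never exceeds the least-squares solution's", {
  set.seed(3)
  for (rep in 1:20) {
    n <- 40
    X <- cbind(1, rnorm(n), runif(n))
    y <- X %*% c(1, 2, -1) + rt(n, df = 3)
    b_l1 <- dmsapk:::.rq_solve(X, y)
    b_ls <- qr.solve(X, y)
    expect_lte(dmsapk:::.rho_tau(y - X %*% b_l1, 0.5),
               dmsapk:::.rho_tau(y - X %*% b_ls, 0.5) + 1e-10)
  }
})

test_that("coefficients are scale/shift equivariant", {
  set.seed(8)
  d <- data.frame(x = rnorm(60))
  d$y <- 0.2 + 0.5 * d$x + rnorm(60, 0, 0.1)
  f0 <- median_regression(y ~ x, d, n_boot = 0)
  d2 <- d; d2$y <- 3 * d$y + 1
  f1 <- median_regression(y ~ x, d2, n_boot = 0)
  expect_equal(unname(coef(f1)),
               unname(c(3 * coef(f0)[1] + 1, 3 * coef(f0)[2])),
               tolerance = 1e-7)
  # per-5-kg convention: rescaling the covariate rescales its coefficient
  d3 <- d; d3$x <- d$x / 5
  f2 <- median_regression(y ~ x, d3, n_boot = 0)
  expect_equal(unname(coef(f2)[2]), unname(5 * coef(f0)[2]),
               tolerance = 1e-7)
})

test_that("rank-deficient designs are rejected naming the column", {
  d <- data.frame(y = rnorm(20), a = rnorm(20))
  d$b <- 2 * d$a
  expect_error(median_regression(y ~ a + b, d, n_boot = 0),
               "collinear.*b")
})

test_that("bootstrap inference is seeded and brackets the estimate", {
  set.seed(31)
  d <- data.frame(female = rep(c(0, 1), c(17, 60)))
  d$y <- 0.3 + 0.064 * d$female + rnorm(77, 0, 0.05)
  f1 <- median_regression(y ~ female, d, n_boot = 150, seed = 9)
  f2 <- median_regression(y ~ female, d, n_boot = 150, seed = 9)
  expect_identical(f1$boot, f2$boot)
  expect_true(all(f1$ci[, 1] <= coef(f1) + 1e-9))
  expect_true(all(f1$ci[, 2] >= coef(f1) - 1e-9))
  expect_lt(f1$p_value["female"], 0.05)
})

test_that("covariate analysis flags only the simulated sex effect", {
  # cohort with a sex effect and no age/weight effect
  rec <- sample_cohort(cohort_spec(seed = 12, between_patient_cv = 0.15,
                                   measurement_cv = 0.1))
  res <- run_covariate_regression(rec, n_boot = 300, seed = 2)
  uni <- res$univariate; multi <- res$multivariable
  expect_true(multi$significant[multi$term == "Female"])
  expect_gt(multi$coefficient[multi$term == "Female"], 0)
  expect_false(multi$significant[multi$term == "Age (per year)"])
  expect_true(all(uni$ci_low <= uni$coefficient + 1e-9))
  expect_true(all(uni$ci_high >= uni$coefficient - 1e-9))
  # null cohort: all CIs cover zero effects
  rec0 <- sample_cohort(cohort_spec(seed = 13, sex_uptake_offset = 0,
                                    between_patient_cv = 0.15,
                                    measurement_cv = 0.1))
  res0 <- run_covariate_regression(rec0, n_boot = 300, seed = 3)
  m0 <- res0$multivariable
  expect_true(all(m0$ci_low <= 0 & m0$ci_high >= 0))
})
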