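# Biokinetic model evaluation, closed-form TIAC and model comparison.

test_that("decay factor matches the closed form", {
  expect_identical(decay_factor(0), 1)
  expect_equal(decay_factor(6, 6), 0.5)
  expect_equal(decay_factor(3, 6), 2^-0.5)
  expect_equal(decay_factor(c(0, 6, 12)), c(1, 0.5, 0.25))
  expect_error(decay_factor(-1), "negative")
  expect_error(decay_factor(1, 0), "positive")
})

test_that("model_fraction evaluates the two-exponential pediatric model", {
  m <- eq_pediatric()
  expect_equal(model_fraction(m, 0), 0.3 * (1.2 - 1))
  expect_equal(model_fraction(m, 1.1), 0.3 * (1.2 - 0.5))
  expect_equal(model_fraction(m, 1e9), 0.36, tolerance = 1e-12)
  # vectorised and consistent with manual evaluation
  t <- c(0.5, 2, 4.7)
  expect_equal(model_fraction(m, t),
               0.3 * (1.2 - exp(-log(2) * t / 1.1)))
  expect_error(model_fraction(m, -0.1), "non-negative")
})

test_that("model constructor enforces its invariants", {
  expect_error(biokinetic_model(1.2, 1, 1), "F_S")
  expect_error(biokinetic_model(0.5, c(-1, 1), 1), "length")
  expect_error(biokinetic_model(0.5, 1, -2), "positive")
  expect_error(biokinetic_model(0.5, c(-1, 0.5), c(1, Inf)), "non-negative")
  # validate = FALSE admits transient fit results
  m <- biokinetic_model(0.5, c(-1, 0.5), c(1, Inf), validate = FALSE)
  expect_s3_class(m, "biokinetic_model")
})

test_that("closed-form TIAC reproduces the published model values", {
  expect_equal(round(tiac(eq_adult())$value, 2), 3.71)
  expect_equal(round(tiac(eq_pediatric())$value, 1), 2.7)
  # degenerate closed forms
  expect_equal(tiac(biokinetic_model(0, numeric(0), numeric(0)))$value, 0)
  expect_equal(tiac(biokinetic_model(0.4, 1, Inf))$value,
               0.4 * 6 / log(2))
})

test_that("closed-form TIAC agrees with adaptive quadrature on random models", {
  set.seed(7)
  for (i in 1:40) {
    Fs <- runif(1, 0.05, 1)
    T1 <- runif(1, 0.2, 5)
    a2 <- runif(1, 1, 3)
    T2 <- if (i %% 2) Inf else runif(1, 3, 50)
    m <- biokinetic_model(Fs, c(-1, a2), c(T1, T2))
    expect_equal(tiac(m)$value, tiac_quadrature(m), tolerance = 1e-6)
  }
})

test_that("TIAC is monotone in F_S and in the physical half-life", {
  m <- eq_pediatric()
  v <- vapply(seq(0.1, 0.9, by = 0.2), function(f)
    tiac(biokinetic_model(f, m$a, m$T_half))$value, numeric(1))
  expect_true(all(diff(v) > 0))
  v2 <- vapply(c(2, 4, 6, 8), function(Tp) tiac(m, Tp)$value, numeric(1))
  expect_true(all(diff(v2) > 0))
})

test_that("model fraction of the pediatric model stays within [0, plateau]", {
  m <- eq_pediatric()
  t <- seq(0, 50, by = 0.05)
  f <- model_fraction(m, t)
  expect_true(all(f >= 0))
  expect_true(all(f <= m$F_S * m$a[2] + 1e-12))
})

test_that("compare_models reports percent TIAC differences vs the reference", {
  models <- dmsa_models()
  cmp <- compare_models(models[c("icrp53", "current_study")])
  expect_equal(cmp$pct_vs_reference[cmp$model == "current_study"], -27)
  expect_equal(cmp$pct_vs_reference[cmp$model == "icrp53"], 0)
  # self-comparison is 0%
  cmp2 <- compare_models(list(icrp53 = models$icrp53, again = models$icrp53))
  expect_equal(cmp2$pct_vs_reference, c(0, 0))
  # the historical planar parameter set: closed form does not reproduce the
  # published 3 h value, and the table says so rather than hiding it
  cmp3 <- compare_models(models[c("icrp53", "evans")])
  ev <- cmp3[cmp3$model == "evans", ]
  expect_equal(ev$tiac_h, 1.3698, tolerance = 1e-4)
  expect_false(ev$closed_form_matches_printed)
  expect_error(compare_models(models[c("evans", "current_study")]),
               "reference")
})

test_that("model YAML round-trips including infinite half-times", {
  path <- tempfile(fileext = ".yaml")
  write_models_yaml(list(a = eq_pediatric(), b = eq_adult()), path)
  back <- read_models_yaml(path)
  expect_equal(back$a$T_half, c(1.1, Inf))
  expect_equal(back$a$F_S, 0.3)
  expect_equal(back$b$a, c(-1, 1))
})
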