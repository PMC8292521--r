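# Synthetic cohort generation with known ground-truth kinetics.

test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(n_patients = 10), "sex_counts")
  expect_error(cohort_spec(n_patients = 77, measurement_cv = -1), "CV")
  expect_error(cohort_spec(time_scheme = list(early = c(0.25, 1.5),
                                              clinical = c(1.9, 3.75),
                                              delayed = c(4, 7))),
               "0-6")
})

test_that("noise-free sampling reproduces the generating model exactly", {
  sp <- cohort_spec(between_patient_cv = 0, measurement_cv = 0,
                    sex_uptake_offset = 0, seed = 4)
  rec <- sample_cohort(sp)
  truth <- eq_pediatric()
  expect_lt(max(abs(rec$fraction - model_fraction(truth, rec$time_h))), 1e-12)
  expect_equal(rec$fraction, rec$fraction_true)
})

test_that("cohort sampling is reproducible from its seed", {
  a <- sample_cohort(cohort_spec(seed = 99))
  b <- sample_cohort(cohort_spec(seed = 99))
  expect_identical(a, b)
  c <- sample_cohort(cohort_spec(seed = 100))
  expect_false(identical(a$fraction, c$fraction))
})

test_that("cohort structure follows the imaging scheme", {
  rec <- sample_cohort(cohort_spec(seed = 2))
  expect_equal(length(unique(rec$patient_id)), 77)
  per_group <- table(rec$group[!duplicated(rec$patient_id)])
  expect_equal(as.numeric(per_group[c("retrospective", "prospective_early",
                                      "prospective_delayed")]),
               c(54, 13, 10))
  sexes <- table(rec$sex[!duplicated(rec$patient_id)])
  expect_equal(as.numeric(sexes[c("male", "female")]), c(17, 60))
  # one SPECT record per patient, at the clinical time window
  sp <- rec[rec$modality == "SPECT", ]
  expect_equal(nrow(sp), 77)
  expect_true(all(sp$time_h >= 1.9 & sp$time_h <= 3.75))
  # early/delayed planar points inside their windows
  early <- rec[rec$group == "prospective_early" & rec$modality == "planar", ]
  expect_true(all(early$time_h >= 0.25 & early$time_h <= 1.5))
  late <- rec[rec$group == "prospective_delayed" & rec$modality == "planar", ]
  expect_true(all(late$time_h >= 4 & late$time_h <= 6))
  expect_true(all(rec$fraction >= 0))
})

test_that("sample mean converges to the model value under measurement noise", {
  # 10,000 noisy draws at t = 3 h: law of large numbers against the
  # closed form 0.3 (1.2 - exp(-ln2 * 3 / 1.1))
  sp <- cohort_spec(n_patients = 10000,
                    sex_counts = c(male = 5000, female = 5000),
                    group_counts = c(retrospective = 10000,
                                     prospective_early = 0,
                                     prospective_delayed = 0),
                    between_patient_cv = 0, sex_uptake_offset = 0,
                    measurement_cv = 0.2,
                    time_scheme = list(early = c(0.25, 1.5),
                                       clinical = c(3, 3),
                                       delayed = c(4, 6)),
                    seed = 8)
  rec <- sample_cohort(sp)
  target <- 0.3 * (1.2 - exp(-log(2) * 3 / 1.1))
  expect_equal(mean(rec$fraction), target, tolerance = 0.01)
})

test_that("female plateau offset shifts uptake by the configured amount", {
  sp <- cohort_spec(between_patient_cv = 0, measurement_cv = 0, seed = 5)
  rec <- sample_cohort(sp)
  sp_rec <- rec[rec$modality == "SPECT", ]
  m <- eq_pediatric()
  male <- sp_rec[sp_rec$sex == "male", ]
  fem <- sp_rec[sp_rec$sex == "female", ]
  expect_equal(male$fraction, model_fraction(m, male$time_h), tolerance = 1e-12)
  # female records sit exactly 0.064 above the male curve (offset enters
  # the plateau term, constant in time)
  expect_equal(fem$fraction - model_fraction(m, fem$time_h),
               rep(0.064, nrow(fem)), tolerance = 1e-12)
})

test_that("cohort records round-trip through CSV", {
  rec <- sample_cohort(cohort_spec(seed = 3))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(rec, path)
  back <- read_cohort_csv(path)
  expect_equal(back$fraction, rec$fraction)
  expect_equal(back$sex, rec$sex)
})
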