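#' Specification of a synthetic patient cohort
#'
#' Defines the generating conditions for a synthetic pediatric cohort
#' whose true kidney kinetics follow a [biokinetic_model()] with
#' between-patient variability (lognormal multiplier on \code{F_S}), an
#' additive sex offset on the plateau uptake of female patients, and
#' multiplicative Gaussian measurement noise. Defaults mirror a 77-patient
#' pediatric DMSA cohort: 17 males / 60 females; 54 retrospective patients
#' with a single clinical-time SPECT, 13 prospective patients with an
#' additional early planar point (0.25-1.5 h) and 10 with a delayed planar
#' point (4-6 h); clinical imaging uniformly between 1.9 and 3.75 h; ages
#' lognormal with median 4 y; weight from a linear pediatric growth curve
#' with lognormal noise.
#'
#' @param n_patients Number of patients.
#' @param sex_counts Named vector \code{c(male=, female=)}, summing to
#'   \code{n_patients}.
#' @param group_counts Named vector \code{c(retrospective=,
#'   prospective_early=, prospective_delayed=)}, summing to
#'   \code{n_patients}.
#' @param truth_model Generating [biokinetic_model()].
#' @param sex_uptake_offset Additive offset on the plateau uptake
#'   (\code{F_S * a2}) of female patients.
#' @param between_patient_cv CV of the lognormal between-patient
#'   multiplier on \code{F_S} (>= 0).
#' @param measurement_cv CV of the multiplicative Gaussian measurement
#'   noise (>= 0).
#' @param age_sampler Function \code{n -> ages} in years.
#' @param weight_from_age Deterministic growth-curve map age -> kg.
#' @param weight_cv CV of the lognormal noise around the growth curve.
#' @param time_scheme List of sampling windows (h): \code{early},
#'   \code{clinical}, \code{delayed}; all within 0-6 h.
#' @param seed RNG seed; all cohort randomness flows from it.
#' @return Object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_patients = 77,
                        sex_counts = c(male = 17, female = 60),
                        group_counts = c(retrospective = 54,
                                         prospective_early = 13,
                                         prospective_delayed = 10),
                        truth_model = NULL,
                        sex_uptake_offset = 0.064,
                        between_patient_cv = 0.25,
                        measurement_cv = 0.2,
                        age_sampler = function(n)
                          pmin(pmax(rlnorm(n, log(4), 0.75), 0.3), 17),
                        weight_from_age = function(age) 8 + 2.35 * age,
                        weight_cv = 0.12,
                        time_scheme = list(early = c(0.25, 1.5),
                                           clinical = c(1.9, 3.75),
                                           delayed = c(4, 6)),
                        seed = 1) {
  if (is.null(truth_model))
    truth_model <- dmsa_models()$current_study
  if (sum(sex_counts) != n_patients)
    stop("sex_counts must sum to n_patients")
  if (sum(group_counts) != n_patients)
    stop("group_counts must sum to n_patients")
  if (between_patient_cv < 0 || measurement_cv < 0 || weight_cv < 0)
    stop("all CVs must be non-negative")
  for (w in time_scheme)
    if (min(w) < 0 || max(w) > 6)
      stop("sampling windows must lie within 0-6 h")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Sample a synthetic cohort of kidney uptake records
#'
#' Draws a cohort per the [cohort_spec()]: each patient receives sex,
#' group, age, weight, a personal biokinetic model (truth with \code{F_S}
#' scaled by a mean-one lognormal between-patient factor; plateau offset
#' added for females), one or two sampling times according to the group's
#' time scheme, and measured fractions
#' \code{true * (1 + Normal(0, measurement_cv))} truncated at 0.
#' Reproducible: identical specs (same seed) give identical records.
#'
#' @param spec A [cohort_spec()].
#' @return \code{data.frame} with columns \code{patient_id}, \code{age_y},
#'   \code{weight_kg}, \code{sex}, \code{group}, \code{modality},
#'   \code{time_h}, \code{fraction_true}, \code{fraction} (measured).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  with_seed(spec$seed, {
    sex <- sample(rep(c("male", "female"), times = spec$sex_counts))
    group <- sample(rep(names(spec$group_counts), times = spec$group_counts))
    age <- spec$age_sampler(n)
    sdw <- sqrt(log(1 + spec$weight_cv^2))
    weight <- spec$weight_from_age(age) * rlnorm(n, -sdw^2 / 2, sdw)
    sdb <- sqrt(log(1 + spec$between_patient_cv^2))
    fs_mult <- rlnorm(n, -sdb^2 / 2, sdb)
    tm <- spec$truth_model
    pid <- tim <- ftr <- vector("list", n)
    mod <- vector("list", n)
    for (i in seq_len(n)) {
      F_i <- min(tm$F_S * fs_mult[i], 1)
      a_i <- tm$a
      if (sex[i] == "female" && length(a_i) >= 2)
        a_i[2] <- a_i[2] + spec$sex_uptake_offset / F_i
      m_i <- biokinetic_model(F_i, a_i, tm$T_half)
      t_clin <- runif(1, spec$time_scheme$clinical[1],
                      spec$time_scheme$clinical[2])
      times <- t_clin
      modality <- "SPECT"
      if (group[i] == "prospective_early") {
        times <- c(runif(1, spec$time_scheme$early[1],
                         spec$time_scheme$early[2]), times)
        modality <- c("planar", modality)
      } else if (group[i] == "prospective_delayed") {
        times <- c(times, runif(1, spec$time_scheme$delayed[1],
                                spec$time_scheme$delayed[2]))
        modality <- c(modality, "planar")
      }
      pid[[i]] <- rep(i, length(times))
      tim[[i]] <- times
      mod[[i]] <- modality
      ftr[[i]] <- model_fraction(m_i, times)
    }
    pid <- unlist(pid); tim <- unlist(tim)
    ftr <- unlist(ftr); mod <- unlist(mod)
    f_meas <- pmax(ftr * (1 + rnorm(length(ftr), 0, spec$measurement_cv)), 0)
    data.frame(
      patient_id = pid, age_y = age[pid], weight_kg = weight[pid],
      sex = sex[pid], group = group[pid], modality = mod,
      time_h = tim, fraction_true = ftr, fraction = f_meas,
      stringsAsFactors = FALSE)
  })
}

#' Read/write cohort record tables as CSV
#'
#' @param records Cohort \code{data.frame} from [sample_cohort()].
#' @param path CSV file path.
#' @return \code{read_cohort_csv} returns the records \code{data.frame}.
#' @export
write_cohort_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
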