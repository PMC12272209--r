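# Configuration objects for the synthetic-cohort generator.

#' Cohort configuration
#'
#' Describes the population from which a synthetic two-timepoint cohort is
#' drawn: sample size, follow-up interval, predictor moments and their
#' correlations, and per-variable missingness rates. The defaults reproduce
#' the demographic structure of a population-based neuroimaging cohort of
#' older adults (age 63.2 +/- 8.94 y, DBP 76.3 +/- 9.33 mmHg,
#' WHR 0.941 +/- 0.0855, TIV 1.45e6 +/- 1.4e5 mm^3, 44.1% female).
#'
#' @param n_subjects number of subjects (>= 2); each contributes two rows.
#' @param seed integer seed governing all randomness of the generator.
#' @param followup_years_mean mean follow-up interval in years.
#' @param followup_years_sd SD of the interval (0 = fixed interval).
#' @param whr_scale nonnegative scaling of the waist-hip-ratio effect family
#'   (grid values 0.5, 1, 1.5 in the power study).
#' @param predictor_means,predictor_sds named numeric vectors with entries
#'   `age` (years), `bp` (mmHg), `whr` (ratio), `tiv` (mm^3).
#' @param predictor_cor 4x4 correlation matrix for (age, bp, whr, tiv);
#'   must be symmetric with unit diagonal and positive semidefinite.
#' @param female_fraction proportion of women in `[0, 1]`.
#' @param education_fraction proportion with tertiary education.
#' @param ht_base_rate,ht_fu_rate prevalence of antihypertensive medication
#'   at baseline and follow-up.
#' @param cesd_mu,cesd_size negative-binomial moments of the depression sum
#'   score (CES-D).
#' @param pulse_mean,pulse_sd pulse pressure (SBP - DBP) moments used to
#'   derive a systolic column from the generic `bp` column.
#' @param missingness_rates named vector of MCAR missingness probabilities
#'   for any of `education`, `tiv`, `dbp`, `whr`, `cesd`, `ht_med`.
#'
#' @return an object of class `wmh_cohort_config`.
#' @seealso [effect_config()], [simulate_cohort()]
#' @export
cohort_config <- function(n_subjects,
                          seed = 1L,
                          followup_years_mean = 6.76,
                          followup_years_sd = 0,
                          whr_scale = 1,
                          predictor_means = c(age = 63.2, bp = 76.3,
                                              whr = 0.941, tiv = 1.45e6),
                          predictor_sds = c(age = 8.94, bp = 9.33,
                                            whr = 0.0855, tiv = 1.4e5),
                          predictor_cor = default_predictor_cor(),
                          female_fraction = 0.441,
                          education_fraction = 0.528,
                          ht_base_rate = 0.439,
                          ht_fu_rate = 0.634,
                          cesd_mu = 6, cesd_size = 2,
                          pulse_mean = 50, pulse_sd = 10,
                          missingness_rates = numeric(0)) {
  stopifnot(length(n_subjects) == 1L, n_subjects >= 2)
  if (whr_scale < 0) stop("'whr_scale' must be nonnegative")
  if (female_fraction < 0 || female_fraction > 1)
    stop("'female_fraction' must be in [0, 1]")
  vars <- c("age", "bp", "whr", "tiv")
  if (!all(vars %in% names(predictor_means)) ||
      !all(vars %in% names(predictor_sds)))
    stop("'predictor_means'/'predictor_sds' need entries age, bp, whr, tiv")
  if (any(predictor_sds < 0)) stop("predictor SDs must be nonnegative")
  check_correlation_matrix(predictor_cor)
  ok_miss <- c("education", "tiv", "dbp", "whr", "cesd", "ht_med")
  if (length(missingness_rates) &&
      (!all(names(missingness_rates) %in% ok_miss) ||
       any(missingness_rates < 0 | missingness_rates > 1)))
    stop("'missingness_rates' must be named probabilities for ",
         paste(ok_miss, collapse = ", "))
  structure(list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    followup_years_mean = followup_years_mean,
    followup_years_sd = followup_years_sd,
    whr_scale = whr_scale,
    predictor_means = predictor_means[vars],
    predictor_sds = predictor_sds[vars],
    predictor_cor = predictor_cor,
    female_fraction = female_fraction,
    education_fraction = education_fraction,
    ht_base_rate = ht_base_rate, ht_fu_rate = ht_fu_rate,
    cesd_mu = cesd_mu, cesd_size = cesd_size,
    pulse_mean = pulse_mean, pulse_sd = pulse_sd,
    missingness_rates = missingness_rates
  ), class = "wmh_cohort_config")
}

#' @rdname cohort_config
#' @export
default_predictor_cor <- function() {
  r <- diag(4)
  dimnames(r) <- list(c("age", "bp", "whr", "tiv"),
                      c("age", "bp", "whr", "tiv"))
  r["age", "bp"] <- r["bp", "age"] <- 0.2
  r["age", "whr"] <- r["whr", "age"] <- 0.1
  r["bp", "whr"] <- r["whr", "bp"] <- 0.1
  r
}

check_correlation_matrix <- function(r) {
  if (!is.matrix(r) || nrow(r) != ncol(r))
    stop("correlation matrix must be square")
  if (max(abs(r - t(r))) > 1e-8) stop("correlation matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8)
    stop("correlation matrix must have unit diagonal")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation matrix is not positive semidefinite")
  invisible(TRUE)
}

#' Derived effect-size constants
#'
#' The longitudinal effect sizes of the power study are assembled from a
#' handful of published ingredients. This helper exposes that arithmetic:
#' the WHR-by-time interaction is the blood-pressure-by-time interaction
#' (0.0052 cm^3/y per mmHg) rescaled by the ratio of the cross-sectional
#' asinh-scale coefficients of WHR (0.84 per unit) and SBP (0.0083 per mmHg);
#' the mean SBP change is an annual drift of 0.76 mmHg/y over a 6.76-year
#' interval; the mean WHR change averages the published male/female 5-year
#' increases and rescales them to a 6-year horizon; and the confirmatory
#' two-sided alpha divides 0.05 across three one-sided hypotheses.
#'
#' @param bp_base_modifier blood-pressure-by-time interaction, cm^3/y per mmHg.
#' @param whr_coef_asinh,bp_coef_asinh cross-sectional asinh-scale coefficients.
#' @param sbp_annual_change annual SBP drift in mmHg/y.
#' @param followup_years follow-up interval used for the SBP change mean.
#' @param whr_5y_increase published 5-year WHR increases (men, women).
#' @param whr_horizon_years horizon the WHR change is rescaled to.
#'
#' @return named list with `whr_interaction` (cm^3/y per WHR unit),
#'   `bp_change_mean` (mmHg), `whr_change_mean` (WHR units) and
#'   `alpha_two_sided`.
#' @export
derived_effect_constants <- function(bp_base_modifier = 0.0052,
                                     whr_coef_asinh = 0.84,
                                     bp_coef_asinh = 0.0083,
                                     sbp_annual_change = 0.76,
                                     followup_years = 6.76,
                                     whr_5y_increase = c(0.0073, 0.0021),
                                     whr_horizon_years = 6) {
  list(
    whr_interaction = bp_base_modifier * whr_coef_asinh / bp_coef_asinh,
    bp_change_mean = sbp_annual_change * followup_years,
    whr_change_mean = mean(whr_5y_increase) / 5 * whr_horizon_years,
    alpha_two_sided = 2 * 0.05 / 3
  )
}

#' Generative effect configuration
#'
#' Constants of the generative model for longitudinal WMH volumes: the
#' cross-sectional Gamma/log-link coefficients, the normally distributed
#' per-subject longitudinal modifiers, the risk-factor change distributions,
#' and the error structure. Setting `whr_scale` scales the whole WHR effect
#' family (both the WHR-by-time interaction and the WHR-change effect).
#'
#' @param whr_scale nonnegative scaling of the WHR effect family.
#' @param cross_sectional named coefficient vector (`intercept`, `age`, `bp`,
#'   `whr`, `male`, `tiv`) of the log-link baseline model, cm^3 scale.
#' @param center_predictors logical; centre continuous predictors (and the
#'   male indicator) at their configured means inside the cross-sectional
#'   linear predictor so that the intercept is the log median volume.
#' @param center_modifiers logical; centre blood pressure and WHR at their
#'   configured means inside the longitudinal modifier terms, so that the
#'   time effect mean stays the marginal mean annual change (the modifiers
#'   then redistribute progression around it). Only the intercept-like part
#'   of the trajectory changes; the interaction coefficients are identical.
#' @param time_mean,time_sd,time_floor per-subject annual time effect
#'   (cm^3/y): normal draws, values below zero replaced by `time_floor`.
#' @param bp_base_mod_mean,bp_base_mod_sd per-subject modifier of the annual
#'   change per mmHg baseline blood pressure (cm^3/y/mmHg).
#' @param bp_change_eff_mean,bp_change_eff_sd effect of blood-pressure change
#'   on follow-up volume (cm^3 per mmHg).
#' @param whr_base_modifier WHR-by-time interaction (cm^3/y per WHR unit);
#'   default is the derived constant times `whr_scale`.
#' @param whr_change_effect effect of WHR change on follow-up volume
#'   (cm^3 per WHR unit); same scale family as `whr_base_modifier`.
#' @param bp_change_mean,bp_change_sd distribution of observed blood-pressure
#'   change (mmHg).
#' @param whr_change_mean,whr_change_sd distribution of observed WHR change.
#' @param random_intercept_sd,residual_sd error structure (cm^3).
#' @param baseline_mean_target expected baseline volume (cm^3) the
#'   cross-sectional intercept is anchored to (the printed coefficient set is
#'   scale-inconsistent with raw predictor units; anchoring the mean to the
#'   observed cohort value keeps the simulated volumes on the observed
#'   scale). `NULL` uses the intercept as given.
#'
#' @return an object of class `wmh_effect_config`.
#' @export
effect_config <- function(whr_scale = 1,
                          cross_sectional = c(intercept = 1.44, age = 0.067,
                                              bp = 0.011, whr = 2.15,
                                              male = -0.40, tiv = 2e-6),
                          center_predictors = TRUE,
                          center_modifiers = TRUE,
                          time_mean = 0.32, time_sd = 0.1, time_floor = 0.01,
                          bp_base_mod_mean = 0.0052, bp_base_mod_sd = 0.001,
                          bp_change_eff_mean = 0.0025,
                          bp_change_eff_sd = 0.001,
                          whr_base_modifier = NULL,
                          whr_change_effect = NULL,
                          bp_change_mean = NULL, bp_change_sd = 4,
                          whr_change_mean = NULL, whr_change_sd = 0.005,
                          random_intercept_sd = 0.5, residual_sd = 1.0,
                          baseline_mean_target = 1.88) {
  der <- derived_effect_constants()
  if (is.null(whr_base_modifier))
    whr_base_modifier <- der$whr_interaction * whr_scale
  if (is.null(whr_change_effect))
    whr_change_effect <- der$whr_interaction * whr_scale
  if (is.null(bp_change_mean)) bp_change_mean <- der$bp_change_mean
  if (is.null(whr_change_mean)) whr_change_mean <- der$whr_change_mean
  sds <- c(time_sd, bp_base_mod_sd, bp_change_eff_sd, bp_change_sd,
           whr_change_sd, random_intercept_sd, residual_sd)
  if (any(sds < 0)) stop("all SDs must be nonnegative")
  if (time_floor <= 0) stop("'time_floor' must be positive")
  need <- c("intercept", "age", "bp", "whr", "male", "tiv")
  if (!all(need %in% names(cross_sectional)))
    stop("'cross_sectional' needs coefficients ",
         paste(need, collapse = ", "))
  structure(list(
    whr_scale = whr_scale,
    cross_sectional = cross_sectional[need],
    center_predictors = isTRUE(center_predictors),
    center_modifiers = isTRUE(center_modifiers),
    time_mean = time_mean, time_sd = time_sd, time_floor = time_floor,
    bp_base_mod_mean = bp_base_mod_mean, bp_base_mod_sd = bp_base_mod_sd,
    bp_change_eff_mean = bp_change_eff_mean,
    bp_change_eff_sd = bp_change_eff_sd,
    whr_base_modifier = whr_base_modifier,
    whr_change_effect = whr_change_effect,
    bp_change_mean = bp_change_mean, bp_change_sd = bp_change_sd,
    whr_change_mean = whr_change_mean, whr_change_sd = whr_change_sd,
    random_intercept_sd = random_intercept_sd, residual_sd = residual_sd,
    baseline_mean_target = baseline_mean_target
  ), class = "wmh_effect_config")
}

#' Cognition link configuration
#'
#' Parameters of the cognition extension of the generator: latent executive,
#' processing-speed and memory domain scores decline with time and with the
#' standardized asinh-scale WMH change at slope `wmh_change_beta`, and raw
#' CERAD-plus test scores are derived from the latents by affine maps plus
#' noise so that the composite-score construction can recover them.
#'
#' @param wmh_change_beta standardized effect of WMH change on the change in
#'   global cognition (default -0.149).
#' @param drift mean annualized-free change of each latent domain between the
#'   two timepoints (SD units).
#' @param test_noise_sd named noise SDs for the raw tests (`tmt_a`, `ratio`,
#'   `fluency_phon`, `fluency_sem`, `wl_learning`, `wl_recall`,
#'   `wl_recognition`), in raw test units.
#' @param seed integer seed.
#' @return an object of class `wmh_cognition_link`.
#' @export
cognition_link_config <- function(wmh_change_beta = -0.149,
                                  drift = -0.1,
                                  test_noise_sd = c(tmt_a = 3, ratio = 0.15,
                                                    fluency_phon = 2,
                                                    fluency_sem = 2.5,
                                                    wl_learning = 1.5,
                                                    wl_recall = 1,
                                                    wl_recognition = 0.8),
                                  seed = 1L) {
  if (any(test_noise_sd < 0)) stop("noise SDs must be nonnegative")
  if (abs(wmh_change_beta) > 1)
    stop("'wmh_change_beta' is a standardized slope and must be in [-1, 1]")
  structure(list(wmh_change_beta = wmh_change_beta, drift = drift,
                 test_noise_sd = test_noise_sd, seed = as.integer(seed)),
            class = "wmh_cognition_link")
}

#' Read / write generator configurations
#'
#' Configurations serialize to YAML or JSON (chosen by file extension).
#'
#' @param config a `wmh_cohort_config` or `wmh_effect_config`.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x[[".class"]] <- class(config)[1L]
  # matrices are stored flat with their dimnames so both formats round-trip
  x <- lapply(x, function(v) {
    if (is.matrix(v))
      list(.matrix = TRUE, nrow = nrow(v), dimnames = rownames(v),
           values = as.numeric(v))
    else if (is.atomic(v) && !is.null(names(v)))
      as.list(v)                      # keep element names in both formats
    else v
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cls <- x[[".class"]]
  x[[".class"]] <- NULL
  x <- lapply(x, function(v) {
    if (is.list(v) && isTRUE(v$.matrix)) {
      nm <- unlist(v$dimnames)
      matrix(unlist(v$values), nrow = v$nrow, dimnames = list(nm, nm))
    } else if (is.list(v)) {
      unlist(v)
    } else v
  })
  x <- x[!vapply(x, is.null, TRUE)]
  maker <- switch(cls,
                  wmh_cohort_config = cohort_config,
                  wmh_effect_config = effect_config,
                  wmh_cognition_link = cognition_link_config,
                  stop("unknown configuration class: ", cls))
  do.call(maker, x)
}

#' @export
print.wmh_cohort_config <- function(x, ...) {
  cat("<wmh_cohort_config>\n")
  cat("  subjects:", x$n_subjects, " seed:", x$seed, "\n")
  cat(sprintf("  follow-up: %.2f y (sd %.2f), whr_scale: %g\n",
              x$followup_years_mean, x$followup_years_sd, x$whr_scale))
  cat(sprintf("  age %.1f+/-%.2f, bp %.1f+/-%.2f, whr %.3f+/-%.4f\n",
              x$predictor_means["age"], x$predictor_sds["age"],
              x$predictor_means["bp"], x$predictor_sds["bp"],
              x$predictor_means["whr"], x$predictor_sds["whr"]))
  invisible(x)
}

#' @export
print.wmh_effect_config <- function(x, ...) {
  cat("<wmh_effect_config>\n")
  cat(sprintf("  time effect %.3g +/- %.3g cm^3/y (floor %.3g)\n",
              x$time_mean, x$time_sd, x$time_floor))
  cat(sprintf("  bp x time %.4g, whr x time %.3g (whr_scale %g)\n",
              x$bp_base_mod_mean, x$whr_base_modifier, x$whr_scale))
  cat(sprintf("  random intercept sd %.3g, residual sd %.3g cm^3\n",
              x$random_intercept_sd, x$residual_sd))
  invisible(x)
}
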