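# Synthetic longitudinal WMH cohorts.

#' Draw baseline predictors
#'
#' Draws one row per subject: continuous predictors (age, blood pressure,
#' waist-hip ratio, intracranial volume) jointly multivariate normal with the
#' configured moments; gender, education, baseline antihypertensive
#' medication and the depression score drawn independently.
#'
#' @param config a [cohort_config()].
#' @return data frame with one row per subject: `subj_id`, `age_base`, `bp`,
#'   `whr`, `tiv`, `gender` (factor female/male), `education`, `ht_med_base`,
#'   `ht_med_fu`, `cesd_base`, `cesd_fu`, `pulse`, `followup_years`.
#' @export
draw_predictors <- function(config) {
  stopifnot(inherits(config, "wmh_cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  sds <- config$predictor_sds
  sigma <- diag(sds) %*% config$predictor_cor %*% diag(sds)
  x <- MASS::mvrnorm(n, mu = config$predictor_means, Sigma = sigma)
  x <- matrix(x, nrow = n, dimnames = list(NULL, names(config$predictor_means)))
  female <- rbinom(n, 1L, config$female_fraction)
  ht_base <- as.numeric(rbinom(n, 1L, config$ht_base_rate))
  # follow-up medication keeps baseline users and adds incident users so the
  # marginal prevalence matches ht_fu_rate
  p_inc <- max(0, min(1, (config$ht_fu_rate - config$ht_base_rate) /
                        max(1e-12, 1 - config$ht_base_rate)))
  ht_fu <- ifelse(ht_base == 1, 1, rbinom(n, 1L, p_inc))
  fu_years <- config$followup_years_mean +
    if (config$followup_years_sd > 0) rnorm(n, 0, config$followup_years_sd) else 0
  fu_years <- pmax(fu_years, 0.5)
  data.frame(
    subj_id = seq_len(n),
    age_base = x[, "age"],
    bp = x[, "bp"],
    whr = x[, "whr"],
    tiv = x[, "tiv"],
    gender = factor(ifelse(female == 1L, "female", "male"),
                    levels = c("female", "male")),
    education = as.numeric(rbinom(n, 1L, config$education_fraction)),
    ht_med_base = ht_base,
    ht_med_fu = ht_fu,
    cesd_base = as.numeric(rnbinom(n, mu = config$cesd_mu,
                                   size = config$cesd_size)),
    cesd_fu = as.numeric(rnbinom(n, mu = config$cesd_mu,
                                 size = config$cesd_size)),
    pulse = pmax(rnorm(n, config$pulse_mean, config$pulse_sd), 5),
    followup_years = fu_years
  )
}

#' Simulate longitudinal WMH trajectories
#'
#' Builds the long cohort table from drawn predictors. Baseline volume is the
#' exponential of the cross-sectional linear predictor; the follow-up volume
#' adds an annual change composed of a per-subject time effect and
#' blood-pressure / WHR modifiers of that change, plus effects of observed
#' risk-factor change, a subject random intercept and per-occasion residual
#' noise. Per-subject time-effect draws below zero are replaced by the
#' configured floor, and volumes are clipped at zero.
#'
#' @param predictors output of [draw_predictors()].
#' @param effects an [effect_config()].
#' @param config the [cohort_config()] used for the draws.
#' @return a long cohort data frame (two rows per subject, class
#'   `wmh_cohort`), columns documented in [simulate_cohort()].
#' @export
simulate_wmh_trajectories <- function(predictors, effects, config) {
  stopifnot(inherits(effects, "wmh_effect_config"))
  need <- c("subj_id", "age_base", "bp", "whr", "tiv", "gender",
            "followup_years")
  miss <- setdiff(need, names(predictors))
  if (length(miss))
    stop("predictor table is missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(predictors)
  set.seed(config$seed + 1L)

  cf <- effects$cross_sectional
  male <- as.numeric(predictors$gender == "male")
  if (effects$center_predictors) {
    mu <- config$predictor_means
    lp <- cf["intercept"] +
      cf["age"] * (predictors$age_base - mu["age"]) +
      cf["bp"] * (predictors$bp - mu["bp"]) +
      cf["whr"] * (predictors$whr - mu["whr"]) +
      cf["male"] * (male - (1 - config$female_fraction)) +
      cf["tiv"] * (predictors$tiv - mu["tiv"])
  } else {
    lp <- cf["intercept"] + cf["age"] * predictors$age_base +
      cf["bp"] * predictors$bp + cf["whr"] * predictors$whr +
      cf["male"] * male + cf["tiv"] * predictors$tiv
  }
  if (effects$center_predictors && !is.null(effects$baseline_mean_target)) {
    # lognormal-correction anchor: shift the intercept so the expected
    # baseline volume matches the target mean under the configured moments
    sds <- config$predictor_sds
    sigma_c <- diag(sds) %*% config$predictor_cor %*% diag(sds)
    cvec <- cf[c("age", "bp", "whr", "tiv")]
    var_cont <- as.numeric(t(cvec) %*% sigma_c %*% cvec)
    pm <- 1 - config$female_fraction
    gf <- pm * exp(cf["male"] * (1 - pm)) + (1 - pm) * exp(-cf["male"] * pm)
    e0 <- exp(cf["intercept"] + var_cont / 2) * gf
    lp <- lp + log(effects$baseline_mean_target) - log(e0)
  }
  wmh_bl_det <- exp(as.numeric(lp))

  time_draw <- rnorm(n, effects$time_mean, effects$time_sd)
  time_draw[time_draw < 0] <- effects$time_floor
  bp_mod <- rnorm(n, effects$bp_base_mod_mean, effects$bp_base_mod_sd)
  bp_change_eff <- rnorm(n, effects$bp_change_eff_mean, effects$bp_change_eff_sd)
  bp_change <- rnorm(n, effects$bp_change_mean, effects$bp_change_sd)
  whr_change <- rnorm(n, effects$whr_change_mean, effects$whr_change_sd)
  ranef <- rnorm(n, 0, effects$random_intercept_sd)
  resid_bl <- rnorm(n, 0, effects$residual_sd)
  resid_fu <- rnorm(n, 0, effects$residual_sd)

  dt <- predictors$followup_years
  bp_ctr <- if (effects$center_modifiers)
    predictors$bp - config$predictor_means["bp"] else predictors$bp
  whr_ctr <- if (effects$center_modifiers)
    predictors$whr - config$predictor_means["whr"] else predictors$whr
  delta <- (time_draw + bp_mod * bp_ctr +
              effects$whr_base_modifier * whr_ctr) * dt +
    bp_change * bp_change_eff +
    whr_change * effects$whr_change_effect

  wmh_bl <- pmax(wmh_bl_det + ranef + resid_bl, 0)
  wmh_fu <- pmax(wmh_bl_det + delta + ranef + resid_fu, 0)

  row_tmpl <- predictors[rep(seq_len(n), 2L), c("subj_id", "age_base",
                                                "gender", "tiv", "education")]
  out <- data.frame(
    row_tmpl,
    time = rep(c(0L, 1L), each = n),
    age_change = rep(c(0, 1), each = n) * rep(dt, 2L),
    dbp = c(predictors$bp, predictors$bp + bp_change),
    whr = c(predictors$whr, predictors$whr + whr_change),
    cesd = c(predictors$cesd_base, predictors$cesd_fu),
    ht_med = c(predictors$ht_med_base, predictors$ht_med_fu),
    wmh_vol = c(wmh_bl, wmh_fu),
    row.names = NULL
  )
  out$sbp <- out$dbp + rep(predictors$pulse, 2L)
  out <- out[order(out$subj_id, out$time), ]
  rownames(out) <- NULL
  attr(out, "truth") <- list(wmh_bl_det = wmh_bl_det, delta = delta,
                             time_draw = time_draw, bp_mod = bp_mod,
                             bp_change_eff = bp_change_eff,
                             bp_change = bp_change, whr_change = whr_change)
  class(out) <- c("wmh_cohort", "data.frame")
  out
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: [draw_predictors()] then
#' [simulate_wmh_trajectories()], optionally [attach_cognition()] and
#' [apply_plausibility_and_missingness()].
#'
#' @param config a [cohort_config()].
#' @param effects an [effect_config()]; by default built with the config's
#'   `whr_scale`.
#' @param cognition `NULL`, or a [cognition_link_config()] to generate raw
#'   cognitive test scores.
#' @param apply_missingness apply plausibility rules and the configured MCAR
#'   missingness.
#' @return long cohort data frame of class `wmh_cohort`: two rows per subject
#'   (`time` 0/1) with `subj_id`, `age_base`, `age_change` (0 at baseline,
#'   elapsed years at follow-up), `gender`, `dbp`, `sbp` (mmHg), `whr`,
#'   `tiv` (mm^3), `education`, `cesd`, `ht_med`, `wmh_vol` (cm^3) and, with
#'   a cognition link, raw test scores `tmt_a`, `tmt_b` (s), `fluency_phon`,
#'   `fluency_sem`, `wl_learning`, `wl_recall`, `wl_recognition` (counts).
#' @export
simulate_cohort <- function(config, effects = effect_config(config$whr_scale),
                            cognition = NULL, apply_missingness = FALSE) {
  pred <- draw_predictors(config)
  cohort <- simulate_wmh_trajectories(pred, effects, config)
  if (!is.null(cognition)) cohort <- attach_cognition(cohort, cognition)
  if (apply_missingness)
    cohort <- apply_plausibility_and_missingness(cohort, config)
  cohort
}

#' Attach raw cognitive test scores
#'
#' Generates latent executive, processing-speed and memory domain scores that
#' decline between the timepoints, with the change in the latent global score
#' (the mean of the three domains) linked to the standardized asinh-scale WMH
#' change at slope `wmh_change_beta` and unit variance. Raw CERAD-plus test
#' scores are affine in the latents plus configured noise, so that
#' [composite_scores()] inverts the construction.
#'
#' @param cohort a `wmh_cohort` with WMH volumes at both timepoints.
#' @param link a [cognition_link_config()].
#' @return the cohort with raw test columns added; latent scores are kept in
#'   `attr(, "cognition_truth")`.
#' @export
attach_cognition <- function(cohort, link) {
  stopifnot(inherits(link, "wmh_cognition_link"))
  set.seed(link$seed)
  wide <- cohort_wide_volumes(cohort)
  n <- nrow(wide)
  dw <- asinh(wide$wmh_fu) - asinh(wide$wmh_bl)
  zw <- if (sd(dw) > 0) (dw - mean(dw)) / sd(dw) else dw * 0
  beta <- link$wmh_change_beta
  doms <- c("exec", "speed", "memory")
  u <- rnorm(n, 0, sqrt(0.6))                       # shared ability
  base <- sapply(doms, function(d) u + rnorm(n, 0, sqrt(0.4)))
  eta_sd <- sqrt(3 * (1 - beta^2))                  # Var(mean eta) = 1 - beta^2
  delta <- sapply(doms, function(d)
    link$drift + beta * zw + rnorm(n, 0, eta_sd))
  fu <- base + delta

  ns <- link$test_noise_sd
  mk <- function(lat_bl, lat_fu, a, b, nm, floor = NULL) {
    v <- c(a + b * lat_bl + rnorm(n, 0, ns[[nm]]),
           a + b * lat_fu + rnorm(n, 0, ns[[nm]]))
    if (!is.null(floor)) v <- pmax(v, floor)
    v
  }
  tmt_a <- mk(base[, "speed"], fu[, "speed"], 40, -8, "tmt_a", floor = 5)
  ratio <- pmax(c(2.5 - 0.35 * base[, "exec"] + rnorm(n, 0, ns[["ratio"]]),
                  2.5 - 0.35 * fu[, "exec"] + rnorm(n, 0, ns[["ratio"]])), 1.05)
  add <- data.frame(
    subj_id = rep(wide$subj_id, 2L),
    time = rep(c(0L, 1L), each = n),
    tmt_a = tmt_a,
    tmt_b = ratio * tmt_a,
    fluency_phon = mk(base[, "exec"], fu[, "exec"], 15, 4, "fluency_phon", 0),
    fluency_sem = mk(base[, "exec"], fu[, "exec"], 22, 5, "fluency_sem", 0),
    wl_learning = mk(base[, "memory"], fu[, "memory"], 20, 3, "wl_learning", 0),
    wl_recall = mk(base[, "memory"], fu[, "memory"], 7, 1.5, "wl_recall", 0),
    wl_recognition = mk(base[, "memory"], fu[, "memory"], 18, 1.5,
                        "wl_recognition", 0)
  )
  idx <- match(paste(cohort$subj_id, cohort$time),
               paste(add$subj_id, add$time))
  stopifnot(!anyNA(idx))
  out <- cbind(cohort, add[idx, -(1:2), drop = FALSE])
  rownames(out) <- NULL
  attr(out, "truth") <- attr(cohort, "truth")
  attr(out, "cognition_truth") <- list(
    base = base, fu = fu, zw = zw,
    global_bl = rowMeans(base), global_fu = rowMeans(fu))
  class(out) <- c("wmh_cohort", "data.frame")
  out
}

#' Plausibility screening and missingness injection
#'
#' Applies the biological plausibility rules — WHR outside `[0.5, 1.5]`,
#' diastolic pressure above 140 mmHg, systolic below diastolic (two
#' independent flags) — setting offending cells missing, then injects MCAR
#' missingness at the configured per-variable rates. Subjects missing WHR or
#' DBP at both timepoints are flagged for exclusion (not removed).
#'
#' @param cohort a `wmh_cohort`.
#' @param config the [cohort_config()] holding `missingness_rates`.
#' @return the cohort with logical columns `implausible_whr`,
#'   `implausible_dbp_high`, `implausible_bp_order` (per row) and `exclude`
#'   (per subject, repeated on both rows).
#' @export
apply_plausibility_and_missingness <- function(cohort, config) {
  set.seed(config$seed + 2L)
  out <- as.data.frame(cohort)
  out$implausible_whr <- !is.na(out$whr) & (out$whr < 0.5 | out$whr > 1.5)
  out$implausible_dbp_high <- !is.na(out$dbp) & out$dbp > 140
  out$implausible_bp_order <- !is.na(out$dbp) & !is.na(out$sbp) &
    out$sbp < out$dbp
  out$whr[out$implausible_whr] <- NA_real_
  out$dbp[out$implausible_dbp_high | out$implausible_bp_order] <- NA_real_
  out$sbp[out$implausible_bp_order] <- NA_real_

  rates <- config$missingness_rates
  for (v in names(rates)) {
    if (rates[[v]] <= 0) next
    hit <- runif(nrow(out)) < rates[[v]]
    if (v %in% c("education", "tiv")) {
      # subject-level variables go missing for the whole subject
      subj_hit <- unique(out$subj_id[hit])
      out[[v]][out$subj_id %in% subj_hit] <- NA
    } else {
      out[[v]][hit] <- NA
    }
  }
  both_missing <- function(v) {
    tapply(is.na(out[[v]]), out$subj_id, all)
  }
  excl <- both_missing("whr") | both_missing("dbp")
  out$exclude <- as.logical(excl[as.character(out$subj_id)])
  attr(out, "truth") <- attr(cohort, "truth")
  class(out) <- c("wmh_cohort", "data.frame")
  out
}

cohort_wide_volumes <- function(cohort) {
  bl <- cohort[cohort$time == 0L, c("subj_id", "wmh_vol")]
  fu <- cohort[cohort$time == 1L, c("subj_id", "wmh_vol")]
  names(bl)[2] <- "wmh_bl"; names(fu)[2] <- "wmh_fu"
  m <- merge(bl, fu, by = "subj_id")
  if (nrow(m) != nrow(bl)) stop("cohort must have two rows per subject")
  m[order(m$subj_id), ]
}

#' Read / write long cohort tables
#'
#' Cohorts are plain delimited text (CSV) with one row per
#' subject-by-timepoint; the column dictionary is documented in
#' [simulate_cohort()].
#'
#' @param cohort a `wmh_cohort` data frame.
#' @param path CSV file path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- read.csv(path)
  if (!is.null(out$gender))
    out$gender <- factor(out$gender, levels = c("female", "male"))
  class(out) <- c("wmh_cohort", "data.frame")
  out
}

#' @export
print.wmh_cohort <- function(x, ...) {
  ns <- length(unique(x$subj_id))
  cat(sprintf("<wmh_cohort> %d subjects x 2 timepoints (%d rows)\n",
              ns, nrow(x)))
  v0 <- x$wmh_vol[x$time == 0L]
  v1 <- x$wmh_vol[x$time == 1L]
  cat(sprintf("  WMH volume (cm^3): baseline %.2f [median %.2f], follow-up %.2f\n",
              mean(v0, na.rm = TRUE), median(v0, na.rm = TRUE),
              mean(v1, na.rm = TRUE)))
  print(head(as.data.frame(x), 4L))
  invisible(x)
}
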