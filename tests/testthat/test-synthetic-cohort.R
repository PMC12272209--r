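# generative cohort model: predictor draws, trajectories, cognition link,
# plausibility screening

test_that("predictor draws match the configured moments at large n", {
  cfg <- cohort_config(1e5, seed = 11)
  pred <- draw_predictors(cfg)
  expect_equal(mean(pred$age_base), 63.2, tolerance = 0.1 / 63.2)
  expect_lt(abs(mean(pred$whr) - 0.941), 0.002)
  expect_lt(abs(sd(pred$bp) - 9.33), 0.1)
  expect_lt(abs(mean(pred$gender == "female") - 0.441), 0.01)
  expect_lt(abs(cor(pred$age_base, pred$bp) - 0.2), 0.02)
})

test_that("degenerate draws and determinism behave as contracted", {
  cfg0 <- cohort_config(20, seed = 5,
                        predictor_sds = c(age = 0, bp = 0, whr = 0, tiv = 0))
  pred <- draw_predictors(cfg0)
  expect_true(all(pred$age_base == 63.2))
  expect_true(all(pred$bp == 76.3))

  cfg <- cohort_config(50, seed = 7)
  expect_identical(draw_predictors(cfg), draw_predictors(cfg))
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- cohort_config(50, seed = 8)
  expect_false(identical(simulate_cohort(cfg), simulate_cohort(cfg2)))

  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(cohort_config(10, predictor_cor = bad), "positive semidefinite")
})

test_that("zero-effect trajectories leave follow-up equal to baseline", {
  cfg <- cohort_config(40, seed = 3)
  coh <- simulate_cohort(cfg, effects = null_effects())
  wide <- merge(coh[coh$time == 0, c("subj_id", "wmh_vol")],
                coh[coh$time == 1, c("subj_id", "wmh_vol")], by = "subj_id")
  expect_equal(wide$wmh_vol.x, wide$wmh_vol.y, tolerance = 1e-12)
})

test_that("a pinned single-subject trajectory matches the hand evaluation", {
  cfg <- cohort_config(2, seed = 1, female_fraction = 1,
                       predictor_sds = c(age = 0, bp = 0, whr = 0, tiv = 0))
  eff <- effect_config(time_sd = 0, bp_base_mod_sd = 0, bp_change_eff_sd = 0,
                       bp_change_sd = 0, whr_change_sd = 0,
                       random_intercept_sd = 0, residual_sd = 0,
                       baseline_mean_target = NULL)
  coh <- simulate_cohort(cfg, effects = eff)
  der <- derived_effect_constants()
  bl_hand <- exp(1.44)                       # all centred predictors at 0
  delta_hand <- 0.32 * 6.76 +                # modifiers centred -> 0
    der$bp_change_mean * 0.0025 +
    der$whr_change_mean * der$whr_interaction
  expect_equal(coh$wmh_vol[coh$time == 0][1], bl_hand, tolerance = 1e-10)
  expect_equal(coh$wmh_vol[coh$time == 1][1], bl_hand + delta_hand,
               tolerance = 1e-10)
})

test_that("the mean annual change reproduces the time-effect constant", {
  cfg <- cohort_config(1e4, seed = 13)
  eff <- effect_config(time_mean = 0.32, time_sd = 0,
                       bp_base_mod_mean = 0, bp_base_mod_sd = 0,
                       bp_change_eff_mean = 0, bp_change_eff_sd = 0,
                       whr_base_modifier = 0, whr_change_effect = 0,
                       random_intercept_sd = 0, residual_sd = 0)
  coh <- simulate_cohort(cfg, effects = eff)
  ann <- (coh$wmh_vol[coh$time == 1] - coh$wmh_vol[coh$time == 0]) / 6.76
  expect_equal(mean(ann), 0.32, tolerance = 0.01)
})

test_that("baseline volume increases with age, all else fixed", {
  cfg <- cohort_config(5, seed = 2, female_fraction = 1,
                       predictor_sds = c(age = 0, bp = 0, whr = 0, tiv = 0))
  pred <- draw_predictors(cfg)
  pred$age_base <- c(50, 55, 60, 70, 80)
  coh <- simulate_wmh_trajectories(pred, null_effects(), cfg)
  bl <- coh$wmh_vol[coh$time == 0][order(unique(coh$subj_id))]
  expect_true(all(diff(bl[order(pred$age_base)]) > 0))
})

test_that("a Gamma log-link fit to generated baselines recovers the coefficients", {
  cfg <- cohort_config(1e5, seed = 17)
  eff <- effect_config(random_intercept_sd = 0.1, residual_sd = 0.1)
  coh <- simulate_cohort(cfg, effects = eff)
  bl <- coh[coh$time == 0 & coh$wmh_vol > 0, ]
  bl$male <- as.numeric(bl$gender == "male")
  mu <- cfg$predictor_means
  fit <- stats::glm(wmh_vol ~ I(age_base - mu["age"]) + I(dbp - mu["bp"]) +
                      I(whr - mu["whr"]) + male + I(tiv - mu["tiv"]),
                    family = stats::Gamma(link = "log"), data = bl)
  est <- coef(fit); se <- sqrt(diag(vcov(fit)))
  truth <- c(NA, 0.067, 0.011, 2.15, -0.40, 2e-6)  # intercept is re-anchored
  # the Gamma quasi-likelihood SE understates the sampling error under the
  # additive-noise mechanism, so allow a small relative slack on top
  for (j in 2:6)
    expect_lt(abs(est[j] - truth[j]),
              3 * se[j] + 0.005 * abs(truth[j]))
})

test_that("the cognition link recovers its standardized slope and nulls cleanly", {
  # null link: no association between WMH change and score change
  coh0 <- simulate_cohort(cohort_config(5000, seed = 19),
                          cognition = noise_free_link(beta = 0, seed = 3))
  m0 <- prepare_model_frame(coh0)
  dz <- m0$z_global[m0$time == 1] - m0$z_global[m0$time == 0]
  zw <- m0$wmh_change[m0$time == 1]
  expect_lt(abs(cor(dz, zw)), 3 / sqrt(5000))

  # configured link: regression recovers the slope within 2 SE
  coh1 <- simulate_cohort(cohort_config(5000, seed = 23),
                          cognition = cognition_link_config(seed = 5))
  m1 <- prepare_model_frame(coh1)
  dz1 <- m1$z_global[m1$time == 1] - m1$z_global[m1$time == 0]
  zw1 <- as.numeric(scale(m1$wmh_change[m1$time == 1]))
  sl <- summary(lm(dz1 ~ zw1))$coefficients
  expect_lt(abs(sl[2, 1] - (-0.149)), 2 * sl[2, 2] + 0.02)

  # determinism
  link <- cognition_link_config(seed = 9)
  c1 <- simulate_cohort(cohort_config(50, seed = 4), cognition = link)
  c2 <- simulate_cohort(cohort_config(50, seed = 4), cognition = link)
  expect_identical(c1$tmt_a, c2$tmt_a)
})

test_that("plausibility rules flag and blank cells, and exclusion is subject-level", {
  cfg <- cohort_config(6, seed = 31)
  coh <- simulate_cohort(cfg)
  coh$whr[coh$subj_id == 1 & coh$time == 0] <- 1.6
  coh$dbp[coh$subj_id == 2 & coh$time == 1] <- 150
  coh$sbp[coh$subj_id == 2 & coh$time == 1] <- 140
  coh$dbp[coh$subj_id == 3] <- NA
  out <- apply_plausibility_and_missingness(coh, cfg)

  r1 <- out$subj_id == 1 & out$time == 0
  expect_true(out$implausible_whr[r1])
  expect_true(is.na(out$whr[r1]))
  expect_false(any(out$exclude[out$subj_id == 1]))   # retained

  r2 <- out$subj_id == 2 & out$time == 1
  expect_true(out$implausible_dbp_high[r2])
  expect_true(out$implausible_bp_order[r2])
  expect_true(is.na(out$dbp[r2]))

  expect_true(all(out$exclude[out$subj_id == 3]))    # DBP missing at both
})

test_that("MCAR missingness respects configured rates", {
  cfg <- cohort_config(2000, seed = 37,
                       missingness_rates = c(dbp = 0.2, cesd = 0.1))
  coh <- simulate_cohort(cfg, apply_missingness = TRUE)
  expect_lt(abs(mean(is.na(coh$dbp)) - 0.2), 0.03)
  expect_lt(abs(mean(is.na(coh$cesd)) - 0.1), 0.02)
  expect_false(anyNA(coh$whr))
})

test_that("cohort tables round-trip through CSV", {
  coh <- small_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$wmh_vol, coh$wmh_vol)
  expect_identical(levels(back$gender), levels(coh$gender))
})

test_that("configurations round-trip through YAML and JSON", {
  cfg <- cohort_config(25, seed = 3, whr_scale = 1.5,
                       missingness_rates = c(dbp = 0.1))
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_config(cfg, path)
    back <- read_config(path)
    expect_equal(back$n_subjects, cfg$n_subjects)
    expect_equal(back$predictor_cor, cfg$predictor_cor)
    expect_equal(back$missingness_rates, cfg$missingness_rates)
  }
})
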