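# influence, stability, collinearity, robustness, residual checks

test_that("constructed outliers are flagged and symmetric data are not", {
  coh <- small_cohort()
  mfr <- prepare_model_frame(coh)
  spec <- build_model_spec("M1")
  fit <- fit_lmm(mfr, spec)

  # a subject shifted by ~50 outcome SDs must dominate Cook's distance
  mfr2 <- mfr
  shift <- 50 * sd(mfr$asinh_wmh)
  mfr2$asinh_wmh[mfr2$subj_id == 7] <- mfr2$asinh_wmh[mfr2$subj_id == 7] + shift
  fit2 <- fit_lmm(mfr2, spec)
  inf2 <- influential_cases(fit2, mfr2)
  expect_true("7" %in% inf2$influential)
  expect_equal(unname(which.max(inf2$cooks_distance)),
               which(names(inf2$cooks_distance) == "7"))

  # refit route agrees on the flagged subject
  inf_r <- influential_cases(fit2, mfr2, method = "refit")
  expect_true("7" %in% inf_r$influential)

  # degenerate threshold: nothing can exceed mean + 1e9 SDs
  expect_equal(influential_cases(fit, mfr,
                                 threshold_sd = 1e9)$influential,
               character(0))
  expect_error(influential_cases(fit, mfr[mfr$subj_id %in% 1:2, ]),
               "at least 3")
})

test_that("leave-one-subject-out ranges contain the full-data estimate", {
  coh <- simulate_cohort(cohort_config(25, seed = 81))
  mfr <- prepare_model_frame(coh)
  spec <- build_model_spec("M1")
  st <- loo_stability(mfr, spec)
  expect_equal(st$n_refits, 25)
  tol <- 1e-6 + 0.05 * abs(st$range$full)
  expect_true(all(st$range$full >= st$range$min - tol &
                    st$range$full <= st$range$max + tol))
})

test_that("VIF is exact for orthogonal and collinear designs and scale-invariant", {
  set.seed(3)
  n <- 64
  # columns orthogonal to each other and to the intercept
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))
  d <- data.frame(subj_id = 1:n, a = Q[, 2], b = Q[, 3], c = Q[, 4])
  sp <- toy_spec("a", c("b", "c"))
  v <- variance_inflation(d, sp)
  expect_equal(as.numeric(v), c(1, 1), tolerance = 1e-8)

  d$c2 <- d$b + rnorm(n, 0, 1e-4)
  v2 <- variance_inflation(d, toy_spec("a", c("b", "c2")))
  expect_true(all(v2 > 100))

  # affine rescaling leaves VIF unchanged
  d2 <- d; d2$b <- 100 + 7 * d2$b
  v3 <- variance_inflation(d2, toy_spec("a", c("b", "c")))
  expect_equal(as.numeric(v3), as.numeric(v), tolerance = 1e-8)

  expect_error(variance_inflation(d, toy_spec("a", "b")), "at least 2")
})

test_that("the robust refit keeps valid weights and resists contamination", {
  spec <- build_model_spec("M1")
  # near-linear regime: symmetric normal errors, so Huber weighting should
  # leave the estimates essentially unchanged
  cfg <- cohort_config(80, seed = 83,
                       predictor_sds = c(age = 0.9, bp = 0.93,
                                         whr = 0.009, tiv = 1.4e4))
  coh <- simulate_cohort(cfg, effects = effect_config(baseline_mean_target = NULL))
  mfr <- prepare_model_frame(coh)

  rob <- robust_refit(mfr, spec)
  expect_true(all(rob$weights > 0 & rob$weights <= 1))
  std <- fit_lmm(mfr, spec)
  row_r <- coef_row(rob, "bp_base:age_change")
  row_s <- coef_row(std, "bp_base:age_change")
  expect_lt(abs(row_r$estimate - row_s$estimate), 0.5 * row_s$se)

  # 5% gross outliers: the robust slope stays closer to the clean fit
  wins <- vapply(1:10, function(s) {
    coh_s <- simulate_cohort(cohort_config(60, seed = 200 + s))
    m <- prepare_model_frame(coh_s)
    clean <- coef_row(fit_lmm(m, spec), "bp_base:age_change")$estimate
    m_bad <- m
    set.seed(s)
    bad <- sample(nrow(m_bad), round(0.05 * nrow(m_bad)))
    m_bad$asinh_wmh[bad] <- m_bad$asinh_wmh[bad] + 15
    e_std <- coef_row(fit_lmm(m_bad, spec), "bp_base:age_change")$estimate
    e_rob <- coef_row(robust_refit(m_bad, spec), "bp_base:age_change")$estimate
    abs(e_rob - clean) <= abs(e_std - clean)
  }, logical(1))
  expect_gte(mean(wins), 0.7)
})

test_that("residual diagnostics report both levels and detect raw-scale skew", {
  spec <- build_model_spec("M1")
  coh <- simulate_cohort(cohort_config(150, seed = 87))
  mfr <- prepare_model_frame(coh)

  rep_asinh <- residual_diagnostics(fit_lmm(mfr, spec))
  expect_true(is.list(rep_asinh$residual_normality))
  expect_true(is.list(rep_asinh$ranef_normality))
  expect_true(is.numeric(rep_asinh$heteroscedasticity$slope))

  # untransformed volumes have skewed residuals
  rep_raw <- residual_diagnostics(
    fit_lmm(mfr, spec, outcome_scale = "raw_volume"))
  expect_lt(rep_raw$residual_normality$p, 0.01)
  expect_false(rep_raw$residual_normality$normal)

  # plot file is written when requested
  png_path <- withr::local_tempfile(fileext = ".png")
  residual_diagnostics(fit_lmm(mfr, spec), plot_file = png_path)
  expect_true(file.exists(png_path))
})

test_that("normality is rarely rejected on well-specified fits", {
  spec <- build_model_spec("M1")
  rejections <- vapply(1:30, function(s) {
    # near-linear regime (small predictor spread) so the volume-scale
    # model is well specified and its errors exactly normal
    cfg <- cohort_config(60, seed = 300 + s,
                         predictor_sds = c(age = 0.9, bp = 0.93,
                                           whr = 0.009, tiv = 1.4e4))
    coh <- simulate_cohort(cfg, effects = effect_config(baseline_mean_target = NULL))
    m <- prepare_model_frame(coh)
    # fit on the volume scale where the generative errors are exactly normal
    d <- residual_diagnostics(fit_lmm(m, spec, outcome_scale = "raw_volume"))
    !d$residual_normality$normal
  }, logical(1))
  expect_lte(mean(rejections), 0.15)
})
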