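# predictor matrix, multilevel chained-equation imputation, pooling, D1

test_that("the predictor matrix encodes the designed relations", {
  pm <- build_predictor_matrix()
  expect_equal(sort(colnames(pm)[pm["education", ]]),
               sort(c("subj_id", "age", "gender")))
  ht <- colnames(pm)[pm["ht_med", ]]
  expect_true(all(c("dbp", "whr") %in% ht))
  expect_false(any(c("education", "tiv", "cesd") %in% ht))
  expect_true(all(c("subj_id", "time", "age", "gender", "education",
                    "whr", "cesd", "ht_med") %in%
                    colnames(pm)[pm["dbp", ]]))
  shared <- intersect(rownames(pm), colnames(pm))
  for (v in shared) expect_false(pm[v, v])      # nothing predicts itself
  # subject-level rows exclude time-varying predictors
  for (v in c("education", "tiv"))
    expect_false(any(pm[v, c("time", "dbp", "whr", "cesd", "ht_med")]))
})

test_that("a complete cohort passes through imputation untouched", {
  coh <- small_cohort()
  imp <- multiply_impute(coh, m = 3, iterations = 2, seed = 5)
  expect_equal(imp$m, 3)
  for (d in imp$imputations) expect_equal(d$dbp, coh$dbp)
  expect_false(any(imp$mask))
})

test_that("imputation fills all holes, preserves observed cells and masks round-trip", {
  cfg <- cohort_config(150, seed = 51,
                       missingness_rates = c(dbp = 0.2, whr = 0.1,
                                             education = 0.1, tiv = 0.1,
                                             cesd = 0.15, ht_med = 0.1))
  coh <- simulate_cohort(cfg, apply_missingness = TRUE)
  imp <- multiply_impute(coh, m = 3, iterations = 3, seed = 6)
  for (v in colnames(imp$mask)) {
    obs <- !imp$mask[, v]
    expect_true(any(imp$mask[, v]))
    for (d in imp$imputations) {
      expect_false(anyNA(d[[v]]))
      expect_identical(d[[v]][obs], coh[[v]][obs])
    }
  }
  expect_equal(imp$mask[, "dbp"], is.na(coh$dbp))

  # serialization round-trip
  dir <- withr::local_tempdir()
  write_imputed_set(imp, dir)
  back <- read_imputed_set(dir)
  expect_equal(back$m, 3)
  expect_equal(back$imputations[[2]]$dbp, imp$imputations[[2]]$dbp)

  # a fully missing variable is an error
  coh2 <- coh; coh2$cesd <- NA
  expect_error(multiply_impute(coh2, seed = 1), "no observed values")
})

test_that("imputation recovers the complete-data blood-pressure mean under MCAR", {
  cfg <- cohort_config(400, seed = 53)
  coh <- simulate_cohort(cfg)
  full_mean <- mean(coh$dbp)
  set.seed(9)
  holes <- runif(nrow(coh)) < 0.2
  cohm <- coh; cohm$dbp[holes] <- NA
  imp <- multiply_impute(cohm, m = 5, iterations = 5, seed = 10)
  pooled_mean <- mean(vapply(imp$imputations, function(d) mean(d$dbp),
                             numeric(1)))
  mc_se <- sd(coh$dbp) / sqrt(sum(!holes))
  expect_lt(abs(pooled_mean - full_mean), 2 * mc_se + 0.2)
})

test_that("Rubin pooling follows the combining rules", {
  mk_fit <- function(est, se, df = 100) {
    structure(list(coefficients = data.frame(
      term = paste0("b", seq_along(est)), estimate = est, se = se, df = df,
      t = est / se, p = 0.5)), class = "wmh_fit")
  }
  # identical fits: pooled equals the common fit, no between-variance
  fits <- replicate(4, mk_fit(c(1, -2), c(0.5, 0.2)), simplify = FALSE)
  p <- pool_estimates(fits)
  expect_equal(p$estimate, c(1, -2))
  expect_equal(p$se, c(0.5, 0.2))
  expect_equal(p$riv, c(0, 0))

  # direct formula: estimates {1,2,3}, within-variance 1, m = 3
  fits3 <- lapply(1:3, function(k) mk_fit(k, 1))
  p3 <- pool_estimates(fits3)
  expect_equal(p3$estimate, 2)
  expect_equal(p3$se^2, 1 + (1 + 1 / 3) * 1, tolerance = 1e-12)

  # degenerate m = 1
  p1 <- pool_estimates(fits3[1])
  expect_equal(p1$estimate, 1)
  expect_equal(p1$se, 1)
  expect_equal(p1$df, 100)

  expect_error(pool_estimates(list(mk_fit(1, 1), {
    f <- mk_fit(1, 1); f$coefficients$term <- "other"; f
  })), "mismatched")

  # pooled SE never below the mean within-imputation SE
  set.seed(4)
  fits_r <- lapply(1:5, function(k) mk_fit(rnorm(1), 0.3))
  pr <- pool_estimates(fits_r)
  expect_gte(pr$se, 0.3)
})

test_that("the pooled Wald test behaves at its degenerate corners", {
  mk_fit <- function(est, se, terms = paste0("b", seq_along(est))) {
    structure(list(coefficients = data.frame(
      term = terms, estimate = est, se = se, df = 100, t = est / se, p = 0.5),
      vcov = diag(se^2, length(est))), class = "wmh_fit")
  }
  full <- replicate(3, mk_fit(c(1, 0), c(0.5, 0.3)), simplify = FALSE)
  red <- replicate(3, mk_fit(1, 0.5, terms = "b1"), simplify = FALSE)

  # dropped term exactly zero with zero between-variance -> p = 1
  out <- pooled_wald_test(full, red)
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1)
  expect_equal(out$terms, "b2")

  # m = 1 agrees with the ordinary Wald chi-square
  full1 <- list(mk_fit(c(1, 0.9), c(0.5, 0.3)))
  out1 <- pooled_wald_test(full1, red[1])
  expect_equal(out1$p, pchisq((0.9 / 0.3)^2, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # non-nested models are rejected
  bad_red <- list(mk_fit(1, 0.5, terms = "zzz"))
  expect_error(pooled_wald_test(full1, bad_red), "not nested")
})

test_that("a strongly injected effect yields a tiny D1 p-value", {
  spec <- build_model_spec("M1")
  red_spec <- spec
  red_spec$fixed <- setdiff(spec$fixed, "bp_base:age_change")
  ps <- vapply(1:3, function(s) {
    cfg <- cohort_config(250, seed = 60 + s,
                         missingness_rates = c(dbp = 0.1))
    coh <- simulate_cohort(cfg, effects = effect_config(bp_base_mod_mean = 0.05),
                           apply_missingness = TRUE)
    imp <- multiply_impute(coh, m = 3, iterations = 3, seed = s)
    fulls <- lapply(imp$imputations,
                    function(d) fit_lmm(prepare_model_frame(d), spec))
    reds <- lapply(imp$imputations,
                   function(d) fit_lmm(prepare_model_frame(d), red_spec))
    pooled_wald_test(fulls, reds)$p
  }, numeric(1))
  expect_true(all(ps < 0.001))
})
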