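# bullseye tables, TIV adjustment, parallel analysis, PCA, component models

region_columns <- function(be) setdiff(names(be), c("subj_id", "time"))

test_that("bullseye allocation conserves the total volume per row", {
  coh <- small_cohort()
  be <- simulate_bullseye(coh, seed = 1)
  cols <- region_columns(be)
  expect_length(cols, 36)
  tot <- rowSums(be[cols])
  key <- match(paste(be$subj_id, be$time), paste(coh$subj_id, coh$time))
  expect_equal(tot, coh$wmh_vol[key], tolerance = 1e-8)
  expect_true(all(as.matrix(be[cols]) >= 0))
})

test_that("a uniform noise-free profile splits volumes equally", {
  coh <- small_cohort()
  be <- simulate_bullseye(coh, profile_base = rep(1 / 36, 36),
                          profile_prog = rep(1 / 36, 36),
                          concentration = Inf, seed = 2)
  cols <- region_columns(be)
  key <- match(paste(be$subj_id, be$time), paste(coh$subj_id, coh$time))
  for (rc in cols[c(1, 18, 36)])
    expect_equal(be[[rc]], coh$wmh_vol[key] / 36, tolerance = 1e-10)
})

test_that("the default profile weights periventricular frontal over distal occipital", {
  coh <- simulate_cohort(cohort_config(1000, seed = 91))
  be <- simulate_bullseye(coh, seed = 3)
  expect_gt(mean(be$frontal_left_s1), mean(be$occipital_left_s4))
  # unnormalized profiles are normalized with a warning
  expect_warning(simulate_bullseye(small_cohort(),
                                   profile_base = rep(2, 36), seed = 1),
                 "normalizing")
})

test_that("TIV adjustment multiplies by the individual-to-mean ratio", {
  coh <- small_cohort()
  be <- simulate_bullseye(coh, seed = 4)
  tv <- setNames(rep(mean(coh$tiv), length(unique(coh$subj_id))),
                 unique(coh$subj_id))
  same <- tiv_adjust(be, tv)
  expect_equal(same$frontal_left_s1, be$frontal_left_s1, tolerance = 1e-12)

  tv2 <- tv; tv2[] <- mean(coh$tiv); tv2["3"] <- 1.1 * mean(tv2)
  # forced arithmetic: a subject at 1.1 x the mean scales by ~1.1
  adj <- tiv_adjust(be, tv2)
  ratio <- tv2["3"] / mean(tv2)
  r3 <- be$subj_id == 3
  expect_equal(adj$parietal_right_s2[r3],
               be$parietal_right_s2[r3] * as.numeric(ratio),
               tolerance = 1e-12)

  tv_bad <- tv; tv_bad[2] <- -1
  expect_error(tiv_adjust(be, tv_bad), "positive")
})

test_that("parallel analysis keeps noise at zero and planted rank at its value", {
  # null calibration under the 95th-percentile retention rule (the mean
  # rule flags a first component on pure noise about half the time by
  # construction, so the percentile rule is the calibrated null reference)
  set.seed(5)
  ks <- vapply(1:20, function(s)
    as.integer(parallel_analysis(matrix(rnorm(500 * 36), 500),
                                 n_random = 30, retention_rule = "p95",
                                 seed = s)),
    integer(1))
  expect_gte(mean(ks <= 1), 0.95)

  # strong rank-2 structure
  set.seed(6)
  f1 <- rnorm(400); f2 <- rnorm(400)
  L <- matrix(rnorm(36 * 2), 36)
  X <- cbind(f1, f2) %*% t(L) * 2 + matrix(rnorm(400 * 36, 0, 0.5), 400)
  expect_equal(as.integer(parallel_analysis(X, n_random = 30, seed = 1)), 2L)

  expect_identical(as.integer(parallel_analysis(X, n_random = 20, seed = 9)),
                   as.integer(parallel_analysis(X, n_random = 20, seed = 9)))
  Xc <- X; Xc[, 3] <- 1
  expect_error(parallel_analysis(Xc, seed = 1), "constant")
})

test_that("the decomposition is orthonormal, idempotent and eigen-consistent", {
  coh <- simulate_cohort(cohort_config(200, seed = 93))
  be <- simulate_bullseye(coh, concentration = 20, seed = 7)
  cols <- region_columns(be)
  bl <- as.matrix(be[be$time == 0, cols])
  dec <- fit_decomposition(bl, 5)

  expect_lt(max(abs(crossprod(dec$loadings) - diag(5))), 1e-10)
  expect_true(all(diff(dec$eigenvalues) <= 1e-10))
  expect_equal(project_decomposition(dec, bl), dec$scores)
  expect_lt(max(abs(cor(dec$scores) - diag(5))), 1e-8)

  # eigenvalue sum equals total variance of the scaled matrix
  expect_equal(sum(dec$eigenvalues), ncol(bl), tolerance = 1e-8)

  # reconstruction error at k equals the discarded eigenvalue mass
  Xs <- scale(bl)
  recon <- dec$scores %*% t(dec$loadings)
  sse <- sum((Xs - recon)^2)
  expect_equal(sse / (nrow(bl) - 1), sum(dec$eigenvalues[-(1:5)]),
               tolerance = 1e-8)

  expect_error(fit_decomposition(bl[1:4, ], 10), "rank")

  dir <- withr::local_tempdir()
  write_decomposition(dec, dir)
  expect_true(file.exists(file.path(dir, "loadings.csv")))
  expect_true(file.exists(file.path(dir, "metadata.json")))
})

test_that("progression planted in one sector is recovered by the component models", {
  cfg <- cohort_config(500, seed = 95)
  coh <- simulate_cohort(cfg)
  reg <- bullseye_regions()
  prog <- ifelse(reg$region %in% c("frontal_left_s1", "frontal_right_s1"),
                 0.5, 0)
  be <- simulate_bullseye(coh, profile_prog = prog, concentration = 50,
                          seed = 8)
  cols <- region_columns(be)
  bl <- as.matrix(be[be$time == 0, cols])
  fu <- as.matrix(be[be$time == 1, cols])
  chg <- fu - bl
  # the leading component of the change matrix loads on frontal shell 1
  pc <- prcomp(chg, scale. = FALSE)
  top2 <- names(sort(abs(pc$rotation[, 1]), decreasing = TRUE))[1:2]
  expect_setequal(top2, c("frontal_left_s1", "frontal_right_s1"))

  # component models: one fit per component, age_change significant only
  # for components carrying progression
  dec <- fit_decomposition(bl, 3)
  fits <- component_models(dec, be, coh, "M1")
  expect_length(fits, 3)
  expect_true(all(vapply(fits, inherits, TRUE, "wmh_fit")))
})
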