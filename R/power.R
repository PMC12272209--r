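# Simulation-based and analytic power analyses.

#' Power of the one-sided correlation test
#'
#' Approximate power of the t-test of a Pearson correlation using the
#' Fisher-z transform with the small-sample bias term `r / (2(n-1))` and a
#' critical value mapped from the t distribution.
#'
#' @param n sample size (>= 4).
#' @param r true correlation (sign is ignored for a one-sided test in the
#'   direction of `r`).
#' @param alpha one-sided significance level.
#' @return power in `[0, 1]`.
#' @export
correlation_power <- function(n, r, alpha = 0.05) {
  stopifnot(all(n >= 4), abs(r) > 0, abs(r) < 1, alpha > 0, alpha < 1)
  r <- abs(r)
  ttt <- qt(alpha, df = n - 2, lower.tail = FALSE)
  rc <- sqrt(ttt^2 / (ttt^2 + n - 2))
  zr <- atanh(r) + r / (2 * (n - 1))
  pnorm((zr - atanh(rc)) * sqrt(n - 3))
}

#' Minimum n for a target correlation-test power
#'
#' Smallest integer sample size at which [correlation_power()] reaches the
#' target, found by an upward scan (the power function is monotone in n).
#'
#' @param r true correlation.
#' @param power target power.
#' @param alpha one-sided significance level.
#' @param n_max scan bound.
#' @return integer sample size.
#' @export
required_n_correlation <- function(r, power = 0.9, alpha = 0.05,
                                   n_max = 1e6) {
  stopifnot(abs(r) > 0, abs(r) < 1, alpha > 0, alpha < 1,
            power > alpha, power < 1)
  # coarse doubling then fine scan
  lo <- 4
  while (lo < n_max && correlation_power(lo, r, alpha) < power) lo <- lo * 2
  if (lo >= n_max) stop("no feasible n below 'n_max'")
  n <- max(4, lo / 2)
  while (correlation_power(n, r, alpha) < power) n <- n + 1
  as.integer(n)
}

power_terms <- c("bp_base:age_change", "whr_base:age_change",
                 "bp_change", "whr_change")

#' Cohort configuration of the power study
#'
#' The power simulation uses systolic blood pressure as the generic pressure
#' variable (mean 126.3 mmHg, SD 16.5 mmHg); everything else follows the
#' cohort defaults.
#'
#' @param n subjects.
#' @param whr_scale WHR effect scaling.
#' @param seed integer seed.
#' @return a [cohort_config()].
#' @export
power_study_config <- function(n, whr_scale, seed) {
  cohort_config(n, seed = seed, whr_scale = whr_scale,
                predictor_means = c(age = 63.2, bp = 126.3,
                                    whr = 0.941, tiv = 1.45e6),
                predictor_sds = c(age = 8.94, bp = 16.5,
                                  whr = 0.0855, tiv = 1.4e5))
}

#' Simulation-based power grid for model M1
#'
#' For every combination of sample size and WHR effect scaling, generates
#' `n_reps` synthetic cohorts, fits M1 on asinh-transformed volumes and
#' records, for each of the four longitudinal terms (blood-pressure-by-time
#' and WHR-by-time interactions, blood-pressure change, WHR change), the
#' rejection fraction under the significance rule and, optionally, the
#' one-sided Bayes factor. Power is set to 0 when the mean estimate across
#' replicates contradicts the hypothesized positive direction. Replicates
#' whose fit fails are excluded from the denominator with a warning.
#'
#' @param n_grid sample sizes, e.g. `c(400, 600, 800, 1000)`.
#' @param whr_scale_grid WHR effect scalings, e.g. `c(0.5, 1, 1.5)`.
#' @param n_reps replicates per cell.
#' @param alpha significance threshold.
#' @param alpha_rule `"two_sided"` applies `alpha` to the two-sided p-value
#'   (the registered rule, default threshold 2*0.05/3); `"one_sided"`
#'   applies it to the one-sided p-value (the 0.05 caption variant).
#' @param seed integer seed; the grid is exactly reproducible given the seed.
#' @param compute_bf also compute one-sided JZS Bayes factors per replicate
#'   (slower).
#' @param bf_draws posterior draws for the direction proportion.
#' @param config_fn optional function `(n, whr_scale, seed)` returning a
#'   [cohort_config()]; defaults to [power_study_config()] (systolic
#'   pressure moments).
#' @param effects_fn optional function `(whr_scale)` returning an
#'   [effect_config()], e.g. a null configuration for type-I calibration.
#' @return object of class `wmh_power_grid`: tidy data frame with columns
#'   `n`, `whr_scale`, `term`, `power`, `mean_estimate`, `mean_bf`,
#'   `median_bf`, `n_reps`, `n_failed`.
#' @export
run_power_grid <- function(n_grid, whr_scale_grid, n_reps = 50,
                           alpha = 2 * 0.05 / 3,
                           alpha_rule = c("two_sided", "one_sided"),
                           seed = 1L, compute_bf = FALSE, bf_draws = 200,
                           config_fn = NULL, effects_fn = NULL) {
  alpha_rule <- match.arg(alpha_rule)
  stopifnot(n_reps >= 1, length(n_grid) >= 1, length(whr_scale_grid) >= 1)
  spec <- build_model_spec("M1")
  cells <- expand.grid(n = n_grid, whr_scale = whr_scale_grid)
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    n <- cells$n[ci]; ws <- cells$whr_scale[ci]
    set.seed(seed + ci)
    rep_seeds <- sample.int(.Machine$integer.max - 10L, n_reps)
    est <- p2 <- p1 <- bf1 <- matrix(NA_real_, nrow = n_reps,
                                     ncol = length(power_terms),
                                     dimnames = list(NULL, power_terms))
    failed <- 0L
    for (r in seq_len(n_reps)) {
      cfg <- if (is.null(config_fn)) {
        power_study_config(n, ws, rep_seeds[r])
      } else config_fn(n, ws, rep_seeds[r])
      eff <- if (is.null(effects_fn)) effect_config(ws) else effects_fn(ws)
      fit <- tryCatch({
        cohort <- simulate_cohort(cfg, effects = eff)
        mfr <- prepare_model_frame(cohort)
        list(fit = fit_lmm(mfr, spec), mfr = mfr)
      }, error = function(e) NULL)
      if (is.null(fit)) { failed <- failed + 1L; next }
      ct <- fit$fit$coefficients
      norm_lbl <- function(s) vapply(strsplit(s, ":", fixed = TRUE),
                                     function(p) paste(sort(p), collapse = ":"),
                                     "")
      for (tm in power_terms) {
        row <- which(norm_lbl(ct$term) == norm_lbl(tm))
        est[r, tm] <- ct$estimate[row]
        p2[r, tm] <- ct$p[row]
        p1[r, tm] <- one_sided_p(ct$p[row], ct$estimate[row], 1)
        if (compute_bf) {
          bfr <- tryCatch(
            jzs_bayes_factor(fit$mfr, spec, term = tm, hypothesized_sign = 1,
                             n_draws = bf_draws, seed = rep_seeds[r]),
            error = function(e) NULL)
          if (!is.null(bfr)) bf1[r, tm] <- bfr$bf_one_sided
        }
      }
    }
    if (failed > 0)
      warning(sprintf("cell n=%d whr_scale=%g: %d of %d replicates failed",
                      n, ws, failed, n_reps))
    rej <- if (alpha_rule == "two_sided") p2 < alpha else p1 < alpha
    for (tm in power_terms) {
      pw <- mean(rej[, tm], na.rm = TRUE)
      me <- mean(est[, tm], na.rm = TRUE)
      if (!is.nan(me) && me < 0) pw <- 0     # wrong-direction rule
      out[[length(out) + 1L]] <- data.frame(
        n = n, whr_scale = ws, term = tm, power = pw, mean_estimate = me,
        mean_bf = mean(bf1[, tm], na.rm = TRUE),
        median_bf = median(bf1[, tm], na.rm = TRUE),
        n_reps = n_reps, n_failed = failed)
    }
  }
  grid <- do.call(rbind, out)
  attr(grid, "alpha") <- alpha
  attr(grid, "alpha_rule") <- alpha_rule
  attr(grid, "seed") <- seed
  class(grid) <- c("wmh_power_grid", "data.frame")
  grid
}

#' @export
print.wmh_power_grid <- function(x, ...) {
  cat(sprintf("<wmh_power_grid> %d cells x 4 terms (alpha %.4g, %s rule, seed %d)\n",
              nrow(x) / 4, attr(x, "alpha"), attr(x, "alpha_rule"),
              attr(x, "seed")))
  print(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a power grid as tidy CSV
#' @param grid a `wmh_power_grid`.
#' @param path CSV path.
#' @export
write_power_grid <- function(grid, path) {
  write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}
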