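# Multilevel multiple imputation and pooling.

imputable_vars <- c("education", "tiv", "dbp", "whr", "cesd", "ht_med")
predictor_cols <- c("subj_id", "time", "age", "gender", "education", "tiv",
                    "dbp", "whr", "cesd", "ht_med")

#' Build the imputation predictor matrix
#'
#' Boolean relation stating which variables predict each imputed variable.
#' Subject-level variables (education, intracranial volume) are predicted
#' from subject, age and gender only; time-varying variables additionally
#' use time, education and the other time-varying covariates; no variable
#' predicts itself.
#'
#' @return logical matrix, rows = imputed variables, columns = predictors
#'   (`subj_id` marks the multilevel grouping, `time` the within-subject
#'   occasion).
#' @export
build_predictor_matrix <- function() {
  pm <- matrix(FALSE, nrow = length(imputable_vars),
               ncol = length(predictor_cols),
               dimnames = list(imputable_vars, predictor_cols))
  pm["education", c("subj_id", "age", "gender")] <- TRUE
  pm["tiv", c("subj_id", "age", "gender")] <- TRUE
  pm["dbp", c("subj_id", "time", "age", "gender", "education", "whr",
              "cesd", "ht_med")] <- TRUE
  pm["whr", c("subj_id", "time", "age", "gender", "education", "dbp",
              "cesd", "ht_med")] <- TRUE
  pm["cesd", c("subj_id", "time", "age", "gender", "education", "dbp",
               "whr", "ht_med")] <- TRUE
  pm["ht_med", c("subj_id", "time", "age", "gender", "dbp", "whr")] <- TRUE
  pm
}

# rhs formula string for one imputed variable; time enters as the elapsed
# years (age_change), age as baseline age
impute_rhs <- function(var, pm) {
  cols <- colnames(pm)[pm[var, ]]
  cols <- setdiff(cols, "subj_id")
  map <- c(time = "age_change", age = "age_base")
  cols <- ifelse(cols %in% names(map), map[cols], cols)
  paste(cols, collapse = " + ")
}

draw_mvn_coef <- function(est, vc) {
  as.numeric(est + t(chol(as.matrix(vc))) %*% rnorm(length(est)))
}

# subject-level view: one row per subject with baseline age
subject_level <- function(d) {
  bl <- d[d$time == 0L, , drop = FALSE]
  bl[order(bl$subj_id), ]
}

impute_binary_subject <- function(d, var, rhs) {
  sl <- subject_level(d)
  obs <- !is.na(sl[[var]])
  fml <- as.formula(paste(var, "~", rhs))
  fit <- suppressWarnings(stats::glm(fml, data = sl[obs, ], family = stats::binomial()))
  beta <- draw_mvn_coef(coef(fit), vcov(fit))
  mmr <- model.matrix(as.formula(paste("~", rhs)), sl[!obs, , drop = FALSE])
  p <- stats::plogis(as.numeric(mmr %*% beta))
  draw <- rbinom(length(p), 1L, p)
  fill <- setNames(draw, sl$subj_id[!obs])
  idx <- is.na(d[[var]])
  d[[var]][idx] <- fill[as.character(d$subj_id[idx])]
  # propagate subject-level value to both rows
  v <- tapply(d[[var]], d$subj_id, function(x) x[!is.na(x)][1])
  d[[var]] <- as.numeric(v[as.character(d$subj_id)])
  d
}

impute_pmm_subject <- function(d, var, rhs, donors = 5L) {
  sl <- subject_level(d)
  obs <- !is.na(sl[[var]])
  fml <- as.formula(paste(var, "~", rhs))
  fit <- lm(fml, data = sl[obs, ])
  beta_hat <- coef(fit)
  beta_draw <- draw_mvn_coef(beta_hat, vcov(fit))
  mm_obs <- model.matrix(as.formula(paste("~", rhs)), sl[obs, , drop = FALSE])
  mm_mis <- model.matrix(as.formula(paste("~", rhs)), sl[!obs, , drop = FALSE])
  pred_obs <- as.numeric(mm_obs %*% beta_hat)
  pred_mis <- as.numeric(mm_mis %*% beta_draw)
  yobs <- sl[[var]][obs]
  fill <- vapply(pred_mis, function(pm_) {
    dist <- abs(pred_obs - pm_)
    cand <- order(dist)[seq_len(min(donors, length(dist)))]
    yobs[sample(cand, 1L)]
  }, numeric(1))
  names(fill) <- sl$subj_id[!obs]
  idx <- is.na(d[[var]])
  d[[var]][idx] <- fill[as.character(d$subj_id[idx])]
  v <- tapply(d[[var]], d$subj_id, function(x) x[!is.na(x)][1])
  d[[var]] <- as.numeric(v[as.character(d$subj_id)])
  d
}

impute_normal_mixed <- function(d, var, rhs) {
  obs <- !is.na(d[[var]])
  fml <- as.formula(paste(var, "~", rhs, "+ (1 | subj_id)"))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(fml, data = d[obs, ],
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))))
  beta <- draw_mvn_coef(lme4::fixef(fit), as.matrix(vcov(fit)))
  sig <- sigma(fit)
  re <- lme4::ranef(fit)$subj_id
  tau <- sqrt(as.data.frame(lme4::VarCorr(fit))$vcov[1])
  b <- setNames(re[, 1], rownames(re))
  mis <- which(!obs)
  mmr <- model.matrix(as.formula(paste("~", rhs)), d[mis, , drop = FALSE])
  b_mis <- b[as.character(d$subj_id[mis])]
  b_mis[is.na(b_mis)] <- rnorm(sum(is.na(b_mis)), 0, tau)
  d[[var]][mis] <- as.numeric(mmr %*% beta) + b_mis + rnorm(length(mis), 0, sig)
  d
}

impute_binary_mixed <- function(d, var, rhs) {
  obs <- !is.na(d[[var]])
  fml <- as.formula(paste(var, "~", rhs, "+ (1 | subj_id)"))
  fit <- suppressWarnings(suppressMessages(
    lme4::glmer(fml, data = d[obs, ], family = stats::binomial(), nAGQ = 0L,
                control = lme4::glmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))))
  beta <- draw_mvn_coef(lme4::fixef(fit), as.matrix(vcov(fit)))
  re <- lme4::ranef(fit)$subj_id
  tau <- sqrt(as.data.frame(lme4::VarCorr(fit))$vcov[1])
  b <- setNames(re[, 1], rownames(re))
  mis <- which(!obs)
  mmr <- model.matrix(as.formula(paste("~", rhs)), d[mis, , drop = FALSE])
  b_mis <- b[as.character(d$subj_id[mis])]
  b_mis[is.na(b_mis)] <- rnorm(sum(is.na(b_mis)), 0, tau)
  p <- stats::plogis(as.numeric(mmr %*% beta) + b_mis)
  d[[var]][mis] <- rbinom(length(mis), 1L, p)
  d
}

#' Multilevel multiple imputation
#'
#' Chained-equation imputation of the six designated variables (education,
#' TIV, DBP or SBP, WHR, CES-D, antihypertensive treatment) following the
#' predictor matrix: subject-level binary variables by a Bayesian logistic
#' draw, subject-level continuous variables by predictive mean matching
#' (5 donors), time-varying continuous variables by linear mixed normal
#' draws with subject intercepts, and time-varying binary variables by a
#' mixed logistic draw. Variables are visited in the predictor-matrix row
#' order for `iterations` sweeps; the whole cycle is repeated for each of
#' the `m` imputed copies. Observed cells are never altered.
#'
#' @param cohort long cohort with missingness only in the imputable
#'   variables (WMH outcome rows must be complete).
#' @param pm predictor matrix from [build_predictor_matrix()].
#' @param m number of imputed copies.
#' @param iterations chained-equation sweeps per copy.
#' @param seed integer seed.
#' @param bp_var which blood-pressure column the `dbp` role refers to
#'   (`"dbp"` or `"sbp"`).
#' @return object of class `wmh_imputed_set`: list with `imputations`
#'   (m completed cohorts), `mask` (logical missingness matrix), `m`,
#'   `iterations`, `seed`.
#' @export
multiply_impute <- function(cohort, pm = build_predictor_matrix(), m = 5L,
                            iterations = 10L, seed = 1L,
                            bp_var = c("dbp", "sbp")) {
  bp_var <- match.arg(bp_var)
  d0 <- as.data.frame(cohort)
  if (anyNA(d0$wmh_vol)) stop("WMH volumes must be complete before imputation")
  vars <- rownames(pm)
  use_vars <- ifelse(vars == "dbp", bp_var, vars)
  for (v in use_vars)
    if (!v %in% names(d0)) stop("cohort lacks imputable column '", v, "'")
  fully_missing <- use_vars[vapply(use_vars, function(v) all(is.na(d0[[v]])),
                                   TRUE)]
  if (length(fully_missing))
    stop("cannot impute variable(s) with no observed values: ",
         paste(fully_missing, collapse = ", "))
  mask <- sapply(use_vars, function(v) is.na(d0[[v]]))
  if (!any(mask)) {
    imps <- replicate(m, d0, simplify = FALSE)
    return(structure(list(imputations = imps, mask = mask, m = m,
                          iterations = iterations, seed = seed,
                          converged = TRUE),
                     class = "wmh_imputed_set"))
  }
  set.seed(seed)
  imps <- vector("list", m)
  for (im in seq_len(m)) {
    d <- d0
    # initial fill: sample from the observed margin
    for (v in use_vars) {
      idx <- is.na(d[[v]])
      if (any(idx))
        d[[v]][idx] <- sample(d[[v]][!idx], sum(idx), replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (k in seq_along(vars)) {
        v <- vars[k]; vc <- use_vars[k]
        if (!any(mask[, vc])) next
        d[[vc]][mask[, vc]] <- NA          # re-impute this variable
        rhs <- impute_rhs(v, pm)
        if (vc %in% c("dbp", "sbp")) rhs <- gsub("\\bdbp\\b", vc, rhs)
        d <- switch(v,
          education = impute_binary_subject(d, vc, rhs),
          tiv = impute_pmm_subject(d, vc, rhs),
          dbp = , whr = , cesd = impute_normal_mixed(d, vc, rhs),
          ht_med = impute_binary_mixed(d, vc, rhs))
      }
    }
    imps[[im]] <- d
  }
  structure(list(imputations = imps, mask = mask, m = m,
                 iterations = iterations, seed = seed, converged = TRUE),
            class = "wmh_imputed_set")
}

#' @export
print.wmh_imputed_set <- function(x, ...) {
  cat(sprintf("<wmh_imputed_set> m = %d copies, %d iterations, seed %d\n",
              x$m, x$iterations, x$seed))
  mr <- colMeans(x$mask)
  cat("  missingness:", paste(sprintf("%s %.1f%%", names(mr), 100 * mr),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / load an imputed set
#'
#' The set is written as a directory of `m` cohort CSV files plus a JSON
#' manifest (m, iterations, seed, missingness-mask digest).
#'
#' @param imp a `wmh_imputed_set`.
#' @param dir directory path.
#' @export
write_imputed_set <- function(imp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(imp$m))
    write.csv(imp$imputations[[i]],
              file.path(dir, sprintf("imputation_%02d.csv", i)),
              row.names = FALSE)
  mask_df <- as.data.frame(imp$mask)
  write.csv(mask_df, file.path(dir, "mask.csv"), row.names = FALSE)
  manifest <- list(m = imp$m, iterations = imp$iterations, seed = imp$seed,
                   mask_cells = sum(imp$mask),
                   variables = colnames(imp$mask))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_imputed_set
#' @export
read_imputed_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^imputation_\\d+\\.csv$",
                           full.names = TRUE))
  imps <- lapply(files, read_cohort)
  mask <- as.matrix(read.csv(file.path(dir, "mask.csv")))
  structure(list(imputations = imps, mask = mask, m = manifest$m,
                 iterations = manifest$iterations, seed = manifest$seed,
                 converged = TRUE),
            class = "wmh_imputed_set")
}

#' Pool estimates across imputations (Rubin's rules)
#'
#' Pooled estimate is the mean across imputations; total variance is the
#' mean within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance; degrees of freedom use the Barnard-Rubin
#' small-sample adjustment based on the average complete-data df.
#'
#' @param fits list of `wmh_fit` objects (the same model on each imputed
#'   copy).
#' @return data frame per term: `estimate`, `se`, `df`, `t`, `p`
#'   (two-sided), `riv` (relative increase in variance), `fmi`.
#' @export
pool_estimates <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "wmh_fit")))
  terms_ref <- fits[[1]]$coefficients$term
  for (f in fits)
    if (!identical(f$coefficients$term, terms_ref))
      stop("fits have mismatched term lists")
  m <- length(fits)
  est <- sapply(fits, function(f) f$coefficients$estimate)
  se <- sapply(fits, function(f) f$coefficients$se)
  dfc <- sapply(fits, function(f) f$coefficients$df)
  est <- matrix(est, ncol = m); se <- matrix(se, ncol = m)
  dfc <- matrix(dfc, ncol = m)
  qbar <- rowMeans(est)
  ubar <- rowMeans(se^2)
  bvar <- if (m > 1) apply(est, 1, var) else rep(0, length(qbar))
  tvar <- ubar + (1 + 1 / m) * bvar
  riv <- (1 + 1 / m) * bvar / ubar
  lambda <- (riv) / (1 + riv)
  dfcom <- rowMeans(dfc)
  df <- ifelse(lambda <= 0, dfcom, {
    df_old <- (m - 1) / pmax(lambda, 1e-12)^2
    df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    df_old * df_obs / (df_old + df_obs)
  })
  tval <- qbar / sqrt(tvar)
  data.frame(term = terms_ref, estimate = qbar, se = sqrt(tvar), df = df,
             t = tval, p = 2 * pt(-abs(tval), df), riv = riv,
             fmi = (riv + 2 / (df + 3)) / (riv + 1))
}

#' Pooled multivariate Wald test (D1)
#'
#' Tests the terms present in the full but not the reduced model across
#' multiply imputed fits, combining the per-imputation estimates and their
#' covariances with the D1 statistic of Li, Raghunathan and Rubin.
#'
#' @param full_fits,reduced_fits lists of `wmh_fit` objects of equal length;
#'   the reduced model must be nested in the full model.
#' @return list with `statistic` (F value), `df1`, `df2`, `p`, and the
#'   tested `terms`.
#' @export
pooled_wald_test <- function(full_fits, reduced_fits) {
  stopifnot(length(full_fits) == length(reduced_fits), length(full_fits) >= 1)
  m <- length(full_fits)
  full_terms <- full_fits[[1]]$coefficients$term
  red_terms <- reduced_fits[[1]]$coefficients$term
  if (!all(red_terms %in% full_terms))
    stop("models are not nested: reduced model has terms absent from the full model")
  tested <- setdiff(full_terms, red_terms)
  if (!length(tested)) stop("models are identical; nothing to test")
  k <- length(tested)
  idx <- match(tested, full_terms)
  qs <- sapply(full_fits, function(f) f$coefficients$estimate[idx])
  qs <- matrix(qs, nrow = k)
  us <- lapply(full_fits, function(f) f$vcov[idx, idx, drop = FALSE])
  qbar <- rowMeans(qs)
  ubar <- Reduce(`+`, us) / m
  bmat <- if (m > 1) {
    dev <- qs - qbar
    tcrossprod(dev) / (m - 1)
  } else matrix(0, k, k)
  r1 <- if (m > 1) (1 + 1 / m) * sum(diag(bmat %*% solve(ubar))) / k else 0
  d1 <- as.numeric(t(qbar) %*% solve(ubar) %*% qbar) / (k * (1 + r1))
  t_ <- k * (m - 1)
  df2 <- if (m == 1 || r1 <= 0) Inf
  else if (t_ > 4) 4 + (t_ - 4) * (1 + (1 - 2 / t_) / r1)^2
  else t_ * (1 + 1 / k) * (1 + 1 / r1)^2 / 2
  p <- if (is.infinite(df2)) pchisq(k * d1, df = k, lower.tail = FALSE)
  else pf(d1, k, df2, lower.tail = FALSE)
  list(statistic = d1, df1 = k, df2 = df2, p = p, terms = tested,
       r1 = r1, m = m)
}
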