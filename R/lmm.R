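# Model specification and linear mixed-model fitting.

model_catalog <- function() {
  m1_rhs <- c("age_base", "age_change", "bp_base", "bp_base:age_change",
              "bp_change", "whr_base", "whr_base:age_change", "whr_change",
              "gender", "ht_med", "z_tiv")
  m23_rhs <- c("age_base", "age_change", "asinh_wmh_base",
               "age_change:asinh_wmh_base", "wmh_change", "gender",
               "education", "asinh_cesd")
  # hypothesized signs refer to the fitted coefficient; gender is coded with
  # female as reference level, so "stronger in women" means a negative
  # coefficient on the male-involved interaction
  list(
    M1 = list(outcome = "asinh_wmh", rhs = m1_rhs, bp_source = "dbp",
              interest = data.frame(term = "bp_base:age_change", sign = 1)),
    M2 = list(outcome = "z_exec", rhs = m23_rhs, bp_source = "dbp",
              interest = data.frame(term = "wmh_change", sign = -1)),
    M3 = list(outcome = "z_global", rhs = m23_rhs, bp_source = "dbp",
              interest = data.frame(term = "wmh_change", sign = -1)),
    M1E2a = list(outcome = "asinh_wmh",
                 rhs = c(m1_rhs, "gender:age_change"), bp_source = "dbp",
                 interest = data.frame(term = "gender:age_change", sign = -1)),
    M1E2b = list(outcome = "asinh_wmh",
                 rhs = c(m1_rhs, "gender:age_change", "gender:bp_base",
                         "gender:bp_base:age_change"), bp_source = "dbp",
                 interest = data.frame(term = "gender:bp_base:age_change",
                                       sign = -1)),
    M1E2c = list(outcome = "asinh_wmh",
                 rhs = c(m1_rhs, "gender:age_change", "gender:whr_base",
                         "gender:whr_base:age_change"), bp_source = "dbp",
                 interest = data.frame(term = "gender:whr_base:age_change",
                                       sign = -1)),
    M2E3a = list(outcome = "z_exec",
                 rhs = c(m23_rhs, "gender:wmh_change"), bp_source = "dbp",
                 interest = data.frame(term = "gender:wmh_change", sign = -1)),
    M3E3b = list(outcome = "z_global",
                 rhs = c(m23_rhs, "gender:wmh_change"), bp_source = "dbp",
                 interest = data.frame(term = "gender:wmh_change", sign = -1)),
    `M1-SBP` = list(outcome = "asinh_wmh", rhs = m1_rhs, bp_source = "sbp",
                    interest = data.frame(term = "bp_base:age_change",
                                          sign = 1))
  )
}

#' Build a model specification
#'
#' Returns the fixed-effect term list, outcome, grouping factor and
#' hypothesized direction of the term of interest for the confirmatory
#' models (M1: vascular risk factors on asinh WMH; M2/M3: WMH change on
#' executive / global cognition) and the exploratory gender-interaction and
#' SBP variants.
#'
#' @param name one of `"M1"`, `"M2"`, `"M3"`, `"M1E2a"`, `"M1E2b"`,
#'   `"M1E2c"`, `"M2E3a"`, `"M3E3b"`, `"M1-SBP"`.
#' @return object of class `wmh_model_spec` with elements `name`, `outcome`,
#'   `fixed` (character term vector), `group` (random-intercept factor),
#'   `bp_source` (`"dbp"` or `"sbp"`), and `interest` (term + hypothesized
#'   coefficient sign).
#' @export
build_model_spec <- function(name) {
  cat_ <- model_catalog()
  if (!name %in% names(cat_))
    stop("unknown model name '", name, "'; available: ",
         paste(names(cat_), collapse = ", "))
  entry <- cat_[[name]]
  structure(list(name = name, outcome = entry$outcome, fixed = entry$rhs,
                 group = "subj_id", bp_source = entry$bp_source,
                 interest = entry$interest),
            class = "wmh_model_spec")
}

#' @export
print.wmh_model_spec <- function(x, ...) {
  cat(sprintf("<wmh_model_spec> %s\n  %s ~ %s + (1|%s)\n", x$name, x$outcome,
              paste(x$fixed, collapse = " + "), x$group))
  cat("  term(s) of interest:",
      paste(sprintf("%s (%s)", x$interest$term,
                    ifelse(x$interest$sign > 0, "+", "-")), collapse = ", "),
      "\n")
  invisible(x)
}

spec_formula <- function(spec, random = TRUE) {
  rhs <- paste(spec$fixed, collapse = " + ")
  if (random) rhs <- paste0(rhs, " + (1 | ", spec$group, ")")
  as.formula(paste(spec$outcome, "~", rhs))
}

#' Prepare a model frame from a long cohort
#'
#' Derives the covariates the models expect from a long cohort table:
#' baseline and change versions of blood pressure and WHR (change coded 0 at
#' baseline and follow-up-minus-baseline at follow-up, so a change effect
#' acts on the follow-up occasion), asinh-transformed WMH and CES-D, the
#' z-scored intracranial volume, baseline asinh WMH and the asinh-scale WMH
#' change, plus the composite cognitive scores if raw tests are present.
#'
#' @param cohort a `wmh_cohort`.
#' @param bp_source use `"dbp"` (default) or `"sbp"` as the blood-pressure
#'   variable.
#' @param drop_excluded drop subjects flagged `exclude`.
#' @return data frame with one row per subject-by-timepoint.
#' @export
prepare_model_frame <- function(cohort, bp_source = c("dbp", "sbp"),
                                drop_excluded = TRUE) {
  bp_source <- match.arg(bp_source)
  d <- as.data.frame(cohort)
  if (drop_excluded && !is.null(d$exclude)) d <- d[!d$exclude, ]
  d <- d[order(d$subj_id, d$time), ]
  bp <- d[[bp_source]]

  base_of <- function(x) {
    b <- tapply(ifelse(d$time == 0L, x, NA), d$subj_id,
                function(v) v[!is.na(v)][1])
    as.numeric(b[as.character(d$subj_id)])
  }
  fu_of <- function(x) {
    f <- tapply(ifelse(d$time == 1L, x, NA), d$subj_id,
                function(v) v[!is.na(v)][1])
    as.numeric(f[as.character(d$subj_id)])
  }
  d$bp_base <- base_of(bp)
  d$bp_change <- ifelse(d$time == 1L, fu_of(bp) - d$bp_base, 0)
  d$whr_base <- base_of(d$whr)
  d$whr_change <- ifelse(d$time == 1L, fu_of(d$whr) - d$whr_base, 0)
  d$asinh_wmh <- asinh(d$wmh_vol)
  d$asinh_wmh_base <- asinh(base_of(d$wmh_vol))
  d$wmh_change <- ifelse(d$time == 1L,
                         asinh(fu_of(d$wmh_vol)) - d$asinh_wmh_base, 0)
  d$z_tiv <- as.numeric(scale(d$tiv))
  if (!is.null(d$cesd)) d$asinh_cesd <- asinh(d$cesd)
  if ("tmt_a" %in% names(d) && !all(is.na(d$tmt_a)))
    d <- add_composite_scores(d)
  d
}

#' Fit a linear mixed model
#'
#' REML fit with a subject random intercept via [lmerTest::lmer()];
#' per-term two-sided p-values use t-statistics with Satterthwaite
#' denominator degrees of freedom (a residual-df fallback is available).
#'
#' @param data a prepared model frame (see [prepare_model_frame()]) or a
#'   `wmh_cohort` (then prepared automatically with the spec's `bp_source`).
#' @param spec a `wmh_model_spec`.
#' @param df_method `"satterthwaite"` or `"residual"`.
#' @param outcome_scale override the outcome: `"spec"` uses the spec's
#'   outcome; `"raw_volume"` fits untransformed `wmh_vol` (useful for
#'   recovering generative constants that live on the volume scale).
#' @return object of class `wmh_fit`: coefficient table (`estimate`, `se`,
#'   `df`, `t`, `p` two-sided), variance components, convergence flag,
#'   residuals/fitted values, fixed-effect covariance and the underlying
#'   `lmerMod`.
#' @export
fit_lmm <- function(data, spec, df_method = c("satterthwaite", "residual"),
                    outcome_scale = c("spec", "raw_volume")) {
  df_method <- match.arg(df_method)
  outcome_scale <- match.arg(outcome_scale)
  stopifnot(inherits(spec, "wmh_model_spec"))
  if (inherits(data, "wmh_cohort")) data <- prepare_model_frame(data, spec$bp_source)
  spec_use <- spec
  if (outcome_scale == "raw_volume") spec_use$outcome <- "wmh_vol"
  need <- unique(c(spec_use$outcome, spec$group,
                   unlist(strsplit(spec$fixed, ":", fixed = TRUE))))
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("model frame lacks column(s): ", paste(miss, collapse = ", "))

  fml <- spec_formula(spec_use)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.scaleX = "ignore", calc.derivs = FALSE)
  fit <- withCallingHandlers(
    tryCatch(lmerTest::lmer(fml, data = data, REML = TRUE, control = ctrl),
             # lmerTest's conversion fails on degenerate (zero-variance)
             # fits; fall back to the plain lme4 fit with residual df
             error = function(e)
               lme4::lmer(fml, data = data, REML = TRUE, control = ctrl)),
    message = function(m) invokeRestart("muffleMessage"))
  dropped <- attr(fit@pp$X, "col.dropped")
  if (!is.null(dropped) && length(dropped))
    stop("fixed-effect design is rank deficient; aliased terms: ",
         paste(names(dropped), collapse = ", "))

  ct <- if (inherits(fit, "lmerModLmerTest"))
    tryCatch(coef(summary(fit, ddf = "Satterthwaite")),
             error = function(e) NULL) else NULL
  if (is.null(ct)) {
    # degenerate fits (e.g. an exactly deterministic outcome) break the
    # Satterthwaite machinery; report the estimates with residual df
    est <- lme4::fixef(fit)
    se <- suppressWarnings(tryCatch(sqrt(diag(as.matrix(vcov(fit)))),
                                    error = function(e) rep(NA_real_,
                                                            length(est))))
    dfres <- nrow(data) - length(est) - 1
    tt <- est / se
    ct <- cbind(Estimate = est, `Std. Error` = se, df = dfres,
                `t value` = tt, `Pr(>|t|)` = 2 * pt(-abs(tt), dfres))
  }
  if (df_method == "residual") {
    dfres <- nrow(data) - ncol(ct) - 1
    tt <- ct[, "Estimate"] / ct[, "Std. Error"]
    ct <- cbind(ct[, c("Estimate", "Std. Error")], df = dfres, `t value` = tt,
                `Pr(>|t|)` = 2 * pt(-abs(tt), dfres))
  }
  coefs <- data.frame(term = rownames(ct), estimate = ct[, "Estimate"],
                      se = ct[, "Std. Error"], df = ct[, "df"],
                      t = ct[, "t value"], p = ct[, "Pr(>|t|)"],
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L
  vmat <- suppressWarnings(tryCatch(as.matrix(vcov(fit)),
                                    error = function(e) NULL))
  structure(list(
    spec = spec, coefficients = coefs,
    vcov = vmat,
    ranef_var = vc$vcov[vc$grp == spec$group][1],
    residual_var = sigma(fit)^2,
    converged = conv, df_method = df_method,
    residuals = residuals(fit), fitted = fitted(fit),
    ranef = lme4::ranef(fit)[[spec$group]][, 1],
    n_obs = nrow(fit@frame),
    n_subjects = lme4::ngrps(fit)[[spec$group]],
    model = fit
  ), class = "wmh_fit")
}

#' @export
print.wmh_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<wmh_fit> %s (%d obs, %d subjects, df: %s%s)\n",
              x$spec$name, x$n_obs, x$n_subjects, x$df_method,
              if (x$converged) "" else ", NOT CONVERGED"))
  cat(sprintf("  random intercept var %.4g, residual var %.4g\n",
              x$ranef_var, x$residual_var))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Coefficient accessor
#' @param fit a `wmh_fit`.
#' @param term optional term name; returns the full table if omitted.
#' @export
fit_coef <- function(fit, term = NULL) {
  tb <- fit$coefficients
  if (is.null(term)) return(tb)
  row <- tb[tb$term == term, ]
  if (!nrow(row)) stop("term '", term, "' not in the fit")
  row
}

#' One-sided p-value for a directed hypothesis
#'
#' Halves the two-sided p-value when the estimated sign agrees with the
#' hypothesized direction and folds it otherwise
#' (`alpha_two_sided = 2 * alpha_one_sided`).
#'
#' @param two_sided_p two-sided p-value in `[0, 1]`.
#' @param estimate_sign sign of the estimate (`+1`/`-1`, or the estimate).
#' @param hypothesized_sign hypothesized sign.
#' @return one-sided p-value.
#' @export
one_sided_p <- function(two_sided_p, estimate_sign, hypothesized_sign) {
  stopifnot(all(two_sided_p >= 0 & two_sided_p <= 1))
  agree <- sign(estimate_sign) * sign(hypothesized_sign) >= 0
  ifelse(agree, two_sided_p / 2, 1 - two_sided_p / 2)
}

#' Map a (p, BF) pair to an evidence category
#'
#' Joint frequentist/Bayesian decision rule of the confirmatory analysis,
#' applied to the two-sided p-value (threshold `2 * 0.05 / 3` after the
#' one-sided Bonferroni adjustment for three hypotheses) and the one-sided
#' Bayes factor. Categories are assigned most-extreme-first; combinations
#' the rule does not cover (significant p with BF at or below 1/3, or
#' non-significant p with BF at or above 3) return `"undefined"`.
#'
#' @param p two-sided p-value.
#' @param bf one-sided Bayes factor (>= 0).
#' @param alpha two-sided significance threshold.
#' @return factor with levels `positive H1`, `moderate H1`, `weak H1`,
#'   `inconclusive`, `moderate H0`, `positive H0`, `undefined`.
#' @export
decide_evidence <- function(p, bf, alpha = 2 * 0.05 / 3) {
  stopifnot(all(p >= 0 & p <= 1), all(bf >= 0))
  lev <- c("positive H1", "moderate H1", "weak H1", "inconclusive",
           "moderate H0", "positive H0", "undefined")
  one <- function(p, bf) {
    if (p < alpha) {
      if (bf > 6) "positive H1"
      else if (bf > 3) "moderate H1"
      else if (bf > 1 / 3) "weak H1"
      else "undefined"
    } else {
      if (bf < 1 / 6) "positive H0"
      else if (bf < 1 / 3) "moderate H0"
      else if (bf < 3) "inconclusive"
      else "undefined"
    }
  }
  factor(mapply(one, p, bf), levels = lev)
}
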