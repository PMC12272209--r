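# Assumption, influence and robustness diagnostics for the mixed models.

refit_without <- function(data, spec, drop_id, ...) {
  fit_lmm(data[data[[spec$group]] != drop_id, , drop = FALSE], spec, ...)
}

#' Influential subjects by Cook's distance
#'
#' Per-subject Cook's distance for the fixed effects. `method = "approx"`
#' (default) deletes each subject's block exactly at the fitted variance
#' components (a one-step generalized-least-squares downdate); `"refit"`
#' re-estimates the whole model without the subject. Subjects with distance
#' above mean + 3 SD are flagged.
#'
#' @param fit a `wmh_fit`.
#' @param data the model frame the fit was computed on.
#' @param method `"approx"` or `"refit"`.
#' @param threshold_sd flag threshold in SD units above the mean distance.
#' @return list with `influential` (subject ids), `cooks_distance` (named
#'   per subject), `threshold`, `method`.
#' @export
influential_cases <- function(fit, data, method = c("approx", "refit"),
                              threshold_sd = 3) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "wmh_fit"))
  spec <- fit$spec
  ids <- unique(data[[spec$group]])
  if (length(ids) < 3) stop("need at least 3 subjects for influence analysis")
  beta <- fit$coefficients$estimate
  p <- length(beta)
  vb <- fit$vcov
  prec <- solve(vb)

  if (method == "refit") {
    dists <- vapply(ids, function(id) {
      b_i <- refit_without(data, spec, id)$coefficients$estimate
      d <- beta - b_i
      as.numeric(t(d) %*% prec %*% d) / p
    }, numeric(1))
  } else {
    # exact block deletion at the fitted variance components:
    # beta_(-i) = (X'V^-1 X - Xi'Vi^-1 Xi)^-1 (X'V^-1 y - Xi'Vi^-1 yi)
    mod <- fit$model
    X <- lme4::getME(mod, "X")
    y <- lme4::getME(mod, "y")
    grp <- mod@frame[[spec$group]]
    tau2 <- fit$ranef_var
    sig2 <- fit$residual_var
    ids <- unique(grp)
    blocks <- lapply(ids, function(id) {
      sel <- which(grp == id)
      ni <- length(sel)
      vi <- diag(sig2, ni) + matrix(tau2, ni, ni)
      vinv <- solve(vi)
      Xi <- X[sel, , drop = FALSE]
      list(XtVX = t(Xi) %*% vinv %*% Xi,
           XtVy = as.numeric(t(Xi) %*% vinv %*% y[sel]))
    })
    XtVX <- Reduce(`+`, lapply(blocks, `[[`, "XtVX"))
    XtVy <- Reduce(`+`, lapply(blocks, `[[`, "XtVy"))
    beta_gls <- solve(XtVX, XtVy)
    dists <- vapply(seq_along(ids), function(i) {
      b_i <- solve(XtVX - blocks[[i]]$XtVX, XtVy - blocks[[i]]$XtVy)
      d <- beta_gls - b_i
      as.numeric(t(d) %*% prec %*% d) / p
    }, numeric(1))
  }
  names(dists) <- as.character(ids)
  mu <- mean(dists); sdd <- sd(dists)
  thr <- mu + threshold_sd * sdd
  infl <- if (sdd == 0) character(0) else names(dists)[dists > thr]
  list(influential = infl, cooks_distance = dists, threshold = thr,
       method = method)
}

#' Leave-one-subject-out stability
#'
#' Refits the model with each subject excluded and reports the range of
#' every fixed-effect estimate, plus any refits that failed to converge.
#'
#' @param data model frame.
#' @param spec a `wmh_model_spec`.
#' @return list with `range` (data frame term/min/max/full),
#'   `non_converged` (subject ids), `n_refits`.
#' @export
loo_stability <- function(data, spec) {
  ids <- unique(data[[spec$group]])
  if (length(ids) < 3) stop("need at least 3 subjects")
  full <- fit_lmm(data, spec)
  ests <- matrix(NA_real_, nrow = length(full$coefficients$term),
                 ncol = length(ids),
                 dimnames = list(full$coefficients$term, as.character(ids)))
  bad <- character(0)
  for (id in ids) {
    f <- tryCatch(refit_without(data, spec, id), error = function(e) NULL)
    if (is.null(f)) { bad <- c(bad, as.character(id)); next }
    if (!f$converged) bad <- c(bad, as.character(id))
    ests[, as.character(id)] <- f$coefficients$estimate
  }
  rng <- data.frame(term = rownames(ests),
                    min = apply(ests, 1, min, na.rm = TRUE),
                    max = apply(ests, 1, max, na.rm = TRUE),
                    full = full$coefficients$estimate, row.names = NULL)
  list(range = rng, non_converged = bad, n_refits = length(ids))
}

#' Variance inflation factors
#'
#' Classical VIF from auxiliary regressions among the main-effect columns of
#' the fixed design (interactions and the random effect omitted). Exact
#' collinearity is reported as infinite with the aliased columns named.
#'
#' @param data model frame.
#' @param spec a `wmh_model_spec`.
#' @return named numeric vector of VIFs with attribute `problematic`
#'   (names with VIF above `threshold`).
#' @param threshold flag level (conventionally 10).
#' @export
variance_inflation <- function(data, spec, threshold = 10) {
  mains <- spec$fixed[!grepl(":", spec$fixed, fixed = TRUE)]
  if (length(mains) < 2) stop("need at least 2 non-intercept main effects")
  mm <- model.matrix(as.formula(paste("~", paste(mains, collapse = " + "))),
                     data)
  X <- mm[, -1, drop = FALSE]
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vifs) <- colnames(X)
  if (any(is.infinite(vifs)))
    warning("exactly collinear columns: ",
            paste(names(vifs)[is.infinite(vifs)], collapse = ", "))
  attr(vifs, "problematic") <- names(vifs)[vifs > threshold]
  vifs
}

#' Robust mixed-model refit
#'
#' Iteratively reweighted REML fit with Huber weights (tuning constant
#' 1.345) on the scaled residuals: observations with large residuals are
#' progressively downweighted until the weights stabilize.
#'
#' @param data model frame.
#' @param spec a `wmh_model_spec`.
#' @param tuning Huber tuning constant.
#' @param max_iter,tol iteration control.
#' @return a `wmh_fit` with elements `weights` and `robust_iterations`
#'   added; `converged` reflects the weight iteration.
#' @export
robust_refit <- function(data, spec, tuning = 1.345, max_iter = 50,
                         tol = 1e-4) {
  if (inherits(data, "wmh_cohort")) data <- prepare_model_frame(data, spec$bp_source)
  fml <- spec_formula(spec)
  w <- NULL
  for (it in seq_len(max_iter)) {
    fit <- suppressWarnings(suppressMessages(
      if (is.null(w))
        lmerTest::lmer(fml, data = data,
                       control = lme4::lmerControl(check.conv.singular = "ignore", check.scaleX = "ignore"))
      else {
        data$..w <- w
        lmerTest::lmer(fml, data = data, weights = ..w,
                       control = lme4::lmerControl(check.conv.singular = "ignore", check.scaleX = "ignore"))
      }))
    r <- residuals(fit)
    s <- mad(r, center = 0)
    if (s <= 0) s <- sigma(fit)
    u <- abs(r / s)
    w_new <- ifelse(u <= tuning, 1, tuning / u)
    if (!is.null(w) && max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  converged <- it < max_iter
  smry <- summary(fit, ddf = "Satterthwaite")
  ct <- coef(smry)
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- structure(list(
    spec = spec,
    coefficients = data.frame(term = rownames(ct), estimate = ct[, "Estimate"],
                              se = ct[, "Std. Error"], df = ct[, "df"],
                              t = ct[, "t value"], p = ct[, "Pr(>|t|)"],
                              row.names = NULL),
    vcov = as.matrix(vcov(fit)),
    ranef_var = vc$vcov[vc$grp == spec$group][1],
    residual_var = sigma(fit)^2,
    converged = converged, df_method = "satterthwaite",
    residuals = residuals(fit), fitted = fitted(fit),
    ranef = lme4::ranef(fit)[[spec$group]][, 1],
    n_obs = nrow(fit@frame),
    n_subjects = lme4::ngrps(fit)[[spec$group]],
    model = fit, weights = w, robust_iterations = it
  ), class = "wmh_fit")
  out
}

#' Residual and random-effect diagnostics
#'
#' Shapiro-Wilk normality tests on the residuals and on the predicted
#' random intercepts, and a heteroscedasticity check regressing absolute
#' residuals on fitted values. Optionally writes a PNG with the QQ plots
#' and the fitted-vs-residual plot.
#'
#' @param fit a `wmh_fit`.
#' @param alpha decision level for the normality tests.
#' @param plot_file optional path for a diagnostic PNG.
#' @return object of class `wmh_diagnostics`: residual and random-effect
#'   normality tests (statistic, p, decision at `alpha`), the
#'   heteroscedasticity slope test, and the plot path if written.
#' @export
residual_diagnostics <- function(fit, alpha = 0.01, plot_file = NULL) {
  stopifnot(inherits(fit, "wmh_fit"))
  r <- fit$residuals
  re <- fit$ranef
  sub <- if (length(r) > 5000) sample(r, 5000) else r
  sw_r <- shapiro.test(sub)
  sw_re <- if (length(re) >= 3 && length(re) <= 5000 && sd(re) > 0)
    shapiro.test(re) else NULL
  het <- summary(lm(abs(r) ~ fit$fitted))$coefficients
  out <- list(
    residual_normality = list(statistic = unname(sw_r$statistic),
                              p = sw_r$p.value,
                              normal = sw_r$p.value >= alpha),
    ranef_normality = if (is.null(sw_re)) NULL else
      list(statistic = unname(sw_re$statistic), p = sw_re$p.value,
           normal = sw_re$p.value >= alpha),
    heteroscedasticity = list(slope = het[2, 1], p = het[2, 4]),
    alpha = alpha, plot_file = plot_file)
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 900, height = 320)
    op <- graphics::par(mfrow = c(1, 3))
    stats::qqnorm(r, main = "Residuals"); stats::qqline(r)
    stats::qqnorm(re, main = "Random intercepts"); stats::qqline(re)
    plot(fit$fitted, r, xlab = "Fitted", ylab = "Residual",
         main = "Fitted vs residuals")
    graphics::abline(h = 0, lty = 2)
    graphics::par(op)
    grDevices::dev.off()
  }
  class(out) <- "wmh_diagnostics"
  out
}

#' @export
print.wmh_diagnostics <- function(x, ...) {
  cat("<wmh_diagnostics>\n")
  cat(sprintf("  residual normality: W = %.4f, p = %.3g (%s at alpha %.2g)\n",
              x$residual_normality$statistic, x$residual_normality$p,
              if (x$residual_normality$normal) "not rejected" else "rejected",
              x$alpha))
  if (!is.null(x$ranef_normality))
    cat(sprintf("  random-effect normality: W = %.4f, p = %.3g\n",
                x$ranef_normality$statistic, x$ranef_normality$p))
  cat(sprintf("  |residual| ~ fitted slope: %.4g (p = %.3g)\n",
              x$heteroscedasticity$slope, x$heteroscedasticity$p))
  invisible(x)
}
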