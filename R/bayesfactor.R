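# One-sided JZS Bayes factors for mixed-model fixed effects.
#
# Model: y = mu * 1 + X theta + Z b + e, with theta_j ~ N(0, g1 sigma^2)
# on standardized fixed-effect columns, b ~ N(0, g2 sigma^2) on subject
# intercepts, flat prior on mu, Jeffreys prior on sigma^2, and
# sqrt(g) ~ half-Cauchy (scale 0.5 fixed, 1 random), i.e.
# g ~ inverse-gamma(1/2, r^2/2). Conditional on (g1, g2) the marginal
# likelihood is available in closed form; the Bayes factor integrates it
# over the g's by Simpson quadrature on the log scale. A per-subject
# orthonormal (grand-mean / within-subject) transform reduces every
# evaluation to p x p linear algebra, p = number of fixed-effect columns.

# Precompute grouped cross-products. Returns sufficient statistics for
# evaluating the conditional log marginal for any subset of X columns.
jzs_prepare <- function(y, X, group = NULL) {
  n <- length(y)
  y <- y - mean(y)
  p <- ncol(X)
  if (is.null(group)) {
    return(list(n = n, p = p, has_group = FALSE,
                A0 = crossprod(X), u0 = crossprod(X, y),
                w0 = colSums(X), cyy0 = sum(y^2), cy10 = sum(y),
                c110 = n, colnames = colnames(X)))
  }
  group <- as.factor(group)
  Sx <- rowsum(X, group)            # J x p
  Sy <- as.numeric(rowsum(y, group))
  ni <- as.numeric(table(group)[rownames(Sx)])
  ks <- sort(unique(ni))
  mean_blocks <- lapply(ks, function(k) {
    sel <- ni == k
    mx <- Sx[sel, , drop = FALSE] / sqrt(k)
    my <- Sy[sel] / sqrt(k)
    m1 <- rep(sqrt(k), sum(sel))
    list(k = k, m = sum(sel),
         A = crossprod(mx), u = crossprod(mx, my), w = colSums(mx * m1),
         cyy = sum(my^2), cy1 = sum(my * m1), c11 = sum(m1^2))
  })
  A0 <- crossprod(X); u0 <- crossprod(X, y); w0 <- colSums(X)
  cyy0 <- sum(y^2); cy10 <- sum(y); c110 <- n
  for (b in mean_blocks) {
    A0 <- A0 - b$A; u0 <- u0 - b$u; w0 <- w0 - b$w
    cyy0 <- cyy0 - b$cyy; cy10 <- cy10 - b$cy1; c110 <- c110 - b$c11
  }
  list(n = n, p = p, has_group = TRUE, blocks = mean_blocks,
       A0 = A0, u0 = u0, w0 = w0, cyy0 = cyy0, cy10 = cy10, c110 = c110,
       colnames = colnames(X))
}

# Conditional log marginal likelihood (up to a model-independent constant)
# for the column subset `cols`, given g1 (fixed) and g2 (random).
# Also returns posterior ingredients when `posterior = TRUE`.
jzs_logm <- function(prep, cols, g1, g2 = NULL, posterior = FALSE) {
  n <- prep$n
  sub <- function(A, idx) A[idx, idx, drop = FALSE]
  idx <- cols
  pk <- length(idx)
  B <- sub(prep$A0, idx); bu <- prep$u0[idx]; bw <- prep$w0[idx]
  cyy <- prep$cyy0; cy1 <- prep$cy10; c11 <- prep$c110
  logdetD <- 0
  if (prep$has_group) {
    for (bl in prep$blocks) {
      d <- 1 + bl$k * g2
      B <- B + sub(bl$A, idx) / d
      bu <- bu + bl$u[idx] / d
      bw <- bw + bl$w[idx] / d
      cyy <- cyy + bl$cyy / d
      cy1 <- cy1 + bl$cy1 / d
      c11 <- c11 + bl$c11 / d
      logdetD <- logdetD + bl$m * log(d)
    }
  }
  if (pk > 0 && g1 > 0) {
    M <- diag(pk) + g1 * B
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    logdetM <- 2 * sum(log(diag(R)))
    Minv_bu <- backsolve(R, forwardsolve(t(R), bu))
    Minv_bw <- backsolve(R, forwardsolve(t(R), bw))
    s11 <- c11 - g1 * sum(bw * Minv_bw)
    s1y <- cy1 - g1 * sum(bw * Minv_bu)
    syy <- cyy - g1 * sum(bu * Minv_bu)
  } else {
    logdetM <- 0
    s11 <- c11; s1y <- cy1; syy <- cyy
  }
  if (s11 <= 0) return(-Inf)
  qstar <- syy - s1y^2 / s11
  if (qstar <= 0) return(-Inf)
  lm <- -0.5 * logdetD - 0.5 * logdetM - 0.5 * log(s11) -
    (n - 1) / 2 * log(qstar)
  if (!posterior) return(lm)
  # posterior of theta given (g1, g2): mean m_th, unscaled covariance
  # (Phi + I/g1)^{-1}, sigma^2 ~ InvGamma((n-1)/2, qstar/2)
  s11D <- c11; phiy <- bu; Phi <- B; w <- bw
  Phi <- Phi - tcrossprod(w) / s11D
  phiy <- phiy - w * cy1 / s11D
  Lam <- Phi + diag(pk) / g1
  Lr <- chol(Lam)
  m_th <- backsolve(Lr, forwardsolve(t(Lr), phiy))
  Lam_inv <- chol2inv(Lr)
  list(logm = lm, qstar = qstar, m_th = as.numeric(m_th),
       Lam_inv = Lam_inv, df = n - 1)
}

log_invgamma <- function(g, rscale) {
  a <- rscale^2 / 2
  0.5 * log(a) - lgamma(0.5) - 1.5 * log(g) - a / g
}

# Simpson weights for an odd-length uniform grid
simpson_w <- function(m, h) {
  w <- rep(c(2, 4), length.out = m); w[1] <- 1; w[m] <- 1
  w * h / 3
}

# integrate exp(logf(u)) over a 1- or 2-d log-g grid centered at the mode.
# Returns log integral, an error estimate (coarse vs fine grid), and the
# grid with normalized weights (for posterior sampling).
jzs_integrate <- function(logf, ndim, n_grid = 61) {
  opt <- optim(rep(0, ndim), function(u) -logf(u),
               method = if (ndim == 1) "Brent" else "Nelder-Mead",
               lower = if (ndim == 1) -40 else -Inf,
               upper = if (ndim == 1) 25 else Inf)
  mode <- opt$par; lmax <- -opt$value
  span <- function(dir, dim) {            # walk out until mass is negligible
    s <- 1
    repeat {
      u <- mode; u[dim] <- u[dim] + dir * s
      if (logf(u) < lmax - 25 || s > 45) break
      s <- s + 1.5
    }
    s
  }
  grids <- lapply(seq_len(ndim), function(d)
    seq(mode[d] - span(-1, d), mode[d] + span(1, d), length.out = n_grid))
  eval_grid <- function(gs) {
    if (ndim == 1) {
      lf <- vapply(gs[[1]], function(u) logf(u), numeric(1))
      w <- simpson_w(length(gs[[1]]), diff(gs[[1]][1:2]))
      pts <- matrix(gs[[1]], ncol = 1)
      lw <- log(w)
    } else {
      pts <- as.matrix(expand.grid(u1 = gs[[1]], u2 = gs[[2]]))
      lf <- apply(pts, 1, function(u) logf(u))
      w1 <- simpson_w(length(gs[[1]]), diff(gs[[1]][1:2]))
      w2 <- simpson_w(length(gs[[2]]), diff(gs[[2]][1:2]))
      lw <- log(as.numeric(outer(w1, w2)[cbind(
        match(pts[, 1], gs[[1]]), match(pts[, 2], gs[[2]]))]))
    }
    lt <- lf + lw
    m <- max(lt)
    list(logI = m + log(sum(exp(lt - m))), pts = pts, lf = lf, lw = lw)
  }
  fine <- eval_grid(grids)
  coarse_grids <- lapply(grids, function(g) g[seq(1, length(g), by = 2)])
  coarse <- eval_grid(coarse_grids)
  lt <- fine$lf + fine$lw
  post_w <- exp(lt - max(lt)); post_w <- post_w / sum(post_w)
  list(logI = fine$logI,
       rel_error = abs(expm1(coarse$logI - fine$logI)),
       pts = fine$pts, post_w = post_w)
}

# Map a term label to model-matrix columns (order-insensitive for
# interaction labels).
term_columns <- function(mm, term) {
  asn <- attr(mm, "assign")
  labs <- attr(mm, "term.labels")
  norm <- function(s) vapply(strsplit(s, ":", fixed = TRUE),
                             function(p) paste(sort(p), collapse = ":"), "")
  hit <- which(norm(labs) == norm(term))
  if (!length(hit)) stop("term '", term, "' not found in the design; ",
                         "available: ", paste(labs, collapse = ", "))
  which(asn == hit)
}

#' JZS Bayes factor for one fixed-effect term
#'
#' Computes the Bayes factor of the full mixed model against the model
#' omitting one term, under a JZS prior: Cauchy scale `rscale_fixed` on the
#' standardized fixed-effect coefficients, Cauchy scale `rscale_random` on
#' the subject intercepts, Jeffreys priors on the grand mean and error
#' variance. Conditional marginal likelihoods are closed-form given the two
#' g-mixing parameters, which are integrated by Simpson quadrature on the
#' log scale; the relative quadrature error (coarse-vs-fine grid) is
#' reported. The posterior direction proportion — the share of posterior
#' draws of the term's coefficient in the hypothesized direction — converts
#' the two-sided Bayes factor into a one-sided one via
#' `bf_one_sided = bf_two_sided * direction_prob / 0.5`.
#'
#' @param data prepared model frame or `wmh_cohort`.
#' @param spec a `wmh_model_spec`.
#' @param term term to test (default: the spec's term of interest).
#' @param hypothesized_sign direction of the one-sided hypothesis (+1/-1;
#'   default from the spec).
#' @param rscale_fixed,rscale_random Cauchy prior scales.
#' @param n_grid quadrature points per dimension (odd).
#' @param n_draws posterior draws for the direction proportion (>= 10).
#' @param seed optional seed for the posterior draws.
#' @return object of class `wmh_bf`: `bf_two_sided`, `direction_prob`,
#'   `bf_one_sided`, `log_bf`, `rel_error`, `term`, `n_draws`.
#' @export
jzs_bayes_factor <- function(data, spec, term = NULL,
                             hypothesized_sign = NULL,
                             rscale_fixed = 0.5, rscale_random = 1,
                             n_grid = 61, n_draws = 1000, seed = NULL) {
  stopifnot(inherits(spec, "wmh_model_spec"))
  if (inherits(data, "wmh_cohort")) data <- prepare_model_frame(data, spec$bp_source)
  if (is.null(term)) term <- spec$interest$term[1]
  if (is.null(hypothesized_sign)) {
    hs <- spec$interest$sign[match(term, spec$interest$term)]
    hypothesized_sign <- if (is.na(hs)) 1 else hs
  }
  if (n_draws < 10) stop("'n_draws' must be at least 10")

  rhs <- paste(spec$fixed, collapse = " + ")
  vars <- unique(c(spec$outcome, spec$group,
                   all.vars(as.formula(paste("~", rhs)))))
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("model frame lacks column(s): ", paste(miss, collapse = ", "))
  d2 <- data[complete.cases(data[, vars]), vars, drop = FALSE]
  group <- d2[[spec$group]]
  mm <- model.matrix(as.formula(paste("~", rhs)), d2)
  attr(mm, "term.labels") <-
    attr(terms(as.formula(paste("~", rhs))), "term.labels")
  drop_cols <- term_columns(mm, term)
  y <- d2[[spec$outcome]]
  X <- mm[, -1, drop = FALSE]                     # drop intercept
  drop_cols <- drop_cols - 1L
  # standardize columns; constant columns are aliased with the mean
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) stop("constant fixed-effect column(s): ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  X <- scale(X)

  prep <- jzs_prepare(y, X, group = if (prep_has_group(group)) group else NULL)
  ndim <- if (prep$has_group) 2L else 1L
  all_cols <- seq_len(ncol(X))
  red_cols <- setdiff(all_cols, drop_cols)

  make_logf <- function(cols) {
    function(u) {
      g1 <- exp(u[1])
      g2 <- if (ndim == 2) exp(u[2]) else NULL
      lm <- jzs_logm(prep, cols, g1, g2)
      lp <- log_invgamma(g1, rscale_fixed) + u[1]
      if (ndim == 2) lp <- lp + log_invgamma(g2, rscale_random) + u[2]
      lm + lp
    }
  }
  int_full <- jzs_integrate(make_logf(all_cols), ndim, n_grid)
  int_red <- jzs_integrate(make_logf(red_cols), ndim, n_grid)
  log_bf <- int_full$logI - int_red$logI
  rel_error <- int_full$rel_error + int_red$rel_error

  # posterior direction proportion from the full-model grid mixture
  if (length(drop_cols) == 1L) {
    if (!is.null(seed)) set.seed(seed)
    cells <- sample.int(nrow(int_full$pts), n_draws, replace = TRUE,
                        prob = int_full$post_w)
    tab <- table(cells)
    draws <- numeric(0)
    for (ci in as.integer(names(tab))) {
      u <- int_full$pts[ci, ]
      g1 <- exp(u[1]); g2 <- if (ndim == 2) exp(u[2]) else NULL
      po <- jzs_logm(prep, all_cols, g1, g2, posterior = TRUE)
      j <- match(drop_cols, all_cols)
      scale_j <- sqrt(po$qstar / po$df * po$Lam_inv[j, j])
      draws <- c(draws, po$m_th[j] + scale_j * stats::rt(tab[[as.character(ci)]],
                                                         df = po$df))
    }
    direction_prob <- mean(sign(draws) == sign(hypothesized_sign))
  } else {
    direction_prob <- NA_real_
  }
  bf2 <- exp(log_bf)
  structure(list(
    term = term, hypothesized_sign = hypothesized_sign,
    bf_two_sided = bf2, direction_prob = direction_prob,
    bf_one_sided = if (is.na(direction_prob)) NA_real_ else
      one_sided_bf(bf2, direction_prob),
    log_bf = log_bf, rel_error = rel_error, n_draws = n_draws,
    n_obs = prep$n
  ), class = "wmh_bf")
}

prep_has_group <- function(group) {
  !is.null(group) && length(unique(group)) > 1 &&
    length(unique(group)) < length(group)
}

#' One-sided Bayes factor from the posterior direction proportion
#'
#' Multiplies the two-sided Bayes factor by the posterior probability of the
#' hypothesized direction divided by 0.5 (equal prior mass on both
#' directions).
#'
#' @param bf_two_sided two-sided Bayes factor.
#' @param direction_prob posterior probability in `[0, 1]` of the effect
#'   lying in the hypothesized direction.
#' @export
one_sided_bf <- function(bf_two_sided, direction_prob) {
  stopifnot(all(bf_two_sided >= 0),
            all(direction_prob >= 0 & direction_prob <= 1))
  bf_two_sided * direction_prob / 0.5
}

#' Pool Bayes factors across imputations
#'
#' The pooled summary is the mean, reported with the range across the
#' imputed datasets.
#'
#' @param bfs numeric vector of (one-sided) Bayes factors, or a list of
#'   `wmh_bf` objects.
#' @return list with `mean`, `range` (min, max) and the per-imputation
#'   `values`.
#' @export
pool_bf <- function(bfs) {
  if (is.list(bfs) && all(vapply(bfs, inherits, TRUE, "wmh_bf")))
    bfs <- vapply(bfs, function(b) b$bf_one_sided, numeric(1))
  stopifnot(is.numeric(bfs), length(bfs) >= 1)
  list(mean = mean(bfs), range = range(bfs), values = bfs)
}

#' @export
print.wmh_bf <- function(x, ...) {
  cat(sprintf("<wmh_bf> term %s (hypothesized %s)\n", x$term,
              if (x$hypothesized_sign > 0) "+" else "-"))
  cat(sprintf("  BF (two-sided) %.4g | direction prob %.3f | BF (one-sided) %.4g\n",
              x$bf_two_sided, x$direction_prob, x$bf_one_sided))
  cat(sprintf("  quadrature rel. error %.2g, n = %d\n", x$rel_error, x$n_obs))
  invisible(x)
}
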