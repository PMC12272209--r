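# Bullseye parcellation tables, PCA spatial components, component models.

#' Bullseye region names
#'
#' 36 regions: 9 sectors (frontal, parietal, temporal, occipital in each
#' hemisphere, plus a basal-ganglia sector) by 4 equidistant shells between
#' the ventricles (shell 1, periventricular) and the cortex (shell 4).
#'
#' @return data frame with `region`, `sector`, `lobe`, `hemisphere`,
#'   `shell`.
#' @export
bullseye_regions <- function() {
  lobes <- c("frontal", "parietal", "temporal", "occipital")
  sectors <- c(paste0(rep(lobes, each = 2), "_", c("left", "right")),
               "basal_ganglia")
  out <- expand.grid(sector = sectors, shell = 1:4,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$lobe <- sub("_(left|right)$", "", out$sector)
  out$hemisphere <- ifelse(grepl("_left$", out$sector), "left",
                           ifelse(grepl("_right$", out$sector), "right",
                                  "midline"))
  out$region <- paste0(out$sector, "_s", out$shell)
  out[, c("region", "sector", "lobe", "hemisphere", "shell")]
}

default_spatial_profile <- function() {
  reg <- bullseye_regions()
  lobe_w <- c(frontal = 0.17, parietal = 0.13, temporal = 0.08,
              occipital = 0.05, basal_ganglia = 0.14)
  shell_w <- c(4, 3, 2, 1) / 10        # periventricular shells weighted up
  w <- lobe_w[reg$lobe] * shell_w[reg$shell]
  # hemispheric sectors appear twice per lobe; basal ganglia once
  w <- ifelse(reg$hemisphere == "midline", w, w)
  w <- w / sum(w)
  setNames(w, reg$region)
}

#' Simulate a bullseye region table
#'
#' Distributes each subject's total WMH volume over the 36 bullseye regions
#' by a Dirichlet draw around a spatial profile. Baseline volumes use
#' `profile_base`; the progression (follow-up minus baseline total) is
#' allocated with `profile_prog`, so cross-sectional and change-related
#' spatial patterns can differ. Volume regression (negative change) shrinks
#' the baseline pattern proportionally. Region volumes sum exactly to the
#' row's total WMH.
#'
#' @param cohort a `wmh_cohort` with volumes at both timepoints.
#' @param profile_base,profile_prog nonnegative weight vectors of length 36
#'   (normalized with a warning if they do not sum to 1); default weights
#'   periventricular frontal/parietal shells highest.
#' @param concentration Dirichlet concentration (`Inf` = no allocation
#'   noise).
#' @param seed integer seed.
#' @return object of class `wmh_bullseye`: data frame `subj_id`, `time`,
#'   then 36 region columns (cm^3); region metadata in
#'   `attr(, "regions")`.
#' @export
simulate_bullseye <- function(cohort, profile_base = NULL,
                              profile_prog = NULL, concentration = 200,
                              seed = 1L) {
  reg <- bullseye_regions()
  norm_profile <- function(p, nm) {
    if (is.null(p)) return(default_spatial_profile())
    if (length(p) != 36 || any(p < 0))
      stop("'", nm, "' must be 36 nonnegative weights")
    if (abs(sum(p) - 1) > 1e-8) {
      warning("'", nm, "' does not sum to 1; normalizing")
      p <- p / sum(p)
    }
    setNames(as.numeric(p), reg$region)
  }
  profile_base <- norm_profile(profile_base, "profile_base")
  profile_prog <- norm_profile(profile_prog, "profile_prog")
  set.seed(seed)
  wide <- cohort_wide_volumes(cohort)
  n <- nrow(wide)
  rdirichlet <- function(conc, prof) {
    if (is.infinite(conc)) return(prof / sum(prof))
    x <- rgamma(length(prof), shape = conc * prof)
    if (sum(x) == 0) return(rep(1 / length(prof), length(prof)))
    x / sum(x)
  }
  bl <- fu <- matrix(0, n, 36, dimnames = list(NULL, reg$region))
  for (i in seq_len(n)) {
    wb <- rdirichlet(concentration, profile_base)
    bl[i, ] <- wide$wmh_bl[i] * wb
    delta <- wide$wmh_fu[i] - wide$wmh_bl[i]
    if (delta >= 0) {
      wp <- rdirichlet(concentration, profile_prog)
      fu[i, ] <- bl[i, ] + delta * wp
    } else {
      fu[i, ] <- bl[i, ] * if (wide$wmh_bl[i] > 0)
        wide$wmh_fu[i] / wide$wmh_bl[i] else 0
    }
  }
  out <- data.frame(subj_id = rep(wide$subj_id, 2L),
                    time = rep(c(0L, 1L), each = n),
                    rbind(bl, fu), check.names = FALSE)
  attr(out, "regions") <- reg
  class(out) <- c("wmh_bullseye", "data.frame")
  out
}

#' Head-size adjustment of region volumes
#'
#' Multiplies every region volume by the subject's intracranial volume over
#' the sample mean intracranial volume.
#'
#' @param table a `wmh_bullseye` table.
#' @param tiv named vector of intracranial volumes (names = subject ids),
#'   or a cohort data frame with `subj_id` and `tiv`.
#' @return adjusted table.
#' @export
tiv_adjust <- function(table, tiv) {
  if (is.data.frame(tiv)) {
    tv <- tapply(tiv$tiv, tiv$subj_id, function(x) x[1])
  } else tv <- tiv
  if (any(tv <= 0, na.rm = TRUE) || anyNA(tv[as.character(table$subj_id)]))
    stop("every subject needs a positive intracranial volume")
  ratio <- tv[as.character(table$subj_id)] / mean(tv)
  cols <- region_cols(table)
  table[cols] <- table[cols] * as.numeric(ratio)
  table
}

region_cols <- function(table) {
  reg <- attr(table, "regions")
  if (is.null(reg)) reg <- bullseye_regions()
  intersect(reg$region, names(table))
}

#' Horn's parallel analysis
#'
#' Retains components whose observed eigenvalues (of the correlation or
#' covariance matrix) exceed the reference eigenvalue from simulated
#' independent normal data of the same dimensions — the mean (default) or
#' the 95th percentile across `n_random` simulations. Components count from
#' the first; retention stops at the first failure.
#'
#' @param x numeric matrix (rows = observations).
#' @param n_random number of random reference datasets.
#' @param retention_rule `"mean"` or `"p95"`.
#' @param use_cor analyse the correlation (TRUE) or covariance matrix.
#' @param seed integer seed.
#' @return integer `k` with attribute `eigenvalues` (observed) and
#'   `reference` (threshold per component).
#' @export
parallel_analysis <- function(x, n_random = 100,
                              retention_rule = c("mean", "p95"),
                              use_cor = TRUE, seed = 1L) {
  retention_rule <- match.arg(retention_rule)
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 columns")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  evs <- function(m) {
    s <- if (use_cor) stats::cor(m) else stats::cov(m)
    eigen(s, symmetric = TRUE, only.values = TRUE)$values
  }
  obs <- evs(x)
  set.seed(seed)
  ref <- replicate(n_random,
                   evs(matrix(rnorm(nrow(x) * ncol(x)), nrow(x))))
  thr <- if (retention_rule == "mean") rowMeans(ref)
  else apply(ref, 1, quantile, probs = 0.95)
  k <- 0L
  for (j in seq_along(obs)) {
    if (obs[j] > thr[j]) k <- k + 1L else break
  }
  structure(k, eigenvalues = obs, reference = thr)
}

#' PCA decomposition of baseline region volumes, with projection
#'
#' Centered (and by default scaled) principal component analysis of the
#' baseline region matrix, keeping `k` components. Follow-up data are
#' projected with the baseline centering/scaling and loadings.
#'
#' @param baseline numeric matrix (subjects x regions) at baseline.
#' @param k number of components (<= rank).
#' @param scale. analyse correlations (TRUE) or covariances.
#' @return object of class `wmh_decomposition`: orthonormal `loadings`
#'   (regions x k), all `eigenvalues`, baseline `scores`, `center`,
#'   `scale`, `k`.
#' @export
fit_decomposition <- function(baseline, k, scale. = TRUE) {
  baseline <- as.matrix(baseline)
  pc <- prcomp(baseline, center = TRUE, scale. = scale.)
  rank <- sum(pc$sdev > 1e-10)
  if (k > rank) stop("k = ", k, " exceeds the matrix rank (", rank, ")")
  structure(list(
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    eigenvalues = pc$sdev^2,
    scores = pc$x[, seq_len(k), drop = FALSE],
    center = pc$center,
    scale = if (isTRUE(scale.)) pc$scale else NULL,
    k = as.integer(k)
  ), class = "wmh_decomposition")
}

#' @rdname fit_decomposition
#' @param decomp a `wmh_decomposition`.
#' @param newdata matrix with the same columns as the training matrix.
#' @export
project_decomposition <- function(decomp, newdata) {
  newdata <- as.matrix(newdata)
  x <- sweep(newdata, 2, decomp$center)
  if (!is.null(decomp$scale)) x <- sweep(x, 2, decomp$scale, `/`)
  x %*% decomp$loadings
}

#' @export
print.wmh_decomposition <- function(x, ...) {
  ve <- x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("<wmh_decomposition> k = %d components (%.1f%% variance)\n",
              x$k, 100 * sum(ve[seq_len(x$k)])))
  invisible(x)
}

#' Save / load a decomposition
#'
#' Loadings as CSV, metadata (k, eigenvalues, centering, scaling) as JSON.
#' @param decomp a `wmh_decomposition`.
#' @param dir directory path.
#' @export
write_decomposition <- function(decomp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(region = rownames(decomp$loadings), decomp$loadings),
            file.path(dir, "loadings.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(k = decomp$k, eigenvalues = decomp$eigenvalues,
         center = as.list(decomp$center),
         scale = if (is.null(decomp$scale)) NULL else as.list(decomp$scale)),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Component-level mixed models
#'
#' Refits the confirmatory models with spatial component scores in place of
#' the WMH terms: for M1-type analyses each component score is the outcome;
#' for M2/M3-type analyses the baseline score and score change replace the
#' baseline asinh WMH and the WMH change. Exploratory results report
#' uncorrected two-sided p-values.
#'
#' @param decomp a `wmh_decomposition` fitted on baseline regions.
#' @param bullseye the `wmh_bullseye` table used for the decomposition.
#' @param cohort the matching `wmh_cohort` (or prepared model frame).
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @return list of `wmh_fit`, one per component.
#' @export
component_models <- function(decomp, bullseye, cohort, model = "M1") {
  stopifnot(model %in% c("M1", "M2", "M3"))
  spec <- build_model_spec(model)
  mfr <- if (inherits(cohort, "wmh_cohort"))
    prepare_model_frame(cohort, spec$bp_source) else cohort
  cols <- region_cols(bullseye)
  bl <- bullseye[bullseye$time == 0L, ]
  fu <- bullseye[bullseye$time == 1L, ]
  sc_bl <- project_decomposition(decomp, as.matrix(bl[cols]))
  sc_fu <- project_decomposition(decomp, as.matrix(fu[cols]))
  ids_bl <- bl$subj_id; ids_fu <- fu$subj_id
  fits <- vector("list", decomp$k)
  for (j in seq_len(decomp$k)) {
    s_bl <- setNames(sc_bl[, j], ids_bl)
    s_fu <- setNames(sc_fu[, j], ids_fu)
    key <- as.character(mfr$subj_id)
    if (anyNA(s_bl[key]) || anyNA(s_fu[key]))
      stop("bullseye table and cohort do not cover the same subjects")
    d <- mfr
    d$comp_score <- ifelse(d$time == 0L, s_bl[key], s_fu[key])
    d$comp_base <- as.numeric(s_bl[key])
    d$comp_change <- ifelse(d$time == 1L, s_fu[key] - s_bl[key], 0)
    spec_j <- spec
    if (model == "M1") {
      spec_j$outcome <- "comp_score"
    } else {
      spec_j$fixed <- gsub("asinh_wmh_base", "comp_base", spec_j$fixed)
      spec_j$fixed <- gsub("\\bwmh_change\\b", "comp_change", spec_j$fixed)
      spec_j$interest$term <- gsub("\\bwmh_change\\b", "comp_change",
                                   spec_j$interest$term)
    }
    fits[[j]] <- fit_lmm(d, spec_j)
  }
  names(fits) <- paste0("PC", seq_len(decomp$k))
  fits
}

#' Write a bullseye table as tidy CSV
#'
#' One row per subject-by-timepoint-by-region with sector, shell and volume.
#' @param table a `wmh_bullseye`.
#' @param path CSV path.
#' @export
write_bullseye <- function(table, path) {
  reg <- attr(table, "regions")
  cols <- region_cols(table)
  long <- do.call(rbind, lapply(cols, function(rc) {
    info <- reg[reg$region == rc, ]
    data.frame(subj_id = table$subj_id, time = table$time,
               sector = info$sector, shell = info$shell,
               volume = table[[rc]])
  }))
  long <- long[order(long$subj_id, long$time, long$sector, long$shell), ]
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
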