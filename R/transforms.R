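# Volume transforms, lesion-change-label extraction and composite scores.

#' Inverse hyperbolic sine volume transform
#'
#' `asinh(v) = log(v + sqrt(v^2 + 1))` is variance-stabilizing for skewed
#' volume distributions and, unlike the log, valid at zero.
#'
#' @param v volume(s) in cm^3, nonnegative.
#' @return transformed value(s).
#' @export
asinh_volume <- function(v) {
  if (any(v < 0, na.rm = TRUE)) stop("volumes must be nonnegative")
  asinh(v)
}

#' WMH change on the asinh scale
#'
#' @param bl,fu baseline and follow-up volumes (cm^3).
#' @return `asinh(fu) - asinh(bl)`.
#' @export
wmh_change <- function(bl, fu) asinh_volume(fu) - asinh_volume(bl)

#' Volumes from a lesion-change label map
#'
#' A lesion-change label (LCL) map is an integer volume with values 0
#' (background), 1 (regressed lesion), 2 (stable lesion), 3 (new lesion).
#' The baseline lesion volume is the volume of all stable voxels (label 2);
#' the follow-up volume adds regressed and new voxels (labels 1 and 3).
#'
#' @param map integer array (any dimensionality) with values in 0..3, or the
#'   path to a NIfTI file (read with the RNifti package; voxel volume taken
#'   from the header unless given).
#' @param voxel_volume_mm3 volume of one voxel in mm^3.
#' @return named numeric: `baseline` and `followup` volumes in cm^3.
#' @export
lcl_volumes <- function(map, voxel_volume_mm3 = NULL) {
  if (is.character(map)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI label maps requires the RNifti package")
    img <- RNifti::readNifti(map)
    if (is.null(voxel_volume_mm3))
      voxel_volume_mm3 <- prod(RNifti::pixdim(img))
    map <- as.array(img)
  }
  if (is.null(voxel_volume_mm3) || voxel_volume_mm3 <= 0)
    stop("'voxel_volume_mm3' must be a positive voxel volume")
  vals <- as.vector(map)
  if (anyNA(vals) || any(vals != as.integer(vals)) ||
      any(!(vals %in% 0:3)))
    stop("label map may only contain integer labels 0, 1, 2, 3")
  mm3_to_cm3 <- 1e-3
  c(baseline = sum(vals == 2L) * voxel_volume_mm3 * mm3_to_cm3,
    followup = sum(vals %in% c(1L, 3L)) * voxel_volume_mm3 * mm3_to_cm3)
}

# z-score against a stored reference (mean/sd), NA-safe
.z <- function(x, ref) (x - ref["mean"]) / ref["sd"]

#' CERAD-plus composite cognitive scores
#'
#' Builds standardized executive, processing-speed, memory and global
#' composites from raw test scores, pooling both timepoints for every
#' z-scoring step:
#' \itemize{
#'   \item executive: mean of -z(TMT-B time / TMT-A time), z(phonemic
#'     fluency), z(semantic fluency);
#'   \item processing speed: -z(TMT-A time);
#'   \item memory: mean of z(word-list learning sum), z(delayed recall),
#'     z(recognition);
#'   \item global: mean of the three domain composites.
#' }
#' All four composites are re-z-scored so each has mean 0 and SD 1 over the
#' scored rows. Timepoints with TMT-A or TMT-B above 300 s are dropped from
#' the executive and speed composites; composites with missing components are
#' built from the remaining components; subjects without any contributing
#' test at both timepoints receive `NA` for that composite.
#'
#' @param data data frame with columns `subj_id`, `time` and the raw tests
#'   `tmt_a`, `tmt_b`, `fluency_phon`, `fluency_sem`, `wl_learning`,
#'   `wl_recall`, `wl_recognition` (missing tests may be `NA` or absent).
#' @param tmt_cutoff_s outlier cutoff for the trail-making times in seconds.
#' @param reference optionally, a reference object returned by a previous
#'   call (in `attr(, "reference")`) so that new data are scored against the
#'   stored standardization population.
#' @return object of class `wmh_composite_scores`: data frame `subj_id`,
#'   `time`, `z_exec`, `z_speed`, `z_memory`, `z_global` plus a logical
#'   component-availability matrix in `attr(, "components")` and the
#'   standardization reference in `attr(, "reference")`.
#' @export
composite_scores <- function(data, tmt_cutoff_s = 300, reference = NULL) {
  tests <- c("tmt_a", "tmt_b", "fluency_phon", "fluency_sem",
             "wl_learning", "wl_recall", "wl_recognition")
  for (t in setdiff(tests, names(data))) data[[t]] <- NA_real_
  if (any(stats::na.omit(data$tmt_a) <= 0) ||
      any(stats::na.omit(data$tmt_b) <= 0))
    stop("trail-making times must be positive")

  tmt_out <- (!is.na(data$tmt_a) & data$tmt_a > tmt_cutoff_s) |
    (!is.na(data$tmt_b) & data$tmt_b > tmt_cutoff_s)
  ratio <- ifelse(tmt_out, NA_real_, data$tmt_b / data$tmt_a)
  tmt_a_use <- ifelse(tmt_out, NA_real_, data$tmt_a)

  subs <- list(
    neg_ratio = -ratio, phon = data$fluency_phon, sem = data$fluency_sem,
    neg_tmt_a = -tmt_a_use,
    learning = data$wl_learning, recall = data$wl_recall,
    recog = data$wl_recognition)

  new_ref <- is.null(reference)
  if (new_ref) reference <- list(sub = list(), comp = list())
  zfit <- function(x, nm, stage) {
    if (new_ref) {
      m <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
      if (!is.finite(s) || s == 0)
        stop("cannot standardize '", nm, "': zero or undefined variance")
      reference[[stage]][[nm]] <<- c(mean = m, sd = s)
    }
    ref <- reference[[stage]][[nm]]
    if (is.null(ref)) stop("reference has no entry for '", nm, "'")
    as.numeric(.z(x, ref))
  }
  zs <- mapply(zfit, subs, names(subs), MoreArgs = list(stage = "sub"),
               SIMPLIFY = FALSE)

  comp_mean <- function(parts) {
    m <- do.call(cbind, parts)
    k <- rowSums(!is.na(m))
    out <- rowMeans(m, na.rm = TRUE)
    out[k == 0] <- NA_real_
    out
  }
  raw <- list(
    z_exec = comp_mean(zs[c("neg_ratio", "phon", "sem")]),
    z_speed = zs$neg_tmt_a,
    z_memory = comp_mean(zs[c("learning", "recall", "recog")]))
  raw$z_global <- comp_mean(raw)

  final <- mapply(zfit, raw, names(raw), MoreArgs = list(stage = "comp"),
                  SIMPLIFY = FALSE)
  out <- data.frame(subj_id = data$subj_id, time = data$time, final)

  comp_avail <- cbind(
    exec = rowSums(!is.na(do.call(cbind, zs[c("neg_ratio", "phon", "sem")]))),
    speed = as.integer(!is.na(zs$neg_tmt_a)),
    memory = rowSums(!is.na(do.call(cbind, zs[c("learning", "recall", "recog")]))))
  attr(out, "components") <- comp_avail
  attr(out, "reference") <- reference
  class(out) <- c("wmh_composite_scores", "data.frame")
  out
}

#' Append composite scores to a cohort
#'
#' @param cohort a `wmh_cohort` with raw test columns.
#' @param ... passed to [composite_scores()].
#' @return cohort with `z_exec`, `z_speed`, `z_memory`, `z_global` columns.
#' @export
add_composite_scores <- function(cohort, ...) {
  sc <- composite_scores(cohort, ...)
  idx <- match(paste(cohort$subj_id, cohort$time),
               paste(sc$subj_id, sc$time))
  for (v in c("z_exec", "z_speed", "z_memory", "z_global"))
    cohort[[v]] <- sc[[v]][idx]
  attr(cohort, "score_reference") <- attr(sc, "reference")
  cohort
}

#' @export
print.wmh_composite_scores <- function(x, ...) {
  cat(sprintf("<wmh_composite_scores> %d rows\n", nrow(x)))
  print(head(as.data.frame(x), 4L))
  invisible(x)
}
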