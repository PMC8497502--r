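# Per-cell normalization of flux metrics and the variation statistics used
# to judge it: within-subject standard scores and the between-subject
# coefficient of variation.

#' Normalize a rate by the estimated cell number
#'
#' Re-expresses a per-well rate at a common reference cell number:
#' `value * reference_cells / estimated_cells`. The default reference is
#' 100,000 cells, the usual plating target. Wells with a non-positive (or
#' missing) cell estimate cannot be normalized and return `NA` with a
#' warning; such wells are excluded from normalized summaries rather than
#' back-filled from seeded counts.
#'
#' @param value numeric rate(s) (pmol/min or mpH/min).
#' @param estimated_cells image-estimated cells in the well (vectorized).
#' @param reference_cells reference cell number (> 0), default 1e5.
#' @return Normalized rate(s), `NA` where un-normalizable.
#' @examples
#' normalize_metric(50, 50000)   # 100
#' @export
normalize_metric <- function(value, estimated_cells, reference_cells = 1e5) {
  stopifnot(is.numeric(value), is.numeric(estimated_cells),
            is.numeric(reference_cells), length(reference_cells) == 1,
            reference_cells > 0)
  bad <- is.na(estimated_cells) | estimated_cells <= 0
  if (any(bad))
    warning(sum(bad), " well(s) with non-positive estimated cell number ",
            "flagged un-normalizable", call. = FALSE)
  out <- ifelse(bad, NA_real_, value * reference_cells / estimated_cells)
  out
}

#' Standard scores of one subject's technical-replicate wells
#'
#' `z_i = (value_i - mean(values)) / sd(values)` with the sample standard
#' deviation (n - 1 denominator), the within-subject variation measure for
#' the 4-10 replicate wells a subject typically contributes.
#'
#' @param values numeric vector of one subject's well values (length >= 2).
#' @param subject_id label used in error messages.
#' @return Numeric vector of z-scores (mean 0, sample s.d. 1).
#' @examples
#' zscore_wells(c(1, 2, 3))
#' @export
zscore_wells <- function(values, subject_id = "<subject>") {
  stopifnot(is.numeric(values))
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop("insufficient wells for subject ", subject_id,
         ": need >= 2 values", call. = FALSE)
  s <- sd(values)
  if (s == 0)
    stop("undefined standard score for subject ", subject_id,
         ": zero standard deviation", call. = FALSE)
  (values - mean(values)) / s
}

#' Between-subject coefficient of variation
#'
#' `100 * sd(subject_means) / mean(subject_means)` (sample s.d.), in
#' percent: the between-subject variation of a cohort summarized by one
#' mean per subject.
#'
#' @param subject_means numeric vector of per-subject means (length >= 2,
#'   mean != 0).
#' @return CV in percent.
#' @examples
#' cohort_cv(c(10, 20))  # 47.14045
#' @export
cohort_cv <- function(subject_means) {
  stopifnot(is.numeric(subject_means))
  subject_means <- subject_means[!is.na(subject_means)]
  if (length(subject_means) < 2)
    stop("need >= 2 subject means", call. = FALSE)
  m <- mean(subject_means)
  if (m == 0) stop("undefined CV: mean of subject means is 0", call. = FALSE)
  100 * sd(subject_means) / m
}

#' Energetic-phenotype coordinates
#'
#' Places each well in the (OCR, ECAR) plane: the basal point
#' `(basal_ocr, basal_ecar)` and, when the uncoupled and oligomycin phases
#' are available, the stressed point `(max_ocr, post_om_ecar)`. Each point
#' is assigned a quadrant relative to configurable axis midpoints:
#' `energetic` (high OCR, high ECAR), `aerobic` (high OCR, low ECAR),
#' `glycolytic` (low, high) or `quiescent` (low, low).
#'
#' @param metrics a `well_metrics` data.frame.
#' @param ocr_mid,ecar_mid axis midpoints; default to the cohort means of
#'   the basal coordinates.
#' @return data.frame with basal and stressed coordinates and quadrant
#'   labels per well (stressed columns `NA` when those phases are missing).
#' @export
energetic_phenotype <- function(metrics, ocr_mid = NULL, ecar_mid = NULL) {
  stopifnot(is.data.frame(metrics),
            all(c("basal_ocr", "basal_ecar") %in% names(metrics)))
  if (is.null(ocr_mid)) ocr_mid <- mean(metrics$basal_ocr, na.rm = TRUE)
  if (is.null(ecar_mid)) ecar_mid <- mean(metrics$basal_ecar, na.rm = TRUE)
  quadrant <- function(ocr, ecar) {
    ifelse(is.na(ocr) | is.na(ecar), NA_character_,
      ifelse(ocr >= ocr_mid,
             ifelse(ecar >= ecar_mid, "energetic", "aerobic"),
             ifelse(ecar >= ecar_mid, "glycolytic", "quiescent")))
  }
  s_ocr <- if ("max_ocr" %in% names(metrics)) metrics$max_ocr else NA_real_
  s_ecar <- if ("post_om_ecar" %in% names(metrics)) metrics$post_om_ecar
            else NA_real_
  data.frame(well = metrics$well,
             basal_ocr = metrics$basal_ocr, basal_ecar = metrics$basal_ecar,
             basal_quadrant = quadrant(metrics$basal_ocr, metrics$basal_ecar),
             stressed_ocr = s_ocr, stressed_ecar = s_ecar,
             stressed_quadrant = quadrant(s_ocr, s_ecar),
             stringsAsFactors = FALSE)
}

#' Read a plate-layout table
#'
#' Layout CSV dialect: `plate_id,well,subject_id,group,seeded_cells`
#' (`group` and `seeded_cells` optional).
#'
#' @param path CSV path.
#' @return data.frame with normalized well coordinates.
#' @export
read_layout_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "subject_id")
  if (!all(need %in% names(x)))
    stop("layout must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(is.na(x$subject_id) | x$subject_id == ""))
    stop("layout has empty subject_id entries", call. = FALSE)
  x$well <- normalize_well(x$well)
  x
}

#' Cohort summary of a per-well metric
#'
#' Joins per-well metrics with the plate layout and summarizes one metric
#' per subject over its QC-passing wells: well count, mean, sample s.d.,
#' per-well standard scores and the mean absolute standard score. Across
#' subjects it reports the coefficient of variation of the subject means.
#' When estimated cell numbers are supplied the same summary is computed on
#' the per-cell normalized metric; wells lacking an estimate drop out of the
#' normalized summary only.
#'
#' QC-failing wells never contribute to subject means. A cohort with no
#' QC-passing wells yields an empty summary with a warning. Subjects with
#' fewer than 2 usable wells, or zero spread, get `NA` standard scores.
#'
#' @param metrics a `well_metrics` data.frame with `qc_pass` set.
#' @param layout layout data.frame (`well`, `subject_id`, ...).
#' @param metric metric column to summarize, default `"basal_ocr"`.
#' @param estimated_cells optional named vector (names = wells) or
#'   data.frame (`well`, `estimated_cells`) of image-estimated cell numbers.
#' @param reference_cells reference for [normalize_metric()], default 1e5.
#' @return List of class `cohort_summary`: `wells` (per-well values and
#'   z-scores), `per_subject` (per-subject summaries), `cohort` (one-row
#'   data.frame with `n_subjects`, `mean_abs_z`, `cv_percent` for the raw
#'   and, when available, normalized variants).
#' @export
cohort_summary <- function(metrics, layout, metric = "basal_ocr",
                           estimated_cells = NULL, reference_cells = 1e5) {
  stopifnot(is.data.frame(metrics), metric %in% names(metrics))
  if (!all(metrics$well %in% layout$well))
    stop("wells with metrics missing from the layout: ",
         paste(setdiff(metrics$well, layout$well), collapse = ", "),
         call. = FALSE)
  d <- merge(as.data.frame(metrics)[, c("well", metric, "qc_pass")],
             layout[, c("well", "subject_id")], by = "well")
  names(d)[names(d) == metric] <- "value"
  if (is.data.frame(estimated_cells))
    estimated_cells <- setNames(estimated_cells$estimated_cells,
                                estimated_cells$well)
  if (!is.null(estimated_cells)) {
    est <- unname(estimated_cells[d$well])
    d$value_norm <- suppressWarnings(
      normalize_metric(d$value, est, reference_cells))
  }
  d <- d[!is.na(d$qc_pass) & d$qc_pass, , drop = FALSE]
  if (nrow(d) == 0) {
    warning("no QC-passing wells: summary is empty", call. = FALSE)
    empty <- data.frame()
    return(structure(list(wells = empty, per_subject = empty,
                          cohort = empty, metric = metric),
                     class = "cohort_summary"))
  }
  summarize <- function(col) {
    dd <- d[!is.na(d[[col]]), , drop = FALSE]
    per <- do.call(rbind, lapply(split(dd, dd$subject_id), function(s) {
      z <- tryCatch(zscore_wells(s[[col]], s$subject_id[1]),
                    error = function(e) rep(NA_real_, nrow(s)))
      data.frame(subject_id = s$subject_id[1], n_wells = nrow(s),
                 mean = mean(s[[col]]), sd = sd(s[[col]]),
                 mean_abs_z = mean(abs(z)), stringsAsFactors = FALSE)
    }))
    rownames(per) <- NULL
    z_all <- unlist(lapply(split(dd, dd$subject_id), function(s)
      tryCatch(zscore_wells(s[[col]], s$subject_id[1]),
               error = function(e) rep(NA_real_, nrow(s)))))
    cv <- if (nrow(per) >= 2 && mean(per$mean) != 0) cohort_cv(per$mean)
          else NA_real_
    list(per = per, z = z_all, cv = cv,
         mean_abs_z = mean(per$mean_abs_z, na.rm = TRUE))
  }
  raw <- summarize("value")
  wells <- d
  cohort <- data.frame(metric = metric, n_subjects = nrow(raw$per),
                       mean_abs_z = raw$mean_abs_z, cv_percent = raw$cv)
  per_subject <- raw$per
  if (!is.null(estimated_cells)) {
    nm <- summarize("value_norm")
    names(nm$per)[-(1:2)] <- paste0(names(nm$per)[-(1:2)], "_norm")
    per_subject <- merge(per_subject, nm$per[, -2], by = "subject_id",
                         all.x = TRUE)
    cohort$mean_abs_z_norm <- nm$mean_abs_z
    cohort$cv_percent_norm <- nm$cv
  }
  structure(list(wells = wells, per_subject = per_subject, cohort = cohort,
                 metric = metric),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary of", x$metric, "\n")
  if (nrow(x$cohort) == 0) {
    cat("  (empty: no QC-passing wells)\n")
    return(invisible(x))
  }
  cat(sprintf("  %d subjects; mean |z| = %.3f; between-subject CV = %.1f%%\n",
              x$cohort$n_subjects, x$cohort$mean_abs_z, x$cohort$cv_percent))
  if ("cv_percent_norm" %in% names(x$cohort))
    cat(sprintf("  normalized: mean |z| = %.3f; CV = %.1f%%\n",
                x$cohort$mean_abs_z_norm, x$cohort$cv_percent_norm))
  invisible(x)
}
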