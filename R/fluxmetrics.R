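# Extraction of mitochondrial and glycolytic metrics from per-well OCR/ECAR
# time-courses structured by a serial-injection schedule (mito stress test
# extended with 2-deoxyglucose).

#' Serial-injection schedule of a flux assay
#'
#' Describes the injection sequence and cycle structure of a plate run. The
#' default is the canonical extended mito stress test: 12 measurement cycles
#' of 3 min with 2 min of mixing in between, basal measurement over cycles
#' 1-3, then serial injections of 1.5 uM oligomycin (cycle 4), 1 uM FCCP
#' (cycle 7), 1.25 uM rotenone + 2.5 uM antimycin A (cycle 9) and 50 mM
#' 2-deoxyglucose (cycle 11). Phase labels are `basal` and `post_<name>` for
#' each injection.
#'
#' @param injections data.frame with columns `name`, `compound`,
#'   `concentration`, `first_cycle` (first measurement cycle after the
#'   injection), ordered by `first_cycle`.
#' @param n_cycles total number of measurement cycles.
#' @param measure_min,mix_min cycle timing in minutes (measurement, mixing).
#' @return An object of class `injection_schedule`.
#' @examples
#' injection_schedule()
#' @export
injection_schedule <- function(injections = NULL, n_cycles = 12,
                               measure_min = 3, mix_min = 2) {
  if (is.null(injections)) {
    injections <- data.frame(
      name = c("om", "fccp", "rotaa", "2dg"),
      compound = c("oligomycin", "FCCP", "rotenone+antimycin A",
                   "2-deoxyglucose"),
      concentration = c("1.5 uM", "1 uM", "1.25 uM + 2.5 uM", "50 mM"),
      first_cycle = c(4L, 7L, 9L, 11L),
      stringsAsFactors = FALSE)
  }
  need <- c("name", "compound", "concentration", "first_cycle")
  if (!all(need %in% names(injections)))
    stop("`injections` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  fc <- injections$first_cycle
  stopifnot(is.numeric(n_cycles), n_cycles >= 1,
            measure_min > 0, mix_min >= 0)
  if (nrow(injections) > 0) {
    if (any(fc < 2) || any(fc > n_cycles))
      stop("injection `first_cycle` values must lie in [2, n_cycles]",
           call. = FALSE)
    if (any(diff(fc) <= 0))
      stop("injections must be ordered with strictly increasing first_cycle",
           call. = FALSE)
    if (anyDuplicated(injections$name))
      stop("injection names must be unique", call. = FALSE)
  }
  structure(list(injections = injections,
                 n_cycles = as.integer(n_cycles),
                 measure_min = measure_min, mix_min = mix_min),
            class = "injection_schedule")
}

#' @export
print.injection_schedule <- function(x, ...) {
  cat(sprintf("Injection schedule: %d cycles (%g min measure + %g min mix)\n",
              x$n_cycles, x$measure_min, x$mix_min))
  ph <- schedule_phases(x)
  for (p in unique(ph)) {
    cyc <- which(ph == p)
    cat(sprintf("  %-11s cycles %d-%d\n", p, min(cyc), max(cyc)))
  }
  invisible(x)
}

#' Phase label of every measurement cycle
#'
#' @param schedule an [injection_schedule()].
#' @return Character vector of length `n_cycles`: `"basal"` before the first
#'   injection, `"post_<name>"` afterwards.
#' @export
schedule_phases <- function(schedule) {
  stopifnot(inherits(schedule, "injection_schedule"))
  phases <- rep("basal", schedule$n_cycles)
  inj <- schedule$injections
  if (nrow(inj) > 0)
    for (i in seq_len(nrow(inj)))
      phases[inj$first_cycle[i]:schedule$n_cycles] <-
        paste0("post_", inj$name[i])
  phases
}

# Nominal time (min) at the end of each cycle's measurement window.
schedule_times <- function(schedule) {
  per <- schedule$measure_min + schedule$mix_min
  (seq_len(schedule$n_cycles) - 1) * per + schedule$measure_min
}

.FLUX_HEADER <- c("plate_id", "well", "cycle", "time_min",
                  "ocr_pmol_min", "ecar_mph_min")

#' Parse a plate flux CSV into phase-labelled well traces
#'
#' Reads the plate flux dialect (header
#' `plate_id,well,cycle,time_min,ocr_pmol_min,ecar_mph_min`, UTF-8, `.`
#' decimal, one row per well and cycle) and labels every cycle with its
#' phase from the schedule. Missing cycles remain gaps; they are never
#' interpolated.
#'
#' @param file path to the CSV.
#' @param schedule an [injection_schedule()].
#' @return A data.frame of class `flux_data` with columns `plate_id, well,
#'   cycle, time_min, ocr, ecar, phase` and the schedule stored as an
#'   attribute.
#' @export
parse_flux_csv <- function(file, schedule = injection_schedule()) {
  if (!file.exists(file)) stop("flux file not found: ", file, call. = FALSE)
  x <- read.csv(file, stringsAsFactors = FALSE)
  if (!identical(names(x), .FLUX_HEADER))
    stop("malformed flux header: expected ",
         paste(.FLUX_HEADER, collapse = ","), call. = FALSE)
  x$well <- normalize_well(x$well)
  dup <- duplicated(x[, c("well", "cycle")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate (well, cycle) at row %d: (%s, %d)",
                 i, x$well[i], x$cycle[i]), call. = FALSE)
  }
  if (any(x$cycle < 1 | x$cycle > schedule$n_cycles))
    stop("cycle index outside the schedule's 1..", schedule$n_cycles,
         call. = FALSE)
  x <- x[order(x$well, x$cycle), , drop = FALSE]
  for (w in unique(x$well)) {
    t <- x$time_min[x$well == w]
    if (any(diff(t) <= 0)) {
      bad <- which(x$well == w)[which(diff(t) <= 0)[1] + 1]
      stop(sprintf("non-monotone time for well %s at row %d", w, bad),
           call. = FALSE)
    }
  }
  out <- data.frame(plate_id = x$plate_id, well = x$well, cycle = x$cycle,
                    time_min = x$time_min, ocr = x$ocr_pmol_min,
                    ecar = x$ecar_mph_min, stringsAsFactors = FALSE)
  out$phase <- schedule_phases(schedule)[out$cycle]
  rownames(out) <- NULL
  structure(out, schedule = schedule, class = c("flux_data", "data.frame"))
}

#' Write phase-labelled traces back to the plate flux dialect
#'
#' Inverse of [parse_flux_csv()]: a written file parses back to identical
#' values.
#'
#' @param flux a `flux_data` data.frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_flux_csv <- function(flux, file) {
  stopifnot(is.data.frame(flux),
            all(c("plate_id", "well", "cycle", "time_min", "ocr", "ecar")
                %in% names(flux)))
  out <- data.frame(plate_id = flux$plate_id, well = flux$well,
                    cycle = flux$cycle, time_min = flux$time_min,
                    ocr_pmol_min = flux$ocr, ecar_mph_min = flux$ecar)
  out <- out[order(out$well, out$cycle), , drop = FALSE]
  write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Summarize one phase of a well trace
#'
#' Two statistics are available. `last_k_mean` averages the final `k` cycles
#' of the phase (default `k = 3`), the stable tail after the response to an
#' injection has settled. `extremum` takes the extreme rate over the phase:
#' the maximum for the FCCP (uncoupled) phase, the minimum for inhibitor
#' phases, which is where inhibition is most complete.
#'
#' @param trace data.frame for one well with columns `cycle`, `phase` and
#'   the measure column.
#' @param phase phase label (e.g. `"basal"`, `"post_om"`).
#' @param statistic `"last_k_mean"` or `"extremum"`.
#' @param k number of trailing cycles averaged by `last_k_mean`.
#' @param measure `"ocr"` or `"ecar"`.
#' @return A single rate (pmol/min for OCR, mpH/min for ECAR).
#' @export
phase_level <- function(trace, phase, statistic = c("last_k_mean", "extremum"),
                        k = 3, measure = c("ocr", "ecar")) {
  statistic <- match.arg(statistic)
  measure <- match.arg(measure)
  stopifnot(is.data.frame(trace), "phase" %in% names(trace),
            measure %in% names(trace))
  v <- trace[[measure]][trace$phase == phase]
  v <- v[order(trace$cycle[trace$phase == phase])]
  if (length(v) == 0)
    stop("phase `", phase, "` absent from trace", call. = FALSE)
  if (statistic == "last_k_mean") {
    if (length(v) < k)
      stop("phase `", phase, "` has ", length(v), " cycles, fewer than k = ",
           k, call. = FALSE)
    mean(v[(length(v) - k + 1):length(v)])
  } else {
    if (identical(phase, "post_fccp")) max(v) else min(v)
  }
}

#' Compute per-well flux metrics
#'
#' Derives the mitochondrial and glycolytic metrics of the extended mito
#' stress test from one well's phase-labelled trace:
#' \describe{
#'   \item{basal_ocr, basal_ecar}{mean of the last `k` basal cycles (raw
#'     rates, not non-mito-corrected; a corrected variant
#'     `basal_ocr_corrected = basal_ocr - nonmito_ocr` is emitted
#'     alongside).}
#'   \item{post_om_ocr}{minimum OCR after oligomycin.}
#'   \item{post_om_ecar}{mean ECAR over the tail of the oligomycin phase.}
#'   \item{max_ocr}{maximum OCR after FCCP (maximal respiration).}
#'   \item{nonmito_ocr}{minimum OCR after rotenone/antimycin A.}
#'   \item{post_2dg_ocr}{minimum OCR after 2-deoxyglucose.}
#'   \item{atp_linked}{`basal_ocr - post_om_ocr`.}
#'   \item{proton_leak}{`post_om_ocr - nonmito_ocr`.}
#'   \item{src}{spare respiratory capacity, `max_ocr - basal_ocr`.}
#'   \item{dg_sensitive_nonmito}{`nonmito_ocr - post_2dg_ocr`.}
#'   \item{om_ecar_response}{`post_om_ecar - basal_ecar`.}
#' }
#' Phases missing from the trace yield `NA` for their metrics and every
#' derived quantity that needs them; an empty basal phase is an error. By
#' construction `basal_ocr = atp_linked + proton_leak + nonmito_ocr`
#' exactly.
#'
#' @param trace one-well data.frame with `cycle`, `phase`, `ocr`, `ecar`.
#' @param k trailing cycles averaged for basal and ECAR levels (default 3).
#' @param well_id well label carried into the result.
#' @return One-row data.frame of class `well_metrics` (field `qc_pass` is
#'   `NA` until [qc_detection_limit()] is applied).
#' @export
compute_metrics <- function(trace, k = 3, well_id = NULL) {
  stopifnot(is.data.frame(trace))
  if (is.null(well_id))
    well_id <- if ("well" %in% names(trace)) trace$well[1] else NA_character_
  if (!any(trace$phase == "basal"))
    stop("empty basal phase for well ", well_id, call. = FALSE)
  lev <- function(phase, statistic, measure) {
    if (!any(trace$phase == phase)) return(NA_real_)
    n <- sum(trace$phase == phase)
    phase_level(trace, phase, statistic, k = min(k, n), measure = measure)
  }
  basal_ocr   <- lev("basal", "last_k_mean", "ocr")
  basal_ecar  <- lev("basal", "last_k_mean", "ecar")
  post_om_ocr <- lev("post_om", "extremum", "ocr")
  post_om_ecar <- lev("post_om", "last_k_mean", "ecar")
  max_ocr     <- lev("post_fccp", "extremum", "ocr")
  nonmito_ocr <- lev("post_rotaa", "extremum", "ocr")
  post_2dg_ocr <- lev("post_2dg", "extremum", "ocr")
  out <- data.frame(
    well = well_id,
    basal_ocr = basal_ocr, basal_ecar = basal_ecar,
    post_om_ocr = post_om_ocr, post_om_ecar = post_om_ecar,
    max_ocr = max_ocr, nonmito_ocr = nonmito_ocr,
    post_2dg_ocr = post_2dg_ocr,
    atp_linked = basal_ocr - post_om_ocr,
    proton_leak = post_om_ocr - nonmito_ocr,
    src = max_ocr - basal_ocr,
    dg_sensitive_nonmito = nonmito_ocr - post_2dg_ocr,
    om_ecar_response = post_om_ecar - basal_ecar,
    basal_ocr_corrected = basal_ocr - nonmito_ocr,
    qc_pass = NA,
    stringsAsFactors = FALSE)
  class(out) <- c("well_metrics", "data.frame")
  out
}

#' Compute metrics for every well of a plate
#'
#' @param flux a `flux_data` data.frame from [parse_flux_csv()] or
#'   [synth_flux_plate()].
#' @param k trailing cycles for [compute_metrics()].
#' @param qc_limit detection limit in pmol/min passed to
#'   [qc_detection_limit()]; `NULL` leaves `qc_pass` unset.
#' @return data.frame of class `well_metrics`, one row per well.
#' @export
compute_plate_metrics <- function(flux, k = 3, qc_limit = 20) {
  stopifnot(is.data.frame(flux))
  rows <- lapply(split(flux, flux$well), compute_metrics, k = k)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("well_metrics", "data.frame")
  if (!is.null(qc_limit)) out <- qc_detection_limit(out, qc_limit)
  out
}

#' Apply the OCR detection-limit QC filter
#'
#' Basal OCR below the instrument's reliable detection limit (20 pmol/min by
#' convention) marks a well as failing QC. The boundary is inclusive: a well
#' exactly at the limit passes. Failing wells are retained in outputs but
#' excluded from group statistics downstream.
#'
#' @param metrics a `well_metrics` data.frame.
#' @param limit detection limit in pmol/min (> 0), default 20.
#' @return `metrics` with `qc_pass` set.
#' @export
qc_detection_limit <- function(metrics, limit = 20) {
  stopifnot(is.data.frame(metrics), "basal_ocr" %in% names(metrics),
            is.numeric(limit), length(limit) == 1, limit > 0)
  metrics$qc_pass <- !is.na(metrics$basal_ocr) & metrics$basal_ocr >= limit
  metrics
}

#' Write a per-well metrics table
#' @param metrics a `well_metrics` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  write.csv(as.data.frame(metrics), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
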