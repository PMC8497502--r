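# Synthetic well images and flux plates with known ground truth. These
# emulate the structure of real data (smooth brightfield background with
# dark cell-sized blobs; phase-structured OCR/ECAR traces with per-well
# cell-count variation) so the analysis modules are testable end to end
# without any real plate. No attempt is made at photorealistic optics.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic brightfield well image
#'
#' Renders a smooth background (constant, linear gradient, or a smooth 2-D
#' quadratic field) with `n_cells` dark soft-edged disks at uniformly
#' sampled centers, plus additive Gaussian noise, clipped to 0-255. Disks
#' have a linear intensity falloff over 1 px beyond their radius so
#' thresholding near edges is exercised. Deterministic for a fixed seed.
#'
#' @param n_cells number of cells to render (>= 0).
#' @param width,height image size in pixels (>= 16).
#' @param radius_range cell radius range in pixels, sampled uniformly.
#' @param darkness intensity drop at a cell center below the background.
#' @param background `"constant"`, `"gradient"` or `"poly"`.
#' @param bg_level mean background intensity (0-255 scale).
#' @param noise_sd additive Gaussian noise s.d. (intensity units).
#' @param allow_overlap if `FALSE`, centers are re-sampled so disks do not
#'   overlap; errors when the area is exhausted.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return List with `image` (matrix, 0-255), `n_cells`, and `centers`
#'   (data.frame `x`, `y`, `radius`).
#' @examples
#' s <- synth_well_image(n_cells = 20, width = 64, height = 64, seed = 1)
#' quantify_well(s$image)
#' @export
synth_well_image <- function(n_cells, width = 256, height = 256,
                             radius_range = c(2, 4), darkness = 60,
                             background = c("constant", "gradient", "poly"),
                             bg_level = 180, noise_sd = 2,
                             allow_overlap = TRUE, seed = NULL) {
  background <- match.arg(background)
  stopifnot(n_cells >= 0, width >= .MIN_DIM, height >= .MIN_DIM,
            length(radius_range) == 2, all(radius_range > 0),
            radius_range[1] <= radius_range[2], darkness >= 0, noise_sd >= 0)
  with_seed(seed, {
    bg <- switch(background,
      constant = matrix(bg_level, height, width),
      gradient = matrix(bg_level, height, width) +
        outer(rep(1, height), seq(-15, 15, length.out = width)),
      poly = {
        u <- seq(-1, 1, length.out = height)
        v <- seq(-1, 1, length.out = width)
        bg_level + 15 * outer(1 - u^2, 1 - v^2)
      })
    centers <- data.frame(x = numeric(0), y = numeric(0), radius = numeric(0))
    drop <- matrix(0, height, width)
    if (n_cells > 0) {
      xs <- ys <- rs <- numeric(n_cells)
      tries <- 0L
      max_tries <- 200L * n_cells
      i <- 1L
      while (i <= n_cells) {
        x <- runif(1, 1, width)
        y <- runif(1, 1, height)
        r <- runif(1, radius_range[1], radius_range[2])
        if (!allow_overlap && i > 1) {
          d2 <- (xs[seq_len(i - 1)] - x)^2 + (ys[seq_len(i - 1)] - y)^2
          if (any(d2 < (rs[seq_len(i - 1)] + r)^2)) {
            tries <- tries + 1L
            if (tries > max_tries)
              stop("cells cannot fit: area exhausted with overlap disallowed",
                   call. = FALSE)
            next
          }
        }
        xs[i] <- x; ys[i] <- y; rs[i] <- r
        # stamp a soft disk: full `darkness` inside radius, linear falloff
        # over 1 px; overlapping cells occlude (max drop wins)
        ri <- max(1L, floor(y - r - 1)):min(height, ceiling(y + r + 1))
        ci <- max(1L, floor(x - r - 1)):min(width, ceiling(x + r + 1))
        dist <- sqrt(outer((ri - y)^2, (ci - x)^2, `+`))
        w <- pmin(pmax(r + 1 - dist, 0), 1)
        drop[ri, ci] <- pmax(drop[ri, ci], darkness * w)
        i <- i + 1L
      }
      centers <- data.frame(x = xs, y = ys, radius = rs)
    }
    img <- bg - drop
    if (noise_sd > 0)
      img <- img + matrix(rnorm(height * width, sd = noise_sd), height, width)
    list(image = pmin(pmax(img, 0), 255), n_cells = as.integer(n_cells),
         centers = centers)
  })
}

# 96-well coordinates in row-major order: A01..A12, B01..B12, ...
plate_wells <- function(n) {
  stopifnot(n >= 1, n <= 96)
  sprintf("%s%02d", rep(LETTERS[1:8], each = 12), rep(1:12, 8))[seq_len(n)]
}

#' Generate a synthetic flux plate with known ground truth
#'
#' Builds a cohort of subjects with technical-replicate wells. The per-cell
#' metabolic rates of every subject are the supplied phase levels scaled by
#' a per-subject multiplier (log-normal, mean 1, CV `subject_rate_cv`); the
#' cells in each well are sampled log-normally around `target_cells` with CV
#' `cell_cv` to mimic pipetting variation. Each well's observed rate in a
#' cycle is its phase level times `true_cells / target_cells` times the
#' subject multiplier, plus Gaussian noise. Phase levels default to a trace
#' typical of primary intestinal epithelial cells: a modest oligomycin
#' response (high apparent proton leak), a small spare respiratory capacity,
#' and a further OCR drop after 2-deoxyglucose.
#'
#' @param n_subjects number of subjects (default 7).
#' @param wells_per_subject technical replicate wells per subject.
#' @param phase_ocr,phase_ecar named per-phase true levels at
#'   `target_cells` cells (pmol/min and mpH/min); names must match the
#'   schedule's phase labels.
#' @param ocr_noise_sd,ecar_noise_sd additive per-cycle noise s.d.
#' @param target_cells seeding target per well (cells).
#' @param cell_cv between-well coefficient of variation of true cell counts.
#' @param subject_rate_cv between-subject CV of per-cell rates.
#' @param schedule an [injection_schedule()].
#' @param plate_id plate label.
#' @param seed RNG seed.
#' @return List with `flux` (a `flux_data` data.frame), `layout`
#'   (`plate_id, well, subject_id, group, seeded_cells`), and `truth` (the
#'   parameters plus per-well `true_cells` and scale factors and per-subject
#'   multipliers).
#' @examples
#' p <- synth_flux_plate(n_subjects = 2, wells_per_subject = 3, seed = 1)
#' compute_plate_metrics(p$flux)
#' @export
synth_flux_plate <- function(n_subjects = 7, wells_per_subject = 8,
                             phase_ocr = c(basal = 70, post_om = 60,
                                           post_fccp = 90, post_rotaa = 18,
                                           post_2dg = 12),
                             phase_ecar = c(basal = 30, post_om = 34,
                                            post_fccp = 30, post_rotaa = 22,
                                            post_2dg = 10),
                             ocr_noise_sd = 2, ecar_noise_sd = 1,
                             target_cells = 1e5, cell_cv = 0.25,
                             subject_rate_cv = 0.15,
                             schedule = injection_schedule(),
                             plate_id = "synth1", seed = NULL) {
  stopifnot(n_subjects >= 1, wells_per_subject >= 1,
            n_subjects * wells_per_subject <= 96,
            all(phase_ocr >= 0), all(phase_ecar >= 0),
            ocr_noise_sd >= 0, ecar_noise_sd >= 0,
            target_cells > 0, cell_cv >= 0, subject_rate_cv >= 0)
  phases <- schedule_phases(schedule)
  if (!all(unique(phases) %in% names(phase_ocr)) ||
      !all(unique(phases) %in% names(phase_ecar)))
    stop("phase levels must be named for every schedule phase: ",
         paste(unique(phases), collapse = ", "), call. = FALSE)
  with_seed(seed, {
    n_wells <- n_subjects * wells_per_subject
    wells <- plate_wells(n_wells)
    subjects <- rep(sprintf("S%02d", seq_len(n_subjects)),
                    each = wells_per_subject)
    rlnorm_cv <- function(n, mean, cv) {
      if (cv == 0) return(rep(mean, n))
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
    }
    subj_mult <- setNames(rlnorm_cv(n_subjects, 1, subject_rate_cv),
                          unique(subjects))
    true_cells <- rlnorm_cv(n_wells, target_cells, cell_cv)
    scale <- (true_cells / target_cells) * subj_mult[subjects]
    times <- schedule_times(schedule)
    nc <- schedule$n_cycles
    flux <- data.frame(
      plate_id = plate_id,
      well = rep(wells, each = nc),
      cycle = rep(seq_len(nc), n_wells),
      time_min = rep(times, n_wells),
      ocr = rep(phase_ocr[phases], n_wells) * rep(scale, each = nc) +
        rnorm(n_wells * nc, sd = ocr_noise_sd),
      ecar = rep(phase_ecar[phases], n_wells) * rep(scale, each = nc) +
        rnorm(n_wells * nc, sd = ecar_noise_sd),
      stringsAsFactors = FALSE)
    flux$phase <- phases[flux$cycle]
    rownames(flux) <- NULL
    flux <- structure(flux, schedule = schedule,
                      class = c("flux_data", "data.frame"))
    layout <- data.frame(plate_id = plate_id, well = wells,
                         subject_id = subjects, group = "cohort",
                         seeded_cells = target_cells,
                         stringsAsFactors = FALSE)
    truth <- list(phase_ocr = phase_ocr, phase_ecar = phase_ecar,
                  target_cells = target_cells, cell_cv = cell_cv,
                  subject_rate_cv = subject_rate_cv,
                  ocr_noise_sd = ocr_noise_sd, ecar_noise_sd = ecar_noise_sd,
                  true_cells = setNames(true_cells, wells),
                  scale = setNames(unname(scale), wells),
                  subject_multiplier = subj_mult)
    list(flux = flux, layout = layout, truth = truth)
  })
}

#' Generate synthetic calibration data
#'
#' Emulates a pooled standard-curve experiment: several subjects, each
#' seeded at a ladder of densities with replicate wells. The underlying
#' pixel response saturates gently with density (crowded cells overlap in
#' the image), and measured cell-pixels carry multiplicative noise.
#'
#' @param n_subjects subjects pooled into the curve (default 3).
#' @param densities seeded cell numbers (default four densities spanning
#'   50,000-150,000 cells/well).
#' @param wells_per_density replicate wells per subject and density.
#' @param noise_cv multiplicative noise CV on measured cell-pixels
#'   (default 0.05).
#' @param px_per_cell pixels contributed per cell at low density.
#' @param saturation fractional pixel loss per cell (crowding), applied as
#'   `pixels = px_per_cell * cells * (1 - saturation * cells)`.
#' @param subject_cv between-subject CV of `px_per_cell` (default 0:
#'   identical imaging response across subjects).
#' @param seed RNG seed.
#' @return List with `points` (data.frame
#'   `subject_id, seeded_cells, cell_pixels`) and `truth` (generator
#'   parameters and the noiseless pixel value per row).
#' @export
synth_calibration_data <- function(n_subjects = 3,
                                   densities = round(seq(50000, 150000,
                                                         length.out = 4)),
                                   wells_per_density = 4, noise_cv = 0.05,
                                   px_per_cell = 0.25, saturation = 1e-6,
                                   subject_cv = 0, seed = NULL) {
  stopifnot(n_subjects >= 1, all(densities > 0), wells_per_density >= 1,
            noise_cv >= 0, px_per_cell > 0, saturation >= 0,
            saturation * max(densities) < 1, subject_cv >= 0)
  with_seed(seed, {
    subj <- sprintf("S%02d", seq_len(n_subjects))
    rate <- px_per_cell * exp(rnorm(n_subjects, sd = subject_cv) -
                                subject_cv^2 / 2)
    rows <- expand.grid(rep_well = seq_len(wells_per_density),
                        seeded_cells = densities, subject_id = subj,
                        stringsAsFactors = FALSE)
    r <- rate[match(rows$subject_id, subj)]
    px_true <- r * rows$seeded_cells * (1 - saturation * rows$seeded_cells)
    px <- px_true * exp(rnorm(nrow(rows), sd = sqrt(log(1 + noise_cv^2))))
    points <- data.frame(subject_id = rows$subject_id,
                         seeded_cells = rows$seeded_cells,
                         cell_pixels = px, stringsAsFactors = FALSE)
    list(points = points,
         truth = list(px_per_cell = setNames(rate, subj),
                      saturation = saturation, noise_cv = noise_cv,
                      pixels_true = px_true))
  })
}
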