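# Quadratic calibration from cell-pixels to seeded cell number.
#
# Wells imaged at known seeding densities (several subjects pooled by plain
# concatenation) define one external calibration curve
#   cells = a * pixels^2 + b * pixels + c
# that converts cell-pixel counts from any plate back to cell numbers.

#' Fit the cell-pixel calibration curve
#'
#' Least-squares second-order polynomial with seeded cell number as the
#' response and cell-pixels as the predictor. Data from multiple subjects are
#' pooled by concatenation (no per-subject weighting); the fitted curve is
#' used as an external calibration applied to every plate.
#'
#' @param points data.frame with columns `cell_pixels` and `seeded_cells`
#'   (a `subject_id` column is allowed and ignored by the fit), or the two
#'   vectors given separately.
#' @param seeded_cells response vector when `points` is a numeric predictor
#'   vector.
#' @return An object of class `calibration_curve`: coefficients `a`, `b`,
#'   `c` (in `coef()` order `c, b, a` they are intercept, linear, quadratic),
#'   `r_squared`, `n_points` and `pixel_range`.
#' @examples
#' p <- 0:4
#' fit <- fit_calibration(data.frame(cell_pixels = p,
#'                                   seeded_cells = 2 * p^2 + 3 * p + 1))
#' coef(fit)
#' @export
fit_calibration <- function(points, seeded_cells = NULL) {
  if (is.data.frame(points)) {
    if (!all(c("cell_pixels", "seeded_cells") %in% names(points)))
      stop("`points` needs columns `cell_pixels` and `seeded_cells`",
           call. = FALSE)
    p <- points$cell_pixels
    y <- points$seeded_cells
  } else {
    p <- points
    y <- seeded_cells
  }
  stopifnot(is.numeric(p), is.numeric(y), length(p) == length(y))
  keep <- is.finite(p) & is.finite(y)
  p <- p[keep]; y <- y[keep]
  if (any(p < 0) || any(y < 0))
    stop("cell_pixels and seeded_cells must be non-negative", call. = FALSE)
  if (length(p) < 3 || length(unique(p)) < 3)
    stop("insufficient data: need >= 3 points with >= 3 distinct ",
         "cell-pixel values", call. = FALSE)
  fit <- lm(y ~ p + I(p^2))
  if (anyNA(coef(fit)))
    stop("rank-deficient design: calibration points are degenerate",
         call. = FALSE)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(a = unname(coef(fit)[3]),
                 b = unname(coef(fit)[2]),
                 c = unname(coef(fit)[1]),
                 r_squared = r2,
                 n_points = length(p),
                 pixel_range = range(p)),
            class = "calibration_curve")
}

#' Convert cell-pixel counts to estimated cell numbers
#'
#' Evaluates the quadratic `a p^2 + b p + c`, clipping negative estimates to
#' 0 (cell numbers are physical counts). Pixel values outside the calibrated
#' range are converted anyway but flagged and reported with a warning, since
#' the quadratic extrapolates without guarantees.
#'
#' @param curve a `calibration_curve`.
#' @param cell_pixels non-negative numeric vector of pixel counts.
#' @return Numeric vector of estimated cells, with logical attributes
#'   `clipped` and `extrapolated` marking affected elements.
#' @examples
#' curve <- fit_calibration(data.frame(cell_pixels = c(0, 10, 20),
#'                                     seeded_cells = c(0, 100, 400)))
#' predict_cells(curve, 15)
#' @export
predict_cells <- function(curve, cell_pixels) {
  stopifnot(inherits(curve, "calibration_curve"), is.numeric(cell_pixels))
  if (any(cell_pixels < 0, na.rm = TRUE))
    stop("`cell_pixels` must be >= 0", call. = FALSE)
  raw <- curve$a * cell_pixels^2 + curve$b * cell_pixels + curve$c
  clipped <- !is.na(raw) & raw < 0
  extrap <- !is.na(cell_pixels) &
    (cell_pixels < curve$pixel_range[1] | cell_pixels > curve$pixel_range[2])
  if (any(extrap))
    warning(sum(extrap), " cell-pixel value(s) outside the calibrated range [",
            format(curve$pixel_range[1]), ", ",
            format(curve$pixel_range[2]), "]; extrapolating", call. = FALSE)
  out <- pmax(raw, 0)
  attr(out, "clipped") <- clipped
  attr(out, "extrapolated") <- extrap
  out
}

#' @export
predict.calibration_curve <- function(object, newdata, ...) {
  predict_cells(object, newdata)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  c(c = object$c, b = object$b, a = object$a)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("External cell-pixel calibration curve\n")
  cat(sprintf("  cells = %.6g * p^2 + %.6g * p + %.6g\n", x$a, x$b, x$c))
  cat(sprintf("  R^2 = %.4f on %d points, pixel range [%s, %s]\n",
              x$r_squared, x$n_points,
              format(x$pixel_range[1]), format(x$pixel_range[2])))
  invisible(x)
}

#' @export
summary.calibration_curve <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Persist or load a calibration curve as plain text
#'
#' The curve is stored as a small `key: value` (DCF) text file holding the
#' three coefficients, goodness of fit, number of points and calibrated
#' pixel range.
#'
#' @param curve a `calibration_curve`.
#' @param path file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns the `calibration_curve`.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  df <- data.frame(a = format(curve$a, digits = 17),
                   b = format(curve$b, digits = 17),
                   c = format(curve$c, digits = 17),
                   r_squared = format(curve$r_squared, digits = 17),
                   n_points = curve$n_points,
                   pixel_min = format(curve$pixel_range[1], digits = 17),
                   pixel_max = format(curve$pixel_range[2], digits = 17))
  write.dcf(df, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("curve file not found: ", path, call. = FALSE)
  d <- read.dcf(path)
  need <- c("a", "b", "c", "r_squared", "n_points", "pixel_min", "pixel_max")
  if (!all(need %in% colnames(d)))
    stop("malformed calibration file: missing fields ",
         paste(setdiff(need, colnames(d)), collapse = ", "), call. = FALSE)
  v <- function(k) as.numeric(d[1, k])
  structure(list(a = v("a"), b = v("b"), c = v("c"),
                 r_squared = v("r_squared"),
                 n_points = as.integer(v("n_points")),
                 pixel_range = c(v("pixel_min"), v("pixel_max"))),
            class = "calibration_curve")
}
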