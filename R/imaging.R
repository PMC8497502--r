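# Canonical intensity scale for all imaging operations. Brightfield well
# images are converted to a single channel on 0-255 before any processing;
# the cell-pixel threshold is expressed on that scale.
.GRAY_MAX <- 255
.MIN_DIM <- 16L

check_gray_image <- function(x, arg = "image", min_dim = .MIN_DIM) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (nrow(x) < min_dim || ncol(x) < min_dim)
    stop(sprintf("`%s` must be at least %dx%d pixels", arg, min_dim, min_dim),
         call. = FALSE)
  if (any(!is.finite(x)))
    stop(sprintf("`%s` contains non-finite pixel values", arg), call. = FALSE)
  invisible(x)
}

#' Imaging parameters for cell-pixel quantification
#'
#' Bundles the three tunables of the brightfield pipeline: the Gaussian
#' standard deviation used to estimate the smooth background, the fraction of
#' each margin cropped away (per side) to remove artefacts from the assay
#' plate's molded stops, and the intensity threshold above which a pixel of
#' the processed image counts as cell material.
#'
#' `background_sigma = NULL` (the default) resolves at run time to
#' `min(height, width) / 10`, which keeps the background filter low-pass
#' relative to single-cell size at typical 4x magnification.
#'
#' @param background_sigma Gaussian s.d. in pixels (> 0), or `NULL` for the
#'   size-relative default.
#' @param crop_fraction fraction of each dimension removed per side,
#'   in `[0, 0.5)`. Default 0.05.
#' @param threshold intensity cutoff on the 0-255 scale (>= 0). Pixels
#'   strictly above it are counted. Default 1.
#' @return An object of class `imaging_params`.
#' @examples
#' imaging_params()
#' imaging_params(background_sigma = 20, threshold = 2)
#' @export
imaging_params <- function(background_sigma = NULL, crop_fraction = 0.05,
                           threshold = 1) {
  if (!is.null(background_sigma)) {
    stopifnot(is.numeric(background_sigma), length(background_sigma) == 1)
    if (!is.finite(background_sigma) || background_sigma <= 0)
      stop("`background_sigma` must be > 0", call. = FALSE)
  }
  stopifnot(is.numeric(crop_fraction), length(crop_fraction) == 1)
  if (!is.finite(crop_fraction) || crop_fraction < 0 || crop_fraction >= 0.5)
    stop("`crop_fraction` must be in [0, 0.5)", call. = FALSE)
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  if (!is.finite(threshold) || threshold < 0)
    stop("`threshold` must be >= 0", call. = FALSE)
  structure(list(background_sigma = background_sigma,
                 crop_fraction = crop_fraction,
                 threshold = threshold),
            class = "imaging_params")
}

#' @export
print.imaging_params <- function(x, ...) {
  cat("Imaging parameters (cell-pixel pipeline)\n")
  cat("  background sigma:", if (is.null(x$background_sigma))
    "min(height, width)/10" else x$background_sigma, "px\n")
  cat("  crop fraction:   ", x$crop_fraction, "per side\n")
  cat("  threshold:       >", x$threshold, "(0-255 scale)\n")
  invisible(x)
}

# Canonical identifier of a parameter set, stored alongside every
# cell-pixel count so results are traceable to settings.
params_hash <- function(params, sigma_used) {
  sprintf("sigma=%s;crop=%s;threshold=%s",
          format(sigma_used, digits = 10),
          format(params$crop_fraction, digits = 10),
          format(params$threshold, digits = 10))
}

resolve_sigma <- function(params, image) {
  if (!is.null(params$background_sigma)) params$background_sigma
  else min(dim(image)) / 10
}

#' Convert an image to single-channel grayscale on the 0-255 scale
#'
#' Accepts a numeric matrix (single channel), an `height x width x 3` array
#' (RGB, converted by the unweighted channel mean), or an
#' [EBImage::Image-class] object. Inputs stored on another scale are
#' rescaled to 0-255: values within `[0, 1]` are multiplied by 255 and
#' 16-bit-range values (max > 255) are scaled so 65535 maps to 255.
#'
#' @param image matrix, 3-channel array, or `EBImage::Image`.
#' @return Numeric matrix of intensities in `[0, 255]`.
#' @examples
#' g <- to_grayscale(matrix(100, 32, 32))
#' range(g)
#' @export
to_grayscale <- function(image) {
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  if (is.array(image) && length(dim(image)) == 3) {
    nch <- dim(image)[3]
    if (nch == 1L) {
      image <- image[, , 1L]
    } else if (nch == 3L) {
      image <- (image[, , 1L] + image[, , 2L] + image[, , 3L]) / 3
    } else {
      stop("unsupported channel count: ", nch, " (expected 1 or 3)",
           call. = FALSE)
    }
  }
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix or a 1- or 3-channel array",
         call. = FALSE)
  if (any(!is.finite(image)))
    stop("`image` contains non-finite pixel values", call. = FALSE)
  if (nrow(image) < .MIN_DIM || ncol(image) < .MIN_DIM)
    stop(sprintf("image must be at least %dx%d pixels", .MIN_DIM, .MIN_DIM),
         call. = FALSE)
  mx <- max(image)
  if (min(image) < 0)
    stop("negative pixel intensities are not a recognized scale", call. = FALSE)
  if (mx <= 1) {
    image <- image * .GRAY_MAX            # unit-scale (file readers)
  } else if (mx > .GRAY_MAX) {
    image <- image * (.GRAY_MAX / 65535)  # 16-bit integer scale
  }
  pmin(image, .GRAY_MAX)
}

gaussian_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  g <- stats::dnorm(-r:r, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

#' Estimate the smooth background of a brightfield well image
#'
#' Applies a normalized Gaussian low-pass filter so that cell-sized features
#' vanish and only the slowly varying illumination field remains. Boundaries
#' are handled by edge replication, so a constant image is reproduced exactly
#' and gradients are undistorted away from the border.
#'
#' @param image numeric matrix on the 0-255 scale.
#' @param sigma Gaussian s.d. in pixels (> 0). The kernel extends to
#'   `ceiling(3 * sigma)` pixels and must fit inside the image.
#' @return Smoothed matrix with the same dimensions.
#' @examples
#' img <- matrix(80, 32, 32)
#' all.equal(estimate_background(img, 3), img)
#' @export
estimate_background <- function(image, sigma) {
  check_gray_image(image)
  stopifnot(is.numeric(sigma), length(sigma) == 1)
  if (!is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be > 0", call. = FALSE)
  k <- gaussian_kernel(sigma)
  if (nrow(k) > 2 * min(dim(image)))
    stop("`sigma` too large: Gaussian kernel does not fit the image",
         call. = FALSE)
  out <- EBImage::imageData(
    EBImage::filter2(EBImage::Image(image), k, boundary = "replicate"))
  dim(out) <- dim(image)
  out
}

#' Background-correct and invert a brightfield image
#'
#' Computes `clip(background - image, 0, 255)`: dark objects (cells) on a
#' light background become bright objects on a black background, in one
#' algebraic step equivalent to subtracting the background and negating.
#' Pixels brighter than the local background map to 0.
#'
#' @param image,background numeric matrices with identical dimensions.
#' @return Matrix of the same dimensions, values in `[0, 255]`.
#' @export
correct_and_invert <- function(image, background) {
  check_gray_image(image)
  check_gray_image(background, "background")
  if (!identical(dim(image), dim(background)))
    stop("`image` and `background` dimensions differ", call. = FALSE)
  pmin(pmax(background - image, 0), .GRAY_MAX)
}

#' Crop image margins
#'
#' Removes `floor(fraction * height)` rows from the top and bottom and
#' `floor(fraction * width)` columns from the left and right. The fraction is
#' per side: the default 0.05 retains the central 90% of each dimension,
#' discarding rim artefacts such as the assay plate's molded stops.
#'
#' @param image numeric matrix.
#' @param fraction margin fraction per side, in `[0, 0.5)`.
#' @return The cropped matrix.
#' @examples
#' dim(crop_margins(matrix(0, 200, 200), 0.05))  # 180 x 180
#' @export
crop_margins <- function(image, fraction) {
  check_gray_image(image)
  stopifnot(is.numeric(fraction), length(fraction) == 1)
  if (!is.finite(fraction) || fraction < 0 || fraction >= 0.5)
    stop("`fraction` must be in [0, 0.5)", call. = FALSE)
  dr <- floor(fraction * nrow(image))
  dc <- floor(fraction * ncol(image))
  out <- image[(dr + 1):(nrow(image) - dr), (dc + 1):(ncol(image) - dc),
               drop = FALSE]
  if (length(out) == 0) stop("cropping left an empty image", call. = FALSE)
  out
}

#' Count cell-pixels in a processed image
#'
#' On the background-corrected, inverted, cropped image, every pixel with
#' intensity strictly greater than `threshold` is counted as evidence of
#' cell material ("cell-pixel").
#'
#' @param image processed numeric matrix.
#' @param threshold intensity cutoff (>= 0) on the 0-255 scale.
#' @return Integer pixel count.
#' @export
count_cell_pixels <- function(image, threshold) {
  # operates on the cropped pipeline output, which may be smaller than the
  # raw-image minimum
  check_gray_image(image, min_dim = 1L)
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold >= 0)
  sum(image > threshold)
}

#' Quantify a well image as a cell-pixel count
#'
#' Runs the full brightfield pipeline: grayscale conversion, Gaussian
#' background estimation, background subtraction with inversion, margin
#' cropping, and thresholded pixel counting. Deterministic for fixed inputs
#' and parameters; the result equals the stepwise application of
#' [to_grayscale()], [estimate_background()], [correct_and_invert()],
#' [crop_margins()] and [count_cell_pixels()].
#'
#' @param image raw well image (matrix, 3-channel array, or `EBImage::Image`).
#' @param params an [imaging_params()] object.
#' @param well_id optional plate coordinate (e.g. `"B07"`) carried into the
#'   result.
#' @return A list of class `cell_pixel_count` with fields `well_id`, `count`
#'   and `params_hash`.
#' @examples
#' img <- synth_well_image(n_cells = 50, width = 96, height = 96, seed = 1)
#' quantify_well(img$image, imaging_params(), well_id = "A01")
#' @export
quantify_well <- function(image, params = imaging_params(), well_id = NA_character_) {
  stopifnot(inherits(params, "imaging_params"))
  g <- to_grayscale(image)
  sigma <- resolve_sigma(params, g)
  bg <- estimate_background(g, sigma)
  obj <- correct_and_invert(g, bg)
  cr <- crop_margins(obj, params$crop_fraction)
  n <- count_cell_pixels(cr, params$threshold)
  structure(list(well_id = well_id, count = as.integer(n),
                 params_hash = params_hash(params, sigma)),
            class = "cell_pixel_count")
}

#' @export
print.cell_pixel_count <- function(x, ...) {
  cat(sprintf("Well %s: %d cell-pixels  [%s]\n",
              ifelse(is.na(x$well_id), "<unknown>", x$well_id),
              x$count, x$params_hash))
  invisible(x)
}
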