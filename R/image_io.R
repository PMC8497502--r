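# File-level I/O for well images and cell-pixel tables.

#' Read a well image from TIFF or PNG
#'
#' Reads 8- or 16-bit grayscale or 8-bit RGB images and converts them to the
#' canonical single-channel 0-255 scale with [to_grayscale()].
#'
#' @param path path to a `.tif`, `.tiff` or `.png` file.
#' @return Numeric matrix of intensities in `[0, 255]`.
#' @export
read_well_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  to_grayscale(EBImage::readImage(path))
}

#' Extract a 96-well coordinate from a filename
#'
#' The well identity is taken from the filename stem: the trailing characters
#' must match a 96-well coordinate `A1`-`H12` (an optional zero pad on the
#' column, any prefix before it). Returns the coordinate normalized to the
#' zero-padded form (`"B7"` and `"B07"` both give `"B07"`), or `NA` when no
#' well coordinate is present.
#'
#' @param filename file name or path.
#' @return Character well id such as `"B07"`, or `NA_character_`.
#' @examples
#' well_from_filename("plate3_B07.tif")
#' well_from_filename("A1.png")
#' @export
well_from_filename <- function(filename) {
  stem <- sub("\\.[A-Za-z]+$", "", basename(filename))
  m <- regmatches(stem, regexpr("[A-H](0?[1-9]|1[0-2])$", stem))
  if (length(m) == 0) return(NA_character_)
  normalize_well(m)
}

# "B7" -> "B07"; validates the coordinate.
normalize_well <- function(well) {
  well <- toupper(trimws(well))
  ok <- grepl("^[A-H](0?[1-9]|1[0-2])$", well)
  if (any(!ok))
    stop("invalid 96-well coordinate(s): ",
         paste(well[!ok], collapse = ", "), call. = FALSE)
  row <- substr(well, 1, 1)
  col <- as.integer(substring(well, 2))
  sprintf("%s%02d", row, col)
}

#' Quantify every well image in a directory
#'
#' Runs [quantify_well()] on each TIFF/PNG file. Well identities come from an
#' optional manifest CSV (`filename,well`) or, absent one, from the filename
#' stems. Unreadable images are recorded as errors and the run continues.
#'
#' @param image_dir directory of well images.
#' @param params an [imaging_params()] object.
#' @param manifest optional path to a CSV with columns `filename,well`.
#' @param plate_id plate label written into the output table.
#' @return A data.frame with columns `plate_id, well, cell_pixels,
#'   params_hash, error` (one row per image; `error` is `NA` on success).
#' @export
quantify_image_dir <- function(image_dir, params = imaging_params(),
                               manifest = NULL, plate_id = "plate1") {
  files <- list.files(image_dir, pattern = "\\.(tif|tiff|png)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0)
    stop("no TIFF or PNG images found in ", image_dir, call. = FALSE)
  if (!is.null(manifest)) {
    man <- read.csv(manifest, stringsAsFactors = FALSE)
    if (!all(c("filename", "well") %in% names(man)))
      stop("manifest must have columns `filename` and `well`", call. = FALSE)
    wells <- setNames(normalize_well(man$well), man$filename)
    well_of <- function(f) unname(wells[basename(f)])
  } else {
    well_of <- well_from_filename
  }
  rows <- lapply(files, function(f) {
    w <- well_of(f)
    res <- tryCatch(quantify_well(read_well_image(f), params, well_id = w),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(plate_id = plate_id, well = if (is.null(w)) NA else w,
                 cell_pixels = NA_integer_, params_hash = NA_character_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(plate_id = plate_id, well = res$well_id,
                 cell_pixels = res$count, params_hash = res$params_hash,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out[order(out$well), , drop = FALSE]
}

#' Write a per-plate cell-pixel table
#'
#' @param counts data.frame from [quantify_image_dir()].
#' @param path output CSV path (columns
#'   `plate_id,well,cell_pixels,params_hash`).
#' @return `path`, invisibly.
#' @export
write_cell_pixel_csv <- function(counts, path) {
  cols <- c("plate_id", "well", "cell_pixels", "params_hash")
  stopifnot(all(cols %in% names(counts)))
  write.csv(counts[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-plate cell-pixel table
#' @param path CSV written by [write_cell_pixel_csv()].
#' @return data.frame with columns `plate_id, well, cell_pixels, params_hash`.
#' @export
read_cell_pixel_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well", "cell_pixels")
  if (!all(need %in% names(x)))
    stop("cell-pixel table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  x$well <- normalize_well(x$well)
  x
}
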