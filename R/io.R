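#' Read a grayscale image
#'
#' Reads a PNG or TIFF image into a plain numeric matrix with intensities
#' rescaled to the unit interval. The pipeline works on a single internal
#' representation (unit-interval floats, row-major, origin at the top-left,
#' pixel centers at integer coordinates with `x` = column and `y` = row)
#' regardless of the source bit depth.
#'
#' Multi-channel images are rejected unless `to_gray = TRUE`, in which case
#' ITU-R BT.601 luminance (0.299 R + 0.587 G + 0.114 B) is applied. CLE
#' acquisitions are single-channel, so a colour file usually indicates a data
#' handling error; the conversion is therefore opt-in rather than silent.
#'
#' @param path path to a PNG or TIFF file.
#' @param to_gray logical; convert RGB(A) input to luminance instead of
#'   failing.
#' @return numeric matrix with values in \[0, 1\]; attributes `bit_depth`
#'   (original bits per sample, `NA` if undeterminable) and `source` (the
#'   file path).
#' @examples
#' f <- tempfile(fileext = ".png")
#' write_gray_image(matrix(runif(64 * 64), 64), f)
#' img <- read_gray_image(f)
#' range(img)
#' @export
read_gray_image <- function(path, to_gray = FALSE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path, info = TRUE),
      stop("unsupported image format '", ext, "' (PNG or TIFF expected)")
    ),
    error = function(e) stop("cannot read image '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  bit_depth <- NA_integer_
  if (ext == "png") {
    # PNG bit depth is byte 25 of the file (IHDR), not exposed by readPNG
    hdr <- readBin(path, "raw", n = 26L)
    if (length(hdr) >= 25L) bit_depth <- as.integer(hdr[25L])
  } else {
    bps <- attr(raw, "bits.per.sample")
    if (!is.null(bps)) bit_depth <- as.integer(bps[1L])
  }
  img <- raw
  if (is.array(img) && length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    if (nc == 2L) {                      # gray + alpha: keep gray
      img <- img[, , 1L]
    } else if (nc %in% c(3L, 4L)) {
      if (!to_gray)
        stop("multi-channel image; pass to_gray = TRUE for ITU-R 601 luminance")
      img <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    } else {
      stop("unsupported channel count: ", nc)
    }
  }
  img <- as.matrix(img)
  validate_gray_image(img)
  attr(img, "bit_depth") <- bit_depth
  attr(img, "source") <- path
  img
}

#' Write a grayscale image to PNG
#'
#' @param image numeric matrix with values in \[0, 1\].
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (anyNA(image) || min(image) < 0 || max(image) > 1)
    stop("image values must be finite and within [0, 1]")
  png::writePNG(image, target = path)
  invisible(path)
}

#' Validate a grayscale image matrix
#'
#' Checks the contract assumed by every downstream operation: numeric matrix,
#' both dimensions at least 32, all values finite. Texture and thresholding
#' additionally require at least two distinct intensities; set
#' `require_variation = TRUE` to enforce that here.
#'
#' @param image candidate matrix.
#' @param require_variation logical; additionally require >= 2 distinct values.
#' @return `image`, invisibly.
#' @export
validate_gray_image <- function(image, require_variation = FALSE) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (nrow(image) < 32L || ncol(image) < 32L)
    stop("image too small: both dimensions must be >= 32 pixels")
  if (!all(is.finite(image)))
    stop("image contains non-finite intensities")
  if (require_variation && diff(range(image)) == 0)
    stop("degenerate input: image is constant (needs >= 2 distinct intensities)")
  invisible(image)
}

.feature_names <- c("fractal_dimension", "lacunarity", "contrast",
                    "correlation", "energy", "homogeneity", "feature_count")

#' Write a feature table to CSV
#'
#' Writes one row per image with columns
#' `id,label,fractal_dimension,lacunarity,contrast,correlation,energy,homogeneity,feature_count`.
#' Numeric values are written with 12 significant digits so the table
#' round-trips losslessly at that precision; UTF-8, LF line endings.
#'
#' @param rows data frame with columns `id`, `label` and the seven parameters.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_feature_table()]
#' @export
write_feature_table <- function(rows, path) {
  cols <- c("id", "label", .feature_names)
  if (!is.data.frame(rows))
    stop("rows must be a data frame")
  missing <- setdiff(cols, names(rows))
  if (length(missing))
    stop("feature table is missing required columns: ",
         paste(missing, collapse = ", "))
  rows <- rows[cols]
  if (nrow(rows) > 0 && !all(vapply(rows[.feature_names],
                                    function(x) all(is.finite(x)), logical(1))))
    stop("feature table contains non-finite parameter values")
  con <- file(path, open = "wb")   # binary mode forces LF on every platform
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con, sep = "\n", useBytes = TRUE)
  if (nrow(rows) > 0) {
    num <- vapply(.feature_names, function(nm)
      formatC(rows[[nm]], digits = 12, format = "g"), character(nrow(rows)))
    num <- matrix(num, nrow = nrow(rows))
    lines <- paste(rows$id, rows$label,
                   apply(num, 1L, paste, collapse = ","), sep = ",")
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return data frame with `id`, `label` and the seven parameter columns.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("id", "label", .feature_names), names(tab))
  if (length(missing))
    stop("not a feature table (missing columns: ",
         paste(missing, collapse = ", "), ")")
  tab
}
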