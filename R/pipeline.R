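#' Pipeline configuration
#'
#' Builds the nested configuration list consumed by [cad_features()], merging
#' any overrides into the defaults. Keys mirror the pipeline stages:
#'
#' \describe{
#'   \item{`fractal$scales`}{box sizes for the fractal fit; `NULL` = dyadic
#'     `{2, 4, ..., side/4}`.}
#'   \item{`fractal$lacunarity_box_sizes`}{gliding-box window sides
#'     (default 2, 4, 8, 16).}
#'   \item{`fractal$binarization`}{`"otsu"` or `"fixed:<t>"`, used only when
#'     `pipeline$share_binarization` is `FALSE`.}
#'   \item{`glcm$levels`, `glcm$offset`, `glcm$symmetric`, `glcm$range`}{GLCM
#'     quantization (default 8 levels, offset `(0, 1)`, asymmetric, per-image
#'     range).}
#'   \item{`features$sigma`}{Gaussian smoothing sd in pixels at the reference
#'     side of 1024; scaled proportionally to the analyzed image side.}
#'   \item{`features$threshold`}{`"otsu"` or `"fixed:<t>"`.}
#'   \item{`features$ratio_threshold`}{area/perimeter roundness cut
#'     (default 4, stated at the 1024-pixel reference scale).}
#'   \item{`features$rescale_threshold`}{rescale the roundness cut by
#'     `side / 1024` (default `TRUE`), keeping the effective minimum crypt
#'     radius proportional to the field of view.}
#'   \item{`features$contour_on`}{`"binary"` (default: contour the
#'     thresholded mask at level 0.5) or `"smoothed"` (contour the smoothed
#'     grayscale at the threshold intensity).}
#'   \item{`pipeline$share_binarization`}{use one Otsu pass on the smoothed
#'     image for both the fractal estimators and the contour module
#'     (default `TRUE`).}
#' }
#'
#' @param ... named overrides, e.g. `cad_config(glcm = list(levels = 16))`.
#' @return nested configuration list.
#' @export
cad_config <- function(...) {
  defaults <- list(
    fractal = list(scales = NULL,
                   lacunarity_box_sizes = c(2L, 4L, 8L, 16L),
                   binarization = "otsu"),
    glcm = list(levels = 8L, offset = c(0L, 1L),
                symmetric = FALSE, range = "image"),
    features = list(sigma = 2, sigma_reference_side = 1024L,
                    threshold = "otsu", ratio_threshold = 4,
                    rescale_threshold = TRUE, contour_on = "binary"),
    pipeline = list(share_binarization = TRUE)
  )
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.list(dots[[1L]]))
    dots <- dots[[1L]]
  bad <- setdiff(names(dots), names(defaults))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(dots)) {
    bad <- setdiff(names(dots[[sec]]), names(defaults[[sec]]))
    if (length(bad)) stop("unknown config key(s) in '", sec, "': ",
                          paste(bad, collapse = ", "))
    defaults[[sec]] <- utils::modifyList(defaults[[sec]], dots[[sec]],
                                         keep.null = TRUE)
  }
  defaults
}

#' Extract the seven-parameter feature vector of an image
#'
#' Runs the full per-image pipeline: Gaussian smoothing, thresholding,
#' box-counting fractal dimension and gliding-box lacunarity of the binary
#' pattern, GLCM texture statistics of the raw grayscale image, and the
#' marching-squares round-crypt count. Returns the parameters in the fixed
#' reporting order `fractal_dimension, lacunarity, contrast, correlation,
#' energy, homogeneity, feature_count`.
#'
#' The computation is fully deterministic: the same image and configuration
#' always yield a bit-identical vector.
#'
#' @param image numeric matrix in \[0, 1\] (see [read_gray_image()]).
#' @param config configuration list from [cad_config()].
#' @param id optional image identifier used to annotate error messages.
#' @return named numeric vector of the seven parameters.
#' @examples
#' ph <- phantom_normal(side = 256, seed = 1)
#' cad_features(ph$image)
#' @export
cad_features <- function(image, config = cad_config(), id = NULL) {
  res <- tryCatch(.cad_features(image, config),
    error = function(e) {
      if (is.null(id)) stop(e)
      stop("feature extraction failed for image '", id, "': ",
           conditionMessage(e), call. = FALSE)
    })
  res
}

.cad_features <- function(image, config) {
  validate_gray_image(image, require_variation = TRUE)
  side <- min(dim(image))
  fc <- config$features
  sigma_eff <- fc$sigma * side / fc$sigma_reference_side
  smoothed <- gaussian_smooth(image, sigma_eff)
  mask <- binarize(smoothed, method = fc$threshold)

  fr_mask <- mask
  if (!isTRUE(config$pipeline$share_binarization))
    fr_mask <- binarize(image, method = config$fractal$binarization)

  fd <- box_count_dimension(fr_mask, config$fractal$scales)
  lac <- gliding_box_lacunarity(fr_mask, config$fractal$lacunarity_box_sizes)

  g <- compute_glcm(image, levels = config$glcm$levels,
                    offset = config$glcm$offset,
                    symmetric = config$glcm$symmetric,
                    range = config$glcm$range)
  tx <- glcm_stats(g)

  if (identical(fc$contour_on, "binary")) {
    contours <- marching_squares_contours(mask + 0, 0.5)
  } else {
    contours <- marching_squares_contours(smoothed, attr(mask, "threshold"))
  }
  thr <- fc$ratio_threshold
  if (isTRUE(fc$rescale_threshold)) thr <- thr * side / 1024
  fs <- count_round_features(contours, thr)

  out <- c(fd$fractal_dimension, as.numeric(lac), tx$contrast,
           tx$correlation, tx$energy, tx$homogeneity, fs$count_round)
  names(out) <- .feature_names
  out
}

#' Extract features for a directory of images
#'
#' @param dir directory containing PNG/TIFF images.
#' @param labels optional data frame with columns `id` (file name without
#'   extension) and `label`; unlabeled images get label `NA`.
#' @param config configuration from [cad_config()].
#' @param to_gray passed to [read_gray_image()].
#' @return feature table data frame (`id`, `label`, seven parameters).
#' @export
cad_extract_dir <- function(dir, labels = NULL, config = cad_config(),
                            to_gray = FALSE) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop("no PNG/TIFF images found in ", dir)
  ids <- tools::file_path_sans_ext(basename(files))
  lab <- rep(NA_character_, length(ids))
  if (!is.null(labels)) {
    stopifnot(all(c("id", "label") %in% names(labels)))
    lab <- as.character(labels$label[match(ids, labels$id)])
  }
  fv <- t(vapply(seq_along(files), function(i)
    cad_features(read_gray_image(files[i], to_gray = to_gray),
                 config, id = ids[i]),
    numeric(length(.feature_names))))
  out <- data.frame(id = ids, label = lab, fv, stringsAsFactors = FALSE)
  names(out) <- c("id", "label", .feature_names)
  out
}
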