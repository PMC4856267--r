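#' Otsu threshold of a grayscale image
#'
#' Finds the intensity threshold maximizing the between-class variance of a
#' 256-bin histogram spanning the image's intensity range. This is the
#' classical global threshold for separating a bimodal foreground/background
#' intensity distribution.
#'
#' @param image numeric matrix (any range; typically \[0, 1\]).
#' @param nbins number of histogram bins.
#' @return scalar threshold; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(image, nbins = 256L) {
  validate_gray_image(image, require_variation = TRUE)
  rng <- range(image)
  breaks <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  counts <- tabulate(findInterval(image, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins)
  p <- counts / sum(counts)
  mids <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)                       # class-0 weight for split after bin k
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  # between-class variance: w0*w1*(mu0-mu1)^2 = (mu_t*w0 - mu)^2 / (w0*(1-w0))
  denom <- w0 * (1 - w0)
  sigma_b <- ifelse(denom > 0, (mu_t * w0 - mu)^2 / denom, -Inf)
  k <- which.max(sigma_b[-nbins])       # split cannot be after the last bin
  breaks[k + 1L]                        # upper edge of the background class
}

#' Binarize a grayscale image
#'
#' Thresholds an image into a logical mask (`TRUE` above the threshold).
#' `method = "otsu"` uses [otsu_threshold()]; `method = "fixed:<t>"` (or a
#' numeric `threshold`) uses a fixed cut. The same binarization feeds both
#' the fractal estimators and the crypt-contour module.
#'
#' @param image numeric matrix.
#' @param method `"otsu"`, `"fixed:<t>"`, or `"fixed"` with `threshold` given.
#' @param threshold numeric threshold when `method = "fixed"`.
#' @return logical matrix with attribute `threshold` (the value used).
#' @examples
#' img <- matrix(rep(c(0.2, 0.8), each = 512), 32)
#' m <- binarize(img)
#' mean(m)  # half the pixels
#' @export
binarize <- function(image, method = "otsu", threshold = NULL) {
  validate_gray_image(image, require_variation = TRUE)
  if (is.character(method) && grepl("^fixed:", method)) {
    threshold <- as.numeric(sub("^fixed:", "", method))
    if (!is.finite(threshold)) stop("bad fixed threshold in '", method, "'")
    method <- "fixed"
  }
  t0 <- switch(method,
    otsu = otsu_threshold(image),
    fixed = {
      if (is.null(threshold) || !is.finite(threshold))
        stop("method = 'fixed' requires a finite threshold")
      threshold
    },
    stop("unknown binarization method: ", method)
  )
  mask <- image > t0
  attr(mask, "threshold") <- t0
  mask
}
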