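#' Box-occupancy counts of a binary mask
#'
#' Counts, for each box size `s`, the number of `s` x `s` grid boxes
#' (anchored at the top-left corner; partial boxes at the right/bottom edges
#' included) that contain at least one `TRUE` pixel.
#'
#' @param mask logical matrix.
#' @param scales integer vector of box sizes in pixels.
#' @return integer vector of occupied-box counts, one per scale.
#' @export
box_count <- function(mask, scales) {
  stopifnot(is.matrix(mask), is.logical(mask))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("degenerate input: empty mask")
  vapply(scales, function(s) {
    bi <- (idx[, 1L] - 1L) %/% s
    bj <- (idx[, 2L] - 1L) %/% s
    nbj <- (ncol(mask) + s - 1L) %/% s
    length(unique(bi * nbj + bj))
  }, integer(1L))
}

#' Box-counting fractal dimension
#'
#' Estimates the fractal dimension of a binary pattern as the least-squares
#' slope of `log N(s)` against `log(1/s)`, where `N(s)` is the number of
#' occupied boxes of side `s` (see [box_count()]). The dimension indexes the
#' space-filling complexity of the pattern: 2 for a filled plane, 1 for a
#' line, log 8 / log 3 for the Sierpinski carpet.
#'
#' The default scale set is dyadic, `{2, 4, 8, ..., side/4}` with
#' `side = min(dim(mask))`. The log-log fit is unweighted; scales with a zero
#' count (impossible for a nonempty mask) would be dropped with a warning.
#' The slope is clipped into \[0, 2\], the valid range for a planar pattern.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @param scales >= 3 distinct box sizes, each at most `min(dim(mask)) / 2`;
#'   `NULL` for the dyadic default.
#' @return list with `fractal_dimension`, `fit_r2`, `scales_used`, `counts`.
#' @examples
#' m <- matrix(TRUE, 256, 256)
#' box_count_dimension(m)$fractal_dimension  # exactly 2
#' @export
box_count_dimension <- function(mask, scales = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask))
  side <- min(dim(mask))
  if (is.null(scales)) {
    scales <- 2^(1:max(floor(log2(side / 4)), 1L))
    scales <- scales[scales <= side / 2]
  }
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) < 3L)
    stop("need at least 3 distinct box sizes")
  if (any(scales < 1L) || any(scales > side / 2))
    stop("box sizes must be within [1, min(dim)/2]")
  n <- box_count(mask, scales)
  keep <- n > 0L
  if (!all(keep)) {
    warning("dropping scales with zero box count")
    scales <- scales[keep]; n <- n[keep]
  }
  x <- log(1 / scales)
  y <- log(n)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2L])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  list(fractal_dimension = min(max(slope, 0), 2),
       fit_r2 = r2, scales_used = scales, counts = n)
}

#' Gliding-box lacunarity
#'
#' Slides an `r` x `r` window over every position of the mask and forms the
#' distribution of box masses (count of `TRUE` pixels per window). With `M1`
#' and `M2` the first and second moments of that distribution, the lacunarity
#' at scale `r` is `Lambda(r) = M2 / M1^2 >= 1`; patterns with more or larger
#' gaps score higher. The returned scalar is the mean over `box_sizes` of
#' `Lambda(r) - 1`, so a translation-invariant mass (e.g. an all-`TRUE`
#' mask, or a window spanning the whole image) gives exactly 0.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @param box_sizes integer window sides, each at most `min(dim(mask))`.
#' @return scalar lacunarity (>= 0) with attribute `per_size`, the
#'   `Lambda(r) - 1` value at each window size.
#' @export
gliding_box_lacunarity <- function(mask, box_sizes = c(2L, 4L, 8L, 16L)) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("degenerate input: empty mask (M1 = 0)")
  h <- nrow(mask); w <- ncol(mask)
  box_sizes <- as.integer(box_sizes)
  if (any(box_sizes < 1L) || any(box_sizes > min(h, w)))
    stop("box sizes must be within [1, min(dim(mask))]")
  # summed-area table with a zero top/left border
  s <- rbind(0, apply(mask, 2L, cumsum))
  s <- cbind(0, t(apply(s, 1L, cumsum)))
  per <- vapply(box_sizes, function(r) {
    m <- s[(1L + r):(h + 1L), (1L + r):(w + 1L), drop = FALSE] -
         s[1:(h - r + 1L), (1L + r):(w + 1L), drop = FALSE] -
         s[(1L + r):(h + 1L), 1:(w - r + 1L), drop = FALSE] +
         s[1:(h - r + 1L), 1:(w - r + 1L), drop = FALSE]
    m1 <- mean(m); m2 <- mean(m * m)
    m2 / m1^2 - 1
  }, numeric(1L))
  out <- mean(per)
  attr(out, "per_size") <- stats::setNames(per, box_sizes)
  out
}
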