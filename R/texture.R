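#' Grey-level co-occurrence matrix
#'
#' Quantizes the image into `levels` equal-width intensity bins spanning its
#' own \[min, max\] range (or a fixed range), counts ordered pixel pairs
#' `(p, p + offset)` that fall inside the image, and normalizes the counts to
#' probabilities. The GLCM records how often pairs of grey levels co-occur at
#' the given displacement and is the basis of the Haralick-style texture
#' statistics in [glcm_stats()].
#'
#' @param image numeric matrix with at least 2 distinct intensities.
#' @param levels number of grey levels (>= 2).
#' @param offset integer displacement `c(dy, dx)` (rows, columns), nonzero.
#' @param symmetric logical; also count each pair in the reversed direction.
#' @param range `"image"` (quantize over the image's own min..max, the
#'   default, which makes the statistics invariant to exposure scaling) or a
#'   numeric `c(lo, hi)` fixed range.
#' @return object of class `"glcm"`: list with `P` (levels x levels
#'   probability matrix, grey level `i` of the first pixel on rows, 0-based),
#'   `levels`, `offset`.
#' @examples
#' img <- rbind(c(0, 0), c(1, 1))[rep(1:2, 16), rep(1:2, 16)]
#' g <- compute_glcm(img, levels = 8, offset = c(0, 1))
#' sum(g$P)  # 1
#' @export
compute_glcm <- function(image, levels = 8L, offset = c(0L, 1L),
                         symmetric = FALSE, range = "image") {
  # no minimum-size requirement here: the GLCM is well defined on any grid
  # with at least one admissible pair
  if (!is.matrix(image) || !is.numeric(image) || !all(is.finite(image)))
    stop("image must be a finite numeric matrix")
  if (max(image) - min(image) == 0)   # NB: `range` is an argument here
    stop("degenerate input: image is constant (needs >= 2 distinct intensities)")
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  offset <- as.integer(offset)
  if (length(offset) != 2L || all(offset == 0L))
    stop("offset must be a nonzero (dy, dx) pair")
  h <- nrow(image); w <- ncol(image)
  dy <- offset[1L]; dx <- offset[2L]
  if (abs(dy) >= h || abs(dx) >= w)
    stop("offset larger than the image")
  if (identical(range, "image")) {
    lo <- min(image); hi <- max(image)
  } else {
    stopifnot(is.numeric(range), length(range) == 2L, range[2L] > range[1L])
    lo <- range[1L]; hi <- range[2L]
  }
  q <- floor((image - lo) / (hi - lo) * levels)
  q <- matrix(pmin(pmax(q, 0), levels - 1L), h, w)
  r1 <- max(1L, 1L - dy):min(h, h - dy)
  c1 <- max(1L, 1L - dx):min(w, w - dx)
  qi <- q[r1, c1, drop = FALSE]
  qj <- q[r1 + dy, c1 + dx, drop = FALSE]
  counts <- tabulate(qi * levels + qj + 1L, nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)  # row = i, col = j
  if (symmetric) P <- P + t(P)
  structure(list(P = P / sum(P), levels = levels, offset = offset),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("GLCM: %d grey levels, offset (dy = %d, dx = %d)\n",
              x$levels, x$offset[1L], x$offset[2L]))
  invisible(x)
}

#' Texture statistics of a GLCM
#'
#' Computes the four texture parameters used for crypt-architecture
#' description, with `P(i, j)` the co-occurrence probabilities and grey
#' levels indexed `0 .. L-1`:
#' \describe{
#'   \item{contrast}{`sum (i - j)^2 P(i, j)` — local intensity variation.}
#'   \item{correlation}{`sum (i - mu_i)(j - mu_j) P(i, j) / (sd_i sd_j)` —
#'     linear grey-level dependence of the pixel pair.}
#'   \item{energy}{`sum P(i, j)^2` — uniformity of the co-occurrence
#'     distribution.}
#'   \item{homogeneity}{`sum P(i, j) / (1 + |i - j|)` — concentration of
#'     mass on the GLCM diagonal.}
#' }
#'
#' @param glcm a [compute_glcm()] result (or a bare probability matrix).
#' @return list with `contrast`, `correlation`, `energy`, `homogeneity`.
#' @export
glcm_stats <- function(glcm) {
  P <- if (inherits(glcm, "glcm")) glcm$P else as.matrix(glcm)
  if (any(P < 0) || abs(sum(P) - 1) > 1e-8)
    stop("GLCM entries must be nonnegative and sum to 1")
  L <- nrow(P)
  i <- matrix(0:(L - 1L), L, L)        # row index (first pixel)
  j <- t(i)
  pi_ <- rowSums(P)
  pj_ <- colSums(P)
  mu_i <- sum((0:(L - 1L)) * pi_)
  mu_j <- sum((0:(L - 1L)) * pj_)
  var_i <- sum((0:(L - 1L) - mu_i)^2 * pi_)
  var_j <- sum((0:(L - 1L) - mu_j)^2 * pj_)
  if (var_i <= 0 || var_j <= 0)
    stop("degenerate GLCM: zero marginal variance (constant image upstream)")
  list(
    contrast    = sum((i - j)^2 * P),
    correlation = sum((i - mu_i) * (j - mu_j) * P) / sqrt(var_i * var_j),
    energy      = sum(P^2),
    homogeneity = sum(P / (1 + abs(i - j)))
  )
}
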