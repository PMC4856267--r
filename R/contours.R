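#' Gaussian smoothing with reflective boundaries
#'
#' Convolves the image with a separable isotropic Gaussian kernel. Kernel
#' weights are bin-integrated (the Gaussian mass falling in each pixel-wide
#' bin) and truncated at 5 sigma, so the discrete step response matches the
#' continuous error-function profile to well below 1e-6. Boundaries are
#' handled by symmetric reflection (edge pixel repeated), which conserves
#' total image mass exactly.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0). `sigma_y` may
#'   be given for an anisotropic (axis-aligned) kernel; defaults to `sigma`.
#' @param sigma_y optional vertical standard deviation.
#' @return smoothed matrix, same shape.
#' @export
gaussian_smooth <- function(image, sigma, sigma_y = sigma) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0 || sigma_y <= 0)
    stop("sigma must be a positive finite scalar")
  a_row <- .smooth_operator(nrow(image), sigma_y)
  a_col <- .smooth_operator(ncol(image), sigma)
  a_row %*% image %*% t(a_col)
}

# n x n linear operator applying a reflected, bin-integrated Gaussian
.smooth_operator <- function(n, sigma) {
  r <- ceiling(5 * sigma)
  k <- (-r):r
  w <- stats::pnorm((k + 0.5) / sigma) - stats::pnorm((k - 0.5) / sigma)
  w <- w / sum(w)
  a <- matrix(0, n, n)
  i <- seq_len(n)
  for (m in seq_along(k)) {
    j <- i + k[m]
    # symmetric reflection with edge repeat: ... c b a | a b c ...
    repeat {
      out_lo <- j < 1L; out_hi <- j > n
      if (!any(out_lo | out_hi)) break
      j[out_lo] <- 1L - j[out_lo]
      j[out_hi] <- 2L * n + 1L - j[out_hi]
    }
    a[cbind(i, j)] <- a[cbind(i, j)] + w[m]
  }
  a
}

# directed marching-squares case table: segments run with the above-level
# region on the LEFT of the travel direction (image frame, y pointing down).
# edges: 1 = top, 2 = right, 3 = bottom, 4 = left of the cell.
.ms_from <- c(3L, 2L, 2L, 1L, NA, 1L, 1L, 4L, 3L, NA, 2L, 4L, 3L, 4L)
.ms_to   <- c(4L, 3L, 4L, 2L, NA, 3L, 4L, 1L, 1L, NA, 1L, 2L, 2L, 3L)

#' Marching-squares isocontours
#'
#' Extracts the iso-level contours of a 2-D grid by the marching-squares
#' algorithm: each 2 x 2 pixel cell is classified by which corners lie above
#' the level, crossing points are placed on cell edges by linear
#' interpolation, and the resulting segments are chained into polylines.
#' Chains that close on themselves are returned as closed polygons (in
#' counter-clockwise orientation, i.e. positive shoelace area in the image
#' frame); chains that run into the image border are left open and flagged
#' `touches_border`. Saddle cells (both diagonals above the level) are
#' disambiguated by comparing the cell's mean value to the level, so results
#' are deterministic.
#'
#' Coordinates follow the package convention: origin at the top-left pixel
#' center, `x` = column - 1, `y` = row - 1.
#'
#' @param grid numeric (or logical) matrix, at least 2 x 2. Binary masks are
#'   contoured at `level = 0.5`.
#' @param level iso-level. A level outside the grid's value range yields an
#'   empty list.
#' @return list of contours; each is a list with `vertices` (two-column
#'   matrix of `x`, `y`), `closed`, and `touches_border`.
#' @examples
#' g <- matrix(0, 5, 5); g[3, 3] <- 1
#' cs <- marching_squares_contours(g, 0.5)
#' cs[[1]]$vertices  # diamond through the 4 edge midpoints
#' @export
marching_squares_contours <- function(grid, level) {
  if (is.logical(grid)) grid <- grid + 0
  stopifnot(is.matrix(grid), is.numeric(grid))
  h <- nrow(grid); w <- ncol(grid)
  if (h < 2L || w < 2L) stop("grid must be at least 2 x 2")
  # corners exactly on the level create degenerate crossings that fragment
  # the chains; nudge them infinitesimally above (deterministic tie-break)
  eq <- grid == level
  if (any(eq)) {
    rng <- diff(range(grid))
    grid[eq] <- level + (if (rng > 0) rng else 1) * 1e-10
  }
  ab <- grid > level
  if (all(ab) || !any(ab)) return(list())

  a <- ab[-h, -w]; b <- ab[-h, -1L]; cc <- ab[-1L, -1L]; d <- ab[-1L, -w]
  code <- 8L * a + 4L * b + 2L * cc + 1L * d
  cells <- which(code > 0L & code < 15L)
  if (!length(cells)) return(list())
  cr <- (cells - 1L) %% (h - 1L) + 1L      # cell row
  cv <- (cells - 1L) %/% (h - 1L) + 1L     # cell col
  cd <- code[cells]

  # edge ids: horizontal edge (r, c) between pixels (r,c)-(r,c+1);
  # vertical edge (r, c) between pixels (r,c)-(r+1,c)
  hid <- function(r, c) (r - 1L) * (w - 1L) + c
  vid <- function(r, c) h * (w - 1L) + (r - 1L) * w + c
  edge_of <- function(side, r, c)
    ifelse(side == 1L, hid(r, c),
    ifelse(side == 3L, hid(r + 1L, c),
    ifelse(side == 4L, vid(r, c), vid(r, c + 1L))))

  plain <- cd != 5L & cd != 10L
  from_e <- edge_of(.ms_from[cd[plain]], cr[plain], cv[plain])
  to_e   <- edge_of(.ms_to[cd[plain]],   cr[plain], cv[plain])

  sad <- which(!plain)
  if (length(sad)) {
    sr <- cr[sad]; sc <- cv[sad]
    ctr <- (grid[cbind(sr, sc)] + grid[cbind(sr, sc + 1L)] +
            grid[cbind(sr + 1L, sc)] + grid[cbind(sr + 1L, sc + 1L)]) / 4
    up <- ctr > level
    is5 <- cd[sad] == 5L
    # (from, to) side pairs for the two segments of each saddle cell
    f1 <- ifelse(is5, ifelse(up, 1L, 1L), ifelse(up, 2L, 4L))
    t1 <- ifelse(is5, ifelse(up, 4L, 2L), ifelse(up, 1L, 1L))
    f2 <- ifelse(is5, ifelse(up, 3L, 3L), ifelse(up, 4L, 2L))
    t2 <- ifelse(is5, ifelse(up, 2L, 4L), ifelse(up, 3L, 3L))
    from_e <- c(from_e, edge_of(f1, sr, sc), edge_of(f2, sr, sc))
    to_e   <- c(to_e,   edge_of(t1, sr, sc), edge_of(t2, sr, sc))
  }

  # interpolated crossing coordinate for each edge id
  coord <- function(e) {
    is_v <- e > h * (w - 1L)
    x <- y <- numeric(length(e))
    if (any(!is_v)) {
      eh <- e[!is_v]
      r <- (eh - 1L) %/% (w - 1L) + 1L
      c <- (eh - 1L) %% (w - 1L) + 1L
      va <- grid[cbind(r, c)]; vb <- grid[cbind(r, c + 1L)]
      t <- (level - va) / (vb - va)
      x[!is_v] <- (c - 1L) + t
      y[!is_v] <- r - 1L
    }
    if (any(is_v)) {
      ev <- e[is_v] - h * (w - 1L)
      r <- (ev - 1L) %/% w + 1L
      c <- (ev - 1L) %% w + 1L
      va <- grid[cbind(r, c)]; vb <- grid[cbind(r + 1L, c)]
      t <- (level - va) / (vb - va)
      x[is_v] <- c - 1L
      y[is_v] <- (r - 1L) + t
    }
    cbind(x, y)
  }
  p_from <- coord(from_e)
  p_to <- coord(to_e)

  m <- length(from_e)
  nxt <- match(to_e, from_e)            # each from-edge is unique
  visited <- logical(m)
  out <- vector("list", 0L)

  trace_chain <- function(s0, closed) {
    chain <- integer(m)
    len <- 0L
    s <- s0
    repeat {
      len <- len + 1L
      chain[len] <- s
      visited[s] <<- TRUE
      s <- nxt[s]
      if (is.na(s) || (closed && s == s0)) break
    }
    chain <- chain[seq_len(len)]
    v <- p_from[chain, , drop = FALSE]
    if (!closed) v <- rbind(v, p_to[chain[length(chain)], ])
    # drop consecutive duplicates (possible when a corner equals the level)
    if (nrow(v) > 1L) {
      dup <- c(FALSE, rowSums(abs(diff(v))) == 0)
      v <- v[!dup, , drop = FALSE]
    }
    colnames(v) <- c("x", "y")
    list(vertices = v, closed = closed, touches_border = !closed)
  }

  open_starts <- which(!(from_e %in% to_e))
  for (s0 in open_starts) out[[length(out) + 1L]] <- trace_chain(s0, FALSE)
  for (s0 in seq_len(m)) {
    if (!visited[s0]) {
      ct <- trace_chain(s0, TRUE)
      if (nrow(ct$vertices) >= 3L) {
        if (.signed_area(ct$vertices) < 0)   # normalize to CCW
          ct$vertices <- ct$vertices[nrow(ct$vertices):1L, , drop = FALSE]
        out[[length(out) + 1L]] <- ct
      }
    }
  }
  out
}

.signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Area and perimeter of a closed contour polygon
#'
#' Shoelace area and Euclidean perimeter (closing edge included) of a closed
#' contour as returned by [marching_squares_contours()].
#'
#' @param poly a contour (list with `vertices` and `closed`) or a two-column
#'   vertex matrix.
#' @return named numeric vector `c(area, perimeter)` in pixel^2 / pixels.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' polygon_area_perimeter(sq)  # area 1, perimeter 4
#' @export
polygon_area_perimeter <- function(poly) {
  v <- if (is.list(poly) && !is.null(poly$vertices)) {
    if (!isTRUE(poly$closed)) stop("polygon must be closed")
    poly$vertices
  } else as.matrix(poly)
  if (nrow(v) < 3L) stop("closed polygon needs at least 3 vertices")
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  c(area = abs(sum(x * yn - xn * y)) / 2,
    perimeter = sum(sqrt((xn - x)^2 + (yn - y)^2)))
}

#' Count round features among contours
#'
#' Scores every closed, non-border contour by its area/perimeter ratio (in
#' pixels; approximately `r / 2` for a disk of radius `r`) and counts those
#' whose ratio exceeds the threshold. Round glandular crypts of usable size
#' score high; elongated or fragmented structures score low, so the count
#' separates normal from disorganized mucosa.
#'
#' @param contours list of contours from [marching_squares_contours()].
#' @param ratio_threshold positive roundness cut in pixels (default 4, i.e.
#'   effective disk radius of about 8 px at the native 1024 px scale).
#' @return object of class `"feature_set"`: list with `contours` (the scored
#'   closed contours), `ratios`, and `count_round`.
#' @export
count_round_features <- function(contours, ratio_threshold = 4) {
  if (!is.numeric(ratio_threshold) || ratio_threshold <= 0)
    stop("ratio_threshold must be > 0")
  keep <- vapply(contours, function(ct)
    isTRUE(ct$closed) && !isTRUE(ct$touches_border) &&
      nrow(ct$vertices) >= 3L, logical(1L))
  closed <- contours[keep]
  ratios <- vapply(closed, function(ct) {
    ap <- polygon_area_perimeter(ct)
    unname(ap["area"] / ap["perimeter"])
  }, numeric(1L))
  structure(list(contours = closed, ratios = ratios,
                 count_round = sum(ratios > ratio_threshold),
                 ratio_threshold = ratio_threshold),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature set: %d closed contour(s), %d round (ratio > %g)\n",
              length(x$contours), x$count_round, x$ratio_threshold))
  invisible(x)
}
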