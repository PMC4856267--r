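#' Synthetic phantom of normal colonic mucosa
#'
#' Generates a CLE-like grayscale phantom of normal mucosa: dark,
#' near-circular glandular crypts placed on a jittered hexagonal lattice
#' over a brighter stroma, with speckle noise and a mild linear illumination
#' gradient. With `noise_sd = 0` and `illumination_gradient = 0` the image
#' has exactly two intensity plateaus (crypt and stroma). Crypt placement
#' that would overlap an existing crypt by more than 20% of the smaller
#' crypt's area is rejected and resampled (up to 1000 attempts). The ground
#' truth records every drawn crypt, so the drawn count is exact by
#' construction. All randomness is governed by `seed`; the same seed yields
#' a bit-identical phantom.
#'
#' The phantom is a stylized stand-in for clinical imagery, not a
#' biophysical simulation: it reproduces the geometric signature that the
#' pipeline measures (round dark crypts at quasi-regular spacing) and the
#' dominant nuisances (speckle, illumination drift), but none of the finer
#' histology (goblet cells, vasculature, fluorescein leakage).
#'
#' @param side image side in pixels (>= 128). Defaults chosen for 512.
#' @param n_crypts number of crypts to draw, or `NULL` to fill the lattice.
#' @param crypt_radius_mean,crypt_radius_sd crypt radius distribution in
#'   pixels (normal, clipped at 3 px).
#' @param lattice_spacing center-to-center lattice distance in pixels.
#' @param lattice_jitter uniform positional jitter half-width in pixels.
#' @param crypt_intensity,stroma_intensity the two intensity plateaus.
#' @param noise_sd Gaussian speckle standard deviation (intensity units).
#' @param illumination_gradient total left-to-right intensity drift.
#' @param seed integer seed.
#' @return list with `image` (matrix in \[0, 1\]), `truth` (list with
#'   `class`, `n_crypts`, `centers`, `radii`), and `seed`.
#' @export
phantom_normal <- function(side = 512L, n_crypts = NULL,
                           crypt_radius_mean = 14, crypt_radius_sd = 2,
                           lattice_spacing = side / 4, lattice_jitter = 6,
                           crypt_intensity = 0.30, stroma_intensity = 0.65,
                           noise_sd = 0.05, illumination_gradient = 0.08,
                           seed = 1L) {
  side <- as.integer(side)
  if (side < 128L) stop("side must be >= 128")
  if (crypt_radius_mean <= 0) stop("crypt radius must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)

  margin <- crypt_radius_mean + 3 * crypt_radius_sd + lattice_jitter + 4
  ys <- seq(margin, side - margin, by = lattice_spacing * sqrt(3) / 2)
  centers <- do.call(rbind, lapply(seq_along(ys), function(i) {
    off <- if (i %% 2 == 0) lattice_spacing / 2 else 0
    xs <- seq(margin + off, side - margin, by = lattice_spacing)
    if (!length(xs)) return(NULL)
    cbind(x = xs, y = ys[i])
  }))
  if (is.null(centers) || nrow(centers) == 0L)
    stop("phantom spec error: lattice admits no crypt site")
  if (!is.null(n_crypts)) {
    if (n_crypts > nrow(centers))
      stop("phantom spec error: requested ", n_crypts, " crypts but only ",
           nrow(centers), " lattice sites fit")
    centers <- centers[sample.int(nrow(centers), n_crypts), , drop = FALSE]
  }
  nc <- nrow(centers)
  radii <- pmax(stats::rnorm(nc, crypt_radius_mean, crypt_radius_sd), 3)
  ecc <- pmin(pmax(stats::rnorm(nc, 1, 0.05), 0.85), 1.18)
  theta <- stats::runif(nc, 0, pi)

  placed <- matrix(numeric(0), 0L, 2L)
  placed_r <- numeric(0)
  for (i in seq_len(nc)) {
    pos <- centers[i, ] + stats::runif(2L, -lattice_jitter, lattice_jitter)
    attempts <- 0L
    while (.crypt_overlap_frac(pos, radii[i], placed, placed_r) > 0.20) {
      attempts <- attempts + 1L
      if (attempts > 1000L)
        stop("phantom spec error: could not place crypt without > 20% overlap")
      pos <- c(stats::runif(1L, margin, side - margin),
               stats::runif(1L, margin, side - margin))
    }
    placed <- rbind(placed, pos)
    placed_r <- c(placed_r, radii[i])
  }

  img <- matrix(stroma_intensity, side, side)
  for (i in seq_len(nc))
    img <- .draw_ellipse(img, placed[i, 1L], placed[i, 2L], radii[i],
                         ecc[i], theta[i], crypt_intensity)
  img <- .add_nuisances(img, side, illumination_gradient, noise_sd)
  list(image = img,
       truth = list(class = "normal", n_crypts = nc,
                    centers = unname(placed), radii = radii),
       seed = seed)
}

# overlap area of two disks as a fraction of the smaller disk's area
.crypt_overlap_frac <- function(pos, r, centers, radii) {
  if (nrow(centers) == 0L) return(0)
  d <- sqrt((centers[, 1L] - pos[1L])^2 + (centers[, 2L] - pos[2L])^2)
  frac <- numeric(length(d))
  for (k in seq_along(d)) {
    r1 <- r; r2 <- radii[k]; dd <- d[k]
    if (dd >= r1 + r2) next
    if (dd <= abs(r1 - r2)) { frac[k] <- 1; next }
    lens <- r1^2 * acos((dd^2 + r1^2 - r2^2) / (2 * dd * r1)) +
            r2^2 * acos((dd^2 + r2^2 - r1^2) / (2 * dd * r2)) -
            0.5 * sqrt((-dd + r1 + r2) * (dd + r1 - r2) *
                       (dd - r1 + r2) * (dd + r1 + r2))
    frac[k] <- lens / (pi * min(r1, r2)^2)
  }
  max(frac)
}

# hard-edged filled ellipse: pixel centers inside get `value`
.draw_ellipse <- function(img, cx, cy, r, ecc, theta, value) {
  side <- nrow(img)
  rx <- r * ecc; ry <- r / ecc
  ext <- ceiling(max(rx, ry)) + 1L
  rows <- max(1L, floor(cy) - ext):min(side, ceiling(cy) + ext)
  cols <- max(1L, floor(cx) - ext):min(side, ceiling(cx) + ext)
  dx <- outer(rep(1, length(rows)), cols - 1 - cx)
  dy <- outer(rows - 1 - cy, rep(1, length(cols)))
  u <- (dx * cos(theta) + dy * sin(theta)) / rx
  v <- (-dx * sin(theta) + dy * cos(theta)) / ry
  sub <- img[rows, cols]
  sub[u^2 + v^2 <= 1] <- value
  img[rows, cols] <- sub
  img
}

.add_nuisances <- function(img, side, illumination_gradient, noise_sd) {
  if (illumination_gradient != 0) {
    g <- illumination_gradient * ((seq_len(side) - 1) / (side - 1) - 0.5)
    img <- img + matrix(g, side, side, byrow = TRUE)
  }
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(side * side, 0, noise_sd), side, side)
  pmin(pmax(img, 0), 1)
}

#' Synthetic phantom of adenocarcinoma mucosa
#'
#' Generates a CLE-like phantom of disorganized malignant mucosa: a white
#' random field is smoothed anisotropically (long axis >> short axis),
#' warped by a smooth random displacement field of the given amplitude, and
#' thresholded at a mass quantile into elongated, branching dark ridges over
#' a brighter background. The result has few or no closed round structures,
#' mimicking the elongated, interrupted crypts of adenocarcinoma. With
#' `distortion_amplitude = 0` the ridges degenerate toward periodic bands (a
#' documented, allowed limiting case). Deterministic in `seed`.
#'
#' @param side image side in pixels (>= 128).
#' @param distortion_amplitude displacement-field amplitude in pixels.
#' @param ridge_sigma_long,ridge_sigma_short anisotropic smoothing scales in
#'   pixels. The long axis sets the typical uninterrupted ridge length;
#'   short ridges fragment into isolated blobs that read as spurious round
#'   features, so the default keeps ridges comparable to the field of view.
#' @param ridge_fraction fraction of the image covered by dark ridges.
#' @param ridge_intensity,background_intensity the two intensity plateaus.
#' @param edge_softening Gaussian sd (pixels) applied to the thresholded
#'   ridge pattern, emulating the blurred epithelial borders of malignant
#'   tissue; 0 disables.
#' @param noise_sd,illumination_gradient as in [phantom_normal()].
#' @param seed integer seed.
#' @return list with `image`, `truth` (`class`, `n_crypts = 0`,
#'   `ridge_fraction`), and `seed`.
#' @export
phantom_tumor <- function(side = 512L, distortion_amplitude = 12,
                          ridge_sigma_long = 64, ridge_sigma_short = 3,
                          ridge_fraction = 0.45,
                          ridge_intensity = 0.35, background_intensity = 0.62,
                          edge_softening = 2.0,
                          noise_sd = 0.025, illumination_gradient = 0.08,
                          seed = 1L) {
  side <- as.integer(side)
  if (side < 128L) stop("side must be >= 128")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)

  z <- matrix(stats::rnorm(side * side), side, side)
  field <- gaussian_smooth(z, sigma = ridge_sigma_long,
                           sigma_y = ridge_sigma_short)
  if (stats::runif(1L) < 0.5) field <- t(field)   # random band orientation

  if (distortion_amplitude > 0) {
    disp <- function() {
      d <- gaussian_smooth(matrix(stats::rnorm(side * side), side, side), 64)
      d / stats::sd(d) * distortion_amplitude
    }
    dx <- disp(); dy <- disp()
    field <- .bilinear_warp(field, dx, dy)
  }

  q <- stats::quantile(field, ridge_fraction)
  img <- matrix(background_intensity, side, side)
  img[field < q] <- ridge_intensity
  if (edge_softening > 0) img <- gaussian_smooth(img, edge_softening)
  img <- .add_nuisances(img, side, illumination_gradient, noise_sd)
  list(image = img,
       truth = list(class = "cancer", n_crypts = 0L,
                    ridge_fraction = ridge_fraction),
       seed = seed)
}

# sample field at (col + dx, row + dy), bilinear, clamped at the borders
.bilinear_warp <- function(field, dx, dy) {
  n <- nrow(field); m <- ncol(field)
  rr <- matrix(seq_len(n), n, m) + dy
  cc <- matrix(seq_len(m), n, m, byrow = TRUE) + dx
  rr <- pmin(pmax(rr, 1), n); cc <- pmin(pmax(cc, 1), m)
  r0 <- pmin(floor(rr), n - 1L); c0 <- pmin(floor(cc), m - 1L)
  fr <- rr - r0; fc <- cc - c0
  idx <- function(r, c) field[cbind(as.vector(r), as.vector(c))]
  out <- (1 - fr) * (1 - fc) * idx(r0, c0) +
         (1 - fr) * fc       * idx(r0, c0 + 1L) +
         fr       * (1 - fc) * idx(r0 + 1L, c0) +
         fr       * fc       * idx(r0 + 1L, c0 + 1L)
  matrix(out, n, m)
}

#' Generate a labeled phantom dataset
#'
#' Draws `n_normal` normal and `n_cancer` adenocarcinoma phantoms, each with
#' an independent per-image seed derived from the master seed, so the whole
#' dataset is reproducible from `seed` alone. When `dir` is given, images
#' are written as PNG together with `labels.csv` and `truth.json`;
#' otherwise a manifest is returned and images can be generated lazily with
#' [phantom_from_manifest()] (useful for large datasets that need not be
#' held in memory).
#'
#' @param n_normal,n_cancer class sizes (>= 0, at least one positive).
#' @param side image side in pixels.
#' @param seed master seed.
#' @param dir optional output directory.
#' @param ... passed to both phantom generators where applicable.
#' @return data frame manifest with columns `id`, `label`, `seed` (with
#'   attribute `side`); written files if `dir` is given.
#' @export
phantom_dataset <- function(n_normal, n_cancer, side = 512L, seed = 42L,
                            dir = NULL, ...) {
  n_normal <- as.integer(n_normal); n_cancer <- as.integer(n_cancer)
  if (n_normal < 0L || n_cancer < 0L || n_normal + n_cancer == 0L)
    stop("need a positive total number of images")
  n <- n_normal + n_cancer
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  manifest <- data.frame(
    id = c(sprintf("normal_%04d", seq_len(n_normal)),
           sprintf("cancer_%04d", seq_len(n_cancer))),
    label = rep(c("normal", "cancer"), c(n_normal, n_cancer)),
    seed = seeds, stringsAsFactors = FALSE)
  attr(manifest, "side") <- side
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    truth <- vector("list", n)
    names(truth) <- manifest$id
    for (i in seq_len(n)) {
      ph <- phantom_from_manifest(manifest, i, ...)
      write_gray_image(ph$image, file.path(dir, paste0(manifest$id[i], ".png")))
      truth[[i]] <- ph$truth
    }
    utils::write.csv(manifest[c("id", "label")],
                     file.path(dir, "labels.csv"), row.names = FALSE,
                     quote = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  manifest
}

#' Generate one phantom from a dataset manifest row
#'
#' @param manifest a [phantom_dataset()] manifest.
#' @param i row index.
#' @param ... extra arguments for the class-specific generator.
#' @return the phantom list (see [phantom_normal()], [phantom_tumor()]).
#' @export
phantom_from_manifest <- function(manifest, i, ...) {
  side <- attr(manifest, "side")
  if (manifest$label[i] == "normal")
    phantom_normal(side = side, seed = manifest$seed[i], ...)
  else
    phantom_tumor(side = side, seed = manifest$seed[i], ...)
}
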