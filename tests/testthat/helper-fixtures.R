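# fixtures and independent oracles shared across the test files; all data
# built in code, most of it under a fixed seed

# disk digitized as a sampled field with a 1 px linear anti-aliased edge;
# iso-level 0.5 recovers the circle of radius r to sub-pixel accuracy
disk_field <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  d <- sqrt(outer(seq_len(n) - cy, rep(1, n))^2 +
            outer(rep(1, n), seq_len(n) - cx)^2)
  pmin(pmax(r + 0.5 - d, 0), 1)
}

# hard binary disk (pixel centers strictly inside)
disk_mask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  d <- sqrt(outer(seq_len(n) - cy, rep(1, n))^2 +
            outer(rep(1, n), seq_len(n) - cx)^2)
  d <= r
}

# Sierpinski carpet at the given construction depth (3^depth square);
# a pixel is filled unless some base-3 digit position has digit 1 in both
# coordinates
sierpinski_carpet <- function(depth) {
  n <- 3^depth
  i0 <- 0:(n - 1)
  digs <- vapply(seq_len(depth) - 1L,
                 function(k) (i0 %/% 3^k) %% 3 == 1, logical(n))
  bad <- (digs + 0) %*% t(digs + 0) > 0
  !bad
}

# brute-force GLCM statistics by explicit double loop over all (i, j)
bf_glcm_stats <- function(P) {
  L <- nrow(P)
  mu_i <- mu_j <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    mu_i <- mu_i + i * P[i + 1, j + 1]
    mu_j <- mu_j + j * P[i + 1, j + 1]
  }
  v_i <- v_j <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    v_i <- v_i + (i - mu_i)^2 * P[i + 1, j + 1]
    v_j <- v_j + (j - mu_j)^2 * P[i + 1, j + 1]
  }
  con <- cor <- en <- hom <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    p <- P[i + 1, j + 1]
    con <- con + (i - j)^2 * p
    cor <- cor + (i - mu_i) * (j - mu_j) * p
    en <- en + p^2
    hom <- hom + p / (1 + abs(i - j))
  }
  list(contrast = con, correlation = cor / sqrt(v_i * v_j),
       energy = en, homogeneity = hom)
}

# brute-force gliding-box lacunarity by explicit window enumeration
bf_lacunarity <- function(mask, r) {
  h <- nrow(mask); w <- ncol(mask)
  masses <- numeric((h - r + 1) * (w - r + 1))
  k <- 0L
  for (i in 1:(h - r + 1)) for (j in 1:(w - r + 1)) {
    k <- k + 1L
    masses[k] <- sum(mask[i:(i + r - 1), j:(j + r - 1)])
  }
  mean(masses^2) / mean(masses)^2 - 1
}

# brute-force GLCM of an image by explicit loop over all pixel pairs
bf_glcm <- function(img, levels, dy, dx) {
  lo <- min(img); hi <- max(img)
  q <- pmin(floor((img - lo) / (hi - lo) * levels), levels - 1)
  P <- matrix(0, levels, levels)
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    r2 <- r + dy; c2 <- c + dx
    if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img))
      P[q[r, c] + 1, q[r2, c2] + 1] <- P[q[r, c] + 1, q[r2, c2] + 1] + 1
  }
  P / sum(P)
}

# brute-force box-occupancy counter (loop over every box of the grid)
bf_box_count <- function(mask, s) {
  h <- nrow(mask); w <- ncol(mask)
  n <- 0L
  for (bi in seq(1, h, by = s)) for (bj in seq(1, w, by = s)) {
    if (any(mask[bi:min(bi + s - 1, h), bj:min(bj + s - 1, w)])) n <- n + 1L
  }
  n
}

# random probability matrix normalized to a valid GLCM
random_glcm <- function(L) {
  P <- matrix(stats::runif(L * L), L, L)
  P / sum(P)
}

# a fake classifier whose softmax output is constant (set by b2), used to
# test evaluation arithmetic against hand computation
constant_prob_model <- function(p1, levels = c("normal", "cancer"), nfeat = 7) {
  structure(list(
    W1 = matrix(0, 4, nfeat), b1 = numeric(4),
    W2 = matrix(0, 2, 4), b2 = c(log(p1), log(1 - p1)),
    input_mean = rep(0, nfeat), input_sd = rep(1, nfeat),
    levels = levels, feature_names = NULL, hidden = 4L,
    best_epoch = 1L), class = "cad_mlp")
}

# separable two-cluster feature fixture from the classifier contract
separable_features <- function(n = 400, gap = 3, p = 7, seed = 11) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n / 2 * p, 0, 1), ncol = p),
             matrix(stats::rnorm(n / 2 * p, gap, 1), ncol = p))
  list(x = x, y = rep(c("normal", "cancer"), each = n / 2))
}

cli_path <- function() system.file("cli", "cryptocad.R", package = "cryptocad")

run_cli <- function(...) {
  out <- system2(file.path(R.home("bin"), "Rscript"),
                 c(cli_path(), ...), stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("CLI failed: ", paste(out, collapse = "\n"))
  invisible(out)
}
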