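test_that("Otsu threshold separates a bimodal image", {
  img <- matrix(rep(c(0.2, 0.8), each = 512), 32)
  t0 <- otsu_threshold(img)
  expect_gt(t0, 0.2); expect_lt(t0, 0.8)
  m <- binarize(img)
  expect_identical(sum(m), 512L)                 # exactly half the pixels
  expect_error(binarize(matrix(0.5, 32, 32)), "constant")
})

test_that("Otsu matches an exhaustive between-class-variance sweep", {
  set.seed(7)
  truth <- rep(c(0L, 1L), each = 2048)
  img <- matrix(ifelse(truth == 0, rnorm(4096, 0.3, 0.05),
                       rnorm(4096, 0.7, 0.05)), 64)
  t_pkg <- otsu_threshold(img)
  # oracle: sweep every observed value as a candidate threshold and maximize
  # the between-class variance computed directly from the pixel values
  cand <- sort(unique(as.vector(img)))
  bcv <- vapply(cand[-length(cand)], function(t) {
    w0 <- mean(img <= t)
    if (w0 == 0 || w0 == 1) return(-Inf)
    w0 * (1 - w0) * (mean(img[img <= t]) - mean(img[img > t]))^2
  }, numeric(1))
  t_oracle <- cand[which.max(bcv)]
  # both thresholds must induce (nearly) the same partition as the truth
  expect_lt(mean((img > t_pkg) != (truth == 1)), 0.01)
  expect_lt(mean((img > t_oracle) != (truth == 1)), 0.01)
  expect_lt(abs(t_pkg - t_oracle), diff(range(img)) / 256 * 2)
})

test_that("fixed-threshold binarization selects exactly the high pixels", {
  img <- matrix(rep(c(0.4, 0.6), 512), 32)
  m <- binarize(img, method = "fixed:0.5")
  expect_equal(m, img == 0.6, ignore_attr = TRUE)
  expect_identical(attr(m, "threshold"), 0.5)
})

test_that("box counting gives exact dimensions for plane and line", {
  scales <- c(2L, 4L, 8L, 16L, 32L)
  full <- matrix(TRUE, 256, 256)
  fit <- box_count_dimension(full, scales)
  expect_equal(fit$fractal_dimension, 2, tolerance = 1e-12)
  expect_equal(fit$counts, as.integer((256 / scales)^2))
  line <- matrix(FALSE, 256, 256); line[100, ] <- TRUE
  fit <- box_count_dimension(line, scales)
  expect_equal(fit$fractal_dimension, 1, tolerance = 1e-12)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-12)
})

test_that("Sierpinski carpet dimension is recovered", {
  mask <- sierpinski_carpet(5)
  fit <- box_count_dimension(mask, c(3L, 9L, 27L, 81L))
  expect_equal(fit$counts, as.integer(8^(4:1)))  # countable by construction
  expect_lt(abs(fit$fractal_dimension - log(8) / log(3)), 0.06)
})

test_that("box counts equal a brute-force counter on random masks", {
  set.seed(5)
  for (k in 1:5) {
    mask <- matrix(runif(64 * 64) < runif(1, 0.05, 0.6), 64)
    if (!any(mask)) mask[1] <- TRUE
    for (s in c(2L, 4L, 8L, 16L))
      expect_identical(box_count(mask, s), bf_box_count(mask, s))
  }
})

test_that("fractal dimension is within [0, 2] and transpose-invariant", {
  set.seed(9)
  for (k in 1:5) {
    mask <- matrix(runif(64 * 64) < 0.3, 64)
    fd <- box_count_dimension(mask)$fractal_dimension
    expect_gte(fd, 0); expect_lte(fd, 2)
    expect_equal(box_count_dimension(t(mask))$fractal_dimension, fd)
  }
  expect_error(box_count_dimension(matrix(FALSE, 64, 64)), "empty")
  expect_error(box_count_dimension(matrix(TRUE, 64, 64), c(2, 4)),
               "at least 3")
})

test_that("lacunarity of uniform patterns is exactly zero", {
  full <- matrix(TRUE, 32, 32)
  expect_identical(as.numeric(gliding_box_lacunarity(full, c(2, 4, 8))), 0)
  # a single window spanning the whole image has zero variance
  set.seed(2)
  mask <- matrix(runif(32 * 32) < 0.4, 32)
  expect_equal(as.numeric(gliding_box_lacunarity(mask, 32L)), 0)
})

test_that("hand-enumerated 4x4 two-pixel lacunarity value is reproduced", {
  mask <- matrix(FALSE, 4, 4); mask[1, 1] <- TRUE; mask[4, 4] <- TRUE
  # 9 windows of size 2: two have mass 1, seven mass 0
  # M1 = 2/9, M2 = 2/9, Lambda = 4.5, returned value 3.5
  expect_equal(as.numeric(gliding_box_lacunarity(mask, 2L)), 3.5)
  expect_equal(bf_lacunarity(mask, 2L), 3.5)
})

test_that("lacunarity matches brute-force enumeration on random masks", {
  set.seed(13)
  for (k in 1:8) {
    mask <- matrix(runif(32 * 32) < runif(1, 0.2, 0.8), 32)
    if (!any(mask)) mask[1] <- TRUE
    lam <- gliding_box_lacunarity(mask, c(2L, 4L, 8L))
    per <- attr(lam, "per_size")
    for (r in c(2L, 4L, 8L))
      expect_equal(unname(per[as.character(r)]), bf_lacunarity(mask, r),
                   tolerance = 1e-12)
    expect_true(all(per >= 0))
    # box-mass heterogeneity washes out with window size on iid masks
    expect_true(all(diff(per) <= 1e-12))
  }
  expect_error(gliding_box_lacunarity(matrix(FALSE, 32, 32)), "empty")
})
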