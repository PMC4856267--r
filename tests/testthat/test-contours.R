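test_that("Gaussian smoothing fixes constants and conserves mass", {
  img <- matrix(0.7, 40, 40)
  expect_equal(gaussian_smooth(img, 3), img, tolerance = 1e-12)
  spike <- matrix(0, 40, 40); spike[20, 20] <- 1
  expect_equal(sum(gaussian_smooth(spike, 1)), 1, tolerance = 1e-12)
  # mass conservation holds with the spike at the border too (reflection)
  spike2 <- matrix(0, 40, 40); spike2[1, 3] <- 1
  expect_equal(sum(gaussian_smooth(spike2, 2)), 1, tolerance = 1e-12)
  expect_error(gaussian_smooth(img, 0), "sigma")
  expect_error(gaussian_smooth(img, -1), "sigma")
})

test_that("step-edge response matches the error-function closed form", {
  n <- 64
  img <- matrix(0, n, n); img[, 33:n] <- 1      # edge between columns 32|33
  sm <- gaussian_smooth(img, 2)
  cols <- 20:45                                 # away from the borders
  expected <- pnorm((cols - 32.5) / 2)
  expect_equal(sm[32, cols], expected, tolerance = 1e-6)
})

test_that("single-pixel diamond contour is exact", {
  g <- matrix(0, 5, 5); g[3, 3] <- 1
  cs <- marching_squares_contours(g, 0.5)
  expect_length(cs, 1L)
  ct <- cs[[1]]
  expect_true(ct$closed); expect_false(ct$touches_border)
  expect_equal(nrow(ct$vertices), 4L)
  # the 4 crossing points are the edge midpoints around the center pixel
  expect_setequal(apply(ct$vertices, 1, paste, collapse = ","),
                  c("2,1.5", "2.5,2", "2,2.5", "1.5,2"))
  ap <- polygon_area_perimeter(ct)
  expect_equal(unname(ap["area"]), 0.5)
  expect_equal(unname(ap["perimeter"]), 2 * sqrt(2))
})

test_that("levels outside the value range give no contours", {
  g <- matrix(runif(64), 8, 8)
  expect_length(marching_squares_contours(g, 2), 0L)
  expect_length(marching_squares_contours(g, -1), 0L)
  expect_error(marching_squares_contours(matrix(1, 1, 5), 0.5), "2 x 2")
})

test_that("disjoint supra-level disks give one closed contour each", {
  g <- disk_field(96, 12, cx = 25, cy = 25) +
       disk_field(96, 12, cx = 70, cy = 70)
  cs <- marching_squares_contours(g, 0.5)
  expect_length(cs, 2L)
  expect_true(all(vapply(cs, `[[`, logical(1), "closed")))
})

test_that("contours crossing the image border are open and flagged", {
  g <- disk_field(64, 20, cx = 2, cy = 32)     # disk sticking out of the left
  cs <- marching_squares_contours(g, 0.5)
  expect_length(cs, 1L)
  expect_false(cs[[1]]$closed)
  expect_true(cs[[1]]$touches_border)
})

test_that("closed contours are returned in counter-clockwise orientation", {
  g <- disk_field(64, 10)
  v <- marching_squares_contours(g, 0.5)[[1]]$vertices
  x <- v[, 1]; y <- v[, 2]
  s <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  expect_gt(s, 0)
})

test_that("polygon area/perimeter are exact on hand-made polygons", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area_perimeter(sq), c(area = 1, perimeter = 4))
  tri <- rbind(c(0, 0), c(3, 0), c(0, 4))
  expect_equal(polygon_area_perimeter(tri), c(area = 6, perimeter = 12))
  expect_error(polygon_area_perimeter(list(vertices = sq, closed = FALSE)),
               "closed")
  expect_error(polygon_area_perimeter(sq[1:2, ]), "3 vertices")
})

test_that("radius-20 disk contour recovers the analytic area and perimeter", {
  cs <- marching_squares_contours(disk_field(64, 20), 0.5)
  expect_length(cs, 1L)
  ap <- polygon_area_perimeter(cs[[1]])
  expect_lt(abs(ap[["area"]] - 400 * pi) / (400 * pi), 0.03)
  expect_lt(abs(ap[["perimeter"]] - 40 * pi) / (40 * pi), 0.03)
})

test_that("contour geometry agrees with grDevices::contourLines", {
  g <- disk_field(64, 15)
  cl <- grDevices::contourLines(seq_len(64), seq_len(64), t(g), levels = 0.5)
  expect_length(cl, 1L)
  v <- cbind(cl[[1]]$x, cl[[1]]$y)
  if (all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), ]
  ap_ref <- polygon_area_perimeter(v)
  ap <- polygon_area_perimeter(marching_squares_contours(g, 0.5)[[1]])
  expect_equal(unname(ap), unname(ap_ref), tolerance = 1e-6)
})

test_that("disk roundness ratio approximates r/2 over the radius range", {
  for (r in c(6, 10, 14, 20, 28, 34, 40)) {
    n <- 2 * r + 16
    ap <- polygon_area_perimeter(
      marching_squares_contours(disk_field(n, r), 0.5)[[1]])
    ratio <- ap[["area"]] / ap[["perimeter"]]
    expect_lt(abs(ratio - r / 2) / (r / 2), 0.10)
    # the hard binary digitization also stays within the 10% band
    apb <- polygon_area_perimeter(
      marching_squares_contours(disk_mask(n, r) + 0, 0.5)[[1]])
    expect_lt(abs(apb[["area"]] / apb[["perimeter"]] - r / 2) / (r / 2), 0.10)
  }
})

test_that("round-feature counting separates disks from strips", {
  n <- 160
  g <- disk_field(n, 12, cx = 40, cy = 40)
  g[100:102, 20:119] <- 1                      # 100 x 3 strip, ratio ~ 1.4
  fs <- count_round_features(marching_squares_contours(g, 0.5), 4)
  expect_length(fs$contours, 2L)
  expect_identical(fs$count_round, 1L)
  expect_true(all(fs$ratios > 0))
})

test_that("count_round is monotone non-increasing in the threshold", {
  set.seed(6)
  g <- matrix(0, 128, 128)
  for (k in 1:6) {
    r <- sample(5:14, 1)
    g <- pmax(g, disk_field(128, r, cx = runif(1, 20, 108),
                            cy = runif(1, 20, 108)))
  }
  cs <- marching_squares_contours(g, 0.5)
  counts <- vapply(c(0.5, 1, 2, 3, 4, 6, 8),
                   function(t) count_round_features(cs, t)$count_round,
                   integer(1))
  expect_true(all(diff(counts) <= 0L))
  expect_identical(count_round_features(list(), 4)$count_round, 0L)
  expect_error(count_round_features(cs, 0), "ratio_threshold")
})
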