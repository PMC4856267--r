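test_that("split sizes follow largest-remainder rounding", {
  s <- split_dataset(1035, c(0.70, 0.15, 0.15), seed = 42)
  expect_length(s$train, 725L)
  expect_length(s$validation, 155L)
  expect_length(s$test, 155L)
  expect_identical(sort(c(s$train, s$validation, s$test)), 1:1035)
  expect_length(intersect(s$train, s$test), 0L)
  s3 <- split_dataset(3, c(1, 1, 1) / 3, seed = 1)
  expect_identical(lengths(unclass(s3)), c(train = 1L, validation = 1L,
                                           test = 1L))
  # remainder tie between validation and test goes to the earlier split
  s10 <- split_dataset(10, c(0.7, 0.15, 0.15), seed = 1)
  expect_identical(lengths(unclass(s10)), c(train = 7L, validation = 2L,
                                            test = 1L))
  expect_error(split_dataset(2), "n >= 3")
  expect_error(split_dataset(10, c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("separable clusters are classified almost perfectly", {
  d <- separable_features()
  fit <- cad_mlp(d$x, d$y, seed = 11)
  expect_lte(fit$evaluation$test$decision_accuracy_error, 2)
  agree <- mean(predict(fit, d$x[fit$split$train, ]) == d$y[fit$split$train])
  expect_gte(agree, 0.98)
})

test_that("label-shuffled data stays near the majority baseline", {
  d <- separable_features()
  set.seed(11)
  ys <- sample(d$y)
  fit <- cad_mlp(d$x, ys, seed = 11)
  test_labels <- ys[fit$split$test]
  baseline <- 100 * min(table(test_labels)) / length(test_labels)
  expect_lte(abs(fit$evaluation$test$decision_accuracy_error - baseline), 10)
})

test_that("training is fully deterministic given data, config and seed", {
  d <- separable_features(n = 200)
  f1 <- cad_mlp(d$x, d$y, seed = 5)
  f2 <- cad_mlp(d$x, d$y, seed = 5)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$evaluation$test$cross_entropy,
                   f2$evaluation$test$cross_entropy)
  f3 <- cad_mlp(d$x, d$y, seed = 6)
  expect_false(identical(coef(f1), coef(f3)))
})

test_that("standardization comes only from the training split (no leakage)", {
  d <- separable_features(n = 200)
  split <- split_dataset(200, seed = 3)
  f1 <- cad_mlp(d$x, d$y, split = split, seed = 3)
  # permute the rows inside validation+test; the split sets are unchanged
  x2 <- d$x; y2 <- d$y
  set.seed(99); perm <- sample(c(split$validation, split$test))
  x2[c(split$validation, split$test), ] <- d$x[perm, ]
  y2[c(split$validation, split$test)] <- d$y[perm]
  # standardization statistics must be identical
  f2 <- cad_mlp(x2, y2, split = split, seed = 3)
  expect_identical(f1$input_mean, f2$input_mean)
  expect_identical(f1$input_sd, f2$input_sd)
})

test_that("early stopping returns the epoch of minimum validation loss", {
  d <- separable_features(n = 200, gap = 1)      # noisy enough to stop early
  fit <- cad_mlp(d$x, d$y, seed = 2, patience = 6)
  tl <- fit$training_log
  expect_identical(fit$best_epoch, which.min(tl$validation_loss))
  expect_lte(tl$train_loss[fit$best_epoch], tl$train_loss[1])
  expect_lte(nrow(tl) - fit$best_epoch, 6L)
})

test_that("single-class or non-finite training inputs are errors", {
  x <- matrix(rnorm(60), 20)
  expect_error(cad_mlp(x, rep("normal", 20), seed = 1), "two classes")
  y <- rep(c("normal", "cancer"), 10)
  x2 <- x; x2[1] <- Inf
  expect_error(cad_mlp(x2, y, seed = 1), "finite")
})

test_that("softmax probabilities sum to one and ties go to cancer", {
  d <- separable_features(n = 100)
  fit <- cad_mlp(d$x, d$y, hidden = 8, seed = 4)
  p <- predict(fit, d$x, type = "prob")
  expect_equal(rowSums(p), rep(1, 100), tolerance = 1e-12)
  # zero output layer: exactly symmetric probabilities
  tie <- constant_prob_model(0.5)
  ptie <- predict(tie, matrix(0, 3, 7), type = "prob")
  expect_equal(unname(ptie), matrix(0.5, 3, 2))
  expect_identical(as.character(predict(tie, matrix(0, 3, 7))),
                   rep("cancer", 3))
})

test_that("evaluation metrics match hand-computed values", {
  x <- matrix(0, 4, 7)
  y <- c("normal", "normal", "cancer", "cancer")
  m <- constant_prob_model(0.8)                  # P(normal) = 0.8 always
  ev <- evaluate_model(m, x, y)
  expect_equal(ev$all$cross_entropy, -(2 * log(0.8) + 2 * log(0.2)) / 4)
  expect_equal(ev$all$decision_accuracy_error, 50)
  expect_equal(sum(ev$all$confusion), 4)
  # uniform predictions: ln 2 cross-entropy
  ev2 <- evaluate_model(constant_prob_model(0.5), x, y)
  expect_equal(ev2$all$cross_entropy, log(2))
  # perfect predictions: zero cross-entropy, zero error (two-sided check
  # via two constant models evaluated on their own class)
  ev3 <- evaluate_model(constant_prob_model(1 - 1e-18), x[1:2, ], y[1:2])
  expect_equal(ev3$all$cross_entropy, 0, tolerance = 1e-12)
  expect_equal(ev3$all$decision_accuracy_error, 0)
})

test_that("model JSON serialization preserves predictions exactly", {
  d <- separable_features(n = 100)
  fit <- cad_mlp(d$x, d$y, hidden = 8, seed = 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_cad_mlp(fit, f)
  back <- read_cad_mlp(f)
  expect_equal(back$W1, fit$W1, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(predict(back, d$x, type = "prob"),
               predict(fit, d$x, type = "prob"), tolerance = 1e-12)
  expect_identical(predict(back, d$x), predict(fit, d$x))
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format": "other"}', bad)
  expect_error(read_cad_mlp(bad), "not a cryptocad model")
})

test_that("the formula interface and accessors work", {
  d <- separable_features(n = 100)
  df <- data.frame(label = d$y, d$x)
  fit <- cad_mlp(label ~ ., df, hidden = 8, seed = 1)
  expect_s3_class(fit, "cad_mlp")
  cf <- coef(fit)
  expect_identical(dim(cf$W1), c(8L, 7L))
  expect_identical(dim(cf$W2), c(2L, 8L))
  expect_output(print(fit), "feed-forward")
  expect_output(print(summary(fit)), "standardization")
})

test_that("an independent implementation agrees on the separable fixture", {
  # nnet's single-hidden-layer network is the reference implementation for
  # the same architecture; both must solve the separable problem
  d <- separable_features(n = 200)
  split <- split_dataset(200, seed = 7)
  fit <- cad_mlp(d$x, d$y, split = split, seed = 7)
  yf <- factor(d$y)
  set.seed(7)
  ref <- nnet::nnet(d$x[split$train, ], nnet::class.ind(yf[split$train]),
                    size = 10, softmax = TRUE, trace = FALSE, maxit = 200)
  ref_err <- 100 * mean(max.col(predict(ref, d$x[split$test, ])) !=
                        as.integer(yf[split$test]))
  expect_lte(fit$evaluation$test$decision_accuracy_error, 2)
  expect_lte(ref_err, 2)
})
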