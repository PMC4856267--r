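#' Train/validation/test split by largest-remainder rounding
#'
#' Partitions `1:n` into three disjoint index sets whose sizes are the
#' largest-remainder rounding of `n * proportions` (ties between equal
#' remainders go to the earlier-listed split, train first), with assignment
#' by a seeded random shuffle. With `n = 1035` and proportions
#' `(0.70, 0.15, 0.15)` this yields sizes 725/155/155.
#'
#' @param n number of samples (>= 3).
#' @param proportions positive train/validation/test fractions summing to 1.
#' @param seed integer seed for the shuffle.
#' @return object of class `"cad_split"`: list with integer vectors `train`,
#'   `validation`, `test`.
#' @export
split_dataset <- function(n, proportions = c(0.70, 0.15, 0.15), seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("need n >= 3 samples to split")
  if (length(proportions) != 3L || any(proportions <= 0) ||
      abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must be three positive numbers summing to 1")
  target <- n * proportions
  sizes <- floor(target)
  rem <- target - sizes
  left <- n - sum(sizes)
  if (left > 0) {
    ord <- order(-rem, seq_along(rem))   # largest remainder, earlier split wins
    sizes[ord[seq_len(left)]] <- sizes[ord[seq_len(left)]] + 1
  }
  set.seed(seed)
  perm <- sample.int(n)
  structure(list(train = sort(perm[seq_len(sizes[1L])]),
                 validation = sort(perm[sizes[1L] + seq_len(sizes[2L])]),
                 test = sort(perm[sizes[1L] + sizes[2L] + seq_len(sizes[3L])])),
            class = "cad_split")
}

#' @export
print.cad_split <- function(x, ...) {
  cat(sprintf("data split: %d train / %d validation / %d test\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass; x already standardized
.mlp_forward <- function(w, x) {
  a1 <- .sigmoid(sweep(x %*% t(w$W1), 2L, w$b1, `+`))
  p <- .softmax(sweep(a1 %*% t(w$W2), 2L, w$b2, `+`))
  list(a1 = a1, p = p)
}

.xent <- function(p, yidx) {
  -mean(log(pmax(p[cbind(seq_along(yidx), yidx)], 1e-15))) + 0  # +0 kills -0
}

#' Two-layer feed-forward classifier for crypt-architecture features
#'
#' Fits the decision module of the CAD pipeline: a feed-forward network with
#' one hidden layer of logistic-sigmoid units (default 100) and a two-unit
#' softmax output, trained by full-batch resilient backpropagation (iRprop-)
#' on the mean natural-log cross-entropy, with early stopping on a held-out
#' validation split (training stops once the validation loss has failed to
#' improve for `patience` consecutive epochs, and the weights at the best
#' validation epoch are returned). Inputs are standardized using the mean
#' and standard deviation of the *training split only*, so no information
#' leaks from validation or test samples into the fit.
#'
#' @param x numeric matrix (or data frame) of feature vectors, one row per
#'   image; for the CAD pipeline the seven columns of [cad_features()].
#' @param y class labels (factor or character, exactly 2 classes); the level
#'   named `"cancer"`, when present, is used for tie-breaking in
#'   [predict.cad_mlp()].
#' @param split a [split_dataset()] result, or `NULL` to draw a 70/15/15
#'   split with `seed`.
#' @param hidden number of hidden units.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience in epochs.
#' @param seed integer seed for the weight initialization (and the split,
#'   when `split = NULL`). Identical data, configuration and seed reproduce
#'   the fit exactly.
#' @param formula,data alternatively, a model formula such as
#'   `label ~ .` with a data frame (formula method).
#' @param ... passed between methods.
#' @return object of class `"cad_mlp"`: weights `W1`, `b1`, `W2`, `b2`,
#'   standardization vectors `input_mean`, `input_sd`, class `levels`, the
#'   `split`, a per-epoch `training_log` (train and validation loss), the
#'   selected `best_epoch`, and an `evaluation` report
#'   (see [evaluate_model()]).
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(200, 0), ncol = 2), matrix(rnorm(200, 3), ncol = 2))
#' y <- rep(c("normal", "cancer"), each = 100)
#' fit <- cad_mlp(x, y, hidden = 10, seed = 1)
#' fit$evaluation$test
#' @export
cad_mlp <- function(x, ...) UseMethod("cad_mlp")

#' @rdname cad_mlp
#' @export
cad_mlp.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- mf[, -1L, drop = FALSE]
  fit <- cad_mlp.default(x, y, ...)
  fit$call <- match.call()
  fit
}

#' @rdname cad_mlp
#' @export
cad_mlp.default <- function(x, y, split = NULL, hidden = 100L,
                            max_epochs = 1000L, patience = 6L, seed = 1L, ...) {
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("features must be finite")
  y <- factor(y)
  if (nlevels(y) != 2L) stop("exactly two classes are required")
  n <- nrow(x); p <- ncol(x)
  if (is.null(split)) split <- split_dataset(n, seed = seed)
  stopifnot(inherits(split, "cad_split"))
  idx_all <- c(split$train, split$validation, split$test)
  if (length(idx_all) != n || !setequal(idx_all, seq_len(n)))
    stop("split does not cover the dataset")
  tr <- split$train
  if (length(unique(y[tr])) < 2L)
    stop("training split contains a single class; cannot train")
  if (min(table(y[tr])) < 2L)
    stop("need at least 2 training examples of each class")

  mu <- colMeans(x[tr, , drop = FALSE])
  sd_ <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
  if (any(sd_ == 0)) {
    warning("constant feature(s) in the training split; scale set to 1")
    sd_[sd_ == 0] <- 1
  }
  xs <- sweep(sweep(x, 2L, mu), 2L, sd_, `/`)
  yidx <- as.integer(y)
  ymat <- diag(2)[yidx, , drop = FALSE]

  set.seed(seed)
  h <- as.integer(hidden)
  r1 <- sqrt(6 / (p + h)); r2 <- sqrt(6 / (h + 2))
  w <- list(W1 = matrix(stats::runif(h * p, -r1, r1), h, p),
            b1 = numeric(h),
            W2 = matrix(stats::runif(2 * h, -r2, r2), 2, h),
            b2 = numeric(2))

  grad <- function(w, x, ymat) {
    n <- nrow(x)
    fwd <- .mlp_forward(w, x)
    d2 <- (fwd$p - ymat) / n
    da1 <- d2 %*% w$W2
    d1 <- da1 * fwd$a1 * (1 - fwd$a1)
    list(W1 = t(d1) %*% x, b1 = colSums(d1),
         W2 = t(d2) %*% fwd$a1, b2 = colSums(d2))
  }

  # iRprop-: per-parameter step sizes adapted from gradient sign agreement
  step <- lapply(w, function(m) m * 0 + 0.01)
  gprev <- lapply(w, function(m) m * 0)
  eta_plus <- 1.2; eta_minus <- 0.5
  step_min <- 1e-12; step_max <- 1.0

  xtr <- xs[tr, , drop = FALSE]; ytr <- ymat[tr, , drop = FALSE]
  xva <- xs[split$validation, , drop = FALSE]
  yva_idx <- yidx[split$validation]
  ytr_idx <- yidx[tr]

  log_tr <- log_va <- numeric(max_epochs)
  best <- list(loss = Inf, epoch = 0L, w = w)
  stall <- 0L
  epoch <- 0L
  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    g <- grad(w, xtr, ytr)
    for (nm in names(w)) {
      sgn <- sign(g[[nm]] * gprev[[nm]])
      step[[nm]] <- pmin(pmax(
        step[[nm]] * ifelse(sgn > 0, eta_plus, ifelse(sgn < 0, eta_minus, 1)),
        step_min), step_max)
      g[[nm]][sgn < 0] <- 0            # iRprop-: forget flipped gradients
      w[[nm]] <- w[[nm]] - sign(g[[nm]]) * step[[nm]]
      gprev[[nm]] <- g[[nm]]
    }
    log_tr[epoch] <- .xent(.mlp_forward(w, xtr)$p, ytr_idx)
    va_loss <- .xent(.mlp_forward(w, xva)$p, yva_idx)
    log_va[epoch] <- va_loss
    if (!is.finite(log_tr[epoch]) || !is.finite(va_loss))
      stop("training diverged: non-finite loss at epoch ", epoch)
    if (va_loss < best$loss) {
      best <- list(loss = va_loss, epoch = epoch, w = w)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }

  obj <- structure(list(
    W1 = best$w$W1, b1 = best$w$b1, W2 = best$w$W2, b2 = best$w$b2,
    input_mean = mu, input_sd = sd_, levels = levels(y),
    feature_names = colnames(x), hidden = h, split = split,
    training_log = data.frame(epoch = seq_len(epoch),
                              train_loss = log_tr[seq_len(epoch)],
                              validation_loss = log_va[seq_len(epoch)]),
    best_epoch = best$epoch, seed = seed, patience = patience,
    call = match.call()), class = "cad_mlp")
  obj$evaluation <- evaluate_model(obj, x, y, split)
  obj
}

#' Predict method for `cad_mlp` fits
#'
#' @param object a [cad_mlp()] fit.
#' @param newdata matrix or data frame of feature vectors.
#' @param type `"class"` for labels, `"prob"` for the softmax probabilities.
#' @param ... ignored.
#' @return factor of predicted labels, or a probability matrix with one
#'   column per class. Exact probability ties are resolved toward the
#'   `"cancer"` class (conservative call) when such a class exists, else
#'   toward the second level.
#' @export
predict.cad_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(as.data.frame(newdata))
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("newdata contains non-finite features")
  xs <- sweep(sweep(x, 2L, object$input_mean), 2L, object$input_sd, `/`)
  p <- .mlp_forward(object, xs)$p
  colnames(p) <- object$levels
  if (type == "prob") return(p)
  tie_to <- if ("cancer" %in% object$levels)
    match("cancer", object$levels) else 2L
  cls <- apply(p, 1L, function(pr) {
    k <- which(pr == max(pr))
    if (length(k) > 1L) tie_to else k
  })
  factor(object$levels[cls], levels = object$levels)
}

#' Evaluate a fitted classifier on labeled data
#'
#' Computes, for each split (or for the full set when `split = NULL`), the
#' mean natural-log cross-entropy of the predicted probabilities, the
#' decision accuracy error (percent of samples misclassified), and the
#' confusion counts.
#'
#' @param model a [cad_mlp()] fit.
#' @param x feature matrix.
#' @param y true labels.
#' @param split optional [split_dataset()] result.
#' @return object of class `"cad_eval"`: a list with one entry per split,
#'   each holding `n`, `cross_entropy`, `decision_accuracy_error` (in
#'   percent) and `confusion`.
#' @export
evaluate_model <- function(model, x, y, split = NULL) {
  x <- as.matrix(as.data.frame(x))
  y <- factor(y, levels = model$levels)
  stopifnot(nrow(x) == length(y), ncol(x) == length(model$input_mean))
  parts <- if (is.null(split)) list(all = seq_len(nrow(x)))
           else list(train = split$train, validation = split$validation,
                     test = split$test)
  p_all <- predict(model, x, type = "prob")
  cls_all <- predict(model, x, type = "class")
  out <- lapply(parts, function(ii) {
    if (!length(ii)) stop("empty split")
    yi <- as.integer(y[ii])
    list(n = length(ii),
         cross_entropy = .xent(p_all[ii, , drop = FALSE], yi),
         decision_accuracy_error = 100 * mean(cls_all[ii] != y[ii]),
         confusion = table(truth = y[ii], predicted = cls_all[ii]))
  })
  structure(out, class = "cad_eval")
}

#' @export
print.cad_eval <- function(x, ...) {
  cat("split        n   cross-entropy   error (%)\n")
  for (nm in names(x))
    cat(sprintf("%-10s %4d   %13.4f   %9.2f\n", nm, x[[nm]]$n,
                x[[nm]]$cross_entropy, x[[nm]]$decision_accuracy_error))
  invisible(x)
}

#' @export
print.cad_mlp <- function(x, ...) {
  cat(sprintf(
    "two-layer feed-forward classifier (%d -> %d sigmoid -> 2 softmax)\n",
    length(x$input_mean), x$hidden))
  if (!is.null(x$training_log))
    cat(sprintf("classes: %s; trained %d epochs, best validation at epoch %d\n",
                paste(x$levels, collapse = " / "),
                nrow(x$training_log), x$best_epoch))
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}

#' @export
summary.cad_mlp <- function(object, ...) {
  structure(list(fit = object), class = "summary.cad_mlp")
}

#' @export
print.summary.cad_mlp <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\ninput standardization (training split only):\n")
  print(rbind(mean = f$input_mean, sd = f$input_sd))
  tl <- f$training_log
  cat(sprintf("\nfinal losses: train %.4f, validation %.4f (best %.4f)\n",
              tl$train_loss[nrow(tl)], tl$validation_loss[nrow(tl)],
              min(tl$validation_loss)))
  invisible(x)
}

#' @export
coef.cad_mlp <- function(object, ...) {
  list(W1 = object$W1, b1 = object$b1, W2 = object$W2, b2 = object$b2)
}

#' Plot the training history of a `cad_mlp` fit
#'
#' @param x a [cad_mlp()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cad_mlp <- function(x, ...) {
  tl <- x$training_log
  graphics::matplot(tl$epoch, cbind(tl$train_loss, tl$validation_loss),
                    type = "l", lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "cross-entropy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Save / load a fitted classifier as JSON
#'
#' The file stores the weights, biases, standardization statistics, class
#' levels, seed and selected epoch as plain nested arrays, so an evaluation
#' report is reproducible from the file alone.
#'
#' @param model a [cad_mlp()] fit.
#' @param path JSON path.
#' @return `path` (write) or a `"cad_mlp"` object (read).
#' @export
write_cad_mlp <- function(model, path) {
  stopifnot(inherits(model, "cad_mlp"))
  payload <- list(
    format = "cryptocad-mlp-1",
    hidden = model$hidden, levels = model$levels,
    feature_names = model$feature_names, seed = model$seed,
    best_epoch = model$best_epoch,
    input_mean = unname(model$input_mean), input_sd = unname(model$input_sd),
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_cad_mlp
#' @export
read_cad_mlp <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "cryptocad-mlp-1"))
    stop("not a cryptocad model file: ", path)
  structure(list(W1 = as.matrix(p$W1), b1 = as.numeric(p$b1),
                 W2 = as.matrix(p$W2), b2 = as.numeric(p$b2),
                 input_mean = stats::setNames(p$input_mean, p$feature_names),
                 input_sd = stats::setNames(p$input_sd, p$feature_names),
                 levels = p$levels, feature_names = p$feature_names,
                 hidden = p$hidden, seed = p$seed, best_epoch = p$best_epoch,
                 training_log = NULL, evaluation = NULL),
            class = "cad_mlp")
}
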