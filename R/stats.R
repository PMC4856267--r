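#' Group-wise comparison of CAD parameters
#'
#' Summarizes each of the seven parameters as mean and standard deviation
#' per group and tests for a group difference with a two-sample, two-tailed
#' Student t-test (Welch's unequal-variance form by default; set
#' `var.equal = TRUE` for the pooled-variance form). No multiple-testing
#' correction is applied: each parameter is tested at `alpha` on its own.
#'
#' Degenerate inputs are resolved by convention: if both groups have zero
#' variance, equal means give `p = 1` (`t = 0`) and unequal means give
#' `p = 0` (`t = +/-Inf`), with a message.
#'
#' Images are treated as independent samples; when several images come from
#' the same patient this overstates the effective sample size, which users
#' should keep in mind when reading the p values.
#'
#' @param features data frame with a `label` column and numeric parameter
#'   columns (e.g. from [cad_extract_dir()]), or a numeric matrix with
#'   `labels` given separately.
#' @param labels group labels (exactly 2 groups) when `features` has no
#'   `label` column.
#' @param alpha significance level in (0, 1).
#' @param var.equal logical; pooled-variance t-test instead of Welch.
#' @return object of class `"cad_comparison"`: data frame with one row per
#'   parameter (`mean` and `sd` per group, `t`, `df`, `p_value`,
#'   `significant`), with attributes `alpha`, `groups`, `n`.
#' @examples
#' tab <- data.frame(label = rep(c("a", "b"), each = 4),
#'                   contrast = c(1, 2, 3, 4, 3, 4, 5, 6))
#' compare_groups(tab)
#' @export
compare_groups <- function(features, labels = NULL, alpha = 0.05,
                           var.equal = FALSE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (is.data.frame(features) && "label" %in% names(features)) {
    labels <- features$label
    num <- features[vapply(features, is.numeric, logical(1L))]
  } else {
    if (is.null(labels)) stop("labels are required")
    num <- as.data.frame(features)
    num <- num[vapply(num, is.numeric, logical(1L))]
  }
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two groups are required")
  if (min(table(labels)) < 2L) stop("each group needs at least 2 samples")
  g1 <- levels(labels)[1L]; g2 <- levels(labels)[2L]

  rows <- lapply(names(num), function(nm) {
    x <- num[[nm]][labels == g1]
    y <- num[[nm]][labels == g2]
    m1 <- mean(x); m2 <- mean(y); s1 <- stats::sd(x); s2 <- stats::sd(y)
    if (s1 == 0 && s2 == 0) {
      if (m1 == m2) {
        tt <- list(statistic = 0, parameter = NA_real_, p.value = 1)
      } else {
        message("parameter '", nm, "': zero variance in both groups with ",
                "unequal means; p set to 0 by convention")
        tt <- list(statistic = sign(m1 - m2) * Inf,
                   parameter = NA_real_, p.value = 0)
      }
    } else {
      ht <- stats::t.test(x, y, var.equal = var.equal)
      tt <- list(statistic = unname(ht$statistic),
                 parameter = unname(ht$parameter), p.value = ht$p.value)
    }
    data.frame(parameter = nm, mean_1 = m1, sd_1 = s1, mean_2 = m2, sd_2 = s2,
               t = tt$statistic, df = tt$parameter, p_value = tt$p.value,
               significant = tt$p.value < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0("mean_", g1), paste0("sd_", g1),
                       paste0("mean_", g2), paste0("sd_", g2))
  structure(out, class = c("cad_comparison", "data.frame"),
            alpha = alpha, groups = c(g1, g2),
            n = as.vector(table(labels)))
}

#' @export
print.cad_comparison <- function(x, digits = 4, ...) {
  g <- attr(x, "groups"); n <- attr(x, "n")
  cat(sprintf("group comparison: %s (n = %d) vs %s (n = %d), alpha = %g\n\n",
              g[1L], n[1L], g[2L], n[2L], attr(x, "alpha")))
  df <- as.data.frame(x)
  df$` ` <- ifelse(df$significant, "*", "")
  df$significant <- NULL
  print(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write a Table-1-shaped group report
#'
#' Produces a CSV with one row per parameter: per-group `mean +/- sd`
#' summaries, the t statistic, p value and significance flag.
#'
#' @param comparison a [compare_groups()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "cad_comparison"))
  df <- as.data.frame(comparison)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 12, format = "g"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
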