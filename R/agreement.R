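#' Pearson correlation between two paired series
#'
#' Thin wrapper around [stats::cor.test()] that degrades gracefully: if
#' either series has zero variance the correlation is undefined and `NA` is
#' returned (with a warning) instead of an error.
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite values.
#' @return List with components `r` and `p` (two-sided).
#' @export
pearson_agreement <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in one series; correlation undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Bland-Altman agreement between two measurement methods
#'
#' Differences `d = x - y`; the bias is `mean(d)`, the spread `sd(d)` with
#' the sample (n-1) denominator, and the limits of agreement are the bias
#' plus/minus `loa_mult` standard deviations (1.96 by convention, covering
#' ~95% of differences under normality).
#'
#' @param x,y paired numeric vectors, n >= 2.
#' @param loa_mult multiplier for the limits of agreement.
#' @return Object of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, plus the per-pair `means` and `diffs` for plotting.
#' @examples
#' ba <- bland_altman(c(1, 3, 2, 5), c(0, 1, 2, 3))
#' ba$bias
#' @export
bland_altman <- function(x, y, loa_mult = 1.96) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs for Bland-Altman analysis")
  d <- x - y
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(
    list(bias = bias, sd_diff = sd_diff,
         loa_low = bias - loa_mult * sd_diff,
         loa_high = bias + loa_mult * sd_diff,
         loa_mult = loa_mult, n = length(d),
         means = (x + y) / 2, diffs = d),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 4, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.*f, SD %.*f, LoA [%.*f, %.*f]\n",
              x$n, digits, x$bias, digits, x$sd_diff,
              digits, x$loa_low, digits, x$loa_high))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Mean of each pair on the x axis, difference on the y axis, with the bias
#' and limits of agreement as horizontal lines.
#'
#' @param x a `bland_altman` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "mean of methods",
                 ylab = "difference between methods", ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Inter-subject coefficient of variation, in percent
#'
#' Sample standard deviation divided by the mean, times 100. Quantifies how
#' much a metric varies across subjects for a given method; scale-invariant
#' under positive rescaling. Undefined (`NA`, with a warning) when the mean
#' is zero.
#'
#' @param values numeric vector, n >= 2.
#' @return CV as a percentage.
#' @export
cv_percent <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) {
    warning("mean is zero; coefficient of variation undefined")
    return(NA_real_)
  }
  stats::sd(values) / m * 100
}

#' Pairwise method-agreement analysis
#'
#' Given a subjects x methods table of one metric (e.g. tract volume per
#' subject under each reconstruction technique), computes for every method
#' pair: Pearson r and p, Bland-Altman bias and limits of agreement, and the
#' paired Wilcoxon signed-rank p; per method: mean, SD, median and the
#' inter-subject CV; across all methods: one-way ANOVA with Tukey HSD
#' post-hoc pairwise p values. Both the parametric and the rank-based
#' batteries are always reported; the caller chooses which to cite per
#' metric. Rows with any missing cell are dropped with a warning.
#'
#' A degenerate Wilcoxon comparison (all paired differences zero) has no
#' defined p value and is reported as `NA`.
#'
#' @param values data frame or matrix, one row per subject, one numeric
#'   column per method (>= 2 methods, >= 3 complete subjects).
#' @param loa_mult limits-of-agreement multiplier, see [bland_altman()].
#' @return Object of class `method_agreement` with components `methods`,
#'   `n`, `per_method` (data frame), `pairs` (data frame with one row per
#'   method pair), `anova_p`, and `bland_altman` (named list of
#'   `bland_altman` objects, for plotting).
#' @export
paired_method_comparison <- function(values, loa_mult = 1.96) {
  values <- as.data.frame(values)
  if (ncol(values) < 2L)
    stop("need at least 2 methods (columns)")
  if (!all(vapply(values, is.numeric, logical(1))))
    stop("all method columns must be numeric")
  complete <- stats::complete.cases(values)
  if (any(!complete)) {
    warning(sum(!complete), " subject(s) with missing cells dropped")
    values <- values[complete, , drop = FALSE]
  }
  if (nrow(values) < 3L)
    stop("need at least 3 complete subjects")
  methods <- colnames(values)

  per_method <- data.frame(
    method = methods,
    mean = vapply(values, mean, numeric(1)),
    sd = vapply(values, stats::sd, numeric(1)),
    median = vapply(values, stats::median, numeric(1)),
    cv_percent = vapply(values, function(v) {
      if (mean(v) == 0) NA_real_ else stats::sd(v) / mean(v) * 100
    }, numeric(1)),
    row.names = NULL)

  long <- data.frame(
    value = unlist(values, use.names = FALSE),
    method = factor(rep(methods, each = nrow(values)), levels = methods))
  fit <- stats::aov(value ~ method, data = long)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tukey <- stats::TukeyHSD(fit)$method

  combs <- utils::combn(methods, 2, simplify = FALSE)
  ba_list <- list()
  pairs <- do.call(rbind, lapply(combs, function(pr) {
    x <- values[[pr[1]]]; y <- values[[pr[2]]]
    pe <- suppressWarnings(pearson_agreement(x, y))
    ba <- bland_altman(x, y, loa_mult = loa_mult)
    key <- paste(pr[1], pr[2], sep = " vs ")
    ba_list[[key]] <<- ba
    d <- x - y
    wil_p <- if (all(d == 0)) NA_real_ else
      suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
    # TukeyHSD labels pairs "b-a" in factor-level order
    tk <- c(paste(pr[2], pr[1], sep = "-"), paste(pr[1], pr[2], sep = "-"))
    tukey_p <- tukey[rownames(tukey) %in% tk, "p adj"][1]
    data.frame(method_a = pr[1], method_b = pr[2],
               pearson_r = pe$r, pearson_p = pe$p,
               bias = ba$bias, sd_diff = ba$sd_diff,
               loa_low = ba$loa_low, loa_high = ba$loa_high,
               wilcoxon_p = wil_p, tukey_p = unname(tukey_p),
               median_a = stats::median(x), median_b = stats::median(y),
               stringsAsFactors = FALSE)
  }))

  structure(list(methods = methods, n = nrow(values),
                 per_method = per_method, pairs = pairs,
                 anova_p = anova_p, bland_altman = ba_list,
                 values = values),
            class = "method_agreement")
}

#' @export
print.method_agreement <- function(x, digits = 4, ...) {
  cat(sprintf("Method agreement: %d methods, %d subjects\n",
              length(x$methods), x$n))
  cat(sprintf("One-way ANOVA across methods: p = %.4g\n\n", x$anova_p))
  cat("Per method:\n")
  print(format(x$per_method, digits = digits), row.names = FALSE)
  cat("\nPairwise:\n")
  show <- x$pairs[, c("method_a", "method_b", "pearson_r", "bias",
                      "loa_low", "loa_high", "wilcoxon_p", "tukey_p")]
  print(format(show, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.method_agreement <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' Scatter and Bland-Altman panels for a method comparison
#'
#' One row per method pair: a scatter plot with the least-squares fit and
#' the identity line, and the Bland-Altman plot.
#'
#' @param x a `method_agreement` object.
#' @param ... passed to the underlying plot calls.
#' @export
plot.method_agreement <- function(x, ...) {
  np <- nrow(x$pairs)
  old <- graphics::par(mfrow = c(np, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (i in seq_len(np)) {
    a <- x$pairs$method_a[i]; b <- x$pairs$method_b[i]
    xa <- x$values[[a]]; xb <- x$values[[b]]
    graphics::plot(xa, xb, xlab = a, ylab = b,
                   main = sprintf("%s vs %s (r = %.2f)", a, b,
                                  x$pairs$pearson_r[i]), ...)
    graphics::abline(stats::lm(xb ~ xa), col = "grey40")
    graphics::abline(0, 1, lty = 3)
    plot(x$bland_altman[[paste(a, b, sep = " vs ")]],
         main = "Bland-Altman", ...)
  }
  invisible(x)
}

#' Pairwise Dice agreement between segmentations from several methods
#'
#' For each pair of methods, computes the per-subject Dice similarity
#' coefficient between the two methods' masks and summarises it (mean, SD,
#' min, max) — the overlap counterpart of the scalar-metric battery in
#' [paired_method_comparison()].
#'
#' @param masks_by_method named list; each element is a list of
#'   `binary_mask` objects, one per subject, in the same subject order.
#' @return Data frame with one row per method pair and columns
#'   `method_a`, `method_b`, `mean_dsc`, `sd_dsc`, `min_dsc`, `max_dsc`.
#' @export
pairwise_dice <- function(masks_by_method) {
  if (!is.list(masks_by_method) || length(masks_by_method) < 2L)
    stop("need masks from at least 2 methods")
  if (is.null(names(masks_by_method)) || any(names(masks_by_method) == ""))
    stop("'masks_by_method' must be a named list")
  ns <- lengths(masks_by_method)
  if (length(unique(ns)) != 1L)
    stop("all methods must cover the same subjects")
  combs <- utils::combn(names(masks_by_method), 2, simplify = FALSE)
  do.call(rbind, lapply(combs, function(pr) {
    d <- mapply(dice, masks_by_method[[pr[1]]], masks_by_method[[pr[2]]])
    data.frame(method_a = pr[1], method_b = pr[2],
               mean_dsc = mean(d), sd_dsc = stats::sd(d),
               min_dsc = min(d), max_dsc = max(d),
               stringsAsFactors = FALSE)
  }))
}
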