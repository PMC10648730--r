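# Method-agreement statistics: Dice similarity, two-way mixed-effects
# single-rater ICC (consistency and absolute agreement) with 95% CIs and
# qualitative level labels, Bland-Altman limits of agreement, MAE and MdAPE.

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two binary masks of identical
#' shape. Two empty masks agree perfectly on absence and score 1.
#'
#' @param mask_a,mask_b Binary arrays of the same shape.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("mask shapes differ: ", paste(dim(mask_a), collapse = "x"), " vs ",
         paste(dim(mask_b), collapse = "x"))
  }
  a <- mask_a != 0; b <- mask_b != 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Paired method measurements
#'
#' @param a,b Numeric vectors of the same length (>= 2): per-subject values of
#'   methods/raters A and B, complete cases only.
#' @param subjects Optional subject identifiers.
#' @return A data frame of class `paired_measurements`.
#' @export
paired_measurements <- function(a, b, subjects = seq_along(a)) {
  stopifnot(length(a) == length(b), length(a) >= 2,
            !anyNA(a), !anyNA(b))
  structure(data.frame(subject = subjects, a = a, b = b),
            class = c("paired_measurements", "data.frame"))
}

icc_level <- function(value) {
  if (is.na(value)) return(NA_character_)
  if (value < 0.5) "poor"
  else if (value <= 0.75) "moderate"
  else if (value <= 0.9) "good"
  else "excellent"
}

two_way_mean_squares <- function(a, b) {
  n <- length(a)
  k <- 2
  x <- cbind(a, b)
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  list(msr = ss_rows / (n - 1), msc = ss_cols / (k - 1),
       mse = ss_err / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Intraclass correlation coefficient (two-way model, single rater)
#'
#' Computes the single-rater ICC from the two-way ANOVA mean squares
#' (subjects x 2 raters): the consistency form
#' `(MSR - MSE) / (MSR + (k-1) MSE)` and the absolute-agreement form
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`, with 95% confidence
#' intervals from the standard F-distribution constructions, and a
#' qualitative label: poor < 0.5, moderate 0.5-0.75, good 0.76-0.9,
#' excellent > 0.9.
#'
#' @param pm A [paired_measurements()] (or a 2-column matrix/data frame).
#' @param form `"consistency"` or `"absolute"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `icc_result`: `value`, `ci` (length 2), `form`,
#'   `level`, and the mean squares. Zero between-subject variance yields an
#'   `NA` value flagged `degenerate`.
#' @export
icc <- function(pm, form = c("consistency", "absolute"), conf_level = 0.95) {
  form <- match.arg(form)
  if (is.matrix(pm)) pm <- data.frame(a = pm[, 1], b = pm[, 2])
  ms <- two_way_mean_squares(pm$a, pm$b)
  n <- ms$n; k <- ms$k
  alpha <- 1 - conf_level
  degenerate <- ms$msr <= .Machine$double.eps * max(1, abs(mean(pm$a))) &&
    ms$mse <= .Machine$double.eps * max(1, abs(mean(pm$a)))
  if (degenerate) {
    return(structure(list(value = NA_real_, ci = c(NA_real_, NA_real_),
                          form = form, level = NA_character_,
                          degenerate = TRUE, mean_squares = ms),
                     class = "icc_result"))
  }
  if (form == "consistency") {
    value <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    fobs <- ms$msr / ms$mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- fobs / qf(1 - alpha / 2, df1, df2)
    fu <- fobs * qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    value <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + k / n * (ms$msc - ms$mse))
    # Satterthwaite approximation for the absolute-agreement CI
    aa <- k * value / (n * (1 - value))
    bb <- 1 + k * value * (n - 1) / (n * (1 - value))
    v <- (aa * ms$msc + bb * ms$mse)^2 /
      ((aa * ms$msc)^2 / (k - 1) + (bb * ms$mse)^2 / ((n - 1) * (k - 1)))
    f1 <- qf(1 - alpha / 2, n - 1, v)
    f2 <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (ms$msr - f1 * ms$mse) /
      (f1 * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    hi <- n * (f2 * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * f2 * ms$msr)
    ci <- c(lo, hi)
  }
  structure(list(value = value, ci = ci, form = form,
                 level = icc_level(value), degenerate = FALSE,
                 mean_squares = ms),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("ICC (", x$form, "): undefined (zero between-subject variance)\n",
        sep = "")
  } else {
    cat(sprintf("ICC (%s): %.3f [%.3f, %.3f], %s\n", x$form, x$value,
                x$ci[1], x$ci[2], x$level))
  }
  invisible(x)
}

#' Bland-Altman analysis
#'
#' Differences are taken as `b - a`; limits of agreement are
#' `mean(d) +/- multiplier * sd(d)` with the sample standard deviation
#' (n - 1 denominator) and multiplier 1.96 by default.
#'
#' @param pm A [paired_measurements()].
#' @param multiplier Width of the limits in standard deviations.
#' @return A list of class `bland_altman`: `mean_diff`, `sd_diff`, `lower`,
#'   `upper`, and `data` (per-subject mean and difference, for plotting).
#' @export
bland_altman <- function(pm, multiplier = 1.96) {
  stopifnot(nrow(pm) >= 2)
  d <- pm$b - pm$a
  m <- (pm$a + pm$b) / 2
  md <- mean(d); sdd <- sd(d)
  structure(list(mean_diff = md, sd_diff = sdd,
                 lower = md - multiplier * sdd,
                 upper = md + multiplier * sdd,
                 multiplier = multiplier,
                 data = data.frame(subject = pm$subject, mean = m,
                                   difference = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean difference %.2f, limits [%.2f, %.2f]\n",
              x$mean_diff, x$lower, x$upper))
  invisible(x)
}

#' Error metrics against a reference method
#'
#' MAE is `mean(|b - a|)`; MdAPE is `median(|b - a| / a) * 100` with the
#' reference method `a` as denominator. Subjects with a zero reference value
#' are excluded from MdAPE and counted in `n_excluded_mdape`.
#'
#' @param pm A [paired_measurements()] with the reference as `a`.
#' @return A list with `mae`, `mdape`, `n`, `n_excluded_mdape`.
#' @export
error_metrics <- function(pm) {
  err <- abs(pm$b - pm$a)
  mae <- mean(err)
  ok <- pm$a != 0
  mdape <- if (any(ok)) median(err[ok] / abs(pm$a[ok])) * 100 else NA_real_
  list(mae = mae, mdape = mdape, n = nrow(pm),
       n_excluded_mdape = sum(!ok))
}

#' Full agreement report between two volume-estimation methods
#'
#' Bundles both ICC forms, the Bland-Altman analysis, MAE and MdAPE, and an
#' optional Dice summary, for the comparison of a candidate method `b`
#' against a reference method `a`.
#'
#' @param pm A [paired_measurements()] (reference as `a`).
#' @param dsc Optional numeric vector of per-image Dice scores to summarise.
#' @param conf_level Confidence level for the ICC intervals.
#' @return A list of class `agreement_report`.
#' @export
agreement_report <- function(pm, dsc = NULL, conf_level = 0.95) {
  rep <- list(
    icc_consistency = icc(pm, "consistency", conf_level),
    icc_absolute = icc(pm, "absolute", conf_level),
    bland_altman = bland_altman(pm),
    errors = error_metrics(pm),
    n = nrow(pm))
  if (!is.null(dsc)) {
    rep$dsc_summary <- c(mean = mean(dsc), median = median(dsc),
                         min = min(dsc), max = max(dsc))
  }
  class(rep) <- "agreement_report"
  rep
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Method agreement (n = ", x$n, ")\n", sep = "")
  print(x$icc_consistency)
  print(x$icc_absolute)
  print(x$bland_altman)
  cat(sprintf("MAE: %.2f ml, MdAPE: %.2f%%\n", x$errors$mae, x$errors$mdape))
  if (!is.null(x$dsc_summary)) {
    cat(sprintf("DSC: mean %.3f, median %.3f, range [%.3f, %.3f]\n",
                x$dsc_summary["mean"], x$dsc_summary["median"],
                x$dsc_summary["min"], x$dsc_summary["max"]))
  }
  invisible(x)
}

#' Tidy a fitted agreement report
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return A data frame with one row per statistic (`statistic`, `estimate`,
#'   `conf_low`, `conf_high`, `label`).
#' @export
tidy.agreement_report <- function(x, ...) {
  rows <- list(
    data.frame(statistic = "icc_consistency",
               estimate = x$icc_consistency$value,
               conf_low = x$icc_consistency$ci[1],
               conf_high = x$icc_consistency$ci[2],
               label = x$icc_consistency$level %||% NA_character_),
    data.frame(statistic = "icc_absolute",
               estimate = x$icc_absolute$value,
               conf_low = x$icc_absolute$ci[1],
               conf_high = x$icc_absolute$ci[2],
               label = x$icc_absolute$level %||% NA_character_),
    data.frame(statistic = "bland_altman_mean_diff",
               estimate = x$bland_altman$mean_diff,
               conf_low = x$bland_altman$lower,
               conf_high = x$bland_altman$upper, label = NA_character_),
    data.frame(statistic = "mae", estimate = x$errors$mae,
               conf_low = NA_real_, conf_high = NA_real_,
               label = NA_character_),
    data.frame(statistic = "mdape", estimate = x$errors$mdape,
               conf_low = NA_real_, conf_high = NA_real_,
               label = NA_character_))
  if (!is.null(x$dsc_summary)) {
    rows <- c(rows, list(
      data.frame(statistic = "dsc_mean", estimate = x$dsc_summary[["mean"]],
                 conf_low = x$dsc_summary[["min"]],
                 conf_high = x$dsc_summary[["max"]], label = NA_character_)))
  }
  do.call(rbind, rows)
}

#' Generic for tidying results
#' @param x Object to tidy.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")
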