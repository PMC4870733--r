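# Test-retest reliability analysis: between-session coefficients of
# variation, ICC(2,1) with F-based confidence intervals, paired /
# independent t-tests, Bland-Altman limits of agreement with
# heteroscedasticity classification, and ratio limits of agreement.

#' Between-session coefficient of variation of a measurement pair
#'
#' 100 * SD(x1, x2) / mean(x1, x2), with the sample (n-1) SD of a pair,
#' i.e. |x1 - x2| / sqrt(2). Vectorized over pairs. A pair mean of zero
#' leaves the CV undefined (`NaN`); this genuinely occurs at the
#' zero-displacement level and is reported as-is.
#'
#' @param x1,x2 the two session measurements (mm or deg).
#' @return CV in percent.
#' @export
cv_between_sessions <- function(x1, x2) {
  m <- (x1 + x2) / 2
  s <- abs(x1 - x2) / sqrt(2)
  ifelse(m == 0, NaN, 100 * s / m)
}

#' Two-session measurement data
#'
#' @param level nominal displacement level per trial.
#' @param session1,session2 measurements, equal length.
#' @return data.frame of class `session_pair_data`.
#' @export
session_pair_data <- function(level, session1, session2) {
  if (length(session1) != length(session2) || length(level) != length(session1))
    stop_mrikin("level, session1 and session2 must have equal length",
                "mrikin_data_error")
  if (length(level) == 0)
    stop_mrikin("no trials supplied", "mrikin_data_error")
  structure(data.frame(level = level, session1 = session1, session2 = session2),
            class = c("session_pair_data", "data.frame"))
}

#' Mean between-session CV at one displacement level
#'
#' Arithmetic mean of the per-trial CVs at that level; trials with an
#' undefined CV (pair mean zero) are skipped and counted in the
#' `"n_skipped"` attribute.
#' @param data a `session_pair_data`.
#' @param level the level to summarize.
#' @export
mean_cv <- function(data, level) {
  d <- data[data$level == level, ]
  if (nrow(d) == 0)
    stop_mrikin("no trials at this level", "mrikin_data_error")
  cv <- cv_between_sessions(d$session1, d$session2)
  ok <- is.finite(cv)
  structure(mean(cv[ok]), n_skipped = sum(!ok))
}

#' Intraclass correlation ICC(2,1)
#'
#' Shrout-Fleiss two-way random effects, single measure, absolute agreement:
#' systematic between-session bias counts against agreement (the stated
#' reason for choosing the (2,1) form). Computed from the two-way ANOVA mean
#' squares with the F-distribution confidence interval.
#'
#' @param mat trials x sessions numeric matrix (>= 3 trials).
#' @param conf confidence level.
#' @return object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `model` ("(2,1) two-way random, single measure"), mean squares, and an
#'   `undefined` flag for zero total variance.
#' @export
icc_2_1 <- function(mat, conf = 0.95) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 3) stop_mrikin("at least 3 trials are required", "mrikin_data_error")
  gm <- mean(mat)
  rm_ <- rowMeans(mat); cm <- colMeans(mat)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((mat - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  if (sst < 1e-24)
    return(structure(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          model = "(2,1) two-way random, single measure",
                          msr = msr, msc = msc, mse = mse, n = n, k = k,
                          undefined = TRUE),
                     class = "icc_result"))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf
  fl <- fu <- NA_real_
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  if (is.finite(a) && is.finite(b) && mse > 0) {
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    fl <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    fu <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  } else if (mse == 0) { fl <- fu <- icc }
  structure(list(icc = icc, ci_low = min(fl, fu, icc), ci_high = max(fl, fu, icc),
                 model = "(2,1) two-way random, single measure",
                 msr = msr, msc = msc, mse = mse, n = n, k = k,
                 undefined = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (isTRUE(x$undefined)) cat("ICC(2,1): undefined (zero total variance)\n")
  else cat(sprintf("ICC(2,1) = %.3f (95%% CI %.3f-%.3f), %s\n",
                   x$icc, x$ci_low, x$ci_high, x$model))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences are session1 - session2 (sign retained); limits of agreement
#' are bias +/- 1.96 * SD of the differences. Heteroscedasticity is
#' classified from the R-squared of the OLS regression of |differences| on
#' pair means: R^2 in \[0, 0.1\] is homoscedastic, > 0.1 heteroscedastic.
#'
#' @param data a `session_pair_data` (>= 3 pairs).
#' @return object of class `bland_altman_result`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `r_squared`, `scedasticity`, `means`, `diffs`.
#' @export
bland_altman <- function(data) {
  if (nrow(data) < 3) stop_mrikin("at least 3 pairs are required", "mrikin_data_error")
  d <- data$session1 - data$session2
  m <- (data$session1 + data$session2) / 2
  bias <- mean(d); sdd <- stats::sd(d)
  r2 <- NA_real_
  if (stats::sd(m) > 1e-12 && stats::sd(abs(d)) > 1e-12)
    r2 <- summary(stats::lm(abs(d) ~ m))$r.squared
  sced <- if (is.na(r2)) "degenerate" else if (r2 > 0.1) "hetero" else "homo"
  structure(list(bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 r_squared = r2, scedasticity = sced,
                 means = m, diffs = d),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4f, SDdiff %.4f, 95%% LOA [%.4f, %.4f]\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high))
  cat(sprintf("  |diff| vs mean R^2 = %s -> %sscedastic\n",
              if (is.na(x$r_squared)) "NA" else sprintf("%.3f", x$r_squared),
              if (x$scedasticity == "hetero") "hetero" else "homo"))
  invisible(x)
}

#' Bland-Altman plot
#' @param x a `bland_altman_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman_result <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "pair mean", ylab = "S1 - S2 difference",
                 main = "Bland-Altman", ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high), lty = c(1, 2, 2))
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Ratio limits of agreement
#'
#' ratio LOA = \[(SDdiffs / AVGmeans) * 1.96\] * 100, with SDdiffs the SD of
#' the between-session differences and AVGmeans the average of the per-trial
#' session means; reported with the systematic-bias component (the mean
#' difference, absolute and as a percent of AVGmeans) alongside the random
#' component.
#'
#' @param data a `session_pair_data`.
#' @return list: `ratio_loa` (percent), `bias` (units), `bias_pct`,
#'   `sd_diff`, `avg_means`.
#' @export
ratio_loa <- function(data) {
  d <- data$session1 - data$session2
  m <- (data$session1 + data$session2) / 2
  avg <- mean(m)
  if (avg == 0) stop_mrikin("AVGmeans is zero; ratio LOA undefined",
                            "mrikin_data_error")
  sdd <- stats::sd(d)
  list(ratio_loa = (sdd / avg * 1.96) * 100,
       bias = mean(d), bias_pct = 100 * mean(d) / avg,
       sd_diff = sdd, avg_means = avg)
}

#' Between-session t-test
#'
#' Classical two-tailed t-test: dependent (paired) across sessions, or
#' independent (equal-variance two-sample) for between-sequence comparisons.
#' @param x1,x2 measurement vectors.
#' @param mode "paired" or "independent".
#' @return list `t`, `p`, `df`; `p` is `NA` with a `degenerate` flag when the
#'   difference variance is zero.
#' @export
paired_t <- function(x1, x2, mode = c("paired", "independent")) {
  mode <- match.arg(mode)
  if (length(x1) < 2) stop_mrikin("n >= 2 required", "mrikin_data_error")
  if (mode == "paired") {
    d <- x1 - x2
    if (stats::sd(d) < 1e-15)
      return(list(t = 0, p = NA_real_, df = length(d) - 1, degenerate = TRUE))
    tt <- stats::t.test(x1, x2, paired = TRUE)
  } else {
    if (stats::sd(c(x1, x2)) < 1e-15)
      return(list(t = 0, p = NA_real_, df = length(x1) + length(x2) - 2,
                  degenerate = TRUE))
    tt <- stats::t.test(x1, x2, var.equal = TRUE)
  }
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       degenerate = FALSE)
}

#' Full test-retest reliability report
#'
#' Assembles the complete analysis for a two-session dataset: per-level mean
#' +/- SD per session, per-level mean CV and the overall mean CV (the average
#' of the per-level CVs), ICC(2,1) with CI, the paired t-test, Bland-Altman
#' limits with heteroscedasticity class, and the ratio LOA.
#'
#' Displacement magnitudes are analyzed: measurements are taken in absolute
#' value by default (`abs_values`), matching how signed extractions are
#' reported against unsigned nominal levels.
#'
#' @param data a `session_pair_data`.
#' @param abs_values analyze |measurements|.
#' @param unit unit label for printing ("mm" or "deg").
#' @return object of class `reliability_report`.
#' @export
reliability_report <- function(data, abs_values = TRUE, unit = "mm") {
  if (!inherits(data, "session_pair_data"))
    data <- session_pair_data(data$level, data$session1, data$session2)
  if (abs_values) {
    data$session1 <- abs(data$session1)
    data$session2 <- abs(data$session2)
  }
  levels_ <- sort(unique(data$level))
  per_level <- do.call(rbind, lapply(levels_, function(l) {
    d <- data[data$level == l, ]
    mcv <- mean_cv(data, l)
    data.frame(level = l, n = nrow(d),
               mean_s1 = mean(d$session1), sd_s1 = stats::sd(d$session1),
               mean_s2 = mean(d$session2), sd_s2 = stats::sd(d$session2),
               mean_cv = as.numeric(mcv),
               cv_skipped = attr(mcv, "n_skipped"))
  }))
  structure(list(per_level = per_level,
                 overall_cv = mean(per_level$mean_cv, na.rm = TRUE),
                 icc = icc_2_1(cbind(data$session1, data$session2)),
                 t_test = paired_t(data$session1, data$session2, "paired"),
                 bland_altman = bland_altman(data),
                 ratio_loa = ratio_loa(data),
                 n_trials = nrow(data), unit = unit, data = data),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  u <- x$unit
  cat(sprintf("Between-session reliability (%d trials)\n", x$n_trials))
  cat(sprintf("%-8s %-3s %-16s %-16s %-10s\n", "Level", "n",
              "Mean+/-SD S1", "Mean+/-SD S2", "Mean CV(%)"))
  for (i in seq_len(nrow(x$per_level))) {
    r <- x$per_level[i, ]
    cat(sprintf("%-8s %-3d %6.2f+/-%-6.2f  %6.2f+/-%-6.2f  %8.2f\n",
                paste0(r$level, " ", u), r$n, r$mean_s1, r$sd_s1,
                r$mean_s2, r$sd_s2, r$mean_cv))
  }
  cat(sprintf("Overall mean CV: %.2f %%\n", x$overall_cv))
  print(x$icc)
  cat(sprintf("Paired t: t = %.3f, p = %s\n", x$t_test$t,
              if (is.na(x$t_test$p)) "NA (zero difference variance)"
              else sprintf("%.3f", x$t_test$p)))
  print(x$bland_altman)
  cat(sprintf("Ratio LOA: bias %.3f %s (%.2f %%), random error +/-%.2f %%\n",
              x$ratio_loa$bias, u, x$ratio_loa$bias_pct, x$ratio_loa$ratio_loa))
  invisible(x)
}

#' @export
summary.reliability_report <- function(object, ...) {
  print(object)
  invisible(object$per_level)
}

#' @export
as.data.frame.reliability_report <- function(x, ...) x$per_level

#' @export
plot.reliability_report <- function(x, ...) plot(x$bland_altman, ...)

#' Write a reliability report to CSV
#' @param report a `reliability_report`.
#' @param path output CSV path.
#' @export
reliability_write_csv <- function(report, path) {
  df <- report$per_level
  df$overall_cv <- report$overall_cv
  df$icc <- report$icc$icc
  df$icc_ci_low <- report$icc$ci_low
  df$icc_ci_high <- report$icc$ci_high
  df$ba_bias <- report$bland_altman$bias
  df$ba_loa_low <- report$bland_altman$loa_low
  df$ba_loa_high <- report$bland_altman$loa_high
  df$ba_r_squared <- report$bland_altman$r_squared
  df$scedasticity <- report$bland_altman$scedasticity
  df$ratio_loa <- report$ratio_loa$ratio_loa
  df$t_p <- report$t_test$p
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
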