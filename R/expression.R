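new_ttest <- function(statistic, df, p, mean_diff, pooled_sd, estimate,
                      labels, method) {
  structure(
    list(statistic = statistic, df = df, p_value = p,
         mean_difference = mean_diff, pooled_sd = pooled_sd,
         estimate = estimate, labels = labels, method = method),
    class = "pedscreen_ttest"
  )
}

#' @export
print.pedscreen_ttest <- function(x, ...) {
  cat(sprintf("%s: %s vs %s\n", x$method, x$labels[1], x$labels[2]))
  cat(sprintf("  t = %.3f, df = %.5g, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  mean difference = %.4g (group means %.4g, %.4g)\n",
              x$mean_difference, x$estimate[1], x$estimate[2]))
  invisible(x)
}

#' Tidy a two-sample t-test result
#' @param x A `pedscreen_ttest` object.
#' @param ... Unused.
#' @return One-row tibble with broom's column conventions.
#' @method tidy pedscreen_ttest
#' @export
tidy.pedscreen_ttest <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_difference,
    estimate1 = x$estimate[1], estimate2 = x$estimate[2],
    statistic = x$statistic, p.value = x$p_value, parameter = x$df,
    method = x$method
  )
}

#' @rdname tidy.pedscreen_ttest
#' @method glance pedscreen_ttest
#' @export
glance.pedscreen_ttest <- function(x, ...) tidy(x, ...)

#' Pooled two-sample t-test from summary statistics
#'
#' The equal-variance (pooled) two-sample t-test computed directly from
#' group summary statistics, for comparisons where only published means,
#' standard deviations and sample sizes are available:
#' \deqn{s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}, \quad
#'       t = \frac{\bar x_1 - \bar x_2}{s_p\sqrt{1/n_1 + 1/n_2}}}
#' with a two-sided p-value on \eqn{n_1+n_2-2} degrees of freedom. The
#' sign convention is first group minus second group. A Welch
#' (unequal-variance) variant is available via `welch = TRUE`.
#'
#' @param data Tibble with columns `group`, `mean`, `sd`, `n` and exactly
#'   two rows; the first row is group 1.
#' @param welch Use the Welch unequal-variance statistic instead?
#' @return A `pedscreen_ttest` object (see [tidy.pedscreen_ttest()]).
#' @examples
#' mice <- tibble::tibble(
#'   group = c("control", "treated"),
#'   mean = c(208.47, 236.46), sd = c(9.23, 23.17), n = c(8, 11)
#' )
#' t_test_summary(mice)
#' @export
t_test_summary <- function(data, welch = FALSE) {
  stopifnot(all(c("group", "mean", "sd", "n") %in% names(data)))
  if (nrow(data) != 2L) {
    stop("`data` must contain exactly two groups", call. = FALSE)
  }
  if (any(data$sd <= 0)) stop("group sd must be positive", call. = FALSE)
  if (any(data$n < 2) || sum(data$n) < 4) {
    stop("each group needs n >= 2 (and n1 + n2 >= 4)", call. = FALSE)
  }
  m <- data$mean; s <- data$sd; n <- data$n
  if (welch) {
    se2 <- s[1]^2 / n[1] + s[2]^2 / n[2]
    t <- (m[1] - m[2]) / sqrt(se2)
    df <- se2^2 / ((s[1]^2 / n[1])^2 / (n[1] - 1) +
                     (s[2]^2 / n[2])^2 / (n[2] - 1))
    pooled_sd <- NA_real_
    method <- "Welch two-sample t-test"
  } else {
    df <- n[1] + n[2] - 2
    pooled_sd <- sqrt(((n[1] - 1) * s[1]^2 + (n[2] - 1) * s[2]^2) / df)
    t <- (m[1] - m[2]) / (pooled_sd * sqrt(1 / n[1] + 1 / n[2]))
    method <- "Pooled two-sample t-test"
  }
  p <- 2 * stats::pt(-abs(t), df)
  new_ttest(t, df, p, m[1] - m[2], pooled_sd, estimate = m,
            labels = as.character(data$group), method = method)
}

#' Two-sample t-test from raw values
#'
#' Computes the group sample moments and applies exactly the same pooled
#' (or Welch) statistic as [t_test_summary()], so the two routes agree to
#' machine precision on identical moments. A paired test is available for
#' before/after designs with matched observations in input order.
#'
#' @param data Tibble of raw measurements with a value column and a group
#'   column; the first group level encountered is group 1.
#' @param value,group Column names (strings) of the measurement and group
#'   label; default `"value"` and `"group"`.
#' @param welch Use the Welch statistic?
#' @param paired Paired t-test (groups must have equal n, matched by
#'   order)?
#' @return A `pedscreen_ttest` object.
#' @export
t_test_raw <- function(data, value = "value", group = "group",
                       welch = FALSE, paired = FALSE) {
  stopifnot(all(c(value, group) %in% names(data)))
  g <- as.character(data[[group]])
  lv <- unique(g)
  if (length(lv) != 2L) {
    stop("`data` must contain exactly two groups", call. = FALSE)
  }
  x1 <- data[[value]][g == lv[1]]
  x2 <- data[[value]][g == lv[2]]
  if (paired) {
    if (length(x1) != length(x2)) {
      stop("paired test requires equal group sizes", call. = FALSE)
    }
    d <- x1 - x2
    if (stats::sd(d) == 0) stop("zero variance of differences", call. = FALSE)
    t <- mean(d) / (stats::sd(d) / sqrt(length(d)))
    df <- length(d) - 1
    return(new_ttest(t, df, 2 * stats::pt(-abs(t), df), mean(d),
                     stats::sd(d), estimate = c(mean(x1), mean(x2)),
                     labels = lv, method = "Paired t-test"))
  }
  summ <- tibble::tibble(
    group = lv,
    mean = c(mean(x1), mean(x2)),
    sd = c(stats::sd(x1), stats::sd(x2)),
    n = c(length(x1), length(x2))
  )
  t_test_summary(summ, welch = welch)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample K-S test of the values against a normal distribution with
#' the sample mean and standard deviation, with the uncorrected asymptotic
#' p-value (the convention of common statistical packages when normality
#' is screened before a t-test). Because the parameters are estimated from
#' the data this p-value is conservative; the Lilliefors-corrected version
#' is available via `lilliefors = TRUE`.
#'
#' @param values Numeric vector, at least 4 finite values.
#' @param lilliefors Use the Lilliefors correction (requires the nortest
#'   package)?
#' @return Object of class `pedscreen_ks` with fields `statistic` (D),
#'   `p_value`, `n`, `method`; has a [tidy()] method.
#' @examples
#' ks_normality(rnorm(50))
#' @export
ks_normality <- function(values, lilliefors = FALSE) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) {
    stop("normality check needs at least 4 finite values", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("values have zero variance; normality test undefined",
         call. = FALSE)
  }
  if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE)) {
      stop("the Lilliefors correction requires the nortest package",
           call. = FALSE)
    }
    ht <- nortest::lillie.test(values)
    method <- "Lilliefors-corrected Kolmogorov-Smirnov"
  } else {
    ht <- suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
    method <- "One-sample Kolmogorov-Smirnov (estimated parameters)"
  }
  structure(
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         n = length(values), method = method),
    class = "pedscreen_ks"
  )
}

#' @export
print.pedscreen_ks <- function(x, ...) {
  cat(sprintf("%s: D = %.4f, p = %.4g (n = %d)\n",
              x$method, x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Tidy a normality-check result
#' @param x A `pedscreen_ks` object.
#' @param ... Unused.
#' @method tidy pedscreen_ks
#' @export
tidy.pedscreen_ks <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value, n = x$n,
                 method = x$method)
}

#' Comparative-Ct (2^-ddCt) fold change
#'
#' Relative quantification of qPCR expression by the comparative threshold
#' cycle method: the target-gene Ct is normalized to a reference gene in
#' both the sample and the calibrator condition, and
#' \deqn{\Delta\Delta C_t = (C_{t,\mathrm{target}} -
#'   C_{t,\mathrm{ref}})_{\mathrm{sample}} - (C_{t,\mathrm{target}} -
#'   C_{t,\mathrm{ref}})_{\mathrm{calibrator}}}
#' gives the fold change \eqn{2^{-\Delta\Delta C_t}} (assuming ~100%
#' amplification efficiency). Replicate Ct rows per condition are averaged
#' before differencing.
#'
#' @param data Tibble with columns `condition` (values `"sample"` and
#'   `"calibrator"`), `ct_target`, `ct_reference`; one or more replicate
#'   rows per condition.
#' @return One-row tibble with `delta_ct_sample`, `delta_ct_calibrator`,
#'   `delta_delta_ct`, `fold_change`.
#' @examples
#' ddct_fold_change(tibble::tibble(
#'   condition = c("sample", "calibrator"),
#'   ct_target = c(24, 26), ct_reference = c(18, 19)
#' ))
#' @export
ddct_fold_change <- function(data) {
  stopifnot(all(c("condition", "ct_target", "ct_reference") %in%
                  names(data)))
  if (!all(is.finite(data$ct_target)) || !all(is.finite(data$ct_reference))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  if (any(data$ct_target <= 0) || any(data$ct_reference <= 0)) {
    stop("Ct values must be positive", call. = FALSE)
  }
  if (!all(c("sample", "calibrator") %in% data$condition)) {
    stop('`data` must contain both a "sample" and a "calibrator" condition',
         call. = FALSE)
  }
  dct <- data |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      delta_ct = mean(.data$ct_target) - mean(.data$ct_reference),
      .groups = "drop"
    )
  ds <- dct$delta_ct[dct$condition == "sample"]
  dc <- dct$delta_ct[dct$condition == "calibrator"]
  ddct <- ds - dc
  tibble::tibble(
    delta_ct_sample = ds, delta_ct_calibrator = dc,
    delta_delta_ct = ddct, fold_change = 2^-ddct
  )
}
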