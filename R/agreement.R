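#' Pair two audiogram sets for agreement analysis
#'
#' Matches per (subject, ear, frequency) cell. A pair is kept only when both
#' sides are present and in range; out-of-range and missing cells are
#' discarded (counts reported in the `discarded` attribute). Subjects
#' present on one side only are an error. Differences throughout the
#' package are oriented `value_a - value_b`; with the conventional call
#' `pair_measurements(pta, mobile)` a positive mean difference means the
#' mobile test reads lower (better) than clinical audiometry.
#'
#' @param audiograms_a,audiograms_b Audiogram tibbles.
#' @param label_a,label_b Method names for reporting.
#' @return Tibble of class `paired_measurements` with columns `subject_id`,
#'   `ear`, `frequency`, `value_a`, `value_b`.
#' @export
pair_measurements <- function(audiograms_a, audiograms_b,
                              label_a = "pta", label_b = "mobile") {
  a <- validate_audiograms(audiograms_a)
  b <- validate_audiograms(audiograms_b)
  only_a <- setdiff(unique(a$subject_id), unique(b$subject_id))
  only_b <- setdiff(unique(b$subject_id), unique(a$subject_id))
  if (length(only_a) || length(only_b)) {
    rlang::abort(paste0(
      "subjects present on one side only: ",
      paste(c(only_a, only_b), collapse = ", ")
    ))
  }
  m <- dplyr::inner_join(
    dplyr::select(a, "subject_id", "ear", "frequency",
                  value_a = "threshold", flag_a = "flag"),
    dplyr::select(b, "subject_id", "ear", "frequency",
                  value_b = "threshold", flag_b = "flag"),
    by = c("subject_id", "ear", "frequency")
  )
  usable_a <- m$flag_a == "in_range" & !is.na(m$value_a)
  usable_b <- m$flag_b == "in_range" & !is.na(m$value_b)
  out <- m[usable_a & usable_b,
           c("subject_id", "ear", "frequency", "value_a", "value_b")]
  out <- tibble::as_tibble(out)
  attr(out, "labels") <- c(a = label_a, b = label_b)
  attr(out, "discarded") <- c(
    a = sum(!usable_a), b = sum(!usable_b),
    either = sum(!(usable_a & usable_b))
  )
  class(out) <- c("paired_measurements", class(out))
  out
}

#' Normal-approximation confidence interval for a mean
#'
#' `mean +/- z * sd / sqrt(n)`. The study's printed intervals are
#' reproduced by the z form at these sample sizes; a t-quantile variant is
#' available.
#'
#' @param mean,sd Summary statistics, dB.
#' @param n Number of records (>= 2).
#' @param conf Confidence level. Default 0.95.
#' @param use_t Use the t quantile on `n - 1` df instead of z.
#' @return Named numeric `c(lower, upper)`, unrounded (report rounding
#'   happens at the formatting boundary).
#' @export
#' @examples
#' round(mean_diff_ci(2.6, 8.3, 967), 1)
mean_diff_ci <- function(mean, sd, n, conf = 0.95, use_t = FALSE) {
  if (n < 2) rlang::abort("n must be >= 2")
  q <- if (use_t) stats::qt((1 + conf) / 2, n - 1) else
    stats::qnorm((1 + conf) / 2)
  half <- q * sd / sqrt(n)
  c(lower = mean - half, upper = mean + half)
}

#' Chi-square confidence interval for a standard deviation
#'
#' Exact-normal-theory interval:
#' `sd * sqrt((n-1)/chisq_{(1+conf)/2})` to
#' `sd * sqrt((n-1)/chisq_{(1-conf)/2})` on `n - 1` df.
#'
#' @inheritParams mean_diff_ci
#' @return Named numeric `c(lower, upper)`.
#' @export
#' @examples
#' round(sd_ci_chi2(8.3, 967), 1)
sd_ci_chi2 <- function(sd, n, conf = 0.95) {
  if (n < 2) rlang::abort("n must be >= 2")
  df <- n - 1
  c(lower = sd * sqrt(df / stats::qchisq((1 + conf) / 2, df)),
    upper = sd * sqrt(df / stats::qchisq((1 - conf) / 2, df)))
}

#' Intraclass correlation, two-way random, consistency, single measurement
#'
#' ICC(C,1) for k = 2 paired methods from the two-way model without
#' interaction: `(MS_rows - MS_error) / (MS_rows + (k-1) MS_error)`.
#' Consistency ICC ignores constant shifts between methods. The confidence
#' interval is the F-ratio interval on `(n-1)` and `(n-1)(k-1)` df.
#'
#' @param pairs A `paired_measurements` tibble (n >= 3 pairs).
#' @param conf Confidence level.
#' @return Object of class `icc_fit` with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
icc_consistency <- function(pairs, conf = 0.95) {
  a <- pairs$value_a
  b <- pairs$value_b
  n <- length(a)
  if (n < 3) rlang::abort("need at least 3 pairs")
  k <- 2
  grand <- mean(c(a, b))
  row_means <- (a + b) / 2
  col_means <- c(mean(a), mean(b))
  ss_total <- sum((c(a, b) - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  if (ss_total <= 0) rlang::abort("zero total variance; ICC undefined")
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  icc <- (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
  if (ms_err <= 0) {
    lower <- upper <- 1
    f_obs <- Inf
  } else {
    f_obs <- ms_rows / ms_err
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    fl <- f_obs / stats::qf((1 + conf) / 2, df1, df2)
    fu <- f_obs * stats::qf((1 + conf) / 2, df2, df1)
    lower <- (fl - 1) / (fl + k - 1)
    upper <- (fu - 1) / (fu + k - 1)
  }
  structure(
    list(icc = icc, lower = lower, upper = upper, conf = conf,
         n = n, k = k, ms_rows = ms_rows, ms_error = ms_err,
         f_statistic = f_obs),
    class = "icc_fit"
  )
}

#' Cronbach alpha for two paired measures
#'
#' k = 2 item form `alpha = 2 (1 - (var_a + var_b) / var_{a+b})`. For two
#' items alpha is algebraically `2 ICC_c / (1 + ICC_c)` with the
#' consistency ICC on the same data; the confidence interval maps the ICC
#' F-ratio interval through that monotone identity.
#'
#' @inheritParams icc_consistency
#' @return Object of class `alpha_fit` with tidy/glance methods.
#' @export
cronbach_alpha <- function(pairs, conf = 0.95) {
  a <- pairs$value_a
  b <- pairs$value_b
  if (length(a) < 3) rlang::abort("need at least 3 pairs")
  v_sum <- stats::var(a + b)
  if (v_sum <= 0) rlang::abort("zero variance of sums; alpha undefined")
  alpha <- 2 * (1 - (stats::var(a) + stats::var(b)) / v_sum)
  icc <- icc_consistency(pairs, conf)
  to_alpha <- function(r) 2 * r / (1 + r)
  structure(
    list(alpha = alpha, lower = to_alpha(icc$lower),
         upper = to_alpha(icc$upper), conf = conf, n = icc$n),
    class = "alpha_fit"
  )
}

#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(term = "icc_consistency", estimate = x$icc,
                 conf.low = x$lower, conf.high = x$upper)
}

#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(icc = x$icc, conf.low = x$lower, conf.high = x$upper,
                 n = x$n, k = x$k, ms_rows = x$ms_rows,
                 ms_error = x$ms_error, f_statistic = x$f_statistic)
}

#' @export
tidy.alpha_fit <- function(x, ...) {
  tibble::tibble(term = "cronbach_alpha", estimate = x$alpha,
                 conf.low = x$lower, conf.high = x$upper)
}

#' @export
glance.alpha_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, conf.low = x$lower, conf.high = x$upper,
                 n = x$n)
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("ICC (two-way random, consistency, single): %.3f (%d%% CI %.3f-%.3f), n = %d\n",
              x$icc, round(100 * x$conf), x$lower, x$upper, x$n))
  invisible(x)
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf("Cronbach alpha: %.3f (%d%% CI %.3f-%.3f), n = %d\n",
              x$alpha, round(100 * x$conf), x$lower, x$upper, x$n))
  invisible(x)
}

# summary block for one subset of pairs
agreement_row_stats <- function(d, pairs_subset, conf,
                                cum_limits = c(5, 10, 15, 20, 25, 30)) {
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  mad_ <- mean(abs(d))
  mad_sd <- stats::sd(abs(d))
  m_ci <- mean_diff_ci(m, s, n, conf)
  s_ci <- sd_ci_chi2(s, n, conf)
  mad_ci <- mean_diff_ci(mad_, mad_sd, n, conf)
  icc_fit <- tryCatch(icc_consistency(pairs_subset, conf),
                      error = function(e) NULL)
  cum <- purrr::map_dbl(cum_limits, ~ 100 * mean(abs(d) <= .x))
  names(cum) <- paste0("pct_le_", cum_limits)
  dplyr::bind_cols(
    tibble::tibble(
      n = n, mean_diff = m, mean_lower = m_ci[["lower"]],
      mean_upper = m_ci[["upper"]], sd_diff = s,
      sd_lower = s_ci[["lower"]], sd_upper = s_ci[["upper"]],
      mean_abs_diff = mad_, abs_lower = mad_ci[["lower"]],
      abs_upper = mad_ci[["upper"]],
      icc = if (is.null(icc_fit)) NA_real_ else icc_fit$icc,
      icc_lower = if (is.null(icc_fit)) NA_real_ else icc_fit$lower,
      icc_upper = if (is.null(icc_fit)) NA_real_ else icc_fit$upper
    ),
    tibble::as_tibble(as.list(cum))
  )
}

#' Agreement summary table
#'
#' Per-frequency rows plus a pooled `"Total"` row: n, mean difference
#' (`value_a - value_b`) with CI, SD of differences with chi-square CI,
#' mean absolute difference with CI, consistency ICC with CI, and the
#' cumulative percentage of absolute differences within 5..30 dB. All
#' values unrounded; each ear-frequency record is treated as independent,
#' replicating the study's n accounting. Use [format_agreement()] for
#' report-style rounding.
#'
#' @param pairs A `paired_measurements` tibble.
#' @param per_frequency Include per-frequency rows. Default TRUE.
#' @param conf Confidence level.
#' @return Tibble of class `agreement_summary`.
#' @export
summarize_agreement <- function(pairs, per_frequency = TRUE, conf = 0.95) {
  if (nrow(pairs) == 0) rlang::abort("no paired records")
  d_all <- pairs$value_a - pairs$value_b
  rows <- list()
  if (per_frequency) {
    rows <- purrr::map(hearing_frequencies(), function(f) {
      sub <- pairs[pairs$frequency == f, ]
      if (nrow(sub) == 0) return(NULL)
      dplyr::bind_cols(tibble::tibble(frequency = as.character(f)),
                       agreement_row_stats(sub$value_a - sub$value_b, sub,
                                           conf))
    })
  }
  total <- dplyr::bind_cols(tibble::tibble(frequency = "Total"),
                            agreement_row_stats(d_all, pairs, conf))
  out <- dplyr::bind_rows(c(rows, list(total)))
  class(out) <- c("agreement_summary", class(out))
  attr(out, "labels") <- attr(pairs, "labels")
  out
}

#' Round an agreement summary for reporting
#'
#' Rounds to the precision the study tables print: 0.1 dB for level
#' statistics, 0.01 for ICC, whole percentages.
#'
#' @param summary From [summarize_agreement()].
#' @return Tibble.
#' @export
format_agreement <- function(summary) {
  summary |>
    dplyr::mutate(
      dplyr::across(dplyr::matches("mean|sd_|abs_"), ~ round(.x, 1)),
      dplyr::across(dplyr::starts_with("icc"), ~ round(.x, 2)),
      dplyr::across(dplyr::starts_with("pct_le_"), ~ round(.x))
    )
}

#' Bland-Altman limits of agreement
#'
#' Mean difference with `mean +/- 1.96 SD` limits, per frequency and
#' pooled. [plot_bland_altman()] draws the corresponding panels.
#'
#' @param pairs A `paired_measurements` tibble.
#' @param per_frequency Include per-frequency rows.
#' @return Tibble `frequency`, `n`, `mean_diff`, `loa_lower`, `loa_upper`.
#' @export
bland_altman <- function(pairs, per_frequency = TRUE) {
  one <- function(sub, label) {
    d <- sub$value_a - sub$value_b
    if (length(d) < 2) return(NULL)
    tibble::tibble(
      frequency = label, n = length(d), mean_diff = mean(d),
      loa_lower = mean(d) - 1.96 * stats::sd(d),
      loa_upper = mean(d) + 1.96 * stats::sd(d)
    )
  }
  rows <- if (per_frequency) {
    purrr::map(hearing_frequencies(),
               ~ one(pairs[pairs$frequency == .x, ], as.character(.x)))
  } else {
    list()
  }
  dplyr::bind_rows(c(rows, list(one(pairs, "Total"))))
}

#' Bland-Altman plot
#'
#' Paired differences against pair means with the mean difference
#' (continuous line) and the +/- 1.96 SD limits (dashed), one panel per
#' frequency.
#'
#' @param pairs A `paired_measurements` tibble.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(pairs) {
  labels <- attr(pairs, "labels") %||% c(a = "a", b = "b")
  df <- pairs |>
    dplyr::mutate(avg = (.data$value_a + .data$value_b) / 2,
                  diff = .data$value_a - .data$value_b)
  lims <- bland_altman(pairs, per_frequency = TRUE) |>
    dplyr::filter(.data$frequency != "Total") |>
    dplyr::mutate(frequency = as.integer(.data$frequency))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(data = lims,
                        ggplot2::aes(yintercept = .data$mean_diff)) +
    ggplot2::geom_hline(data = lims,
                        ggplot2::aes(yintercept = .data$loa_lower),
                        linetype = "dashed") +
    ggplot2::geom_hline(data = lims,
                        ggplot2::aes(yintercept = .data$loa_upper),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~frequency) +
    ggplot2::labs(
      x = sprintf("Mean of %s and %s (dB)", labels[["a"]], labels[["b"]]),
      y = sprintf("%s - %s (dB)", labels[["a"]], labels[["b"]])
    )
}

#' Cumulative difference distribution plot
#'
#' Share of absolute paired differences within 5..30 dB, per frequency.
#'
#' @param object An `agreement_summary` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_summary <- function(object, ...) {
  df <- object |>
    tidyr::pivot_longer(dplyr::starts_with("pct_le_"),
                        names_to = "limit", values_to = "pct",
                        names_prefix = "pct_le_") |>
    dplyr::mutate(limit = as.integer(.data$limit))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$limit, y = .data$pct,
                                   colour = .data$frequency)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Absolute difference limit (dB)",
                  y = "Differences within limit (%)",
                  colour = "Frequency (Hz)")
}

#' Examination-order effect on paired differences
#'
#' Compares mean paired differences between the two counterbalanced order
#' groups (clinical test first vs mobile test first): per-group means with
#' normal-approximation CIs and a Welch two-sample comparison. The returned
#' decision says whether the groups may be pooled for the joint analysis.
#'
#' @param diffs_group1,diffs_group2 Numeric difference vectors.
#' @param alpha_level Significance level of the comparison. Default 0.05.
#' @param conf Confidence level for the group CIs.
#' @param labels Group names.
#' @return List of class `order_effect`: `groups` tibble, `p_value`,
#'   `pool` (logical decision).
#' @export
order_effect <- function(diffs_group1, diffs_group2, alpha_level = 0.05,
                         conf = 0.95,
                         labels = c("pta_first", "mobile_first")) {
  stopifnot(length(diffs_group1) > 0, length(diffs_group2) > 0)
  one <- function(d, label) {
    ci <- mean_diff_ci(mean(d), stats::sd(d), length(d), conf)
    tibble::tibble(group = label, n = length(d), mean_diff = mean(d),
                   lower = ci[["lower"]], upper = ci[["upper"]])
  }
  groups <- dplyr::bind_rows(one(diffs_group1, labels[1]),
                             one(diffs_group2, labels[2]))
  p <- stats::t.test(diffs_group1, diffs_group2)$p.value
  structure(
    list(groups = groups, p_value = p, pool = p >= alpha_level,
         alpha_level = alpha_level),
    class = "order_effect"
  )
}

#' @export
print.order_effect <- function(x, ...) {
  cat("Order-of-examination comparison (Welch)\n")
  print(x$groups)
  cat(sprintf("p = %.3f -> %s\n", x$p_value,
              if (x$pool) "no order effect, pool groups"
              else "order effect, keep groups separate"))
  invisible(x)
}
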