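#' Hearing-loss screening criterion
#'
#' Loss is diagnosed for an ear when the threshold exceeds (strictly)
#' 30 dB at one of 500, 1000 or 2000 Hz, or 25 dB at more than one of
#' them (count >= 2), or 50 dB at 4000 Hz. The other grid frequencies play
#' no role in the criterion.
#'
#' @param single_freq_limit dB limit for the single-frequency rule.
#' @param multi_freq_limit dB limit for the more-than-one rule.
#' @param f4k_limit dB limit at 4000 Hz.
#' @param core_freqs Frequencies of the first two rules.
#' @return Named list of class `screening_criterion`.
#' @export
screening_criterion <- function(single_freq_limit = 30,
                                multi_freq_limit = 25,
                                f4k_limit = 50,
                                core_freqs = c(500, 1000, 2000)) {
  stopifnot(single_freq_limit > 0, multi_freq_limit > 0, f4k_limit > 0,
            all(core_freqs %in% hearing_frequencies()))
  structure(
    list(single_freq_limit = single_freq_limit,
         multi_freq_limit = multi_freq_limit,
         f4k_limit = f4k_limit, core_freqs = core_freqs),
    class = "screening_criterion"
  )
}

#' Apply the hearing-loss screening criterion per ear
#'
#' All rules are evaluated independently; every rule that fires is listed.
#' Thresholds at 500, 1000, 2000 and 4000 Hz must be present for each ear
#' (out-of-range cells have no threshold and raise an error unless
#' `oor_as_extreme = TRUE`, which scores `above_max` as `+Inf` and
#' `below_min` as `-Inf` — the censored value certainly exceeds / cannot
#' exceed any limit).
#'
#' @param audiograms Audiogram tibble (any number of subjects/ears).
#' @param criterion [screening_criterion()].
#' @param oor_as_extreme Score out-of-range flags as infinite thresholds
#'   instead of erroring. Default FALSE.
#' @return Tibble `subject_id`, `ear`, `loss` (logical), `fired_rules`
#'   (list of character).
#' @export
classify_hearing_loss <- function(audiograms,
                                  criterion = screening_criterion(),
                                  oor_as_extreme = FALSE) {
  audiograms <- validate_audiograms(audiograms)
  need <- c(criterion$core_freqs, 4000)
  df <- audiograms |> dplyr::filter(.data$frequency %in% need)
  if (oor_as_extreme) {
    df <- df |>
      dplyr::mutate(threshold = dplyr::case_when(
        .data$flag == "above_max" ~ Inf,
        .data$flag == "below_min" ~ -Inf,
        TRUE ~ .data$threshold
      ))
  }
  df |>
    dplyr::group_by(.data$subject_id, .data$ear) |>
    dplyr::group_modify(function(g, key) {
      core <- g$threshold[match(criterion$core_freqs, g$frequency)]
      t4k <- g$threshold[match(4000, g$frequency)]
      if (anyNA(c(core, t4k))) {
        rlang::abort(paste0(
          "missing threshold at a screening frequency for ",
          key$subject_id, "/", key$ear
        ))
      }
      fired <- character()
      if (any(core > criterion$single_freq_limit)) {
        fired <- c(fired, "single_freq_gt_30")
      }
      if (sum(core > criterion$multi_freq_limit) >= 2) {
        fired <- c(fired, "multi_freq_gt_25")
      }
      if (t4k > criterion$f4k_limit) fired <- c(fired, "f4k_gt_50")
      tibble::tibble(loss = length(fired) > 0, fired_rules = list(fired))
    }) |>
    dplyr::ungroup()
}

#' Normal-hearing classification per ear
#'
#' TRUE iff every threshold on the full grid is no higher than 25 dB HL
#' (boundary inclusive). Missing cells are an error.
#'
#' @param audiograms Audiogram tibble.
#' @param limit dB limit, default 25.
#' @return Tibble `subject_id`, `ear`, `normal` (logical).
#' @export
classify_normal <- function(audiograms, limit = 25) {
  audiograms <- validate_audiograms(audiograms)
  audiograms |>
    dplyr::group_by(.data$subject_id, .data$ear) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) != length(hearing_frequencies()) || anyNA(g$threshold)) {
        rlang::abort(paste0(
          "full-grid thresholds required for ", key$subject_id, "/", key$ear
        ))
      }
      tibble::tibble(normal = all(g$threshold <= limit))
    }) |>
    dplyr::ungroup()
}

#' Screening sensitivity and specificity
#'
#' From matched truth/prediction label vectors. Wald confidence intervals
#' (default, clipped to \[0, 100\]%) or Wilson intervals.
#'
#' @param truth,predicted Logical vectors of equal length (TRUE = loss).
#' @param conf Confidence level.
#' @param method `"wald"` or `"wilson"`.
#' @return Tibble with rows `sensitivity`, `specificity`: `estimate`,
#'   `conf.low`, `conf.high` in percent; confusion counts as attribute
#'   `confusion`.
#' @export
sens_spec <- function(truth, predicted, conf = 0.95,
                      method = c("wald", "wilson")) {
  method <- match.arg(method)
  stopifnot(length(truth) == length(predicted),
            is.logical(truth), is.logical(predicted))
  if (!any(truth)) rlang::abort("no positive cases; sensitivity undefined")
  if (!any(!truth)) rlang::abort("no negative cases; specificity undefined")
  tp <- sum(truth & predicted)
  fn <- sum(truth & !predicted)
  tn <- sum(!truth & !predicted)
  fp <- sum(!truth & predicted)
  ci <- function(x, n) {
    p <- x / n
    z <- stats::qnorm((1 + conf) / 2)
    if (method == "wald") {
      half <- z * sqrt(p * (1 - p) / n)
      lims <- c(p - half, p + half)
    } else {
      centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      lims <- c(centre - half, centre + half)
    }
    100 * pmin(pmax(lims, 0), 1)
  }
  se_ci <- ci(tp, tp + fn)
  sp_ci <- ci(tn, tn + fp)
  out <- tibble::tibble(
    metric = c("sensitivity", "specificity"),
    estimate = 100 * c(tp / (tp + fn), tn / (tn + fp)),
    conf.low = c(se_ci[1], sp_ci[1]),
    conf.high = c(se_ci[2], sp_ci[2])
  )
  attr(out, "confusion") <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  out
}

#' Paired sample-size calculation
#'
#' Number of paired units needed to detect a mean paired difference of
#' `effect` dB when the difference SD is `sd`, two-sided, by the normal
#' approximation: `n = ceil(((z_{1-alpha/2} + z_power) sd / effect)^2)`.
#' With sd 8.42 dB, effect 2.0 dB, alpha 0.05 and power 0.8 this gives
#' 140 ears (70 subjects). A t-based iteration is available.
#'
#' @param sd Expected SD of paired differences (> 0), dB.
#' @param effect Smallest mean difference to detect (> 0), dB.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param use_t Iterate with t quantiles on `n - 1` df.
#' @return Integer number of paired units.
#' @export
#' @examples
#' sample_size_paired(8.42, 2.0) # 140
sample_size_paired <- function(sd, effect, alpha = 0.05, power = 0.8,
                               use_t = FALSE) {
  stopifnot(sd > 0, effect > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  n <- ceiling(((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) *
                  sd / effect)^2)
  if (use_t) {
    repeat {
      n_new <- ceiling(((stats::qt(1 - alpha / 2, n - 1) +
                           stats::qt(power, n - 1)) * sd / effect)^2)
      if (n_new == n) break
      n <- n_new
    }
  }
  as.integer(n)
}

#' Simulated screening experiment
#'
#' For each cohort subject, runs a clinical reference exam and a mobile
#' self-test (on a fresh instance of a randomly assigned calibrated model),
#' applies the screening criterion to both per ear, and computes
#' sensitivity and specificity of the mobile screen against the clinical
#' truth. Out-of-range cells are scored as infinite censored thresholds.
#'
#' @param cohort Listener tibble.
#' @param models Device model tibble.
#' @param references Reference tibble covering all models (valid).
#' @param config [procedure_config()].
#' @param criterion [screening_criterion()].
#' @param conf Confidence level.
#' @return List: `metrics` ([sens_spec()] tibble), `per_ear` tibble with
#'   truth/prediction labels.
#' @export
screening_experiment <- function(cohort, models, references,
                                 config = procedure_config(),
                                 criterion = screening_criterion(),
                                 conf = 0.95) {
  res <- purrr::map(seq_len(nrow(cohort)), function(i) {
    listener <- cohort[i, ]
    model <- models[sample.int(nrow(models), 1), ]
    inst <- generate_device_instance(model)
    ref <- references[references$model_id == model$model_id, ]
    pta <- run_full_exam(listener, "pta", config = config)
    mob <- run_full_exam(listener, "mobile", device_instance = inst,
                         reference = ref, config = config)
    truth <- classify_hearing_loss(pta, criterion, oor_as_extreme = TRUE)
    pred <- classify_hearing_loss(mob, criterion, oor_as_extreme = TRUE)
    dplyr::inner_join(
      dplyr::select(truth, "subject_id", "ear", truth = "loss"),
      dplyr::select(pred, "subject_id", "ear", predicted = "loss"),
      by = c("subject_id", "ear")
    )
  }) |>
    dplyr::bind_rows()
  list(
    metrics = sens_spec(res$truth, res$predicted, conf),
    per_ear = res
  )
}
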