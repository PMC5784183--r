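#' Study configuration
#'
#' Everything that defines one simulated validation study: cohort, crowd,
#' device fleet, procedure parameters, screening criterion and analysis
#' options. A configuration plus a seed uniquely determines the report.
#'
#' @param n_subjects Cohort size. Default 70.
#' @param class_mix Cohort composition (36/21/13 of 70 by default).
#' @param n_models Device models in circulation. Default 8.
#' @param records_per_model Crowd calibration sessions (= distinct devices)
#'   per model. Default 30.
#' @param crowd_size Calibration crowd size. Default 240.
#' @param contamination_rate Impaired fraction of the crowd. Default 0.26.
#' @param device_offset_sd,device_instance_sd,device_min,device_max Device
#'   fleet parameters (dB / dB mHL).
#' @param min_devices Calibration validity threshold. Default 15.
#' @param listener [listener_params()].
#' @param procedure [procedure_config()].
#' @param criterion [screening_criterion()].
#' @param medians [literature_medians()].
#' @param conf Confidence level for all intervals.
#' @return Named list of class `study_config`.
#' @export
study_config <- function(n_subjects = 70,
                         class_mix = c(normal = 36 / 70,
                                       sensorineural = 21 / 70,
                                       conductive_mixed = 13 / 70),
                         n_models = 8, records_per_model = 30,
                         crowd_size = 240, contamination_rate = 0.26,
                         device_offset_sd = 5, device_instance_sd = 2,
                         device_min = -10, device_max = 80,
                         min_devices = 15,
                         listener = listener_params(),
                         procedure = procedure_config(),
                         criterion = screening_criterion(),
                         medians = literature_medians(),
                         conf = 0.95) {
  structure(
    list(n_subjects = n_subjects, class_mix = class_mix,
         n_models = n_models, records_per_model = records_per_model,
         crowd_size = crowd_size, contamination_rate = contamination_rate,
         device_offset_sd = device_offset_sd,
         device_instance_sd = device_instance_sd,
         device_min = device_min, device_max = device_max,
         min_devices = min_devices, listener = listener,
         procedure = procedure, criterion = criterion, medians = medians,
         conf = conf),
    class = "study_config"
  )
}

# one global seed expanded into independent per-stage seeds, so a change in
# one stage's draw count does not perturb the others
stage_seed <- function(seed, stage) {
  idx <- match(stage, c("devices", "crowd", "calibration", "cohort",
                        "assignment", "exams"))
  stopifnot(!is.na(idx))
  as.integer((as.numeric(seed) * 48271 + idx * 2654435) %% 2147483647)
}

#' Run the full simulated validation study
#'
#' End-to-end pipeline: generate the device fleet, the calibration crowd
#' and its Bekesy sessions; compute per-model reference levels (failing
#' loudly when any model lacks the required distinct devices); generate
#' the patient cohort; assign devices and a counterbalanced examination
#' order (half clinical-first, half mobile-first); run the clinical exam
#' once and the mobile test twice (test and retest, each with a freshly
#' drawn session offset); compute the order-effect comparison, the
#' clinical-vs-mobile and test-retest agreement tables, Cronbach alpha and
#' the screening metrics. Deterministic given `(config, seed)`.
#'
#' @param config [study_config()].
#' @param seed Integer seed.
#' @return List of class `study_report`.
#' @export
run_study <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "study_config"))

  set.seed(stage_seed(seed, "devices"))
  models <- generate_device_models(
    config$n_models, offset_sd = config$device_offset_sd,
    instance_sd = config$device_instance_sd,
    min_level = config$device_min, max_level = config$device_max
  )

  set.seed(stage_seed(seed, "crowd"))
  crowd <- generate_crowd(config$crowd_size, config$contamination_rate,
                          config$listener)

  set.seed(stage_seed(seed, "calibration"))
  records <- purrr::map(seq_len(nrow(models)), function(i) {
    simulate_calibration_records(models[i, ], crowd,
                                 config$records_per_model,
                                 config$procedure)
  }) |>
    dplyr::bind_rows()
  references <- records |>
    dplyr::group_split(.data$model_id) |>
    purrr::map(~ compute_reference(.x, config$medians,
                                   config$min_devices)) |>
    dplyr::bind_rows()
  bad <- references |>
    dplyr::filter(!.data$valid) |>
    dplyr::distinct(.data$model_id, .data$n_devices)
  if (nrow(bad) > 0) {
    rlang::abort(paste0(
      "model(s) without valid calibration: ",
      paste(sprintf("%s (%d of %d devices)", bad$model_id, bad$n_devices,
                    config$min_devices), collapse = ", ")
    ))
  }

  set.seed(stage_seed(seed, "cohort"))
  cohort <- generate_cohort(config$n_subjects, config$class_mix,
                            config$listener)

  set.seed(stage_seed(seed, "assignment"))
  n <- config$n_subjects
  order_lab <- sample(rep(c("pta_first", "mobile_first"), length.out = n))
  model_idx <- sample.int(nrow(models), n, replace = TRUE)

  set.seed(stage_seed(seed, "exams"))
  exams <- purrr::map(seq_len(n), function(i) {
    listener <- cohort[i, ]
    model <- models[model_idx[i], ]
    inst <- generate_device_instance(
      model, instance_id = sprintf("%s_subj%03d", model$model_id, i))
    ref <- references[references$model_id == model$model_id, ]
    # in-silico both orders are exchangeable; the label feeds the
    # order-effect table exactly as in a counterbalanced crossover
    pta <- run_full_exam(listener, "pta", config = config$procedure)
    test <- run_full_exam(listener, "mobile", device_instance = inst,
                          reference = ref, config = config$procedure)
    retest <- run_full_exam(listener, "mobile", device_instance = inst,
                            reference = ref, config = config$procedure)
    list(pta = pta, test = test, retest = retest)
  })
  pta <- dplyr::bind_rows(purrr::map(exams, "pta"))
  test <- dplyr::bind_rows(purrr::map(exams, "test"))
  retest <- dplyr::bind_rows(purrr::map(exams, "retest"))

  pairs_tm <- pair_measurements(pta, test, "pta", "mobile")
  pairs_rr <- pair_measurements(test, retest, "test", "retest")

  order_map <- tibble::tibble(subject_id = cohort$subject_id,
                              order = order_lab)
  d_tm <- pairs_tm |>
    dplyr::left_join(order_map, by = "subject_id") |>
    dplyr::mutate(diff = .data$value_a - .data$value_b)
  order_cmp <- order_effect(
    d_tm$diff[d_tm$order == "pta_first"],
    d_tm$diff[d_tm$order == "mobile_first"],
    conf = config$conf
  )

  agreement <- summarize_agreement(pairs_tm, conf = config$conf)
  retest_agreement <- summarize_agreement(pairs_rr, conf = config$conf)
  alpha_tm <- cronbach_alpha(pairs_tm, config$conf)
  alpha_rr <- cronbach_alpha(pairs_rr, config$conf)

  truth <- classify_hearing_loss(pta, config$criterion,
                                 oor_as_extreme = TRUE)
  pred <- classify_hearing_loss(test, config$criterion,
                                oor_as_extreme = TRUE)
  screen_tbl <- dplyr::inner_join(
    dplyr::select(truth, "subject_id", "ear", truth = "loss"),
    dplyr::select(pred, "subject_id", "ear", predicted = "loss"),
    by = c("subject_id", "ear")
  )
  screening <- sens_spec(screen_tbl$truth, screen_tbl$predicted,
                         config$conf)

  n_cells <- n * 2L * length(hearing_frequencies())
  discards <- tibble::tibble(
    set = c("test", "retest", "pta"),
    discarded = c(sum(test$flag != "in_range" | is.na(test$threshold)),
                  sum(retest$flag != "in_range" | is.na(retest$threshold)),
                  sum(pta$flag != "in_range" | is.na(pta$threshold))),
    of = n_cells
  )

  structure(
    list(
      seed = seed, config = config,
      references = references,
      cohort_classes = table(cohort$hearing_class),
      order = order_cmp,
      order_split = table(order_lab),
      agreement = agreement,
      retest_agreement = retest_agreement,
      alpha = alpha_tm, retest_alpha = alpha_rr,
      screening = screening,
      screening_table = screen_tbl,
      discards = discards,
      n_cells = n_cells,
      audiograms = list(pta = pta, test = test, retest = retest),
      pairs = list(pta_mobile = pairs_tm, test_retest = pairs_rr)
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  tot <- x$agreement[x$agreement$frequency == "Total", ]
  rr <- x$retest_agreement[x$retest_agreement$frequency == "Total", ]
  cat("Simulated mobile-audiometry validation study\n")
  cat(sprintf("  subjects: %d (seed %s), cells before discards: %d\n",
              x$config$n_subjects, format(x$seed), x$n_cells))
  cat(sprintf("  order split: %s\n",
              paste(names(x$order_split), x$order_split,
                    sep = "=", collapse = ", ")))
  cat(sprintf("  clinical vs mobile (n=%d): mean diff %.1f dB (%.1f-%.1f), SD %.1f dB (%.1f-%.1f)\n",
              tot$n, tot$mean_diff, tot$mean_lower, tot$mean_upper,
              tot$sd_diff, tot$sd_lower, tot$sd_upper))
  cat(sprintf("    ICC %.2f (%.2f-%.2f), Cronbach alpha %.2f (%.2f-%.2f), |d|<=10 dB: %.0f%%\n",
              tot$icc, tot$icc_lower, tot$icc_upper, x$alpha$alpha,
              x$alpha$lower, x$alpha$upper, tot$pct_le_10))
  cat(sprintf("  test-retest (n=%d): mean diff %.1f dB, SD %.1f dB (%.1f-%.1f), |d|<=10 dB: %.0f%%\n",
              rr$n, rr$mean_diff, rr$sd_diff, rr$sd_lower, rr$sd_upper,
              rr$pct_le_10))
  s <- x$screening
  cat(sprintf("  screening: sensitivity %.0f%% (%.0f-%.1f), specificity %.0f%% (%.0f-%.1f)\n",
              s$estimate[1], s$conf.low[1], s$conf.high[1],
              s$estimate[2], s$conf.low[2], s$conf.high[2]))
  cat(sprintf("  discards: %s\n",
              paste(sprintf("%d of %d (%s)", x$discards$discarded,
                            x$discards$of, x$discards$set),
                    collapse = ", ")))
  invisible(x)
}

#' One-row study headline summary
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return Tibble with the headline agreement, reliability and screening
#'   numbers.
#' @export
glance.study_report <- function(x, ...) {
  tot <- x$agreement[x$agreement$frequency == "Total", ]
  rr <- x$retest_agreement[x$retest_agreement$frequency == "Total", ]
  tibble::tibble(
    n_subjects = x$config$n_subjects,
    n_cells = x$n_cells,
    n_pairs = tot$n,
    mean_diff = tot$mean_diff,
    sd_diff = tot$sd_diff,
    mean_abs_diff = tot$mean_abs_diff,
    pct_within_10 = tot$pct_le_10,
    icc = tot$icc,
    alpha = x$alpha$alpha,
    retest_n_pairs = rr$n,
    retest_mean_diff = rr$mean_diff,
    retest_sd_diff = rr$sd_diff,
    sensitivity = x$screening$estimate[1],
    specificity = x$screening$estimate[2]
  )
}

#' Report-scale study tables
#'
#' The formatted (report-rounded) agreement and screening tables of a
#' study report, mirroring the validation-study table layouts.
#'
#' @param report A `study_report`.
#' @return Named list of tibbles: `order`, `agreement`,
#'   `cumulative`, `retest`, `retest_cumulative`, `screening`, `discards`.
#' @export
study_tables <- function(report) {
  stopifnot(inherits(report, "study_report"))
  fmt <- format_agreement(report$agreement)
  fmt_rr <- format_agreement(report$retest_agreement)
  list(
    order = report$order$groups |>
      dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ round(.x, 1))),
    agreement = dplyr::select(fmt, "frequency", "n",
                              dplyr::matches("mean|sd_|abs_|icc")),
    cumulative = dplyr::select(fmt, "frequency", "n",
                               dplyr::starts_with("pct_le_")),
    retest = dplyr::select(fmt_rr, "frequency", "n",
                           dplyr::matches("mean|sd_|abs_|icc")),
    retest_cumulative = dplyr::select(fmt_rr, "frequency", "n",
                                      dplyr::starts_with("pct_le_")),
    screening = report$screening |>
      dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ round(.x, 1))),
    discards = report$discards
  )
}

#' Export a study report to files
#'
#' Writes the formatted tables as CSV and the headline summary as JSON.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_study_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- study_tables(report)
  purrr::iwalk(tabs, function(tab, name) {
    readr::write_csv(tab, file.path(dir, paste0(name, ".csv")))
  })
  jsonlite::write_json(as.list(glance(report)),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
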