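#' Literature medians of normal hearing thresholds (ages 18-35)
#'
#' The crowd reference estimate is lowered by the median hearing threshold
#' of normal-hearing 18-35 year olds taken from literature, so that 0 dB mHL
#' corresponds to the normal-hearing threshold rather than to the crowd's
#' raw central tendency. The default (5 dB at every frequency) equals the
#' median of this package's own normal-hearing archetype, which keeps the
#' simulated mHL scale aligned with the simulated dB HL scale; supply real
#' literature values when modelling a specific population.
#'
#' @param value Numeric length 1 or 7, dB.
#' @return Tibble `frequency`, `median_db` over the full grid.
#' @export
literature_medians <- function(value = 5) {
  grid <- hearing_frequencies()
  if (length(value) == 1) value <- rep(value, length(grid))
  stopifnot(length(value) == length(grid))
  tibble::tibble(frequency = grid, median_db = value)
}

#' Robust central-tendency estimator for contaminated crowds
#'
#' The 37th percentile (linear interpolation between order statistics,
#' `stats::quantile` type 7). Its design logic: if 26% of self-declared
#' normal-hearing calibrators actually have elevated thresholds, the 37th
#' percentile of the mixture equals the median of the clean 74%
#' (0.37 = 0.5 x 0.74), so the estimator recovers the clean-population
#' median without identifying the contaminated records.
#'
#' @param values Non-empty numeric vector (dB).
#' @return The 37th percentile, dB.
#' @export
#' @examples
#' percentile_37(0:100) # 37
percentile_37 <- function(values) {
  if (length(values) == 0 || all(is.na(values))) {
    rlang::abort("percentile_37 requires a non-empty vector")
  }
  stats::quantile(values, 0.37, type = 7, names = FALSE, na.rm = TRUE)
}

#' Build a calibration record table
#'
#' One record is one Bekesy self-measurement session on one device instance:
#' raw thresholds on the device command scale for every grid frequency,
#' with the crowd user's age and a timestamp. Long format, one row per
#' frequency.
#'
#' @param model_id,device_id,user_age,timestamp Scalars for the session.
#' @param raw_db Numeric length 7 (per grid frequency), device scale; `NA`
#'   where the track was invalid.
#' @return Tibble of 7 rows.
#' @export
calibration_record <- function(model_id, device_id, user_age, timestamp,
                               raw_db) {
  grid <- hearing_frequencies()
  stopifnot(length(raw_db) == length(grid))
  tibble::tibble(
    model_id = as.character(model_id),
    device_id = as.character(device_id),
    user_age = user_age,
    timestamp = as.numeric(timestamp),
    frequency = grid,
    raw_db = as.numeric(raw_db)
  )
}

#' Crowd-sourced reference level for one device model
#'
#' Defines 0 dB mHL for a model: per frequency, the 37th percentile of the
#' crowd's raw self-measured thresholds, decreased by the literature median
#' for the 18-35 population. Records from users outside the closed age
#' interval are excluded; by default only each distinct device's most
#' recent session enters the percentile (honouring the requirement that
#' measurements come from various devices). The reference is flagged valid
#' only when at least `min_devices` distinct devices contribute; an invalid
#' reference is still computed but unusable for testing.
#'
#' @param records Calibration record tibble (one model only).
#' @param medians [literature_medians()].
#' @param min_devices Distinct-device validity threshold. Default 15.
#' @param age_range Closed eligibility interval in years.
#' @param per_device `"latest"` (default: most recent session per device) or
#'   `"all"` (every session enters).
#' @return Tibble per frequency: `model_id`, `frequency`, `reference`,
#'   `n_records`, `n_devices`, `valid`.
#' @export
compute_reference <- function(records, medians = literature_medians(),
                              min_devices = 15,
                              age_range = c(18, 35),
                              per_device = c("latest", "all")) {
  per_device <- match.arg(per_device)
  if (dplyr::n_distinct(records$model_id) > 1) {
    rlang::abort("records mix several model_ids; calibrate one model at a time")
  }
  model_id <- records$model_id[1]
  eligible <- records |>
    dplyr::filter(.data$user_age >= age_range[1],
                  .data$user_age <= age_range[2],
                  !is.na(.data$raw_db))
  if (per_device == "latest") {
    eligible <- eligible |>
      dplyr::group_by(.data$device_id, .data$frequency) |>
      dplyr::slice_max(.data$timestamp, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  n_devices <- dplyr::n_distinct(eligible$device_id)
  out <- medians |>
    dplyr::rowwise() |>
    dplyr::mutate(
      model_id = model_id,
      reference = {
        v <- eligible$raw_db[eligible$frequency == .data$frequency]
        if (length(v) == 0) NA_real_ else percentile_37(v) - .data$median_db
      },
      n_records = sum(eligible$frequency == .data$frequency)
    ) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      model_id = .data$model_id, frequency = .data$frequency,
      reference = .data$reference, n_records = .data$n_records,
      n_devices = n_devices,
      valid = n_devices >= min_devices
    )
  out
}

#' Create an empty calibration registry
#'
#' The registry accumulates calibration records across models and keeps the
#' per-model reference levels up to date: after each inserted measurement
#' the affected model's reference is recomputed automatically.
#'
#' @param medians,min_devices,age_range,per_device Passed to
#'   [compute_reference()].
#' @return Object of class `calibration_registry`.
#' @export
calibration_registry <- function(medians = literature_medians(),
                                 min_devices = 15, age_range = c(18, 35),
                                 per_device = "latest") {
  structure(
    list(
      records = tibble::tibble(
        model_id = character(), device_id = character(),
        user_age = numeric(), timestamp = numeric(),
        frequency = integer(), raw_db = numeric()
      ),
      references = NULL,
      medians = medians, min_devices = min_devices,
      age_range = age_range, per_device = per_device
    ),
    class = "calibration_registry"
  )
}

#' Insert calibration records into a registry
#'
#' Recomputes the reference of every model touched by the new records;
#' other models are untouched. Duplicate sessions (same device instance and
#' timestamp) are ignored, so insertion is idempotent, and streaming
#' insertion in any order equals one batch [compute_reference()].
#'
#' @param registry From [calibration_registry()].
#' @param new_records Calibration record tibble (any mix of models).
#' @return The updated registry.
#' @export
update_registry <- function(registry, new_records) {
  stopifnot(inherits(registry, "calibration_registry"))
  combined <- dplyr::bind_rows(registry$records, new_records) |>
    dplyr::distinct(.data$device_id, .data$timestamp, .data$frequency,
                    .keep_all = TRUE)
  registry$records <- combined
  touched <- unique(new_records$model_id)
  refs <- purrr::map(touched, function(m) {
    compute_reference(
      dplyr::filter(combined, .data$model_id == m),
      medians = registry$medians, min_devices = registry$min_devices,
      age_range = registry$age_range, per_device = registry$per_device
    )
  }) |>
    dplyr::bind_rows()
  old <- registry$references
  if (!is.null(old)) {
    refs <- dplyr::bind_rows(
      dplyr::filter(old, !.data$model_id %in% touched), refs
    )
  }
  registry$references <- dplyr::arrange(refs, .data$model_id,
                                        .data$frequency)
  registry
}

#' @export
print.calibration_registry <- function(x, ...) {
  n_rec <- dplyr::n_distinct(x$records$device_id, x$records$timestamp)
  cat("<calibration_registry>\n")
  cat("  sessions:", n_rec, "\n")
  if (!is.null(x$references)) {
    s <- x$references |>
      dplyr::distinct(.data$model_id, .data$n_devices, .data$valid)
    cat("  models:\n")
    for (i in seq_len(nrow(s))) {
      cat(sprintf("    %s: %d devices, %s\n", s$model_id[i], s$n_devices[i],
                  if (s$valid[i]) "valid" else "not yet valid"))
    }
  }
  invisible(x)
}

#' Simulate crowd calibration sessions for a model
#'
#' Draws `n_records` sessions, each on a fresh device instance of the model
#' with a crowd user sampled from `crowd` (distinct users while the crowd
#' lasts, re-used with replacement otherwise), running the Bekesy track at
#' every grid frequency on the left ear.
#'
#' @param model One-row model tibble.
#' @param crowd Listener tibble from [generate_crowd()].
#' @param n_records Number of sessions (= distinct devices).
#' @param config [procedure_config()].
#' @return Calibration record tibble.
#' @export
simulate_calibration_records <- function(model, crowd, n_records,
                                         config = procedure_config()) {
  grid <- hearing_frequencies()
  # one user per session when the crowd allows; fall back to re-use
  user_idx <- sample.int(nrow(crowd), n_records,
                         replace = nrow(crowd) < n_records)
  purrr::map(seq_len(n_records), function(i) {
    inst <- generate_device_instance(
      model, instance_id = sprintf("%s_d%05d", model$model_id, i))
    user <- crowd[user_idx[i], ]
    session_offset <- stats::rnorm(1, 0, user$session_sd)
    raw <- purrr::map_dbl(grid, function(f) {
      tr <- bekesy_track(user, "left", f, inst, config, session_offset)
      if (tr$valid) tr$raw else NA_real_
    })
    calibration_record(model$model_id, inst$instance_id, user$age,
                       timestamp = i, raw_db = raw)
  }) |>
    dplyr::bind_rows()
}

#' Reference-estimator recovery experiment
#'
#' Validation harness for the crowd calibration estimator: simulates
#' calibration sessions on instances of a known model, computes the
#' reference, and returns the per-frequency estimation error
#' \deqn{reference - true\_offset - (clean\ median - literature\ median).}
#' Under the design contamination rate the error is pure sampling noise; on
#' a clean crowd the 37th percentile sits below the clean median by about
#' 0.33 of the clean threshold spread (documented bias), and at high
#' contamination the estimator breaks down.
#'
#' @param model One-row model tibble.
#' @param crowd Listener tibble.
#' @param n_records Sessions to simulate.
#' @param medians [literature_medians()].
#' @param clean_median Median of the clean (truly normal) crowd threshold
#'   distribution, dB; default 5, the normal-archetype median.
#' @param config [procedure_config()].
#' @return Tibble `frequency`, `error` (dB).
#' @export
recover_offset_experiment <- function(model, crowd, n_records,
                                      medians = literature_medians(),
                                      clean_median = 5,
                                      config = procedure_config()) {
  records <- simulate_calibration_records(model, crowd, n_records, config)
  ref <- compute_reference(records, medians, min_devices = 15)
  truth <- model$true_offset[[1]]
  ref |>
    dplyr::left_join(truth, by = "frequency") |>
    dplyr::left_join(medians, by = "frequency") |>
    dplyr::transmute(
      frequency = .data$frequency,
      error = .data$reference - .data$offset_db -
        (clean_median - .data$median_db)
    )
}
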