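#' Define a mobile device model
#'
#' A device *model* (handset type) has a per-frequency deviation of its
#' acoustic output from nominal (`true_offset`, the quantity biological
#' calibration must recover: the raw threshold a listener self-measures on
#' the device's command scale is shifted by `+true_offset`). Individual
#' device *instances* of the model scatter around it with SD `instance_sd`.
#' `min_level`/`max_level` bound the playable range (dB mHL).
#'
#' @param model_id Identifier.
#' @param true_offset Numeric length 1 or 7 (per grid frequency), dB.
#' @param instance_sd Device-to-device spread within the model, dB (>= 0).
#' @param min_level,max_level Dynamic range in dB mHL (`min < max`).
#' @return One-row tibble with a `true_offset` list-column (frequency,
#'   offset_db).
#' @export
device_model <- function(model_id, true_offset = 0, instance_sd = 2,
                         min_level = -10, max_level = 80) {
  stopifnot(min_level < max_level, instance_sd >= 0)
  grid <- hearing_frequencies()
  if (length(true_offset) == 1) true_offset <- rep(true_offset, length(grid))
  stopifnot(length(true_offset) == length(grid))
  tibble::tibble(
    model_id = as.character(model_id),
    instance_sd = instance_sd,
    min_level = min_level,
    max_level = max_level,
    true_offset = list(tibble::tibble(frequency = grid,
                                      offset_db = true_offset))
  )
}

#' Generate a set of device models
#'
#' Model output offsets are drawn N(0, `offset_sd`^2) per frequency,
#' reflecting the significant between-model differences in sound-system
#' frequency response that motivate per-model calibration.
#'
#' @param n_models Number of models.
#' @param offset_sd SD of per-frequency model offsets, dB. Default 5.
#' @inheritParams device_model
#' @return Tibble of models, one row each.
#' @export
generate_device_models <- function(n_models, offset_sd = 5, instance_sd = 2,
                                   min_level = -10, max_level = 80) {
  purrr::map(seq_len(n_models), function(i) {
    device_model(
      sprintf("model_%02d", i),
      true_offset = stats::rnorm(length(hearing_frequencies()), 0, offset_sd),
      instance_sd = instance_sd,
      min_level = min_level, max_level = max_level
    )
  }) |>
    dplyr::bind_rows()
}

#' Generate a device instance of a model
#'
#' The instance offset is the model's true offset plus independent
#' N(0, `instance_sd`^2) noise per frequency.
#'
#' @param model One-row model tibble from [device_model()].
#' @param instance_id Identifier; default auto-generated.
#' @return One-row tibble with an `offset` list-column (frequency,
#'   offset_db).
#' @export
generate_device_instance <- function(model, instance_id = NULL) {
  stopifnot(nrow(model) == 1)
  if (is.null(instance_id)) {
    instance_id <- sprintf("%s_d%05d", model$model_id, sample.int(99999L, 1))
  }
  off <- model$true_offset[[1]]
  tibble::tibble(
    model_id = model$model_id,
    instance_id = as.character(instance_id),
    min_level = model$min_level,
    max_level = model$max_level,
    offset = list(tibble::tibble(
      frequency = off$frequency,
      offset_db = off$offset_db +
        stats::rnorm(nrow(off), 0, model$instance_sd)
    ))
  )
}

#' @keywords internal
instance_offset <- function(instance, frequency) {
  off <- instance$offset[[1]]
  off$offset_db[off$frequency == frequency]
}
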