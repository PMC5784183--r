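# deterministic listener: exact step response, no lapses, no session shift
det_params <- function() {
  listener_params(slope = 0, guess_rate = 0, lapse_rate = 0, session_sd = 0)
}

# listener with a fixed flat true threshold in both ears
fixed_listener <- function(t_db, params = det_params(), id = "T1",
                           t_contra = t_db) {
  l <- generate_listener(30, "normal", params, subject_id = id)
  thr <- l$thresholds[[1]]
  thr$true_db <- ifelse(thr$ear == "left", t_db, t_contra)
  l$thresholds[[1]] <- thr
  l
}

# zero-offset device and a perfect (error-free) calibration reference
perfect_instance <- function(min_level = -10, max_level = 80) {
  mod <- device_model("m_test", true_offset = 0, instance_sd = 0,
                      min_level = min_level, max_level = max_level)
  generate_device_instance(mod, "d_test")
}

perfect_reference <- function(model_id = "m_test", value = 0) {
  tibble::tibble(
    model_id = model_id, frequency = hearing_frequencies(),
    reference = value, n_records = 20, n_devices = 20, valid = TRUE
  )
}

# small random audiogram set on the grid, all in range
random_audiograms <- function(n_subjects = 3, scale = "HL") {
  grid <- hearing_frequencies()
  cells <- tidyr::expand_grid(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    ear = c("left", "right"),
    frequency = grid
  )
  audiogram(
    subject_id = cells$subject_id, ear = cells$ear, scale = scale,
    frequency = cells$frequency,
    threshold = 5 * sample(-2:16, nrow(cells), replace = TRUE)
  )
}

# paired_measurements built directly from difference vectors
pairs_from_values <- function(value_a, value_b,
                              frequency = rep(1000, length(value_a))) {
  out <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_along(value_a)),
    ear = "left", frequency = frequency,
    value_a = value_a, value_b = value_b
  )
  class(out) <- c("paired_measurements", class(out))
  out
}
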