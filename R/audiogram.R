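#' The standard test-frequency grid
#'
#' Pure-tone thresholds are measured at seven frequencies spanning the
#' speech-relevant range plus the high-frequency octaves most sensitive to
#' noise-induced and age-related loss.
#'
#' @return Integer vector of frequencies in Hz: 250, 500, 1000, 2000, 4000,
#'   6000, 8000.
#' @export
#' @examples
#' hearing_frequencies()
hearing_frequencies <- function() {
  c(250L, 500L, 1000L, 2000L, 4000L, 6000L, 8000L)
}

#' @keywords internal
audiogram_flag_levels <- function() {
  c("in_range", "above_max", "below_min", "invalid")
}

#' Snap a continuous level to the measurement grid
#'
#' Measured levels are reported on a fixed dB grid (5 dB by default, matching
#' the step size of both procedures). Exact midpoints round away from zero so
#' the rule is symmetric for negative levels.
#'
#' @param level Numeric vector of levels in dB (continuous).
#' @param step Grid step in dB, must be positive. Default 5.
#' @return Numeric vector of levels on the grid.
#' @export
#' @examples
#' snap_to_grid(12.4) # 10
#' snap_to_grid(12.5) # 15 (midpoint away from zero)
#' snap_to_grid(-12.5) # -15
snap_to_grid <- function(level, step = 5) {
  stopifnot(is.numeric(level), is.numeric(step), length(step) == 1, step > 0)
  sign(level) * floor(abs(level) / step + 0.5) * step
}

#' Construct an audiogram table
#'
#' The canonical audiogram container is a long tibble with one row per
#' (subject, ear, frequency) cell. Thresholds are integers on the 5 dB grid;
#' a cell whose flag is not `"in_range"` carries no usable threshold
#' (`NA`). The flag vocabulary is `in_range`, `above_max`, `below_min`
#' (dynamic-range clipping) and `invalid` (a procedure that failed to
#' converge); everything but `in_range` is excluded from agreement analysis.
#'
#' @param subject_id Character, subject identifiers.
#' @param ear `"left"` or `"right"`.
#' @param scale `"HL"` (clinical hearing level) or `"mHL"` (the biologically
#'   calibrated mobile scale).
#' @param frequency Frequencies in Hz, each on [hearing_frequencies()].
#' @param threshold Thresholds in dB, multiples of 5, `NA` when flagged.
#' @param flag Cell flags, see above. Default `"in_range"`.
#' @return A tibble of class `audiogram_tbl`.
#' @export
audiogram <- function(subject_id, ear, scale, frequency, threshold,
                      flag = "in_range") {
  out <- tibble::tibble(
    subject_id = as.character(subject_id),
    ear = as.character(ear),
    scale = as.character(scale),
    frequency = as.integer(frequency),
    threshold = as.numeric(threshold),
    flag = as.character(flag)
  )
  validate_audiograms(out)
}

#' @keywords internal
validate_audiograms <- function(x, call = rlang::caller_env()) {
  need <- c("subject_id", "ear", "scale", "frequency", "threshold", "flag")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    rlang::abort(paste0(
      "audiogram table lacks column(s): ", paste(missing_cols, collapse = ", ")
    ), call = call)
  }
  if (!all(x$ear %in% c("left", "right"))) {
    rlang::abort("ear must be 'left' or 'right'", call = call)
  }
  if (!all(x$scale %in% c("HL", "mHL"))) {
    rlang::abort("scale must be 'HL' or 'mHL'", call = call)
  }
  bad_freq <- !x$frequency %in% hearing_frequencies()
  if (any(bad_freq)) {
    rlang::abort(paste0(
      "frequency not on the test grid: ",
      paste(unique(x$frequency[bad_freq]), collapse = ", ")
    ), call = call)
  }
  if (!all(x$flag %in% audiogram_flag_levels())) {
    rlang::abort("unknown out-of-range flag", call = call)
  }
  present <- !is.na(x$threshold)
  off_grid <- present & (x$threshold %% 5 != 0)
  if (any(off_grid)) {
    rlang::abort(paste0(
      "threshold not a multiple of 5 dB: ",
      paste(unique(x$threshold[off_grid]), collapse = ", ")
    ), call = call)
  }
  if (any(present & x$flag != "in_range")) {
    rlang::abort("flagged cells must have NA threshold", call = call)
  }
  class(x) <- unique(c("audiogram_tbl", class(x)))
  x
}

#' Write audiograms to CSV
#'
#' One row per (subject, ear): columns `subject_id`, `ear`, `scale`, one
#' threshold column per grid frequency (`f250` ... `f8000`, empty cell =
#' missing) and one flag column per frequency (`flag_250` ...). The format
#' round-trips losslessly with [read_audiograms()].
#'
#' @param audiograms Audiogram tibble as produced by [audiogram()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_audiograms <- function(audiograms, path) {
  audiograms <- validate_audiograms(audiograms)
  grid <- hearing_frequencies()
  wide <- audiograms |>
    dplyr::mutate(frequency = factor(.data$frequency, levels = grid)) |>
    tidyr::pivot_wider(
      id_cols = c("subject_id", "ear", "scale"),
      names_from = "frequency",
      values_from = c("threshold", "flag"),
      names_glue = "{.value}_{frequency}"
    ) |>
    dplyr::rename_with(
      ~ sub("^threshold_", "f", .x),
      dplyr::starts_with("threshold_")
    )
  readr::write_csv(wide, path, na = "")
  invisible(path)
}

#' Read audiograms from CSV
#'
#' Inverse of [write_audiograms()]. Unknown frequency columns, thresholds off
#' the 5 dB grid and malformed rows are rejected with the offending line
#' number (header = line 1).
#'
#' @param path File path.
#' @return An audiogram tibble (long, one row per cell).
#' @export
read_audiograms <- function(path) {
  wide <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  grid <- hearing_frequencies()
  f_cols <- paste0("f", grid)
  flag_cols <- paste0("flag_", grid)
  extra <- setdiff(names(wide), c("subject_id", "ear", "scale", f_cols, flag_cols))
  if (length(extra)) {
    rlang::abort(paste0(
      "unknown column(s) in audiogram file: ", paste(extra, collapse = ", ")
    ))
  }
  need <- setdiff(c("subject_id", "ear", "scale", f_cols), names(wide))
  if (length(need)) {
    rlang::abort(paste0(
      "audiogram file lacks column(s): ", paste(need, collapse = ", ")
    ))
  }
  if (nrow(wide) == 0) {
    return(audiogram(character(), character(), character(),
                     integer(), numeric(), character()))
  }
  rows <- purrr::map(seq_len(nrow(wide)), function(i) {
    line <- i + 1L
    row <- wide[i, ]
    thr <- suppressWarnings(as.numeric(row[f_cols]))
    raw <- as.character(row[f_cols])
    malformed <- !is.na(raw) & raw != "" & is.na(thr)
    if (any(malformed) || is.na(row$subject_id) ||
        !row$ear %in% c("left", "right") || !row$scale %in% c("HL", "mHL")) {
      rlang::abort(paste0("malformed audiogram row at line ", line))
    }
    if (any(!is.na(thr) & thr %% 5 != 0)) {
      rlang::abort(paste0(
        "threshold off the 5 dB grid at line ", line, ": ",
        paste(thr[!is.na(thr) & thr %% 5 != 0], collapse = ", ")
      ))
    }
    flags <- if (all(flag_cols %in% names(wide))) {
      fl <- as.character(row[flag_cols])
      fl[is.na(fl) | fl == ""] <- "in_range"
      fl
    } else {
      rep("in_range", length(grid))
    }
    if (!all(flags %in% audiogram_flag_levels())) {
      rlang::abort(paste0("unknown flag at line ", line))
    }
    tibble::tibble(
      subject_id = row$subject_id, ear = row$ear, scale = row$scale,
      frequency = grid, threshold = thr, flag = flags
    )
  })
  validate_audiograms(dplyr::bind_rows(rows))
}

#' Long-format usable observations
#'
#' Extracts one record per present, in-range threshold; cells that are
#' missing or carry an out-of-range flag are dropped (the two are treated
#' identically for statistics). The record count is the `n` that the
#' agreement tables pool over (70 subjects x 2 ears x 7 frequencies = 980
#' cells before any discards).
#'
#' @param audiograms Audiogram tibble.
#' @return Tibble with columns `subject_id`, `ear`, `frequency`, `value`,
#'   `scale`.
#' @export
audiograms_long <- function(audiograms) {
  audiograms <- validate_audiograms(audiograms)
  audiograms |>
    dplyr::filter(.data$flag == "in_range", !is.na(.data$threshold)) |>
    dplyr::transmute(
      subject_id = .data$subject_id, ear = .data$ear,
      frequency = .data$frequency, value = .data$threshold,
      scale = .data$scale
    )
}

#' Plot audiograms in clinical orientation
#'
#' Threshold against log frequency with the dB axis reversed (better hearing
#' up), one panel per subject, line per ear.
#'
#' @param audiograms Audiogram tibble.
#' @return A ggplot object.
#' @export
plot_audiogram <- function(audiograms) {
  audiograms <- validate_audiograms(audiograms)
  ggplot2::ggplot(
    dplyr::filter(audiograms, !is.na(.data$threshold)),
    ggplot2::aes(x = .data$frequency, y = .data$threshold,
                 colour = .data$ear, group = .data$ear)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10(breaks = hearing_frequencies()) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~subject_id) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Threshold (dB)", colour = "Ear")
}
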