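#' Measurement procedure configuration
#'
#' Parameters of the three simulated procedures: the clinical bracketing
#' staircase (10 dB down after a heard tone, 5 dB up after a miss; threshold
#' = lowest level heard on at least `ascents_required` of up to
#' `max_ascents` ascending presentations), the app's self-adjustment test
#' (5 dB steps, confirmation when the listener hears a level twice whose
#' next-lower level was not heard), and the Bekesy calibration track (level
#' falls while audible, rises while not; threshold = mean midpoint of the
#' last `bekesy_pairs` reversal pairs after discarding the first
#' `bekesy_discard` reversals). Contralateral masking is triggered when the
#' presented level exceeds `masking_trigger` on the measurement scale and is
#' modelled as complete removal of the cross-hearing path, which otherwise
#' reaches the other cochlea attenuated by `interaural_attenuation`
#' (40 dB, the supra-aural convention).
#'
#' @param step_down,step_up Bracketing staircase steps, dB.
#' @param self_adjust_step Self-adjustment step, dB.
#' @param masking_trigger Level above which masking is on, dB.
#' @param interaural_attenuation Cross-hearing attenuation, dB.
#' @param start_level Starting presentation level, dB.
#' @param ascents_required,max_ascents Bracketing threshold rule.
#' @param confirm_repeats Times the self-adjustment up-reversal pattern
#'   (miss at `L - step`, hear at `L`) must be seen at the same level before
#'   the listener confirms "barely audible". Default 2 (robust to a single
#'   attention lapse); 1 confirms at the first reversal pair.
#' @param pta_min,pta_max Clinical audiometer output range, dB HL.
#' @param max_presentations Safety cap; exceeding it flags the result
#'   `invalid`.
#' @param bekesy_step Tracking step per tick, dB (level rate discretised).
#' @param bekesy_start Track starting level (device command scale), chosen
#'   comfortably suprathreshold for the eligible calibration population.
#' @param bekesy_discard Initial reversals dropped.
#' @param bekesy_pairs Reversal pairs averaged.
#' @param bekesy_max_ticks Tick cap before the track is flagged invalid.
#' @param bekesy_spread_limit Max SD of pair midpoints (dB) for a track to
#'   count as valid.
#' @param bekesy_min_initial_run Minimum ticks before the first reversal: a
#'   listener who cannot hold a response to a clearly audible starting tone
#'   produces an invalid track.
#' @param bekesy_min_level,bekesy_max_level Raw hardware output range on the
#'   command scale, wider than the guaranteed mHL test range (after
#'   calibration the command for a given mHL level shifts by the reference,
#'   so the hardware must span more than the advertised range).
#' @return Named list of class `procedure_config`.
#' @export
procedure_config <- function(step_down = 10, step_up = 5,
                             self_adjust_step = 5,
                             masking_trigger = 40,
                             interaural_attenuation = 40,
                             start_level = 40,
                             ascents_required = 2, max_ascents = 4,
                             confirm_repeats = 2,
                             pta_min = -10, pta_max = 110,
                             max_presentations = 400,
                             bekesy_step = 1, bekesy_start = 50,
                             bekesy_discard = 2, bekesy_pairs = 4,
                             bekesy_max_ticks = 2000,
                             bekesy_spread_limit = 6,
                             bekesy_min_initial_run = 3,
                             bekesy_min_level = -30,
                             bekesy_max_level = 100) {
  stopifnot(step_down > 0, step_up > 0, self_adjust_step > 0,
            bekesy_step > 0, pta_min < pta_max,
            ascents_required >= 1, ascents_required <= max_ascents)
  structure(
    list(step_down = step_down, step_up = step_up,
         self_adjust_step = self_adjust_step,
         masking_trigger = masking_trigger,
         interaural_attenuation = interaural_attenuation,
         start_level = start_level,
         ascents_required = ascents_required, max_ascents = max_ascents,
         confirm_repeats = confirm_repeats,
         pta_min = pta_min, pta_max = pta_max,
         max_presentations = max_presentations,
         bekesy_step = bekesy_step, bekesy_start = bekesy_start,
         bekesy_discard = bekesy_discard, bekesy_pairs = bekesy_pairs,
         bekesy_max_ticks = bekesy_max_ticks,
         bekesy_spread_limit = bekesy_spread_limit,
         bekesy_min_initial_run = bekesy_min_initial_run,
         bekesy_min_level = bekesy_min_level,
         bekesy_max_level = bekesy_max_level),
    class = "procedure_config"
  )
}

#' Effective levels at the two cochleas
#'
#' The test ear receives the presented level. Without masking the
#' contralateral cochlea receives the presented level minus the interaural
#' attenuation (cross-hearing); masking removes that path entirely.
#'
#' @param presented Presented level at the test ear, dB.
#' @param masking_on Logical.
#' @param interaural_attenuation dB.
#' @return Named list `test`, `contra` (dB; `contra = -Inf` under masking).
#' @export
effective_level <- function(presented, masking_on,
                            interaural_attenuation = 40) {
  list(
    test = presented,
    contra = if (masking_on) -Inf else presented - interaural_attenuation
  )
}

# one presentation; thresholds already include the session offset
present_tone <- function(level, t_test, t_contra, slope, guess, lapse,
                         config) {
  masking_on <- level > config$masking_trigger
  eff <- effective_level(level, masking_on, config$interaural_attenuation)
  p <- response_probability(eff$test, t_test, slope, guess, lapse,
                            contra_level = eff$contra,
                            contra_threshold = t_contra)
  list(heard = stats::runif(1) < p, masking = masking_on)
}

# shared scaffolding for staircase traces
new_trace <- function() {
  list(level = numeric(), heard = logical(), masking = logical())
}
trace_add <- function(tr, level, heard, masking) {
  tr$level <- c(tr$level, level)
  tr$heard <- c(tr$heard, heard)
  tr$masking <- c(tr$masking, masking)
  tr
}
trace_tbl <- function(tr) {
  tibble::tibble(presentation = seq_along(tr$level), level = tr$level,
                 heard = tr$heard, masking = tr$masking)
}

#' Simulated clinical bracketing audiometry (one ear, one frequency)
#'
#' The conventional 10-down/5-up bracketing staircase. After each heard
#' response the level drops by `step_down`; after each miss it rises by
#' `step_up`. A presentation that follows a miss is an *ascending*
#' presentation; the threshold is the lowest level heard on at least
#' `ascents_required` ascending presentations (of up to `max_ascents`).
#' When the listener keeps hearing at the output floor, or keeps missing at
#' the ceiling, the result is clamped and flagged `below_min` / `above_max`.
#'
#' @param listener One-row listener tibble.
#' @param ear `"left"` or `"right"`.
#' @param frequency Hz, on the grid.
#' @param config [procedure_config()].
#' @param session_offset Per-exam threshold shift, dB.
#' @return List: `threshold` (dB HL on the 5 dB grid, `NA` when flagged),
#'   `flag`, `trace` (tibble of presentations).
#' @export
hughson_westlake <- function(listener, ear, frequency,
                             config = procedure_config(),
                             session_offset = 0) {
  contra_ear <- setdiff(c("left", "right"), ear)
  t_test <- listener_threshold(listener, ear, frequency) + session_offset
  t_contra <- listener_threshold(listener, contra_ear, frequency) +
    session_offset
  slope <- listener$slope; guess <- listener$guess_rate
  lapse <- listener$lapse_rate

  level <- config$start_level
  tr <- new_trace()
  asc_n <- new.env(parent = emptyenv())
  asc_heard <- new.env(parent = emptyenv())
  prev_missed <- FALSE
  pinned_low <- 0L
  pinned_high <- 0L
  threshold <- NA_real_
  flag <- "invalid"

  for (i in seq_len(config$max_presentations)) {
    res <- present_tone(level, t_test, t_contra, slope, guess, lapse, config)
    tr <- trace_add(tr, level, res$heard, res$masking)
    key <- as.character(level)
    if (prev_missed) {
      asc_n[[key]] <- (asc_n[[key]] %||% 0L) + 1L
      if (res$heard) {
        asc_heard[[key]] <- (asc_heard[[key]] %||% 0L) + 1L
        if (asc_heard[[key]] >= config$ascents_required) {
          threshold <- level
          flag <- "in_range"
          break
        }
      }
    }
    if (res$heard) {
      nxt <- level - config$step_down
      if (nxt < config$pta_min) {
        pinned_low <- pinned_low + 1L
        if (pinned_low >= 2L) {
          flag <- "below_min"
          break
        }
        level <- config$pta_min
      } else {
        level <- nxt
      }
      prev_missed <- FALSE
    } else {
      nxt <- level + config$step_up
      if (nxt > config$pta_max) {
        pinned_high <- pinned_high + 1L
        if (pinned_high >= 2L) {
          flag <- "above_max"
          break
        }
        level <- config$pta_max
      } else {
        level <- nxt
      }
      prev_missed <- TRUE
    }
  }
  list(threshold = threshold, flag = flag, trace = trace_tbl(tr))
}

#' Simulated self-adjustment hearing test (one ear, one frequency)
#'
#' The app procedure: the listener steps the level down while hearing the
#' tone and up while not, and confirms the lowest audible level. The
#' confirmation rule requires the pattern "not heard at `L - step`, heard at
#' `L`" to be observed twice at the same level `L` (two consistent
#' up-reversals), which makes the simulated behaviour robust to single
#' attention lapses. Levels are commanded on the dB mHL scale: the device
#' translates `L` mHL into output via the model's calibrated reference, so
#' the level reaching the ear is `L + reference - instance_offset` on the
#' dB HL scale. Masking is applied above `masking_trigger` (mHL); results at
#' the device's dynamic-range limits are flagged.
#'
#' @inheritParams hughson_westlake
#' @param device_instance From [generate_device_instance()].
#' @param reference Reference-level tibble for the device's model (from
#'   [compute_reference()]); must be valid.
#' @return List: `threshold` (dB mHL on the 5 dB grid, `NA` when flagged),
#'   `flag`, `trace`.
#' @export
self_adjust_test <- function(listener, ear, frequency, device_instance,
                             reference, config = procedure_config(),
                             session_offset = 0) {
  ref_row <- reference[reference$frequency == frequency, ]
  if (nrow(ref_row) != 1 || !isTRUE(ref_row$valid[1]) ||
      !identical(ref_row$model_id[1], device_instance$model_id[1])) {
    rlang::abort(paste0(
      "no valid calibration reference for model '",
      device_instance$model_id[1], "' at ", frequency, " Hz"
    ))
  }
  ref <- ref_row$reference[1]
  o <- instance_offset(device_instance, frequency)
  contra_ear <- setdiff(c("left", "right"), ear)
  t_test <- listener_threshold(listener, ear, frequency) + session_offset
  t_contra <- listener_threshold(listener, contra_ear, frequency) +
    session_offset
  slope <- listener$slope; guess <- listener$guess_rate
  lapse <- listener$lapse_rate
  step <- config$self_adjust_step
  lo <- device_instance$min_level
  hi <- device_instance$max_level

  level <- min(max(config$start_level, lo), hi)
  tr <- new_trace()
  rev_count <- new.env(parent = emptyenv())
  prev_level <- NA_real_
  prev_heard <- NA
  pinned_low <- 0L
  pinned_high <- 0L
  threshold <- NA_real_
  flag <- "invalid"

  for (i in seq_len(config$max_presentations)) {
    # dB mHL command `level` reaches the ear at level + ref - offset (dB HL)
    at_ear <- level + ref - o
    masking_on <- level > config$masking_trigger
    eff <- effective_level(at_ear, masking_on, config$interaural_attenuation)
    p <- response_probability(eff$test, t_test, slope, guess, lapse,
                              contra_level = eff$contra,
                              contra_threshold = t_contra)
    heard <- stats::runif(1) < p
    tr <- trace_add(tr, level, heard, masking_on)
    if (heard && isFALSE(prev_heard) && isTRUE(prev_level == level - step)) {
      key <- as.character(level)
      rev_count[[key]] <- (rev_count[[key]] %||% 0L) + 1L
      if (rev_count[[key]] >= config$confirm_repeats) {
        threshold <- snap_to_grid(level, step)
        flag <- "in_range"
        break
      }
    }
    prev_level <- level
    prev_heard <- heard
    if (heard) {
      if (level - step < lo) {
        pinned_low <- pinned_low + 1L
        if (pinned_low >= 2L) {
          flag <- "below_min"
          break
        }
      } else {
        level <- level - step
      }
    } else {
      if (level + step > hi) {
        pinned_high <- pinned_high + 1L
        if (pinned_high >= 2L) {
          flag <- "above_max"
          break
        }
      } else {
        level <- level + step
      }
    }
  }
  list(threshold = threshold, flag = flag, trace = trace_tbl(tr))
}

#' Simulated Bekesy self-tracking (one ear, one frequency)
#'
#' The calibration measurement: the level falls by `bekesy_step` per tick
#' while the listener holds the button (audible) and rises while released.
#' Each direction change is a reversal; after discarding the first
#' `bekesy_discard` reversals, the raw threshold is the mean of the
#' midpoints of `bekesy_pairs` consecutive reversal pairs. The result is on
#' the device *command* scale (so it embeds the instance's output offset —
#' exactly what crowd calibration aggregates), moving within the raw
#' hardware range (`bekesy_min_level`/`bekesy_max_level`). Tracks are
#' flagged invalid when they fail to collect enough reversals, reverse
#' within `bekesy_min_initial_run` ticks of the suprathreshold start (the
#' listener is not responding reliably to a clearly audible tone), touch
#' the hardware limits at a reversal, or spread their pair midpoints more
#' than `bekesy_spread_limit` dB.
#'
#' @inheritParams self_adjust_test
#' @return List: `raw` (dB, command scale; `NA` when invalid), `valid`,
#'   `trace`.
#' @export
bekesy_track <- function(listener, ear, frequency, device_instance,
                         config = procedure_config(), session_offset = 0) {
  o <- instance_offset(device_instance, frequency)
  t_test <- listener_threshold(listener, ear, frequency) + session_offset
  slope <- listener$slope; guess <- listener$guess_rate
  lapse <- listener$lapse_rate
  lo <- config$bekesy_min_level
  hi <- config$bekesy_max_level
  step <- config$bekesy_step
  need <- config$bekesy_discard + 2L * config$bekesy_pairs

  level <- min(max(config$bekesy_start, lo), hi)
  reversals <- numeric()
  first_reversal_tick <- NA_integer_
  limit_touch <- FALSE
  prev_heard <- NA
  levels_seen <- numeric()
  heard_seen <- logical()

  for (i in seq_len(config$bekesy_max_ticks)) {
    p <- response_probability(level - o, t_test, slope, guess, lapse)
    heard <- stats::runif(1) < p
    levels_seen[i] <- level
    heard_seen[i] <- heard
    if (!is.na(prev_heard) && heard != prev_heard) {
      reversals <- c(reversals, level)
      if (is.na(first_reversal_tick)) first_reversal_tick <- i
      if (level <= lo || level >= hi) limit_touch <- TRUE
      if (length(reversals) >= need) break
    }
    prev_heard <- heard
    level <- if (heard) max(level - step, lo) else min(level + step, hi)
  }

  trace <- tibble::tibble(tick = seq_along(levels_seen),
                          level = levels_seen, heard = heard_seen)
  if (length(reversals) < need) {
    return(list(raw = NA_real_, valid = FALSE, trace = trace))
  }
  kept <- reversals[(config$bekesy_discard + 1L):need]
  mids <- (kept[c(TRUE, FALSE)] + kept[c(FALSE, TRUE)]) / 2
  spread <- stats::sd(mids)
  valid <- !limit_touch &&
    first_reversal_tick > config$bekesy_min_initial_run &&
    (is.na(spread) || spread <= config$bekesy_spread_limit)
  list(raw = mean(mids), valid = valid, trace = trace)
}

#' Run a full examination (both ears, full grid)
#'
#' One simulated visit of one listener: draws a fresh session offset
#' (headphones repositioned between exams) and measures all 14
#' ear-frequency cells with the chosen procedure.
#'
#' @param listener One-row listener tibble.
#' @param procedure `"pta"` (clinical bracketing, dB HL; the clinical
#'   audiometer is modelled as perfectly calibrated) or `"mobile"`
#'   (self-adjustment on a device, dB mHL).
#' @param device_instance,reference Required for `"mobile"`.
#' @param config [procedure_config()].
#' @param keep_traces Keep per-cell staircase traces as an attribute.
#' @return An audiogram tibble (14 rows); attribute `traces` when requested.
#' @export
run_full_exam <- function(listener, procedure = c("pta", "mobile"),
                          device_instance = NULL, reference = NULL,
                          config = procedure_config(), keep_traces = FALSE) {
  procedure <- match.arg(procedure)
  session_offset <- stats::rnorm(1, 0, listener$session_sd)
  grid <- hearing_frequencies()
  cells <- tidyr::expand_grid(ear = c("left", "right"), frequency = grid)
  traces <- list()
  res <- purrr::pmap(cells, function(ear, frequency) {
    r <- if (procedure == "pta") {
      hughson_westlake(listener, ear, frequency, config, session_offset)
    } else {
      self_adjust_test(listener, ear, frequency, device_instance, reference,
                       config, session_offset)
    }
    if (keep_traces) {
      traces[[paste(ear, frequency, sep = "_")]] <<- r$trace
    }
    tibble::tibble(threshold = r$threshold, flag = r$flag)
  }) |>
    dplyr::bind_rows()
  out <- audiogram(
    subject_id = listener$subject_id,
    ear = cells$ear,
    scale = if (procedure == "pta") "HL" else "mHL",
    frequency = cells$frequency,
    threshold = res$threshold,
    flag = res$flag
  )
  if (keep_traces) attr(out, "traces") <- traces
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
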