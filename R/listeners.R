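#' Listener simulation parameters
#'
#' Defaults for the hidden listener model. The psychometric function for a
#' single yes/no presentation is a cumulative normal:
#' \deqn{P(heard) = g + (1 - g - l)\,\Phi((L - (T + s))/\sigma)}
#' with level `L`, true threshold `T`, session offset `s`, spread `slope`
#' (`sigma`, default 3 dB, a typical pure-tone detection spread), guess rate
#' `g` and lapse rate `l` (2% each). `session_sd` is the between-session
#' threshold shift (headphone repositioning etc., default 2.5 dB, chosen so
#' simulated test-retest difference SD lands near 4.4 dB).
#'
#' Class archetypes for true thresholds (dB HL, continuous, per frequency):
#' * `normal`: N(5, 5^2) truncated to \[-10, 20\] (always passes the
#'   25 dB normal-hearing screen);
#' * `sensorineural`: flat base severity drawn from mild to profound
#'   (15/25/40/55 dB with probabilities .4/.3/.2/.1) plus a
#'   +10 dB/octave slope above 1 kHz, plus N(0, 5^2) per-frequency noise;
#' * `conductive_mixed`: flat elevation uniform on \[20, 50\] dB plus
#'   N(0, 5^2) per-frequency noise.
#' Loss classes receive a between-ear asymmetry of +/- a/2 with
#' a ~ N(0, 5^2); all thresholds are clamped to \[-10, 110\].
#'
#' @param slope Psychometric spread in dB (>= 0; 0 gives the exact
#'   deterministic step-listener limit, hears iff level >= threshold).
#' @param guess_rate,lapse_rate Probabilities in \[0, 0.1\].
#' @param session_sd Between-session threshold shift SD in dB.
#' @param normal_mean,normal_sd,normal_range Normal-class archetype.
#' @param snhl_base Severity levels (dB) for sensorineural flat component.
#' @param snhl_base_prob Sampling weights for `snhl_base`.
#' @param snhl_slope_per_octave High-frequency slope above 1 kHz (dB/octave).
#' @param conductive_range Flat-loss range (dB) for conductive/mixed class.
#' @param freq_noise_sd Per-frequency threshold noise SD (dB).
#' @param asymmetry_sd Between-ear asymmetry SD (dB) for loss classes.
#' @return Named list of parameters.
#' @export
listener_params <- function(slope = 3, guess_rate = 0.02, lapse_rate = 0.02,
                            session_sd = 2.5,
                            normal_mean = 5, normal_sd = 5,
                            normal_range = c(-10, 20),
                            snhl_base = c(15, 25, 40, 55),
                            snhl_base_prob = c(0.4, 0.3, 0.2, 0.1),
                            snhl_slope_per_octave = 10,
                            conductive_range = c(20, 50),
                            freq_noise_sd = 5,
                            asymmetry_sd = 5) {
  stopifnot(
    slope >= 0, guess_rate >= 0, guess_rate <= 0.1,
    lapse_rate >= 0, lapse_rate <= 0.1, session_sd >= 0,
    normal_range[1] < normal_range[2], freq_noise_sd >= 0, asymmetry_sd >= 0
  )
  list(
    slope = slope, guess_rate = guess_rate, lapse_rate = lapse_rate,
    session_sd = session_sd, normal_mean = normal_mean, normal_sd = normal_sd,
    normal_range = normal_range, snhl_base = snhl_base,
    snhl_base_prob = snhl_base_prob,
    snhl_slope_per_octave = snhl_slope_per_octave,
    conductive_range = conductive_range, freq_noise_sd = freq_noise_sd,
    asymmetry_sd = asymmetry_sd
  )
}

#' @keywords internal
hearing_class_labels <- function() {
  c("normal", "sensorineural", "conductive_mixed")
}

# truncated-normal draws via inverse CDF (proper truncation, no clamping mass)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' @keywords internal
archetype_thresholds <- function(hearing_class, params) {
  grid <- hearing_frequencies()
  n <- length(grid)
  per_ear <- function() {
    switch(hearing_class,
      normal = rtruncnorm(n, params$normal_mean, params$normal_sd,
                          params$normal_range[1], params$normal_range[2]),
      sensorineural = {
        base <- sample(params$snhl_base, 1, prob = params$snhl_base_prob)
        slope_part <- params$snhl_slope_per_octave *
          pmax(0, log2(grid / 1000))
        base + slope_part + stats::rnorm(n, 0, params$freq_noise_sd)
      },
      conductive_mixed = {
        flat <- stats::runif(1, params$conductive_range[1],
                             params$conductive_range[2])
        flat + stats::rnorm(n, 0, params$freq_noise_sd)
      },
      rlang::abort(paste0("unknown hearing class: ", hearing_class))
    )
  }
  left <- per_ear()
  right <- per_ear()
  if (hearing_class != "normal") {
    asym <- stats::rnorm(1, 0, params$asymmetry_sd)
    left <- left + asym / 2
    right <- right - asym / 2
  }
  tibble::tibble(
    ear = rep(c("left", "right"), each = length(grid)),
    frequency = rep(grid, 2),
    true_db = pmin(pmax(c(left, right), -10), 110)
  )
}

#' Generate a synthetic listener
#'
#' Draws the hidden state of one simulated participant: continuous true
#' thresholds for both ears on the full frequency grid plus psychometric
#' response parameters. Reproducible from the R RNG state (`set.seed()`).
#'
#' @param age Age in years.
#' @param hearing_class One of `"normal"`, `"sensorineural"`,
#'   `"conductive_mixed"`.
#' @param params See [listener_params()].
#' @param subject_id Identifier; default auto-generated.
#' @param self_reported_normal Logical flag (used for calibration crowds).
#' @return One-row tibble with a `thresholds` list-column
#'   (ear x frequency tibble of `true_db`).
#' @export
generate_listener <- function(age, hearing_class, params = listener_params(),
                              subject_id = NULL,
                              self_reported_normal = hearing_class == "normal") {
  if (!hearing_class %in% hearing_class_labels()) {
    rlang::abort(paste0("unknown hearing class: ", hearing_class))
  }
  if (is.null(subject_id)) {
    subject_id <- sprintf("S%06d", sample.int(999999L, 1))
  }
  tibble::tibble(
    subject_id = as.character(subject_id),
    age = age,
    hearing_class = hearing_class,
    slope = params$slope,
    guess_rate = params$guess_rate,
    lapse_rate = params$lapse_rate,
    session_sd = params$session_sd,
    self_reported_normal = self_reported_normal,
    thresholds = list(archetype_thresholds(hearing_class, params))
  )
}

#' Generate a patient cohort
#'
#' Ages are N(36, 11^2) truncated to \[18, 71\]; classes are drawn
#' multinomially from `class_mix`. The default mix reproduces the study
#' cohort composition: 36/70 normal, 21/70 sensorineural, 13/70
#' conductive or mixed loss.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param class_mix Named proportions over the three classes, summing to 1.
#' @param params See [listener_params()].
#' @param age_mean,age_sd,age_range Age distribution.
#' @return Tibble of listeners, one row each.
#' @export
generate_cohort <- function(n_subjects,
                            class_mix = c(normal = 36 / 70,
                                          sensorineural = 21 / 70,
                                          conductive_mixed = 13 / 70),
                            params = listener_params(),
                            age_mean = 36, age_sd = 11, age_range = c(18, 71)) {
  if (n_subjects < 1) rlang::abort("n_subjects must be >= 1")
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% hearing_class_labels())) {
    rlang::abort("class_mix must be named with known hearing classes")
  }
  if (abs(sum(class_mix) - 1) > 1e-8) {
    rlang::abort("class_mix proportions must sum to 1")
  }
  classes <- sample(names(class_mix), n_subjects, replace = TRUE,
                    prob = class_mix)
  ages <- rtruncnorm(n_subjects, age_mean, age_sd, age_range[1], age_range[2])
  purrr::map2(seq_len(n_subjects), classes, function(i, cl) {
    generate_listener(ages[i], cl, params,
                      subject_id = sprintf("P%04d", i))
  }) |>
    dplyr::bind_rows()
}

#' Generate a self-selected calibration crowd
#'
#' Emulates application users aged 18-35 who consider themselves
#' normal-hearing. A fraction `contamination_rate` are actually drawn from
#' hearing-loss classes (elevated thresholds) despite the self-report. The
#' default rate 0.26 matches the design logic of the 37th-percentile
#' reference estimator: 0.37 = 0.5 x 0.74, so at 26% contamination the
#' mixture's 37th percentile coincides with the clean-population median.
#'
#' @param n_users Crowd size.
#' @param contamination_rate Fraction in \[0, 1) of truly impaired users.
#' @param params See [listener_params()].
#' @param contaminated_classes Loss classes the contaminated users are drawn
#'   from (relative weights of the cohort default, 21:13).
#' @param contamination_shift If numeric, contaminated users are instead
#'   normal-archetype listeners with all thresholds shifted up by this many
#'   dB (a controlled contamination model for estimator experiments).
#' @return Tibble of listeners, all with ages in \[18, 35\] and
#'   `self_reported_normal = TRUE`.
#' @export
generate_crowd <- function(n_users, contamination_rate = 0.26,
                           params = listener_params(),
                           contaminated_classes = c(sensorineural = 21 / 34,
                                                    conductive_mixed = 13 / 34),
                           contamination_shift = NULL) {
  stopifnot(contamination_rate >= 0, contamination_rate < 1, n_users >= 1)
  impaired <- stats::runif(n_users) < contamination_rate
  ages <- stats::runif(n_users, 18, 35)
  purrr::map(seq_len(n_users), function(i) {
    if (!impaired[i]) {
      generate_listener(ages[i], "normal", params,
                        subject_id = sprintf("U%05d", i),
                        self_reported_normal = TRUE)
    } else if (!is.null(contamination_shift)) {
      l <- generate_listener(ages[i], "normal", params,
                             subject_id = sprintf("U%05d", i),
                             self_reported_normal = TRUE)
      l$thresholds[[1]]$true_db <- l$thresholds[[1]]$true_db +
        contamination_shift
      l
    } else {
      cl <- sample(names(contaminated_classes), 1,
                   prob = contaminated_classes)
      l <- generate_listener(ages[i], cl, params,
                             subject_id = sprintf("U%05d", i),
                             self_reported_normal = TRUE)
      l
    }
  }) |>
    dplyr::bind_rows()
}

#' @keywords internal
listener_threshold <- function(listener, ear, frequency) {
  thr <- listener$thresholds[[1]]
  thr$true_db[thr$ear == ear & thr$frequency == frequency]
}

#' Probability of a "heard" response
#'
#' Closed form of the listener model for one presentation, optionally with a
#' cross-hearing path to the contralateral cochlea: the tone is detected if
#' either ear's detector fires, and guess/lapse apply once to the combined
#' detection.
#'
#' @param level Effective level at the test ear (dB on the threshold scale).
#' @param threshold True threshold of the test ear (incl. session offset).
#' @param slope,guess_rate,lapse_rate Psychometric parameters.
#' @param contra_level Effective level reaching the contralateral cochlea
#'   (`-Inf` = no cross-path, e.g. under masking).
#' @param contra_threshold Contralateral true threshold.
#' @return Probability in \[0, 1\].
#' @export
response_probability <- function(level, threshold, slope,
                                 guess_rate = 0.02, lapse_rate = 0.02,
                                 contra_level = -Inf,
                                 contra_threshold = Inf) {
  # slope = 0 is the exact deterministic limit: detect iff level >= threshold
  detect <- function(lev, thr) {
    if (slope == 0) as.numeric(lev >= thr) else
      stats::pnorm((lev - thr) / slope)
  }
  d_test <- detect(level, threshold)
  d_contra <- if (is.finite(contra_level) && is.finite(contra_threshold)) {
    detect(contra_level, contra_threshold)
  } else {
    0
  }
  d <- 1 - (1 - d_test) * (1 - d_contra)
  guess_rate + (1 - guess_rate - lapse_rate) * d
}

#' Simulate one yes/no response
#'
#' Bernoulli draw from [response_probability()] for a single tone
#' presentation to a listener. Stands in for the participant pressing
#' "I can hear" / "I cannot hear".
#'
#' @inheritParams response_probability
#' @param listener One-row listener tibble.
#' @param ear Test ear.
#' @param frequency Test frequency in Hz.
#' @param session_offset Session-level threshold shift in dB (added to the
#'   true thresholds of both ears).
#' @return Logical: heard or not.
#' @export
respond <- function(listener, ear, frequency, level, session_offset = 0,
                    contra_level = -Inf) {
  contra_ear <- setdiff(c("left", "right"), ear)
  p <- response_probability(
    level,
    listener_threshold(listener, ear, frequency) + session_offset,
    listener$slope, listener$guess_rate, listener$lapse_rate,
    contra_level = contra_level,
    contra_threshold = listener_threshold(listener, contra_ear, frequency) +
      session_offset
  )
  stats::runif(1) < p
}
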