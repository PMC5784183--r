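test_that("effective levels implement cross-hearing and masking", {
  e <- effective_level(60, masking_on = FALSE, interaural_attenuation = 40)
  expect_equal(e$test, 60)
  expect_equal(e$contra, 20)
  expect_equal(effective_level(30, FALSE, 40)$contra, -10)
  expect_equal(effective_level(60, TRUE, 40)$contra, -Inf)
})

test_that("bracketing staircase is exact for deterministic listeners", {
  r <- withr::with_seed(1, hughson_westlake(fixed_listener(32.5), "left", 1000))
  expect_equal(r$threshold, 35)
  expect_equal(r$flag, "in_range")
  expect_true(35 %in% r$trace$level)

  # exact oracle: smallest grid level >= T, over T swept across the range
  for (t_db in seq(-7.5, 100, by = 2.5)) {
    got <- hughson_westlake(fixed_listener(t_db), "right", 2000)$threshold
    expect_equal(got, 5 * ceiling(t_db / 5))
  }

  # dynamic-range clamps
  low <- withr::with_seed(2, hughson_westlake(fixed_listener(-100), "left", 500))
  expect_true(is.na(low$threshold))
  expect_equal(low$flag, "below_min")
  high <- withr::with_seed(3, hughson_westlake(fixed_listener(200), "left", 500))
  expect_equal(high$flag, "above_max")
})

test_that("bracketing staircase is nearly unbiased for stochastic listeners", {
  p3 <- listener_params(session_sd = 0)
  withr::with_seed(4, {
    est <- purrr::map_dbl(1:500, function(i) {
      hughson_westlake(fixed_listener(32.5, p3), "left", 1000)$threshold
    })
  })
  # the bracketing rule rounds up to the next grid level (35 here); the
  # stochastic mean stays within half a grid step of that exact answer
  expect_lt(abs(mean(est) - 35), 2.5)
  expect_lt(sd(est), 5)
})

test_that("staircase traces obey the configured step transitions", {
  withr::with_seed(5, {
    r <- hughson_westlake(fixed_listener(27.5, listener_params(session_sd = 0)),
                          "left", 4000)
  })
  steps <- diff(r$trace$level)
  expect_true(all(steps %in% c(-10, 5, 0)))
  expect_true(r$threshold %in% r$trace$level)
})

test_that("masking can only raise the measured threshold (deterministic)", {
  cfg_mask <- procedure_config(masking_trigger = -1e9) # always masked
  cfg_open <- procedure_config(masking_trigger = 1e9) # never masked
  # contralateral ear much better: cross-hearing helps detection when open
  for (t_contra in c(-10, 0, 10)) {
    l <- fixed_listener(70, t_contra = t_contra)
    masked <- withr::with_seed(6, hughson_westlake(l, "left", 1000, cfg_mask))
    open <- withr::with_seed(6, hughson_westlake(l, "left", 1000, cfg_open))
    expect_gte(masked$threshold, open$threshold)
    # unmasked threshold equals min(T_test, T_contra + IA) on the grid
    expect_equal(open$threshold, 5 * ceiling(min(70, t_contra + 40) / 5))
    expect_equal(masked$threshold, 70)
  }
})

test_that("self-adjustment recovers deterministic thresholds exactly", {
  inst <- perfect_instance()
  ref <- perfect_reference()
  r <- withr::with_seed(7, self_adjust_test(fixed_listener(20), "left", 1000,
                                            inst, ref))
  expect_equal(r$threshold, 20)
  expect_equal(r$flag, "in_range")

  for (t_db in seq(-7.5, 75, by = 2.5)) {
    got <- self_adjust_test(fixed_listener(t_db), "left", 2000, inst,
                            ref)$threshold
    expect_equal(got, 5 * ceiling(t_db / 5))
  }
})

test_that("a reference error shifts self-adjusted thresholds linearly", {
  inst <- perfect_instance()
  over <- perfect_reference(value = 5) # reference overestimated by +5 dB
  for (t_db in c(7.5, 20, 42.5)) {
    base <- self_adjust_test(fixed_listener(t_db), "left", 1000, inst,
                             perfect_reference())$threshold
    shifted <- self_adjust_test(fixed_listener(t_db), "left", 1000, inst,
                                over)$threshold
    expect_equal(shifted, base - 5)
  }
})

test_that("self-adjustment flags device-range violations and bad references", {
  inst <- perfect_instance(max_level = 80)
  ref <- perfect_reference()
  hi <- withr::with_seed(8, self_adjust_test(fixed_listener(95), "left", 1000,
                                             inst, ref))
  expect_true(is.na(hi$threshold))
  expect_equal(hi$flag, "above_max")
  lo <- withr::with_seed(9, self_adjust_test(fixed_listener(-100), "left",
                                             1000, inst, ref))
  expect_equal(lo$flag, "below_min")

  bad_ref <- dplyr::mutate(ref, valid = FALSE)
  expect_error(
    self_adjust_test(fixed_listener(20), "left", 1000, inst, bad_ref),
    "calibration"
  )
})

test_that("Bekesy tracking estimates thresholds on the device scale", {
  inst <- perfect_instance()
  r <- withr::with_seed(10, bekesy_track(fixed_listener(30), "left", 1000, inst))
  expect_true(r$valid)
  expect_lt(abs(r$raw - 30), 0.5 + 1e-9)

  # the raw value embeds the instance offset (command scale)
  mod <- device_model("m_off", true_offset = 7, instance_sd = 0)
  inst7 <- generate_device_instance(mod, "d7")
  r7 <- withr::with_seed(11, bekesy_track(fixed_listener(30), "left", 1000,
                                          inst7))
  expect_lt(abs(r7$raw - 37), 0.5 + 1e-9)

  # stochastic bias under the default psychometric spread
  p3 <- listener_params(session_sd = 0)
  withr::with_seed(12, {
    est <- purrr::map_dbl(1:500, function(i) {
      bekesy_track(fixed_listener(30.2, p3), "left", 1000, inst)$raw
    })
  })
  expect_lt(abs(mean(est, na.rm = TRUE) - 30.2), 1)
})

test_that("inattentive listeners produce invalid Bekesy tracks", {
  p_ok <- listener_params(session_sd = 0)
  p_bad <- listener_params(lapse_rate = 0.1, session_sd = 0)
  p_bad$lapse_rate <- 0.5 # degenerate inattention, beyond the normal range
  inst <- perfect_instance()
  rate <- function(params) {
    mean(purrr::map_lgl(1:60, function(i) {
      !bekesy_track(fixed_listener(25, params), "left", 1000, inst)$valid
    }))
  }
  withr::with_seed(13, {
    r_bad <- rate(p_bad)
    r_ok <- rate(p_ok)
  })
  expect_gt(r_bad, r_ok + 0.3)
})

test_that("a full exam covers both ears on the full grid, deterministically", {
  l <- fixed_listener(25)
  a <- withr::with_seed(14, run_full_exam(l, "pta"))
  expect_equal(nrow(a), 14)
  expect_equal(sort(unique(a$frequency)), hearing_frequencies())
  expect_setequal(unique(a$ear), c("left", "right"))
  expect_equal(unique(a$scale), "HL")

  # session_sd = 0 and a deterministic listener: exams are identical
  b <- withr::with_seed(15, run_full_exam(l, "pta"))
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))

  inst <- perfect_instance()
  m <- withr::with_seed(16, run_full_exam(l, "mobile", device_instance = inst,
                                          reference = perfect_reference()))
  expect_equal(unique(m$scale), "mHL")
  expect_equal(m$threshold, a$threshold)
})
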