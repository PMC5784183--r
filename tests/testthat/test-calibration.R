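test_that("percentile_37 follows the documented quantile definition", {
  expect_equal(percentile_37(rep(10, 100)), 10)
  expect_equal(percentile_37(0:100), 37)
  expect_error(percentile_37(numeric(0)), "non-empty")

  # independent oracle: manual linear interpolation between order statistics
  withr::with_seed(1, {
    for (i in 1:20) {
      x <- rnorm(sample(5:40, 1))
      s <- sort(x)
      h <- (length(x) - 1) * 0.37
      manual <- s[floor(h) + 1] +
        (h - floor(h)) * (s[floor(h) + 2] - s[floor(h) + 1])
      expect_equal(percentile_37(x), manual)
    }
  })

  # translation equivariance
  withr::with_seed(2, {
    x <- rnorm(57)
    expect_equal(percentile_37(x + 12.5), percentile_37(x) + 12.5)
  })
})

test_that("the 37th percentile of a 26%-contaminated mixture is the clean median", {
  withr::with_seed(3, {
    n <- 20000
    contaminated <- runif(n) < 0.26
    x <- ifelse(contaminated, rnorm(n, 30, 1), rnorm(n, 0, 1))
  })
  expect_lt(abs(percentile_37(x) - 0), 0.1)
})

test_that("compute_reference applies the estimator, age filter and validity rule", {
  grid <- hearing_frequencies()
  mk <- function(n, age = 25) {
    purrr::map(seq_len(n), function(i) {
      calibration_record("m1", sprintf("d%03d", i), age, i, rep(60, 7))
    }) |> dplyr::bind_rows()
  }
  ref <- compute_reference(mk(15), literature_medians(5))
  expect_equal(ref$reference, rep(55, 7))
  expect_true(all(ref$valid))
  expect_equal(unique(ref$n_devices), 15)

  # 14 distinct devices: computed but flagged unusable
  ref14 <- compute_reference(mk(14), literature_medians(5))
  expect_equal(ref14$reference, rep(55, 7))
  expect_false(any(ref14$valid))

  # over-age users excluded before estimation
  recs <- dplyr::bind_rows(mk(20), local({
    r <- purrr::map(1:6, function(i) {
      calibration_record("m1", sprintf("old%02d", i), 40, 100 + i, rep(90, 7))
    })
    dplyr::bind_rows(r)
  }))
  ref_age <- compute_reference(recs, literature_medians(5))
  expect_equal(unique(ref_age$n_devices), 20)
  expect_equal(ref_age$reference, rep(55, 7))

  mixed <- dplyr::bind_rows(
    calibration_record("m1", "d1", 25, 1, rep(60, 7)),
    calibration_record("m2", "d2", 25, 1, rep(60, 7))
  )
  expect_error(compute_reference(mixed), "one model at a time")
})

test_that("only each device's most recent session enters the percentile", {
  base <- purrr::map(1:15, function(i) {
    calibration_record("m1", sprintf("d%03d", i), 25, 10 + i, rep(50, 7))
  }) |> dplyr::bind_rows()
  stale <- purrr::map(1:5, function(i) {
    calibration_record("m1", sprintf("d%03d", i), 25, i, rep(100, 7))
  }) |> dplyr::bind_rows()
  with_dupes <- dplyr::bind_rows(base, stale)
  ref <- compute_reference(with_dupes, literature_medians(0))
  expect_equal(ref$reference, rep(50, 7))
  # record order is irrelevant
  ref_rev <- compute_reference(dplyr::arrange(with_dupes, dplyr::desc(timestamp)),
                               literature_medians(0))
  expect_equal(ref, ref_rev)
})

test_that("the registry updates incrementally and idempotently", {
  recs <- purrr::map(1:15, function(i) {
    calibration_record("m1", sprintf("d%03d", i), 25, i, rep(40, 7))
  })
  reg <- calibration_registry(medians = literature_medians(0))
  for (i in 1:14) reg <- update_registry(reg, recs[[i]])
  expect_false(any(reg$references$valid))
  reg <- update_registry(reg, recs[[15]])
  expect_true(all(reg$references$valid)) # the 15th device flips validity

  # duplicate insert changes nothing
  reg2 <- update_registry(reg, recs[[7]])
  expect_equal(reg$references, reg2$references)
  expect_equal(nrow(reg$records), nrow(reg2$records))

  # streaming insertion in any order equals batch computation
  withr::with_seed(4, {
    perm <- sample(15)
  })
  reg_perm <- calibration_registry(medians = literature_medians(0))
  for (i in perm) reg_perm <- update_registry(reg_perm, recs[[i]])
  batch <- compute_reference(dplyr::bind_rows(recs), literature_medians(0))
  expect_equal(reg_perm$references, batch)

  # a second model does not disturb the first
  reg3 <- update_registry(reg, calibration_record("m2", "x1", 25, 1, rep(70, 7)))
  expect_equal(
    dplyr::filter(reg3$references, model_id == "m1"),
    reg$references
  )
})

test_that("reference recovery: clean crowds show the documented percentile bias", {
  # independent oracle for the clean 37th-percentile bias: direct draws from
  # the threshold distribution (no Bekesy, no calibration pipeline)
  withr::with_seed(5, {
    t_draws <- qnorm(runif(2e5, pnorm(-10, 5, 5), pnorm(20, 5, 5)), 5, 5) +
      rnorm(2e5, 0, 2)
    expected_bias <- quantile(t_draws, 0.37, type = 7, names = FALSE) - 5
  })
  withr::with_seed(6, {
    mod <- device_model("m1", rnorm(7, 0, 5), instance_sd = 2)
    crowd <- generate_crowd(500, 0, det_params())
    err <- recover_offset_experiment(mod, crowd, 500)$error
  })
  expect_lt(max(abs(err - expected_bias)), 1.25)
})

test_that("reference recovery breaks down at high contamination", {
  withr::with_seed(7, {
    mod <- device_model("m1", rnorm(7, 0, 5), instance_sd = 2)
    crowd <- generate_crowd(500, 0.6, det_params(), contamination_shift = 30)
    err <- recover_offset_experiment(mod, crowd, 300)$error
  })
  # at 60% contamination the estimator tracks a deep tail quantile of the
  # clean component: errors blow up (analytically ~ +8 dB here), though the
  # tail quantile is noisy frequency by frequency
  expect_gt(mean(err), 5)
  expect_gt(min(err), 2)
})
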