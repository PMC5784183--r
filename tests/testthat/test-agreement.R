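test_that("pairing keeps only cells usable on both sides", {
  a <- random_audiograms(70)
  b <- random_audiograms(70)
  b$scale <- "mHL"
  p <- pair_measurements(a, b)
  expect_equal(nrow(p), 980)

  b2 <- b
  i <- sample(nrow(b2), 13)
  b2$threshold[i] <- NA
  b2$flag[i] <- "above_max"
  p2 <- pair_measurements(a, b2)
  expect_equal(nrow(p2), 967)
  expect_equal(attr(p2, "discarded")[["b"]], 13L)

  a_sub <- dplyr::filter(a, subject_id != "S01")
  expect_error(pair_measurements(a_sub, b), "one side only")

  empty <- a[0, ]
  expect_equal(nrow(pair_measurements(empty, empty)), 0)
})

test_that("mean and SD confidence intervals reproduce the printed summaries", {
  expect_equal(round(mean_diff_ci(2.6, 8.3, 967), 1)[["upper"]], 3.1)
  expect_equal(unname(round(mean_diff_ci(-0.1, 4.4, 952), 1)), c(-0.4, 0.2))
  expect_equal(round(mean_diff_ci(7.0, 9.3, 133), 1)[["upper"]], 8.6)
  ci0 <- mean_diff_ci(0, 3, 50)
  expect_equal(ci0[["lower"]], -ci0[["upper"]])
  expect_error(mean_diff_ci(1, 1, 1), ">= 2")

  expect_equal(unname(round(sd_ci_chi2(8.3, 967), 1)), c(7.9, 8.7))
  expect_equal(unname(round(sd_ci_chi2(4.4, 952), 1)), c(4.2, 4.6))
  expect_equal(unname(sd_ci_chi2(0, 10)), c(0, 0))
})

test_that("agreement summaries report differences, spread and cumulative shares", {
  p0 <- pairs_from_values(c(10, 20, 30, 40), c(10, 20, 30, 40))
  s0 <- summarize_agreement(p0, per_frequency = FALSE)
  expect_equal(s0$mean_diff, 0)
  expect_equal(s0$sd_diff, 0)
  expect_true(all(s0[paste0("pct_le_", c(5, 10, 15, 20, 25, 30))] == 100))

  p1 <- pairs_from_values(c(3, -7, 12), c(0, 0, 0))
  s1 <- format_agreement(summarize_agreement(p1, per_frequency = FALSE))
  expect_equal(s1$pct_le_5, 33)
  expect_equal(s1$pct_le_10, 67)
  expect_equal(s1$pct_le_15, 100)

  # pooled n equals the sum of per-frequency n
  withr::with_seed(1, {
    p <- pairs_from_values(rnorm(140), rnorm(140),
                           frequency = rep(hearing_frequencies(), each = 20))
  })
  s <- summarize_agreement(p)
  expect_equal(s$n[s$frequency == "Total"],
               sum(s$n[s$frequency != "Total"]))
  expect_true(all(diff(as.numeric(
    s[s$frequency == "Total", paste0("pct_le_", c(5, 10, 15, 20, 25, 30))]
  )) >= 0))
})

test_that("swapping the two methods negates the mean and preserves the rest", {
  withr::with_seed(2, {
    p_ab <- pairs_from_values(rnorm(60, 20, 8), rnorm(60, 18, 8),
                              frequency = rep(c(500, 1000, 2000), 20))
  })
  p_ba <- p_ab
  p_ba$value_a <- p_ab$value_b
  p_ba$value_b <- p_ab$value_a
  s_ab <- summarize_agreement(p_ab, per_frequency = FALSE)
  s_ba <- summarize_agreement(p_ba, per_frequency = FALSE)
  expect_equal(s_ab$mean_diff, -s_ba$mean_diff)
  expect_equal(s_ab$sd_diff, s_ba$sd_diff)
  expect_equal(s_ab$mean_abs_diff, s_ba$mean_abs_diff)
  expect_equal(s_ab$icc, s_ba$icc)
  expect_equal(s_ab$pct_le_10, s_ba$pct_le_10)

  # shuffling the record order changes nothing
  s_perm <- summarize_agreement(p_ab[sample(nrow(p_ab)), ],
                                per_frequency = FALSE)
  expect_equal(tibble::as_tibble(s_ab), tibble::as_tibble(s_perm))
})

test_that("consistency ICC matches the two-way ANOVA oracle and its limits", {
  # constant shift between methods: consistency ICC is 1
  withr::with_seed(3, {
    x <- rnorm(30, 20, 10)
  })
  p_shift <- pairs_from_values(x, x + 7)
  expect_equal(icc_consistency(p_shift)$icc, 1)

  # independent sides: ICC near 0
  withr::with_seed(4, {
    p_ind <- pairs_from_values(rnorm(4000), rnorm(4000))
  })
  expect_lt(abs(icc_consistency(p_ind)$icc), 0.06)

  # oracle equivalence on random small instances via stats::aov
  withr::with_seed(5, {
    for (i in 1:15) {
      n <- sample(3:20, 1)
      p <- pairs_from_values(rnorm(n, 10, 6), rnorm(n, 12, 6))
      fit <- icc_consistency(p)
      long <- data.frame(
        y = c(p$value_a, p$value_b),
        row = factor(rep(seq_len(n), 2)),
        col = factor(rep(c("a", "b"), each = n))
      )
      ms <- summary(stats::aov(y ~ row + col, data = long))[[1]][, "Mean Sq"]
      ms_rows <- ms[1]
      ms_err <- ms[3]
      icc_oracle <- (ms_rows - ms_err) / (ms_rows + ms_err)
      expect_equal(fit$icc, icc_oracle, tolerance = 1e-10)
    }
  })

  expect_error(icc_consistency(pairs_from_values(rep(1, 5), rep(1, 5))),
               "zero total variance")
  expect_error(icc_consistency(pairs_from_values(1, 2)), "at least 3")
})

test_that("Cronbach alpha obeys its algebraic link to the consistency ICC", {
  withr::with_seed(6, {
    x <- rnorm(40, 30, 12)
  })
  expect_equal(cronbach_alpha(pairs_from_values(x, x + 5))$alpha, 1)

  withr::with_seed(7, {
    for (i in 1:10) {
      n <- sample(5:50, 1)
      p <- pairs_from_values(rnorm(n, 10, 6), rnorm(n, 12, 6))
      a <- cronbach_alpha(p)
      r <- icc_consistency(p)
      expect_equal(a$alpha, 2 * r$icc / (1 + r$icc), tolerance = 1e-10)
      expect_equal(a$lower, 2 * r$lower / (1 + r$lower), tolerance = 1e-10)
    }
  })

  withr::with_seed(8, {
    p_ind <- pairs_from_values(rnorm(4000), rnorm(4000))
  })
  expect_lt(abs(cronbach_alpha(p_ind)$alpha), 0.12)

  # tidy/glance accessors
  td <- tidy(cronbach_alpha(pairs_from_values(x, x + rnorm(40))))
  expect_named(td, c("term", "estimate", "conf.low", "conf.high"))
})

test_that("Bland-Altman limits bracket the mean difference", {
  p_const <- pairs_from_values(c(15, 25, 35), c(10, 20, 30))
  ba <- bland_altman(p_const, per_frequency = FALSE)
  expect_equal(ba$mean_diff, 5)
  expect_equal(ba$loa_lower, 5)
  expect_equal(ba$loa_upper, 5)

  withr::with_seed(9, {
    p <- pairs_from_values(rnorm(20000), rep(0, 20000))
  })
  ba2 <- bland_altman(p, per_frequency = FALSE)
  expect_equal(ba2$loa_lower, -1.96, tolerance = 0.05)
  expect_equal(ba2$loa_upper, 1.96, tolerance = 0.05)
  expect_true(ba2$loa_lower <= ba2$mean_diff &&
                ba2$mean_diff <= ba2$loa_upper)
})

test_that("the order-effect comparison pools identical groups and splits shifted ones", {
  withr::with_seed(10, {
    d <- rnorm(200, 2, 5)
  })
  same <- order_effect(d, d)
  expect_true(same$pool)
  expect_equal(same$groups$mean_diff, rep(mean(d), 2))

  withr::with_seed(11, {
    g1 <- rnorm(200, 0, 5)
    g2 <- rnorm(200, 10 * 5 / sqrt(200), 5) # shifted by 10 standard errors
  })
  split <- order_effect(g1, g2)
  expect_false(split$pool)
  expect_equal(split$groups$mean_diff[1], mean(g1))
  expect_equal(split$groups$n, c(200L, 200L))
})
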