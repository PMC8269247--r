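test_that("umbrella exact p equals brute-force enumeration", {
  set.seed(31)
  configs <- list(c(2, 2, 2), c(2, 2, 2, 2), c(3, 2, 2), c(2, 3, 2, 2))
  for (sizes in configs) {
    K <- length(sizes)
    values <- rnorm(sum(sizes))
    cls <- rep(seq_len(K), sizes)
    got <- umbrella_rank_test(values, cls)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, oracle_umbrella_test(values, cls),
                 tolerance = 1e-12)
  }
})

test_that("perfect umbrella around a phase class is maximally significant", {
  # 6 classes x 3 obs, cyclically monotone rise to class 3 then fall
  means <- c(2, 3, 5, 4, 2.5, 1.5)
  values <- rep(means, each = 3) + rep(c(-0.01, 0, 0.01), 6)
  cls <- rep(1:6, each = 3)
  got <- umbrella_rank_test(values, cls)
  expect_equal(got$peak_class, "3")
  # the combined p must be at or below 6 x the smallest achievable
  # one-arrangement p for this configuration
  expect_lt(got$p_value, 1e-4)
  # constant series
  expect_equal(umbrella_rank_test(rep(2, 18), cls)$p_value, 1)
  expect_error(umbrella_rank_test(rnorm(4), c(1, 1, 2, 2)), ">= 3")
  expect_error(umbrella_rank_test(rnorm(3), c(1, 2, 3)), ">= 2")
})

test_that("normal approximation tracks the exact tail", {
  set.seed(77)
  sizes <- rep(4, 6)
  cls <- rep(1:6, sizes)
  p_ex <- p_no <- numeric(200)
  for (i in seq_len(200)) {
    v <- rnorm(sum(sizes))
    p_ex[i] <- umbrella_rank_test(v, cls, exact_n_max = 30)$p_value
    p_no[i] <- umbrella_rank_test(v, cls, exact_n_max = 0)$p_value
  }
  expect_lt(max(abs(p_ex - p_no)), 0.06)
  expect_lt(median(abs(p_ex - p_no)), 0.01)
})

test_that("tied observations fall back to the corrected approximation", {
  set.seed(5)
  v <- sample(rep(1:6, 4))  # heavy ties
  got <- umbrella_rank_test(v, rep(1:6, each = 4))
  expect_equal(got$method, "normal")
  expect_true(got$p_value > 0 && got$p_value <= 1)
})

test_that("phase equivariance: rotating the clock rotates the peak", {
  set.seed(12)
  des <- study_design(n_days_per_period = 4)
  tr <- signal_truth("x", baseline = 20, fold_change = 3, peak_hour = 14,
                     noise_cv = 0.1)
  t_hours <- seq(0, 96, by = 4)
  v <- diel_signal(t_hours, tr, des) * rlnorm(25, 0, 0.1)
  clock <- (6 + t_hours) %% 24
  p0 <- umbrella_rank_test(v, factor(clock))
  p4 <- umbrella_rank_test(v, factor((clock + 4) %% 24))
  expect_equal(p0$p_value, p4$p_value)
  expect_equal((as.numeric(p0$peak_class) + 4) %% 24,
               as.numeric(p4$peak_class) %% 24)
  c0 <- cosinor_fit(clock, v)
  c4 <- cosinor_fit((clock + 4) %% 24, v)
  expect_equal((c0$peak_hour + 4) %% 24, c4$peak_hour, tolerance = 1e-6)
})

test_that("bh_fdr implements the step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.1, NA)), "finite")
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  # oracle: stats::p.adjust on random vectors; order invariance
  set.seed(4)
  for (i in 1:25) {
    p <- runif(40)^2
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
    o <- sample(40)
    expect_equal(bh_fdr(p[o]), bh_fdr(p)[o])
  }
})

test_that("cosinor recovers phase and amplitude of clean signals", {
  t <- seq(0, 96, by = 4)
  v <- 5 + 2 * cos(2 * pi * (t - 18) / 24)
  for (h in 1:2) {
    cf <- cosinor_fit(t %% 24, v, harmonics = h)
    expect_equal(cf$peak_hour, 18, tolerance = 0.05)
    expect_equal(cf$amplitude, 2, tolerance = 0.01)
    expect_equal(cf$mesor, 5, tolerance = 0.01)
  }
  cc <- cosinor_fit(t %% 24, rep(3, length(t)))
  expect_true(cc$degenerate)
  expect_equal(cc$amplitude, 0)
  expect_true(is.na(cc$peak_hour))
  expect_error(cosinor_fit(c(1, 2, 3, 4), rnorm(4)), "5 distinct")
})

test_that("cosinor peak error is small at field-like noise", {
  set.seed(9)
  des <- study_design(n_days_per_period = 4)
  t <- seq(0, 96, by = 4)
  errs <- vapply(1:100, function(i) {
    pk <- runif(1, 0, 24)
    tr <- signal_truth("x", baseline = 50, fold_change = 4, peak_hour = pk,
                       noise_cv = 0.2)
    v <- diel_signal(t, tr, des) * rlnorm_cv_oracle(length(t), 0.2)
    cf <- cosinor_fit((6 + t) %% 24, v)
    abs(((cf$peak_hour - pk + 12) %% 24) - 12)
  }, 0)
  expect_lte(median(errs), 2)
})

test_that("daily fold change averages complete 24-h windows", {
  # two days: (max, min) = (10, 4) then (12, 6)
  t <- seq(0, 44, by = 4)
  v <- c(10, 8, 6, 4, 5, 7, 12, 10, 8, 6, 7, 9)
  fc <- daily_fold_change(t, v)
  expect_equal(fc$mean_fold_change, (2.5 + 2) / 2)
  expect_equal(fc$n_windows_used, 2)
  expect_equal(daily_fold_change(t, rep(5, 12))$mean_fold_change, 1)
  expect_error(daily_fold_change(0:3, 1:4, interval = 4), "complete")
  # zero-minimum windows are excluded and counted
  v0 <- v; v0[2] <- 0
  fc0 <- daily_fold_change(t, v0)
  expect_equal(fc0$n_windows_zero_min, 1)
  expect_equal(fc0$mean_fold_change, 2)
  # noiseless F = 4 cosine with peak on a sampled hour -> exactly 4
  des <- study_design()
  tr <- signal_truth("x", baseline = 10, fold_change = 4, peak_hour = 14)
  tt <- seq(0, 96, by = 4)
  vv <- diel_signal(tt, tr, des)
  expect_equal(daily_fold_change(tt, vv)$mean_fold_change, 4,
               tolerance = 1e-12)
})

test_that("power is monotone in fold change", {
  des <- study_design(n_days_per_period = 4)
  t <- seq(0, 96, by = 4)
  clock <- factor((6 + t) %% 24)
  set.seed(2024)
  rej <- vapply(c(1.5, 2, 4, 8), function(F) {
    mean(vapply(1:60, function(i) {
      tr <- signal_truth("x", baseline = 30, fold_change = F,
                         peak_hour = 15, noise_cv = 0.25)
      v <- diel_signal(t, tr, des) * rlnorm_cv_oracle(length(t), 0.25)
      umbrella_rank_test(v, clock)$p_value < 0.05
    }, TRUE))
  }, 0)
  expect_true(all(diff(rej) >= -0.05))  # non-decreasing up to MC noise
  expect_gt(rej[4], rej[1])
})

test_that("classify_signals returns one row per signal and scope", {
  des <- study_design(n_days_per_period = c(2, 2), gap_between_periods = 12)
  tr <- rbind(signal_truth("up", 50, TRUE, 4, 14, 0.05),
              signal_truth("flat", 50, FALSE, 1, 0, 0.05))
  st <- simulate_study(des, tr, seed = 2,
                       model = measurement_model(is_injection_cv = 0))
  fld <- st$samples[st$samples$sample_class == "smp", ]
  ser <- merge(st$areas, fld[, c("sample_id", "t_hours", "clock_hour",
                                 "period")])
  names(ser)[names(ser) == "compound"] <- "signal_id"
  names(ser)[names(ser) == "area"] <- "value"
  rh <- classify_signals(ser, design = des)
  expect_equal(nrow(rh), 2 * 3)
  expect_setequal(unique(rh$scope), c("period1", "period2", "joint"))
  j <- rh[rh$scope == "joint", ]
  expect_true(j$is_diel[j$signal_id == "up"])
  expect_false(j$is_diel[j$signal_id == "flat"])
  expect_equal(j$peak_hour[j$signal_id == "up"], 14, tolerance = 0.5)
  # empty input
  empty <- classify_signals(ser[0, ], design = des)
  expect_equal(nrow(empty), 0)
})
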