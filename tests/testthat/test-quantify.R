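# fixture: small area tables with a controllable injection factor
make_bmis_fixture <- function(inj, noise = NULL, seed = 1) {
  set.seed(seed)
  ids <- paste0("Q", seq_along(inj))
  samples <- data.frame(sample_id = ids, sample_class = "qc",
                        stringsAsFactors = FALSE)
  eps <- if (is.null(noise)) rep(1, length(inj)) else noise
  areas <- data.frame(compound = "cmp", sample_id = ids,
                      area = 1000 * inj * eps, stringsAsFactors = FALSE)
  is_areas <- rbind(
    data.frame(is_name = "IS_good", sample_id = ids, area = 500 * inj),
    data.frame(is_name = "IS_bad", sample_id = ids,
               area = 500 * rev(inj)))
  list(areas = areas, is_areas = is_areas, samples = samples)
}

test_that("BMIS picks the internal standard sharing the injection factor", {
  fx <- make_bmis_fixture(inj = c(0.8, 1.0, 1.3, 0.9))
  out <- bmis_select(fx$areas, fx$is_areas, fx$samples)
  expect_equal(out$choice$is_used, "IS_good")
  expect_equal(out$choice$rsd_best, 0, tolerance = 1e-12)
  # normalized areas are flat across QC samples
  expect_lt(diff(range(out$normalized$area)), 1e-9)
})

test_that("BMIS falls back to none when improvement is below threshold", {
  # modest injection spread, large independent noise: normalization helps
  # but not by 40%
  fx <- make_bmis_fixture(inj = c(0.98, 1.0, 1.02, 1.0),
                          noise = c(0.7, 1.2, 1.0, 1.4))
  out <- bmis_select(fx$areas, fx$is_areas, fx$samples)
  expect_equal(out$choice$is_used, "none")
  expect_false(out$choice$accepted)
  expect_identical(out$normalized$area, fx$areas$area)
})

test_that("BMIS choice equals a brute-force RSD recomputation", {
  set.seed(21)
  inj <- exp(rnorm(5, 0, 0.2))
  fx <- make_bmis_fixture(inj, noise = exp(rnorm(5, 0, 0.05)))
  out <- bmis_select(fx$areas, fx$is_areas, fx$samples,
                     min_improvement = 0)
  # oracle: recompute RSD for each candidate directly
  rsd0 <- function(x) sd(x) / mean(x)
  raw <- fx$areas$area
  cands <- list(none = raw)
  for (nm in unique(fx$is_areas$is_name)) {
    isv <- fx$is_areas$area[fx$is_areas$is_name == nm]
    cands[[nm]] <- raw * mean(isv) / isv
  }
  rsds <- vapply(cands, rsd0, 0)
  expect_equal(out$choice$is_used, names(which.min(rsds)))
  expect_equal(out$choice$rsd_best, min(rsds), tolerance = 1e-12)
})

test_that("isotopologue quantification is exact ratio arithmetic", {
  expect_equal(quant_isotopologue(5000, 10000, 100, 3.5),
               100 / 2 / 3.5, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(as.numeric(quant_isotopologue(0, 10000, 100, 3.5)), 0)
  # ratio invariance under a shared factor
  a <- quant_isotopologue(5000, 10000, 100, 3.5)
  b <- quant_isotopologue(10000, 20000, 100, 3.5)
  expect_equal(as.numeric(a), as.numeric(b))
  z <- quant_isotopologue(c(10, 10), c(0, 5), 100, 3.5)
  expect_true(is.na(z[1]) && !is.na(z[2]))
  expect_equal(attr(z, "flagged"), 1L)
})

test_that("standard addition extrapolates the x-intercept", {
  q <- quant_standard_addition(c(0, 10, 20), c(100, 200, 300), volume = 3.5)
  expect_equal(q$conc_pmol_per_L, 10 / 3.5, tolerance = 1e-9)
  expect_error(quant_standard_addition(c(0, 10, 20), c(100, 100, 100), 3.5),
               "slope")
  expect_error(quant_standard_addition(c(10, 20), c(1, 2), 3.5), ">= 3")
  # negative extrapolation clips to zero with a flag
  qn <- quant_standard_addition(c(0, 10, 20), c(-50, 60, 150), 1)
  expect_equal(qn$conc_pmol_per_L, 0)
  expect_true("negative_intercept" %in% qn$flags)
})

test_that("standard addition CI covers the truth (simulation)", {
  set.seed(8)
  lev <- c(0, 50, 100, 150)
  truth <- 40  # endogenous pmol
  cover <- vapply(1:1000, function(i) {
    resp <- 12 * (truth + lev) * exp(rnorm(4, 0, 0.02))
    q <- quant_standard_addition(lev, resp, volume = 1)
    abs(q$conc_pmol_per_L - truth) < 3 * q$se
  }, TRUE)
  expect_gte(mean(cover), 0.97)
})

test_that("matrix-matched external calibration corrects suppression", {
  q <- quant_matrix_external(50, rf_water = 10, rf_matrix = 5, volume = 1)
  expect_equal(q$conc_pmol_per_L, 10)
  expect_equal(q$suppression_factor, 0.5)
  # suppression 1: identical to water calibration
  q2 <- quant_matrix_external(50, 10, 10, 1)
  expect_equal(q2$conc_pmol_per_L, 50 / 10 / 1)
  expect_error(quant_matrix_external(50, 10, 0, 1), "> 0")
  expect_equal(response_factor_matrix(100, 200, 20), 5)
})

test_that("blank flagging matches a direct recomputation", {
  samples <- data.frame(sample_id = c("A", "B", "K1"),
                        sample_class = c("smp", "smp", "blk"))
  areas <- data.frame(compound = rep(c("lo", "hi"), each = 3),
                      sample_id = rep(c("A", "B", "K1"), 2),
                      area = c(2, 2, 1, 100, 80, 1))
  fl <- blank_flag(areas, samples, ratio_threshold = 3)
  expect_equal(fl$blank_flag[fl$compound == "lo"], "flagged")
  expect_equal(fl$blank_flag[fl$compound == "hi"], "pass")
  # blank mean zero passes everything
  areas0 <- areas; areas0$area[areas0$sample_id == "K1"] <- 0
  expect_true(all(blank_flag(areas0, samples)$blank_flag == "pass"))
  # no blanks -> not evaluated
  s2 <- samples[samples$sample_class == "smp", ]
  expect_true(all(blank_flag(areas[areas$sample_id != "K1", ], s2)$blank_flag
                  == "not_evaluated"))
})

test_that("noise-free studies are quantified exactly (round trip)", {
  des <- study_design(n_days_per_period = 2)
  tr <- example_metabolite_truths(n_signals = 10, n_diel = 6, noise_cv = 0)
  tr$peak_hour <- 14  # on the sampling grid
  # all noise off: BMIS's QC-mean anchoring introduces no scale bias
  mod <- measurement_model(is_injection_cv = 0, matrix_suppression = 0.6)
  st <- simulate_study(des, tr, model = mod, seed = 5)
  conc <- suppressMessages(quantify_study(st))
  m <- merge(conc$concentrations, truth_concentrations(st))
  expect_lt(max(abs(m$pmol_per_L / m$truth - 1)), 1e-9)
  # and the rhythm stage then recovers fold change and peak hour exactly
  rh <- classify_signals(as_series(conc$concentrations), design = des,
                         scopes = "joint")
  cm <- merge(rh, tr, by.x = "signal_id", by.y = "signal_id",
              suffixes = c("_est", "_true"))
  diel <- cm$fold_change_true > 1
  expect_equal(cm$fold_change_est[diel], cm$fold_change_true[diel],
               tolerance = 1e-9)
  expect_true(all(abs(cm$peak_hour_est[diel] - 14) < 1e-6))
  expect_equal(cm$mesor[diel] / cm$baseline[diel], rep(1, sum(diel)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("quantification error stays below the replicate noise", {
  des <- study_design(n_days_per_period = 2)
  tr <- example_metabolite_truths(n_signals = 12, n_diel = 8, noise_cv = 0.2)
  mod <- measurement_model(is_injection_cv = 0.1, matrix_suppression = 0.5)
  st <- simulate_study(des, tr, model = mod, seed = 17)
  conc <- suppressMessages(quantify_study(st))
  m <- merge(conc$concentrations, truth_concentrations(st))
  expect_lt(median(abs(m$pmol_per_L / m$truth - 1), na.rm = TRUE), 0.2)
})
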