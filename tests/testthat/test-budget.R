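test_that("composition fractions reconcile pmol and umol scales", {
  f <- composition_fraction(1000, n_carbon = 12, n_nitrogen = 0,
                            poc_umol = 3.5)
  expect_equal(f$pct_poc, 12 / 3500 * 100, tolerance = 1e-12)
  expect_equal(f$pct_pn, 0)
  expect_error(composition_fraction(10, 6, 0, poc_umol = 0), "POC")
  expect_error(composition_fraction(10, 6, 2, poc_umol = 1, pn_umol = 0),
               "PN")
  # additivity: summed per-compound %POC equals the pooled-carbon %POC
  conc <- c(100, 250, 40)
  nc <- c(6, 12, 3)
  per <- composition_fraction(conc, nc, rep(0, 3), poc_umol = 2)$pct_poc
  pooled <- composition_fraction(sum(conc * nc), 1, 0, poc_umol = 2)$pct_poc
  expect_equal(sum(per), pooled, tolerance = 1e-12)
})

test_that("net turnover converts daily swings to elemental fluxes", {
  t <- seq(0, 44, by = 4)
  med <- data.frame(compound = "trehalose", t_hours = t,
                    clock_hour = t %% 24, period = 1,
                    median_pmol_per_L = c(10, 8, 6, 4, 5, 7,
                                          10, 8, 6, 4, 5, 7))
  cmp <- data.frame(name = "trehalose", n_carbon = 12, n_nitrogen = 0)
  nt <- net_turnover(med, cmp, interval = 4)
  expect_equal(nt$flux$swing_pmol_per_L_d, 6)
  expect_equal(nt$flux$carbon_pmol_per_L_d, 72)
  expect_equal(nt$total_carbon_nmol_per_L_d, 0.072)
  # constant compound has zero flux
  med$median_pmol_per_L <- 5
  expect_equal(net_turnover(med, cmp, interval = 4)$flux$swing_pmol_per_L_d,
               0)
})

test_that("turnover totals equal the sum of parts (additivity)", {
  set.seed(6)
  t <- seq(0, 92, by = 4)
  meds <- do.call(rbind, lapply(1:10, function(i)
    data.frame(compound = sprintf("c%02d", i), t_hours = t,
               clock_hour = (6 + t) %% 24, period = 1,
               median_pmol_per_L = runif(length(t), 1, 50))))
  cmp <- data.frame(name = sprintf("c%02d", 1:10), n_carbon = 1:10,
                    n_nitrogen = rep(0:1, 5))
  nt <- net_turnover(meds, cmp, interval = 4)
  expect_equal(nt$total_carbon_nmol_per_L_d,
               sum(nt$flux$carbon_pmol_per_L_d) / 1000, tolerance = 1e-12)
  sub <- net_turnover(meds, cmp, include = c("c01", "c03"), interval = 4)
  sel <- sub$flux$compound %in% c("c01", "c03")
  expect_equal(sub$total_carbon_nmol_per_L_d,
               sum(sub$flux$carbon_pmol_per_L_d[sel]) / 1000)
})

test_that("quota attribution predicts pools and round-trips quotas", {
  qa <- quota_attribution(pool_pmol_per_L = 128, cells_per_L = 0.16e6,
                          quota_light_fmol = 0.8, quota_dark_fmol = 0.07)
  expect_equal(qa$predicted_light_pmol_per_L, 128)
  expect_equal(qa$field_quota_fmol_per_cell, 0.8)
  expect_equal(quota_attribution(0, 1e5, 0.8, 0.07)$field_quota_fmol_per_cell,
               0)
  # round trip: pool built from a known quota series returns that quota
  set.seed(3)
  cells <- runif(20, 2e4, 8e5)
  quota <- runif(20, 0.07, 0.8)
  pool <- cells * quota / 1000
  rt <- quota_attribution(pool, cells, 0.8, 0.07)
  expect_equal(rt$field_quota_fmol_per_cell, quota, tolerance = 1e-12)
  # zero abundance flagged
  z <- quota_attribution(c(10, 10), c(0, 1e5), 0.8, 0.07)
  expect_equal(z$zero_abundance, 1L)
  expect_true(is.na(z$field_quota_fmol_per_cell[1]))
  # carbon-normalized content
  qc <- quota_attribution(274, 1.6e5, 0.8, 0.07, molar_mass_g = 342.3,
                          ugC_per_L = 0.24)
  expect_equal(qc$mg_per_g_cell_carbon, 274 * 342.3 * 1e-3 / 0.24,
               tolerance = 1e-12)
})

test_that("the nitrogen-fixation budget takes the limiting constraint", {
  p <- stoichiometry_params()  # atp 30/16 vs electrons 24/8: ATP limits
  r <- n2_fixation_fraction(trehalose_swing = 1e-9,
                            n2_fixation_rate = 1e-8, params = p)
  glc <- 1e-9 * 2
  expect_equal(r$unadjusted_pct, 100 * glc * 30 / 16 / 1e-8)
  expect_equal(r$limiting, "atp")
  expect_equal(r$adjusted_pct, r$unadjusted_pct * 0.4)
  # electron-limited parameterization
  p2 <- stoichiometry_params(atp_per_glucose = 100)
  r2 <- n2_fixation_fraction(1e-9, 1e-8, p2)
  expect_equal(r2$limiting, "electrons")
  expect_equal(r2$unadjusted_pct, 100 * glc * 24 / 8 / 1e-8)
  # monotone in swing, antitone in fixation rate; adjusted <= unadjusted
  a <- n2_fixation_fraction(2e-9, 1e-8)$unadjusted_pct
  b <- n2_fixation_fraction(1e-9, 1e-8)$unadjusted_pct
  c <- n2_fixation_fraction(1e-9, 2e-8)$unadjusted_pct
  expect_gt(a, b); expect_gt(b, c)
  expect_error(n2_fixation_fraction(1e-9, 0), "> 0")
})

test_that("oxygen-drawdown adjustment is the stated linear discount", {
  expect_equal(adjust_o2_drawdown(9), 3.6)
  expect_equal(adjust_o2_drawdown(28), 11.2)
  expect_equal(adjust_o2_drawdown(5, 0), 5)
  expect_error(adjust_o2_drawdown(5, 1), "0, 1")
})

test_that("type II regression is the geometric-mean line", {
  x <- 1:10
  y <- 2 * x + 1
  r <- type2_regression(x, y)
  expect_equal(r$slope, 2); expect_equal(r$intercept, 1)
  expect_equal(r$r, 1)
  # swapping axes inverts the slope
  set.seed(11)
  x <- rnorm(30); y <- 1.5 * x + rnorm(30, 0, 0.5)
  a <- type2_regression(x, y); b <- type2_regression(y, x)
  expect_equal(a$slope, 1 / b$slope, tolerance = 1e-12)
  # oracle: slope magnitude = sqrt(Syy / Sxx)
  expect_equal(abs(a$slope),
               sqrt(sum((y - mean(y))^2) / sum((x - mean(x))^2)),
               tolerance = 1e-12)
  expect_error(type2_regression(rep(1, 5), 1:5), "variance")
})
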