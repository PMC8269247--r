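test_that("transcript aggregation group-sums and drops KO-less rows", {
  contigs <- data.frame(
    taxon = c("A", "A", "A", "B", "B"),
    ko = c("K1", "K1", NA, "K1", "K2"),
    sample_id = c("s1", "s1", "s1", "s1", "s1"),
    abundance = c(3, 5, 99, 2, 7))
  expect_warning(agg <- suppressMessages(aggregate_transcripts(contigs)),
                 "duplicate")
  expect_equal(agg$abundance[agg$taxon == "A" & agg$ko == "K1"], 8)
  expect_equal(attr(agg, "n_dropped_no_ko"), 1L)
  expect_equal(nrow(agg), 3)
  # oracle: nested-loop aggregation on a random fixture
  set.seed(14)
  big <- data.frame(taxon = sample(c("A", "B", "C"), 60, TRUE),
                    ko = sample(c("K1", "K2"), 60, TRUE),
                    sample_id = sample(c("s1", "s2"), 60, TRUE),
                    abundance = runif(60))
  got <- suppressWarnings(suppressMessages(aggregate_transcripts(big)))
  for (r in seq_len(nrow(got))) {
    sel <- big$taxon == got$taxon[r] & big$ko == got$ko[r] &
      big$sample_id == got$sample_id[r]
    expect_equal(got$abundance[r], sum(big$abundance[sel]))
  }
})

test_that("circular lag wraps into (-12, 12] with the +12 boundary", {
  expect_equal(circular_lag(18, 2), 8)
  expect_equal(circular_lag(5, 5), 0)
  expect_equal(circular_lag(6, 18), 12)
  expect_equal(circular_lag(18, 6), 12)  # boundary maps to +12 either way
  # antisymmetry away from the boundary
  set.seed(2)
  a <- runif(50, 0, 24); b <- runif(50, 0, 24)
  la <- circular_lag(a, b); lb <- circular_lag(b, a)
  off <- abs(la) < 12 - 1e-9
  expect_equal(la[off], -lb[off])
})

test_that("link join has the expected cardinality and reports unlinked", {
  met <- data.frame(signal_id = c("m1", "m2"), is_diel = c(TRUE, TRUE),
                    peak_hour = c(14, 18))
  tra <- expand.grid(taxon = c("A", "B", "C"), ko = c("K1", "K2"),
                     stringsAsFactors = FALSE)
  tra$signal_id <- paste(tra$taxon, tra$ko, sep = "|")
  tra$is_diel <- TRUE
  tra$peak_hour <- 20
  links <- data.frame(metabolite = "m1", kegg_compound_id = "C1",
                      ko_id = c("K1", "K2"), role = "produces")
  lk <- link_and_classify(links, tra, met)
  expect_equal(nrow(lk$pairs), 6)  # 1 metabolite x 2 KOs x 3 taxa
  expect_equal(lk$unlinked, "m2")
  expect_true(all(lk$pairs$lag_hours == circular_lag(14, 20)))
  expect_equal(lk$metabolite_summary$n_links[
    lk$metabolite_summary$metabolite == "m1"], 6)
  # empty link table: everything unlinked
  lk0 <- link_and_classify(links[0, ], tra, met)
  expect_setequal(lk0$unlinked, c("m1", "m2"))
  # unknown metabolite skipped with a warning
  badlinks <- rbind(links, data.frame(metabolite = "ghost",
                                      kegg_compound_id = "C9",
                                      ko_id = "K1", role = "both"))
  expect_warning(link_and_classify(badlinks, tra, met), "ghost")
})

test_that("peak-time association handles locked and uniform lags", {
  # transcripts peaking exactly at metabolite peaks: r = 1, all lags 0
  set.seed(8)
  m <- runif(20, 10, 20)
  a <- peak_time_association(m, m)
  expect_equal(a$pearson_r, 1, tolerance = 1e-12)
  expect_true(all(a$lags == 0))
  expect_error(peak_time_association(c(1, 2), c(3, 4)), ">= 3")
  # lags uniform by construction (independent transcript peaks): the raw
  # Pearson is rarely significant
  sig <- vapply(1:300, function(i) {
    mm <- runif(15, 0, 24)
    tt <- (mm + runif(15, -12, 12)) %% 24
    peak_time_association(mm, tt)$pearson_p < 0.05
  }, TRUE)
  expect_lte(mean(sig), 0.10)
})

test_that("phase-locked transcripts put the lag mode at the true offset", {
  des <- study_design(n_days_per_period = 4)
  set.seed(19)
  tr <- example_metabolite_truths(n_signals = 8, n_diel = 8,
                                  noise_cv = 0.1)
  lag_true <- 6
  trt <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
    tt <- example_transcript_truths(paste0("taxon", i), "K00001",
                                    frac_diel = 1,
                                    peak_hours = tr$peak_hour[i] + lag_true,
                                    noise_cv = 0.1)
    tt
  }))
  st <- simulate_study(des, tr, seed = 20, transcript_truths = trt)
  # classify both layers
  fld <- st$samples[st$samples$sample_class == "smp", ]
  conc <- suppressMessages(quantify_study(st))
  met_rh <- classify_signals(as_series(conc$concentrations), design = des,
                             scopes = "period1")
  tser <- merge(st$transcripts,
                fld[, c("sample_id", "t_hours", "clock_hour", "period")])
  tser$signal_id <- paste(tser$taxon, tser$ko, sep = "|")
  names(tser)[names(tser) == "abundance"] <- "value"
  tr_rh <- classify_signals(tser, design = des, scopes = "period1")
  links <- data.frame(metabolite = tr$signal_id, kegg_compound_id = "C",
                      ko_id = "K00001", role = "produces")
  lk <- link_and_classify(links, tr_rh, met_rh)
  # each metabolite matches all 8 taxa through the shared KO; keep the
  # taxon generated from it
  own <- lk$pairs[lk$pairs$taxon == paste0("taxon",
                                           match(lk$pairs$metabolite,
                                                 tr$signal_id)), ]
  a <- peak_time_association(own$metabolite_peak_hour,
                             own$transcript_peak_hour)
  hist <- a$lag_histogram
  modal <- hist[which.max(hist$count), ]
  expect_true(modal$bin_low <= lag_true && lag_true <= modal$bin_high)
})
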