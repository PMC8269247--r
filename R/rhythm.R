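# Nonparametric 24-h rhythm detection.
#
# The test statistic for a candidate peak phase is the umbrella (rise-then-
# fall) Jonckheere-Terpstra-type sum of pairwise Mann-Whitney counts over
# the phase classes arranged in cyclic order from the antiphase (trough)
# class up to the peak and back down.  Its exact null distribution is the
# convolution of three independent components: the Mann-Whitney count of
# the peak class against everything else, and one Jonckheere-Terpstra
# distribution per arm (peak class excluded).  That decomposition is exact
# for tie-free data and is verified against brute-force enumeration in the
# test suite.  P-values for the K candidate peak phases are combined by
# Bonferroni, which is conservative under their positive dependence.

# -- exact null machinery -----------------------------------------------

# counts of the Mann-Whitney statistic when interleaving m "old" and n "new"
# observations: Gaussian binomial [m+n, n]_q coefficients
#' @noRd
mw_counts <- function(m, n) {
  if (m == 0 || n == 0) return(1)
  G <- vector("list", n + 1)
  for (j in 0:n) G[[j + 1]] <- 1
  for (i in seq_len(m)) {
    Gnew <- vector("list", n + 1)
    Gnew[[1]] <- 1
    for (j in seq_len(n)) {
      a <- G[[j + 1]]        # element i is "old", placed last: adds 0
      b <- Gnew[[j]]         # element j is "new", all i old below: adds i
      v <- rep(0, i * j + 1)
      v[seq_along(a)] <- a
      idx <- (i + 1):(i + length(b))
      v[idx] <- v[idx] + b
      Gnew[[j + 1]] <- v
    }
    G <- Gnew
  }
  G[[n + 1]]
}

#' @noRd
poly_conv <- function(a, b) {
  if (length(a) == 1) return(a * b)
  if (length(b) == 1) return(b * a)
  out <- rep(0, length(a) + length(b) - 1)
  for (i in seq_along(a)) if (a[i] != 0) {
    idx <- i:(i + length(b) - 1)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# Jonckheere-Terpstra null counts for groups of the given sizes
#' @noRd
jt_counts <- function(sizes) {
  tot <- 1; M <- 0
  for (s in sizes) {
    tot <- poly_conv(tot, mw_counts(M, s))
    M <- M + s
  }
  tot
}

# cyclic arrangement for candidate peak class k of K: classes listed from
# the trough class rising to the peak, then falling; peak sits at position
# floor(K/2) + 1
#' @noRd
umbrella_arrangement <- function(k, K) {
  (((k - 1 + ceiling(K / 2)) + 0:(K - 1)) %% K) + 1
}

# memoized exact null survival function P(A >= a), a = 0..max
.null_cache <- new.env(parent = emptyenv())
#' @noRd
umbrella_null_survival <- function(sizes, q) {
  key <- paste(c(sizes, "q", q), collapse = ",")
  hit <- .null_cache[[key]]
  if (!is.null(hit)) return(hit)
  N <- sum(sizes)
  C <- mw_counts(N - sizes[q], sizes[q])
  up <- if (q > 1) jt_counts(sizes[1:(q - 1)]) else 1
  dn <- if (q < length(sizes)) jt_counts(sizes[length(sizes):(q + 1)]) else 1
  cnt <- poly_conv(poly_conv(C, up), dn)
  surv <- rev(cumsum(rev(cnt / sum(cnt))))
  .null_cache[[key]] <- surv
  surv
}

# umbrella statistic for groups (list of numeric vectors) in arrangement
# order with peak position q; ties count 0.5
#' @noRd
umbrella_statistic <- function(groups, q) {
  K <- length(groups)
  A <- 0
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    counted_up <- j <= q
    counted_dn <- i >= q
    if (!counted_up && !counted_dn) next
    lo <- if (counted_up) groups[[i]] else groups[[j]]
    hi <- if (counted_up) groups[[j]] else groups[[i]]
    A <- A + sum(outer(lo, hi, "<")) + 0.5 * sum(outer(lo, hi, "=="))
  }
  A
}

# JT-style variance (tie-free) for a set of group sizes
#' @noRd
jt_var <- function(sizes) {
  N <- sum(sizes)
  (N^2 * (2 * N + 3) - sum(sizes^2 * (2 * sizes + 3))) / 72
}

#' Umbrella rank test for 24-h periodicity
#'
#' Tests whether observations grouped by clock-phase class follow a
#' rise-then-fall (umbrella) pattern around some peak phase.  For each of
#' the K candidate peak classes the umbrella statistic is computed on the
#' classes arranged cyclically from trough to peak to trough; p-values are
#' exact (convolution of the tie-free null) when the total sample size is
#' at most \code{exact_n_max} and there are no ties, and use a normal
#' approximation with a global tie correction otherwise.  The K per-phase
#' p-values are combined by Bonferroni.
#'
#' @param values Numeric observations (e.g. per-time-point triplicate
#'   medians pooled across days within one analysis period).
#' @param phase_class Integer or factor assigning each observation to a
#'   clock-phase class; class levels must be in cyclic (clock) order.
#' @param exact_n_max Largest total n for the exact null (default 30).
#' @return List: \code{p_value} (Bonferroni-combined), \code{p_per_phase},
#'   \code{peak_class} (argmin phase), \code{method} ("exact" or "normal").
#' @export
umbrella_rank_test <- function(values, phase_class, exact_n_max = 30) {
  keep <- is.finite(values)
  values <- values[keep]
  phase_class <- factor(phase_class[keep])
  K <- nlevels(phase_class)
  if (K < 3) stop("umbrella test needs >= 3 phase classes")
  groups <- split(values, phase_class)
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("umbrella test needs >= 2 observations per class")
  N <- sum(sizes)
  if (length(unique(values)) == 1)
    return(list(p_value = 1, p_per_phase = rep(1, K), peak_class = NA,
                method = "degenerate"))
  has_ties <- anyDuplicated(values) > 0
  exact <- !has_ties && N <= exact_n_max
  q <- floor(K / 2) + 1
  p_phase <- numeric(K)
  for (k in seq_len(K)) {
    ord <- umbrella_arrangement(k, K)
    A <- umbrella_statistic(groups[ord], q)
    n_ord <- sizes[ord]
    if (exact) {
      surv <- umbrella_null_survival(n_ord, q)
      p_phase[k] <- surv[min(round(A), length(surv) - 1) + 1]
    } else {
      # counted ordered pairs: within-up (incl. peak) and within-down
      up <- n_ord[1:q]; dn <- n_ord[q:K]
      npairs <- (sum(up)^2 - sum(up^2)) / 2 + (sum(dn)^2 - sum(dn^2)) / 2
      mu <- npairs / 2
      # independent components: MW(peak vs rest) + JT(up arm) + JT(down arm)
      v <- n_ord[q] * (N - n_ord[q]) * (N + 1) / 12 +
        jt_var(n_ord[1:(q - 1)]) + jt_var(n_ord[K:(q + 1)])
      if (has_ties) {
        tt <- table(values)
        v <- v * (1 - sum(tt^3 - tt) / (N^3 - N))
      }
      z <- (A - mu - 0.5) / sqrt(v)
      p_phase[k] <- stats::pnorm(z, lower.tail = FALSE)
    }
  }
  list(p_value = min(1, K * min(p_phase)), p_per_phase = p_phase,
       peak_class = levels(phase_class)[which.min(p_phase)],
       method = if (exact) "exact" else "normal")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up procedure; returns monotone q-values with q >= p elementwise.
#'
#' @param p_values Numeric vector of p-values in [0, 1] (no NAs).
#' @return Vector of q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (!all(is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must be finite and in [0, 1]")
  n <- length(p_values)
  if (n == 0) return(numeric(0))
  o <- order(p_values, decreasing = TRUE)
  q <- pmin(1, cummin(n / (n:1) * p_values[o]))
  q[order(o)]
}

#' Cosinor (harmonic regression) fit
#'
#' Least squares of \code{mesor + sum_h a_h cos(2 pi h t / P) + b_h
#' sin(2 pi h t / P)}.  For a single harmonic the peak is closed-form
#' (\code{atan2}); with two harmonics the fitted curve is scanned over one
#' cycle at 0.1-h resolution.  Amplitude is half the fitted peak-to-trough
#' range.
#'
#' @param times Sampling times, hours (clock hours or hours since start;
#'   the returned \code{peak_hour} is on the same clock, wrapped mod P).
#' @param values Observations.
#' @param period Cycle length, hours (default 24).
#' @param harmonics 1 (default) or 2.
#' @return List: \code{mesor}, \code{amplitude}, \code{peak_hour},
#'   \code{p_value} (F-test of the rhythmic terms), \code{degenerate} flag
#'   (constant input: amplitude 0, peak undefined).
#' @export
cosinor_fit <- function(times, values, period = 24, harmonics = 1) {
  keep <- is.finite(values) & is.finite(times)
  times <- times[keep]; values <- values[keep]
  if (length(unique(times)) < 5)
    stop("cosinor needs >= 5 distinct time points")
  if (!harmonics %in% c(1, 2)) stop("harmonics must be 1 or 2")
  if (length(unique(values)) == 1)
    return(list(mesor = values[1], amplitude = 0, peak_hour = NA_real_,
                p_value = 1, degenerate = TRUE))
  X <- matrix(1, length(times), 1)
  for (h in seq_len(harmonics))
    X <- cbind(X, cos(2 * pi * h * times / period),
               sin(2 * pi * h * times / period))
  fit <- stats::lm.fit(X, values)
  if (fit$rank < ncol(X)) stop("cosinor design matrix is rank deficient")
  cf <- fit$coefficients
  if (harmonics == 1) {
    amp <- sqrt(cf[2]^2 + cf[3]^2)
    peak <- wrap_hour(atan2(cf[3], cf[2]) * period / (2 * pi)) %% period
  } else {
    grid <- seq(0, period, by = 0.1)
    Xg <- cbind(1, cos(2 * pi * grid / period), sin(2 * pi * grid / period),
                cos(4 * pi * grid / period), sin(4 * pi * grid / period))
    yg <- drop(Xg %*% cf)
    amp <- (max(yg) - min(yg)) / 2
    peak <- grid[which.max(yg)] %% period
  }
  # F test: rhythmic terms vs intercept-only
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum((values - mean(values))^2)
  df1 <- 2 * harmonics
  df2 <- length(values) - ncol(X)
  pval <- if (df2 > 0 && rss1 > 0)
    stats::pf((rss0 - rss1) / df1 / (rss1 / df2), df1, df2,
              lower.tail = FALSE) else NA_real_
  list(mesor = unname(cf[1]), amplitude = unname(amp),
       peak_hour = unname(peak), p_value = pval, degenerate = FALSE)
}

#' Mean daily fold change of a median series
#'
#' Partitions the series into consecutive 24-h windows, computes
#' max/min of the per-time-point medians within each complete window, and
#' averages across windows.  Windows whose minimum is zero are excluded
#' and counted.
#'
#' @param t_hours Time points, hours since period start.
#' @param values Per-time-point medians.
#' @param start_clock_hour Clock hour of \code{t = 0} (default 0).
#' @param window_start_hour Clock hour at which daily windows begin;
#'   default is the first sample's clock hour.
#' @param interval Sampling interval in hours; inferred from the time grid
#'   when NULL.  A window is complete when it contains \code{24 / interval}
#'   time points.
#' @return List: \code{mean_fold_change}, \code{n_windows_used},
#'   \code{n_windows_zero_min}, \code{per_window} (data.frame).
#' @export
daily_fold_change <- function(t_hours, values, start_clock_hour = 0,
                              window_start_hour = NULL, interval = NULL) {
  o <- order(t_hours)
  t_hours <- t_hours[o]; values <- values[o]
  interval <- interval %||% min(diff(unique(t_hours)))
  offset <- if (is.null(window_start_hour)) t_hours[1] else
    t_hours[1] + wrap_hour(window_start_hour - start_clock_hour - t_hours[1])
  widx <- floor((t_hours - offset) / 24)
  per_day <- 24 / interval
  res <- list()
  for (w in sort(unique(widx[widx >= 0]))) {
    v <- values[widx == w]
    if (length(v) < per_day) next  # incomplete window
    res[[length(res) + 1]] <- data.frame(window = w, max = max(v),
                                         min = min(v))
  }
  if (length(res) == 0) stop("no complete 24-h window in series")
  pw <- do.call(rbind, res)
  usable <- pw$min > 0
  if (!any(usable))
    return(list(mean_fold_change = NA_real_, n_windows_used = 0,
                n_windows_zero_min = sum(!usable), per_window = pw))
  list(mean_fold_change = mean(pw$max[usable] / pw$min[usable]),
       n_windows_used = sum(usable), n_windows_zero_min = sum(!usable),
       per_window = pw)
}

#' Classify signals as diel or not, with peak and fold-change estimates
#'
#' Per analysis scope ("period1", "period2", "joint") and per signal:
#' collapses replicates to per-time-point medians, pools the medians by
#' clock-phase class across days, runs the umbrella rank test, adjusts
#' p-values across signals by Benjamini-Hochberg within the scope, and
#' estimates peak clock hour and amplitude by cosinor and mean daily fold
#' change from the median series.
#'
#' @param series Long data.frame: \code{signal_id}, \code{t_hours},
#'   \code{clock_hour}, \code{period}, \code{value}; replicate rows at the
#'   same time point are collapsed by median.
#' @param design A \code{\link{study_design}} (used for the window
#'   bookkeeping); optional, defaults to \code{study_design()}.
#' @param alpha FDR threshold for the diel flag (default 0.05).
#' @param scopes Which analysis sets to run (default all three).
#' @param harmonics Cosinor harmonics (default 1).
#' @param window_start_hour Passed to \code{\link{daily_fold_change}}.
#' @param exact_n_max Passed to \code{\link{umbrella_rank_test}}.
#' @return Data.frame: one row per signal x scope with \code{p_raw},
#'   \code{q_fdr}, \code{is_diel}, \code{peak_hour}, \code{amplitude},
#'   \code{mesor}, \code{fold_change}, \code{n_windows_used}.
#' @export
classify_signals <- function(series, design = study_design(), alpha = 0.05,
                             scopes = c("period1", "period2", "joint"),
                             harmonics = 1, window_start_hour = NULL,
                             exact_n_max = 30) {
  stopifnot(all(c("signal_id", "t_hours", "clock_hour", "period", "value")
                %in% names(series)))
  ids <- unique(series$signal_id)
  if (length(ids) == 0) {
    return(data.frame(signal_id = character(0), scope = character(0),
                      n_obs = integer(0), p_raw = numeric(0),
                      q_fdr = numeric(0), is_diel = logical(0),
                      peak_hour = numeric(0), amplitude = numeric(0),
                      mesor = numeric(0), fold_change = numeric(0),
                      n_windows_used = integer(0)))
  }
  periods_present <- sort(unique(series$period))
  out <- list()
  for (sc in scopes) {
    per <- switch(sc, period1 = 1L, period2 = 2L, joint = periods_present,
                  stop("unknown scope: ", sc))
    if (!all(per %in% periods_present)) next
    sub <- series[series$period %in% per, ]
    rows <- vector("list", length(ids))
    pvec <- rep(NA_real_, length(ids))
    for (i in seq_along(ids)) {
      ss <- sub[sub$signal_id == ids[i], ]
      med <- stats::aggregate(value ~ t_hours + clock_hour + period,
                              data = ss, FUN = stats::median, na.rm = TRUE)
      med <- med[order(med$t_hours), ]
      # one umbrella test on the scope's pooled medians: both periods share
      # the same 4-h clock grid, so their medians fall in the same classes
      ut <- tryCatch(
        umbrella_rank_test(med$value, factor(med$clock_hour),
                           exact_n_max = exact_n_max),
        error = function(e) NULL)
      pvec[i] <- if (is.null(ut)) NA_real_ else ut$p_value
      cf <- tryCatch(cosinor_fit(med$clock_hour, med$value,
                                 harmonics = harmonics),
                     error = function(e) list(mesor = NA_real_,
                                              amplitude = NA_real_,
                                              peak_hour = NA_real_))
      fc <- tryCatch({
        fcs <- lapply(unique(med$period), function(p) {
          m <- med[med$period == p, ]
          daily_fold_change(m$t_hours, m$value,
                            start_clock_hour = m$clock_hour[1] - m$t_hours[1],
                            window_start_hour = window_start_hour,
                            interval = design$sampling_interval)
        })
        nw <- vapply(fcs, `[[`, 0, "n_windows_used")
        mf <- vapply(fcs, `[[`, 0, "mean_fold_change")
        ok <- nw > 0 & is.finite(mf)
        list(mean_fold_change = if (any(ok))
          sum(mf[ok] * nw[ok]) / sum(nw[ok]) else NA_real_,
          n_windows_used = sum(nw))
      }, error = function(e) list(mean_fold_change = NA_real_,
                                  n_windows_used = 0L))
      rows[[i]] <- data.frame(
        signal_id = ids[i], scope = sc, n_obs = nrow(med),
        p_raw = pvec[i], peak_hour = cf$peak_hour, amplitude = cf$amplitude,
        mesor = cf$mesor, fold_change = fc$mean_fold_change,
        n_windows_used = fc$n_windows_used, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    ok <- is.finite(tab$p_raw)
    tab$q_fdr <- NA_real_
    tab$q_fdr[ok] <- bh_fdr(tab$p_raw[ok])
    tab$is_diel <- !is.na(tab$q_fdr) & tab$q_fdr < alpha
    out[[sc]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("signal_id", "scope", "n_obs", "p_raw", "q_fdr", "is_diel",
          "peak_hour", "amplitude", "mesor", "fold_change",
          "n_windows_used")]
}
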