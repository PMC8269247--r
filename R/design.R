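#' Define a diel sampling design
#'
#' Describes a cruise-style sampling campaign: samples are collected every
#' \code{sampling_interval} hours, in \code{n_replicates} biological
#' replicates, over one or more multi-day periods separated by a gap.  The
#' default reproduces a two-period design (4 days then 3 days, 4-h
#' resolution, triplicates, 3.5 L filtered per sample) starting at 06:00,
#' which yields 25 and 19 time points respectively.
#'
#' @param start_clock_hour Clock hour in [0, 24) at which the first period
#'   starts (default 6, i.e. 06:00).
#' @param sampling_interval Hours between consecutive time points; must
#'   divide 24 (default 4).
#' @param n_days_per_period Integer vector, days spanned by each sampling
#'   period (default \code{c(4, 3)}).  A period of d days has
#'   \code{d * 24 / sampling_interval + 1} time points (both endpoints
#'   sampled).
#' @param gap_between_periods Hours between the end of one period and the
#'   start of the next (default 36, which moves a 06:00 start to an 18:00
#'   start for the second period).
#' @param n_replicates Biological replicates per time point (default 3).
#' @param volume_filtered Liters of water filtered per sample (default 3.5).
#' @param start_date ISO date of the first sample, used only to render
#'   human-readable timestamps (default "2015-07-26").
#'
#' @return An object of class \code{study_design}.
#' @export
#' @examples
#' d <- study_design()
#' nrow(sample_schedule(d, n_blanks = 0, n_qc = 0))  # (25 + 19) * 3
study_design <- function(start_clock_hour = 6, sampling_interval = 4,
                         n_days_per_period = c(4, 3), gap_between_periods = 36,
                         n_replicates = 3, volume_filtered = 3.5,
                         start_date = "2015-07-26") {
  assert_finite(c(start_clock_hour, sampling_interval, n_days_per_period,
                  gap_between_periods, n_replicates, volume_filtered),
                "study_design parameters")
  if (24 %% sampling_interval != 0)
    stop("sampling_interval must divide 24")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (volume_filtered <= 0) stop("volume_filtered must be > 0")
  if (any(n_days_per_period < 1)) stop("each period must span at least 1 day")
  if (gap_between_periods < 0) stop("gap_between_periods must be >= 0")
  structure(list(start_clock_hour = wrap_hour(start_clock_hour),
                 sampling_interval = sampling_interval,
                 n_days_per_period = as.integer(n_days_per_period),
                 gap_between_periods = gap_between_periods,
                 n_replicates = as.integer(n_replicates),
                 volume_filtered = volume_filtered,
                 start_date = start_date),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("study_design:", length(x$n_days_per_period), "period(s) of",
      paste(x$n_days_per_period, collapse = "/"), "days,",
      sprintf("every %g h, %d replicates, %.1f L per sample, start %02d:00\n",
              x$sampling_interval, x$n_replicates, x$volume_filtered,
              x$start_clock_hour))
  invisible(x)
}

# time points (hours since study start) of one period, and period offsets
#' @noRd
period_offsets <- function(design) {
  offs <- numeric(length(design$n_days_per_period))
  for (p in seq_along(offs)[-1]) {
    offs[p] <- offs[p - 1] + 24 * design$n_days_per_period[p - 1] +
      design$gap_between_periods
  }
  offs
}

#' Expand a design into a per-sample metadata table
#'
#' @param design A \code{\link{study_design}}.
#' @param n_blanks Number of methodological extraction blanks (default 3).
#' @param n_qc Number of pooled quality-control injections (default 4);
#'   at least 2 are needed for BMIS internal-standard selection.
#' @return A data.frame with one row per sample: \code{sample_id},
#'   \code{datetime_iso}, \code{t_hours} (since study start),
#'   \code{clock_hour}, \code{period}, \code{replicate}, \code{volume_L} and
#'   \code{sample_class} ("smp", "blk" or "qc").
#' @export
sample_schedule <- function(design, n_blanks = 3, n_qc = 4) {
  stopifnot(inherits(design, "study_design"))
  offs <- period_offsets(design)
  rows <- list()
  tp <- 0L
  for (p in seq_along(design$n_days_per_period)) {
    tt <- offs[p] + seq(0, 24 * design$n_days_per_period[p],
                        by = design$sampling_interval)
    for (t in tt) {
      tp <- tp + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("S%03d_R%d", tp, seq_len(design$n_replicates)),
        t_hours = t, period = p,
        replicate = seq_len(design$n_replicates),
        sample_class = "smp", stringsAsFactors = FALSE)
    }
  }
  smp <- do.call(rbind, rows)
  extra <- list()
  if (n_blanks > 0)
    extra[[length(extra) + 1L]] <- data.frame(
      sample_id = sprintf("BLK%d", seq_len(n_blanks)), t_hours = 0,
      period = NA_integer_, replicate = seq_len(n_blanks),
      sample_class = "blk", stringsAsFactors = FALSE)
  if (n_qc > 0) {
    # spread QC injections across the run
    tq <- stats::quantile(smp$t_hours, probs = seq(0, 1, length.out = n_qc))
    extra[[length(extra) + 1L]] <- data.frame(
      sample_id = sprintf("QC%d", seq_len(n_qc)), t_hours = as.numeric(tq),
      period = NA_integer_, replicate = seq_len(n_qc),
      sample_class = "qc", stringsAsFactors = FALSE)
  }
  out <- rbind(smp, if (length(extra)) do.call(rbind, extra))
  out$clock_hour <- wrap_hour(design$start_clock_hour + out$t_hours)
  out$volume_L <- design$volume_filtered
  t0 <- as.POSIXct(paste0(design$start_date, " 00:00:00"), tz = "UTC") +
    3600 * design$start_clock_hour
  out$datetime_iso <- format(t0 + 3600 * out$t_hours, "%Y-%m-%dT%H:%M:%S")
  rownames(out) <- NULL
  out[, c("sample_id", "datetime_iso", "t_hours", "clock_hour", "period",
          "replicate", "volume_L", "sample_class")]
}

#' Ground-truth description of one simulated signal
#'
#' @param signal_id Character identifier (compound name or taxon/KO tag).
#' @param baseline Mean level: pmol per liter for metabolites, normalized
#'   counts for transcripts.  Must be > 0.
#' @param is_diel Logical; does the signal oscillate with a 24-h period?
#' @param fold_change Peak-to-trough ratio of the noiseless waveform
#'   (>= 1; forced to 1 when \code{is_diel} is FALSE).
#' @param peak_hour Clock hour in [0, 24) of the waveform maximum.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   replicate noise (>= 0).
#' @param waveform "cosine" (default) or "truncated_cosine" (cosine with the
#'   trough third of the cycle flattened, then rescaled so the peak-to-trough
#'   ratio is still exactly \code{fold_change}).
#' @return One-row data.frame.
#' @export
signal_truth <- function(signal_id, baseline, is_diel = TRUE, fold_change = 2,
                         peak_hour = 18, noise_cv = 0.2, waveform = "cosine") {
  assert_finite(c(baseline, fold_change, peak_hour, noise_cv), "signal_truth")
  if (baseline <= 0) stop("baseline must be > 0")
  if (fold_change < 1) stop("fold_change must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  waveform <- match.arg(waveform, c("cosine", "truncated_cosine"))
  if (!is_diel) fold_change <- 1
  data.frame(signal_id = signal_id, baseline = baseline, is_diel = is_diel,
             fold_change = fold_change, peak_hour = wrap_hour(peak_hour),
             noise_cv = noise_cv, waveform = waveform,
             stringsAsFactors = FALSE)
}

#' Measurement-process parameters for the synthetic study
#'
#' Describes the instrument-facing distortions the quantification stage has
#' to undo: a per-sample injection/extraction factor shared by every compound
#' and internal standard in that sample (removable by BMIS), per-compound
#' electrospray ion suppression in the sample matrix, and the carry-over
#' level seen in extraction blanks.
#'
#' @param is_injection_cv CV of the shared per-sample injection factor
#'   (default 0.1).
#' @param matrix_suppression Scalar or per-compound named vector in (0, 1]:
#'   ratio of the response factor in matrix to that in clean water
#'   (default 0.7).
#' @param blank_level Fraction of a compound's baseline signal that appears
#'   in extraction blanks (default 0.02).
#' @return Object of class \code{measurement_model}.
#' @export
measurement_model <- function(is_injection_cv = 0.1, matrix_suppression = 0.7,
                              blank_level = 0.02) {
  assert_finite(c(is_injection_cv, matrix_suppression, blank_level),
                "measurement_model")
  if (is_injection_cv < 0) stop("is_injection_cv must be >= 0")
  if (any(matrix_suppression <= 0 | matrix_suppression > 1))
    stop("matrix_suppression must be in (0, 1]")
  if (blank_level < 0) stop("blank_level must be >= 0")
  structure(list(is_injection_cv = is_injection_cv,
                 matrix_suppression = matrix_suppression,
                 blank_level = blank_level),
            class = "measurement_model")
}
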