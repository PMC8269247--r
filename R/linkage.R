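#' Aggregate contig-level transcript counts to taxon x KO series
#'
#' Rows sharing taxon, KO and sample are summed; rows without a KO
#' assignment are dropped (counted and reported).
#'
#' @param contigs Data.frame: \code{taxon}, \code{ko}, \code{sample_id},
#'   \code{abundance} (and optionally \code{domain}, carried through).
#' @return Aggregated data.frame with attribute \code{"n_dropped_no_ko"}.
#' @export
aggregate_transcripts <- function(contigs) {
  req <- c("taxon", "ko", "sample_id", "abundance")
  if (!all(req %in% names(contigs)))
    stop("contig table needs columns: ", paste(req, collapse = ", "))
  no_ko <- is.na(contigs$ko) | contigs$ko == ""
  if (any(no_ko))
    message("aggregate_transcripts: dropped ", sum(no_ko),
            " rows without a KO assignment")
  keep <- contigs[!no_ko, ]
  keys <- c("taxon", "ko", "sample_id",
            intersect("domain", names(keep)))
  dup <- duplicated(keep[, keys])
  if (any(dup))
    warning("summed ", sum(dup), " duplicate (taxon, ko, sample) rows")
  agg <- stats::aggregate(keep["abundance"], by = keep[keys], FUN = sum)
  agg <- agg[order(agg$taxon, agg$ko, agg$sample_id), ]
  rownames(agg) <- NULL
  attr(agg, "n_dropped_no_ko") <- sum(no_ko)
  agg
}

#' Signed circular lag between two peak hours
#'
#' \code{wrap(peak_b - peak_a)} into (-12, 12], with the antiphase boundary
#' mapped to +12.
#'
#' @param peak_a,peak_b Clock hours (vectorized).
#' @return Signed lag in hours; NA where either peak is undefined.
#' @export
#' @examples
#' circular_lag(18, 2)   # +8
#' circular_lag(6, 18)   # +12 (boundary convention)
circular_lag <- function(peak_a, peak_b) {
  lag <- ((peak_b - peak_a + 12) %% 24) - 12
  ifelse(abs(lag + 12) < 1e-9, 12, lag)
}

#' Join metabolites to transcript series through a curated KO link table
#'
#' Inner join of links to taxon x KO rhythm results, annotated with each
#' side's diel flag and peak hour and the circular lag from metabolite to
#' transcript.  Metabolites with no link are reported.
#'
#' @param links Data.frame: \code{metabolite}, \code{kegg_compound_id},
#'   \code{ko_id}, \code{role} ("produces", "consumes" or "both"), optional
#'   \code{note}.
#' @param transcript_rhythm Rhythm results for transcript series whose
#'   \code{signal_id} is "taxon|ko" (as produced by the simulator), or a
#'   data.frame already carrying \code{taxon}, \code{ko}, \code{p_raw},
#'   \code{q_fdr}, \code{is_diel}, \code{peak_hour}.
#' @param metabolite_rhythm Rhythm results for metabolites
#'   (\code{signal_id} = metabolite name).
#' @return List: \code{pairs} (one row per metabolite x taxon x KO x role),
#'   \code{metabolite_summary} (link and diel-transcript counts),
#'   \code{unlinked} (metabolites with no link row).
#' @export
link_and_classify <- function(links, transcript_rhythm, metabolite_rhythm) {
  req <- c("metabolite", "ko_id", "role")
  if (!all(req %in% names(links)))
    stop("link table needs columns: ", paste(req, collapse = ", "))
  bad_role <- !links$role %in% c("produces", "consumes", "both")
  if (any(bad_role)) stop("invalid role values in link table")
  tr <- transcript_rhythm
  if (!all(c("taxon", "ko") %in% names(tr))) {
    parts <- strsplit(tr$signal_id, "|", fixed = TRUE)
    tr$taxon <- vapply(parts, `[`, "", 1)
    tr$ko <- vapply(parts, `[`, "", 2)
  }
  known <- metabolite_rhythm$signal_id
  unknown <- setdiff(unique(links$metabolite), known)
  if (length(unknown) > 0) {
    warning("links reference unknown metabolites, skipped: ",
            paste(unknown, collapse = ", "))
    links <- links[links$metabolite %in% known, ]
  }
  pairs <- merge(links, tr, by.x = "ko_id", by.y = "ko")
  if (nrow(pairs) > 0) {
    mi <- match(pairs$metabolite, metabolite_rhythm$signal_id)
    pairs$metabolite_is_diel <- metabolite_rhythm$is_diel[mi]
    pairs$metabolite_peak_hour <- metabolite_rhythm$peak_hour[mi]
    pairs$transcript_is_diel <- pairs$is_diel
    pairs$transcript_peak_hour <- pairs$peak_hour
    pairs$lag_hours <- circular_lag(pairs$metabolite_peak_hour,
                                    pairs$transcript_peak_hour)
    keep <- c("metabolite", "ko_id", "role", "taxon",
              intersect("domain", names(pairs)),
              "metabolite_is_diel", "metabolite_peak_hour",
              "transcript_is_diel", "transcript_peak_hour", "lag_hours")
    pairs <- pairs[order(pairs$metabolite, pairs$taxon, pairs$ko_id),
                   keep]
    rownames(pairs) <- NULL
  }
  summ <- do.call(rbind, lapply(known, function(m) {
    sub <- pairs[pairs$metabolite == m, , drop = FALSE]
    data.frame(metabolite = m, n_links = nrow(sub),
               n_taxa = length(unique(sub$taxon)),
               n_diel_transcripts = sum(sub$transcript_is_diel,
                                        na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, metabolite_summary = summ,
       unlinked = known[!known %in% pairs$metabolite])
}

# circular mean direction of clock hours
#' @noRd
circ_mean_angle <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))

# Jammalamadaka-SenGupta circular-circular correlation with large-sample p
#' @noRd
circular_correlation <- function(a_hours, b_hours) {
  a <- a_hours * 2 * pi / 24
  b <- b_hours * 2 * pi / 24
  sa <- sin(a - circ_mean_angle(a))
  sb <- sin(b - circ_mean_angle(b))
  r <- sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
  n <- length(a)
  l20 <- mean(sa^2); l02 <- mean(sb^2); l22 <- mean(sa^2 * sb^2)
  z <- if (l22 > 0) sqrt(n * l20 * l02 / l22) * r else 0
  list(r = r, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Association between metabolite and transcript peak times
#'
#' Pearson correlation of paired peak clock hours (as printed, 0-24), the
#' same correlation after unwrapping each transcript peak to its
#' representative within +/- 12 h of the metabolite peak, and a
#' circular-circular correlation as a robustness check, plus a 2-h-binned
#' histogram of the circular lags.  Note the unwrapped variant is biased
#' toward positive correlation by construction (the representative is
#' anchored at the metabolite peak), so the raw Pearson is the primary
#' report and the circular correlation the statistically honest one.
#'
#' @param metabolite_peaks,transcript_peaks Paired peak clock hours; pairs
#'   with an undefined peak are dropped.
#' @param bin_width Lag histogram bin width, hours (default 2).
#' @return List: \code{n}, \code{pearson_r}, \code{pearson_p} (raw hours),
#'   \code{pearson_unwrapped_r}, \code{pearson_unwrapped_p},
#'   \code{circular_r}, \code{circular_p}, \code{lags},
#'   \code{lag_histogram} (data.frame of bins over (-12, 12]).
#' @export
peak_time_association <- function(metabolite_peaks, transcript_peaks,
                                  bin_width = 2) {
  keep <- is.finite(metabolite_peaks) & is.finite(transcript_peaks)
  m <- metabolite_peaks[keep]; t <- transcript_peaks[keep]
  if (length(m) < 3) stop("peak-time association needs >= 3 pairs")
  lags <- circular_lag(m, t)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(list(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x, y)
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  raw <- safe_cor(m, t)
  unw <- safe_cor(m, m + lags)
  cc <- circular_correlation(m, t)
  breaks <- seq(-12, 12, by = bin_width)
  cnt <- table(cut(lags, breaks = breaks, right = TRUE,
                   include.lowest = FALSE))
  hist <- data.frame(bin_low = breaks[-length(breaks)],
                     bin_high = breaks[-1], count = as.integer(cnt))
  list(n = length(m), pearson_r = raw$r, pearson_p = raw$p,
       pearson_unwrapped_r = unw$r, pearson_unwrapped_p = unw$p,
       circular_r = cc$r, circular_p = cc$p_value,
       lags = lags, lag_histogram = hist)
}
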