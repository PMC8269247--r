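#' Best-matched internal standard (BMIS) selection and normalization
#'
#' For every compound, each candidate internal standard (IS) defines a
#' normalized area \code{raw * mean(IS area over pooled-QC samples) /
#' IS area in that sample}.  The candidate (including "none") minimizing the
#' relative standard deviation (RSD) of the compound across pooled-QC
#' samples is chosen; an IS is accepted over "none" only if it improves the
#' QC RSD by at least \code{min_improvement} (fractional, default 0.4).
#'
#' @param areas Long data.frame: \code{compound}, \code{sample_id},
#'   \code{area}.
#' @param is_areas Long data.frame: \code{is_name}, \code{sample_id},
#'   \code{area}.
#' @param samples Sample metadata (needs \code{sample_id},
#'   \code{sample_class}); pooled-QC samples have class "qc".
#' @param qc_ids Optional explicit QC sample ids (overrides
#'   \code{samples$sample_class}).
#' @param min_improvement Minimum fractional RSD improvement over "none"
#'   (default 0.4).
#' @return List: \code{choice} (per-compound data.frame with chosen IS, QC
#'   RSD before/after, improvement, accepted flag) and \code{normalized}
#'   (the input \code{areas} with the chosen normalization applied to every
#'   sample; unchanged where "none" was chosen).
#' @export
bmis_select <- function(areas, is_areas, samples, qc_ids = NULL,
                        min_improvement = 0.4) {
  qc_ids <- qc_ids %||% samples$sample_id[samples$sample_class == "qc"]
  if (length(qc_ids) < 2) stop("BMIS needs >= 2 pooled-QC samples")
  is_names <- unique(is_areas$is_name)

  # per-sample normalization factor for each candidate IS
  factors <- list()
  for (nm in is_names) {
    sub <- is_areas[is_areas$is_name == nm, ]
    v <- stats::setNames(sub$area, sub$sample_id)
    qv <- v[qc_ids]
    if (any(is.na(qv)) || any(qv <= 0)) {
      message("BMIS: candidate '", nm,
              "' excluded (missing or nonpositive QC areas)")
      next
    }
    factors[[nm]] <- mean(qv) / v
  }

  cmp <- unique(areas$compound)
  choice <- data.frame(compound = cmp, is_used = "none",
                       rsd_none = NA_real_, rsd_best = NA_real_,
                       improvement = 0, accepted = FALSE,
                       stringsAsFactors = FALSE)
  norm <- areas
  for (k in seq_along(cmp)) {
    sel <- areas$compound == cmp[k]
    v <- stats::setNames(areas$area[sel], areas$sample_id[sel])
    qv <- v[qc_ids]
    r0 <- rsd(qv)
    choice$rsd_none[k] <- r0
    best <- "none"; rb <- r0
    for (nm in names(factors)) {
      rn <- rsd(qv * factors[[nm]][qc_ids])
      if (is.finite(rn) && (!is.finite(rb) || rn < rb)) {
        rb <- rn; best <- nm
      }
    }
    choice$rsd_best[k] <- rb
    if (best != "none" && is.finite(r0) && r0 > 0) {
      impr <- (r0 - rb) / r0
      choice$improvement[k] <- impr
      if (impr >= min_improvement) {
        choice$is_used[k] <- best
        choice$accepted[k] <- TRUE
        norm$area[sel] <- areas$area[sel] *
          factors[[best]][areas$sample_id[sel]]
      }
    }
  }
  list(choice = choice, normalized = norm)
}

#' Quantify by isotopologue internal standard
#'
#' \code{conc = (area_light / area_heavy) * spike_amount / volume}.  The
#' light/heavy ratio cancels any per-sample factor shared by the compound
#' and its co-eluting heavy partner, including injection variance and
#' matrix ion suppression.
#'
#' @param area_light,area_heavy Peak areas (vectorized); \code{area_heavy}
#'   must be > 0 (NA is returned and a flag raised otherwise).
#' @param spike_amount Heavy-standard spike, pmol.
#' @param volume Liters filtered.
#' @return Numeric vector, pmol per liter, with attribute
#'   \code{"flagged"} marking samples where the heavy area was not > 0.
#' @export
quant_isotopologue <- function(area_light, area_heavy, spike_amount, volume) {
  if (any(volume <= 0)) stop("volume must be > 0")
  bad <- !(area_heavy > 0) | is.na(area_heavy)
  out <- ifelse(bad, NA_real_, (area_light / area_heavy) * spike_amount / volume)
  attr(out, "flagged") <- which(bad)
  out
}

#' Quantify by standard additions
#'
#' Ordinary least squares of response on added amount; the endogenous
#' amount is the magnitude of the x-intercept (\code{intercept / slope}),
#' converted to concentration by the filtered volume.  The standard error
#' is propagated from the regression by the delta method.
#'
#' @param added_levels Added amounts, pmol; must include 0 and have at
#'   least 3 levels.
#' @param responses Measured areas at each level.
#' @param volume Liters filtered.
#' @return List: \code{conc_pmol_per_L}, \code{se}, \code{slope},
#'   \code{intercept}, \code{flags} (character vector; "negative_intercept"
#'   when the endogenous estimate was clipped to zero).
#' @export
quant_standard_addition <- function(added_levels, responses, volume) {
  if (length(added_levels) < 3 || !any(added_levels == 0))
    stop("standard addition needs >= 3 levels including 0")
  if (volume <= 0) stop("volume must be > 0")
  fit <- stats::lm(responses ~ added_levels)
  b <- stats::coef(fit)
  if (!is.finite(b[2]) || b[2] <= 0)
    stop("standard addition failed: nonpositive slope")
  endog <- unname(b[1] / b[2])
  flags <- character(0)
  if (endog < 0) {
    flags <- "negative_intercept"
    endog <- 0
  }
  # covariance computed directly; avoids summary.lm warnings on exact fits
  X <- cbind(1, added_levels)
  rss <- sum(stats::residuals(fit)^2)
  sigma2 <- rss / (length(responses) - 2)
  V <- sigma2 * solve(crossprod(X))
  se <- if (endog > 0) {
    # var(b0/b1) by delta method
    endog * sqrt(V[1, 1] / b[1]^2 + V[2, 2] / b[2]^2 -
                 2 * V[1, 2] / (b[1] * b[2])) / volume
  } else NA_real_
  list(conc_pmol_per_L = endog / volume, se = unname(se),
       slope = unname(b[2]), intercept = unname(b[1]), flags = flags)
}

#' Matrix response factor from a spike-recovery pair
#'
#' @param area_unspiked,area_spiked Areas of the pooled matrix sample
#'   before and after spiking.
#' @param spike_pmol Spiked amount, pmol.
#' @return Response factor in matrix, area per pmol.
#' @export
response_factor_matrix <- function(area_unspiked, area_spiked, spike_pmol) {
  (area_spiked - area_unspiked) / spike_pmol
}

#' Quantify by matrix-matched external calibration
#'
#' \code{conc = area / rf_matrix / volume}, where \code{rf_matrix} is the
#' response factor measured in the pooled sample matrix (which already
#' carries the ion suppression of co-eluting matrix).  The ratio
#' \code{rf_matrix / rf_water} is reported as the ion-suppression factor.
#'
#' @param area Peak area(s), ideally BMIS-normalized.
#' @param rf_water Response factor in clean water, area per pmol.
#' @param rf_matrix Response factor in matrix, area per pmol; must be > 0.
#' @param volume Liters filtered.
#' @return List: \code{conc_pmol_per_L} (vector), \code{suppression_factor}.
#' @export
quant_matrix_external <- function(area, rf_water, rf_matrix, volume) {
  if (any(volume <= 0)) stop("volume must be > 0")
  if (!is.finite(rf_matrix) || rf_matrix <= 0)
    stop("matrix response factor must be > 0")
  list(conc_pmol_per_L = area / rf_matrix / volume,
       suppression_factor = rf_matrix / rf_water)
}

#' Flag compounds not resolved above extraction blanks
#'
#' A compound is flagged when its mean field-sample area is below
#' \code{ratio_threshold} times its mean blank area.  Flags annotate;
#' nothing is removed.
#'
#' @param areas Long area table (\code{compound}, \code{sample_id},
#'   \code{area}).
#' @param samples Sample metadata with \code{sample_class} ("smp"/"blk").
#' @param ratio_threshold Field-to-blank ratio required to pass (default 3).
#' @return Data.frame: \code{compound}, \code{field_mean}, \code{blank_mean},
#'   \code{blank_flag} in \{"pass", "flagged", "not_evaluated"\}.
#' @export
blank_flag <- function(areas, samples, ratio_threshold = 3) {
  fld <- samples$sample_id[samples$sample_class == "smp"]
  blk <- samples$sample_id[samples$sample_class == "blk"]
  cmp <- unique(areas$compound)
  fm <- vapply(cmp, function(cn)
    mean(areas$area[areas$compound == cn & areas$sample_id %in% fld],
         na.rm = TRUE), 0)
  if (length(blk) == 0) {
    return(data.frame(compound = cmp, field_mean = fm, blank_mean = NA_real_,
                      blank_flag = "not_evaluated", stringsAsFactors = FALSE))
  }
  bm <- vapply(cmp, function(cn)
    mean(areas$area[areas$compound == cn & areas$sample_id %in% blk],
         na.rm = TRUE), 0)
  data.frame(compound = cmp, field_mean = fm, blank_mean = bm,
             blank_flag = ifelse(fm < ratio_threshold * bm, "flagged", "pass"),
             stringsAsFactors = FALSE)
}

#' Quantify a whole synthetic or assembled study
#'
#' Runs BMIS selection on the compound areas, then applies the per-compound
#' quantification mode: isotopologue ratios on raw areas (the ratio removes
#' shared per-sample factors itself), and standard-addition or
#' matrix-matched external response factors on BMIS-normalized areas.  The
#' standard-addition slope doubles as the matrix response factor for the
#' compound's time series.  Per-time-point triplicate medians and blank
#' flags are attached.
#'
#' @param study A \code{diel_study} from \code{\link{simulate_study}} or
#'   \code{\link{read_study}}.
#' @param min_improvement BMIS acceptance threshold (default 0.4).
#' @param blank_ratio Blank-flag ratio threshold (default 3).
#' @return List of class \code{concentration_series}: \code{concentrations}
#'   (per sample), \code{medians} (per time point), \code{bmis},
#'   \code{blanks}, \code{compounds}.
#' @export
quantify_study <- function(study, min_improvement = 0.4, blank_ratio = 3) {
  samples <- study$samples
  cmp <- study$compounds
  bm <- bmis_select(study$areas, study$is_areas, samples,
                    min_improvement = min_improvement)
  norm <- bm$normalized
  cal <- study$calibration
  fld <- samples[samples$sample_class == "smp", ]
  vol <- stats::setNames(samples$volume_L, samples$sample_id)

  rows <- vector("list", nrow(cmp))
  for (k in seq_len(nrow(cmp))) {
    cn <- cmp$name[k]
    mode <- cmp$quant_mode[k]
    flags <- character(0)
    if (mode == "isotopologue") {
      part <- cmp$isotopologue_partner[k]
      sub <- study$areas[study$areas$compound == cn &
                           study$areas$sample_id %in% fld$sample_id, ]
      hv <- study$is_areas[study$is_areas$is_name == part, ]
      heavy <- stats::setNames(hv$area, hv$sample_id)[sub$sample_id]
      spk <- cal$is_spikes$spike_pmol[match(part, cal$is_spikes$is_name)]
      conc <- quant_isotopologue(sub$area, heavy, spk, vol[sub$sample_id])
      used_is <- part
    } else if (mode == "std_addition") {
      sub <- norm[norm$compound == cn & norm$sample_id %in% fld$sample_id, ]
      sa <- cal$std_addition[cal$std_addition$compound == cn, ]
      fit <- quant_standard_addition(sa$added_pmol, sa$response,
                                     volume = 1)  # slope reused as matrix rf
      conc <- sub$area / fit$slope / vol[sub$sample_id]
      flags <- fit$flags
      used_is <- bm$choice$is_used[bm$choice$compound == cn]
    } else if (mode == "matrix_external") {
      sub <- norm[norm$compound == cn & norm$sample_id %in% fld$sample_id, ]
      ec <- cal$external_cal[cal$external_cal$compound == cn, ]
      rfm <- response_factor_matrix(ec$area_matrix_unspiked,
                                    ec$area_matrix_spiked, ec$spike_pmol)
      qq <- quant_matrix_external(sub$area, ec$rf_water, rfm,
                                  vol[sub$sample_id])
      conc <- qq$conc_pmol_per_L
      used_is <- bm$choice$is_used[bm$choice$compound == cn]
    } else stop("unknown quant_mode: ", mode)
    if (isTRUE(cmp$underestimate_flag[k])) flags <- c(flags, "underestimate")
    rows[[k]] <- data.frame(
      compound = cn, sample_id = sub$sample_id,
      pmol_per_L = as.numeric(conc), method = mode, is_used = used_is,
      flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
  }
  conc <- do.call(rbind, rows)
  conc <- merge(conc, fld[, c("sample_id", "t_hours", "clock_hour", "period",
                              "replicate")], by = "sample_id", sort = FALSE)
  med <- stats::aggregate(pmol_per_L ~ compound + t_hours + clock_hour + period,
                          data = conc, FUN = stats::median, na.rm = TRUE)
  names(med)[names(med) == "pmol_per_L"] <- "median_pmol_per_L"
  med <- med[order(med$compound, med$t_hours), ]
  rownames(med) <- NULL
  structure(list(concentrations = conc, medians = med, bmis = bm$choice,
                 blanks = blank_flag(study$areas, samples, blank_ratio),
                 compounds = cmp),
            class = "concentration_series")
}
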