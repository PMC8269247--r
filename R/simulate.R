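#' Noiseless expected concentration of a diel signal
#'
#' Evaluates \code{baseline * (1 + a * w(theta))} where \code{w} is the
#' waveform (maximum 1 at the peak, minimum -1 at the trough) and
#' \code{a = (F - 1) / (F + 1)}, so that the peak-to-trough ratio over one
#' cycle equals the fold change \code{F} exactly.
#'
#' @param t_hours Hours since study start (vectorized).
#' @param truth One-row data.frame from \code{\link{signal_truth}} (or a
#'   list with the same fields).
#' @param design A \code{\link{study_design}}; supplies the clock hour of
#'   \code{t = 0}.
#' @return Numeric vector of expected concentrations.
#' @export
#' @examples
#' tr <- signal_truth("x", baseline = 10, fold_change = 4, peak_hour = 14)
#' d <- study_design()
#' diel_signal(8, tr, d) / diel_signal(20, tr, d)  # peak / trough = 4
diel_signal <- function(t_hours, truth, design) {
  assert_finite(t_hours, "t_hours")
  assert_finite(c(truth$baseline, truth$fold_change, truth$peak_hour),
                "truth parameters")
  if (truth$fold_change < 1) stop("fold_change must be >= 1")
  h <- wrap_hour(design$start_clock_hour + t_hours)
  a <- (truth$fold_change - 1) / (truth$fold_change + 1)
  theta <- 2 * pi * (h - truth$peak_hour) / 24
  w <- cos(theta)
  if (identical(truth$waveform, "truncated_cosine")) {
    # flatten the trough third of the cycle (cos < -0.5), rescale to [-1, 1]
    u <- pmax(w, -0.5)
    w <- (2 * (u + 0.5) / 1.5) - 1
  }
  truth$baseline * (1 + a * w)
}

#' Example metabolite truth set emulating a field study
#'
#' Builds a ground-truth table for \code{n_signals} compounds of which
#' \code{n_diel} oscillate, with fold changes drawn log-uniformly from
#' \code{fc_range} and peak clock hours concentrated in the afternoon
#' (uniform over \code{peak_range}), matching the observed pattern of
#' afternoon/dusk maxima.  The first compounds get the names of well-known
#' marine osmolytes and primary metabolites so the quantification modes can
#' be exercised; the rest are generic.
#'
#' @param n_signals Total number of compounds (default 79).
#' @param n_diel Number with 24-h periodicity (default 55).
#' @param fc_range Fold-change range for diel compounds (default
#'   \code{c(1.6, 12.8)}).
#' @param peak_range Clock-hour range for peak times (default
#'   \code{c(14, 18)}).
#' @param noise_cv Replicate noise CV (default 0.2).
#' @param baseline_range Baseline range, pmol per liter, drawn log-uniformly
#'   (default \code{c(5, 500)}).
#' @return Data.frame of \code{\link{signal_truth}} rows.
#' @export
example_metabolite_truths <- function(n_signals = 79, n_diel = 55,
                                      fc_range = c(1.6, 12.8),
                                      peak_range = c(14, 18),
                                      noise_cv = 0.2,
                                      baseline_range = c(5, 500)) {
  if (n_diel > n_signals) stop("n_diel cannot exceed n_signals")
  nm <- default_compound_names(n_signals)
  base <- exp(stats::runif(n_signals, log(baseline_range[1]),
                           log(baseline_range[2])))
  diel <- seq_len(n_signals) <= n_diel
  fc <- ifelse(diel,
               exp(stats::runif(n_signals, log(fc_range[1]), log(fc_range[2]))),
               1)
  pk <- wrap_hour(stats::runif(n_signals, peak_range[1], peak_range[2]))
  do.call(rbind, lapply(seq_len(n_signals), function(i)
    signal_truth(nm[i], baseline = base[i], is_diel = diel[i],
                 fold_change = fc[i], peak_hour = pk[i],
                 noise_cv = noise_cv)))
}

# named compounds come first so standard-addition / isotopologue modes are
# always represented; remaining names are generic
#' @noRd
default_compound_names <- function(n) {
  named <- c("trehalose", "sucrose", "DHPS", "glycine betaine", "homarine",
             "DMSP", "glutamic acid", "glucosylglycerol", "AMP", "SAM")
  c(named[seq_len(min(n, length(named)))],
    if (n > length(named)) sprintf("metab_%02d", seq_len(n - length(named))))
}

#' Compound annotations for a truth set
#'
#' Assigns carbon/nitrogen atom counts, KEGG compound ids, osmolyte and
#' underestimate flags, and the quantification mode for each compound:
#' trehalose, sucrose and DHPS by standard additions, a handful by
#' isotopologue internal standards, and everything else by matrix-matched
#' external calibration.
#'
#' @param truths Truth table from \code{\link{example_metabolite_truths}}
#'   (only \code{signal_id} is used).
#' @return Data.frame with the \code{compounds.csv} schema.
#' @export
default_compound_info <- function(truths) {
  known <- data.frame(
    name = c("trehalose", "sucrose", "DHPS", "glycine betaine", "homarine",
             "DMSP", "glutamic acid", "glucosylglycerol", "AMP", "SAM"),
    n_carbon = c(12, 12, 3, 5, 7, 5, 5, 9, 10, 15),
    n_nitrogen = c(0, 0, 0, 1, 1, 0, 1, 0, 5, 6),
    kegg_compound_id = c("C01083", "C00089", "C19675", "C00719", "C01004",
                         "C04022", "C00025", "C06608", "C00020", "C00019"),
    osmolyte = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    quant_mode = c("std_addition", "std_addition", "std_addition",
                   "isotopologue", "isotopologue", "matrix_external",
                   "isotopologue", "matrix_external", "isotopologue",
                   "matrix_external"),
    underestimate_flag = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                           FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  nm <- truths$signal_id
  out <- data.frame(name = nm, stringsAsFactors = FALSE)
  idx <- match(nm, known$name)
  out$n_carbon <- ifelse(is.na(idx), 3 + (seq_along(nm) %% 10),
                         known$n_carbon[idx])
  out$n_nitrogen <- ifelse(is.na(idx), seq_along(nm) %% 3, known$n_nitrogen[idx])
  out$kegg_compound_id <- ifelse(is.na(idx),
                                 sprintf("C9%04d", seq_along(nm)),
                                 known$kegg_compound_id[idx])
  out$osmolyte <- ifelse(is.na(idx), FALSE, known$osmolyte[idx])
  out$quant_mode <- ifelse(is.na(idx), "matrix_external", known$quant_mode[idx])
  out$underestimate_flag <- ifelse(is.na(idx), FALSE,
                                   known$underestimate_flag[idx])
  out$isotopologue_partner <- ifelse(out$quant_mode == "isotopologue",
                                     paste0(out$name, "_hvy"), NA_character_)
  rownames(out) <- NULL
  out
}

#' Example transcript truth set
#'
#' Taxon-by-KEGG-ortholog transcript series share the metabolite signal
#' model.  Each (taxon, KO) pair either oscillates with a peak offset
#' \code{lag_hours} after a chosen anchor hour, or is arrhythmic.
#'
#' @param taxa Character vector of taxon labels.
#' @param kos Character vector of KO identifiers.
#' @param frac_diel Fraction of (taxon, KO) series that oscillate
#'   (default 0.7).
#' @param peak_hours Optional vector (recycled) of peak clock hours;
#'   default draws uniformly over the day.
#' @param noise_cv Noise CV (default 0.2).
#' @param domain "prokaryote" or "eukaryote" tag (recycled over taxa).
#' @return Data.frame: one row per taxon x KO with truth fields plus
#'   \code{taxon}, \code{ko}, \code{domain}.
#' @export
example_transcript_truths <- function(taxa, kos, frac_diel = 0.7,
                                      peak_hours = NULL, noise_cv = 0.2,
                                      domain = "prokaryote") {
  grid <- expand.grid(taxon = taxa, ko = kos, stringsAsFactors = FALSE)
  n <- nrow(grid)
  grid$domain <- rep_len(domain, length(taxa))[match(grid$taxon, taxa)]
  diel <- stats::runif(n) < frac_diel
  pk <- if (is.null(peak_hours)) stats::runif(n, 0, 24) else
    rep_len(peak_hours, n)
  tr <- do.call(rbind, lapply(seq_len(n), function(i)
    signal_truth(paste(grid$taxon[i], grid$ko[i], sep = "|"),
                 baseline = exp(stats::runif(1, log(50), log(5000))),
                 is_diel = diel[i],
                 fold_change = if (diel[i]) exp(stats::runif(1, log(1.6), log(8))) else 1,
                 peak_hour = pk[i], noise_cv = noise_cv)))
  cbind(grid, tr[, setdiff(names(tr), "signal_id")])
}

#' Simulate a complete synthetic diel study
#'
#' Generates everything the pipeline consumes: sample metadata (field
#' triplicates, extraction blanks, pooled QC injections), long-format peak
#' areas for compounds and internal standards, calibration inputs for the
#' three quantification modes, a covariate series (POC, PN, cell counts,
#' carbon biomass), taxon-by-KO transcript series, and the serialized ground
#' truth.  Measured area for compound c in sample s is
#' \code{conc * volume * rf_c * suppression_c * inj_s * eps}, where
#' \code{inj_s} is a lognormal per-sample injection factor shared with every
#' internal standard in that sample (so BMIS can remove it) and \code{eps}
#' is lognormal replicate noise at the compound's \code{noise_cv}.
#'
#' @param design A \code{\link{study_design}}.
#' @param truths Metabolite truth table (\code{\link{signal_truth}} rows).
#' @param model A \code{\link{measurement_model}}.
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @param compounds Optional compound annotation table; defaults to
#'   \code{\link{default_compound_info}(truths)}.
#' @param transcript_truths Optional table from
#'   \code{\link{example_transcript_truths}}; omit for no transcript layer.
#' @param n_blanks,n_qc Numbers of blank and pooled-QC samples (3 and 4).
#' @param covariate_noise_cv CV of the lognormal noise on covariate series
#'   (default 0.05).
#' @return List of class \code{diel_study} with elements \code{design},
#'   \code{samples}, \code{areas}, \code{is_areas}, \code{compounds},
#'   \code{calibration}, \code{covariates}, \code{transcripts},
#'   \code{transcript_truth}, \code{truth}, \code{model}, \code{seed}.
#' @export
simulate_study <- function(design, truths, model = measurement_model(),
                           seed = 1L, compounds = NULL,
                           transcript_truths = NULL, n_blanks = 3, n_qc = 4,
                           covariate_noise_cv = 0.05) {
  stopifnot(inherits(design, "study_design"),
            inherits(model, "measurement_model"))
  if (is.null(truths) || nrow(truths) == 0) stop("empty truth list")
  set.seed(seed)
  samples <- sample_schedule(design, n_blanks = n_blanks, n_qc = n_qc)
  compounds <- compounds %||% default_compound_info(truths)
  if (!all(truths$signal_id %in% compounds$name))
    stop("compounds table does not cover all truth signal_ids")
  ncmp <- nrow(truths)
  nsmp <- nrow(samples)

  # per-compound response factor (area per pmol) and suppression
  rf <- exp(stats::runif(ncmp, log(100), log(2000)))
  names(rf) <- truths$signal_id
  suppr <- rep_len(model$matrix_suppression, ncmp)
  if (!is.null(names(model$matrix_suppression)))
    suppr <- model$matrix_suppression[truths$signal_id]
  names(suppr) <- truths$signal_id

  # shared per-sample injection factor
  inj <- rlnorm_cv(nsmp, model$is_injection_cv)
  names(inj) <- samples$sample_id

  # expected concentrations (field samples follow the waveform; QC samples
  # measure the pooled mean; blanks see blank_level * baseline)
  field <- samples$sample_class == "smp"
  exp_conc <- matrix(0, ncmp, nsmp,
                     dimnames = list(truths$signal_id, samples$sample_id))
  for (i in seq_len(ncmp)) {
    tr <- truths[i, ]
    exp_conc[i, field] <- diel_signal(samples$t_hours[field], tr, design)
    pooled <- mean(exp_conc[i, field])
    exp_conc[i, samples$sample_class == "qc"] <- pooled
    exp_conc[i, samples$sample_class == "blk"] <-
      model$blank_level * tr$baseline
  }

  # measured areas
  noise <- matrix(1, ncmp, nsmp)
  for (i in seq_len(ncmp))
    noise[i, ] <- rlnorm_cv(nsmp, truths$noise_cv[i])
  vol <- samples$volume_L
  area <- exp_conc * outer(rf * suppr, inj * vol) * noise
  areas <- data.frame(compound = rep(truths$signal_id, nsmp),
                      sample_id = rep(samples$sample_id, each = ncmp),
                      area = as.vector(area), stringsAsFactors = FALSE)

  # internal standards: one broad injection standard plus a heavy
  # isotopologue partner (co-eluting, hence equally suppressed) for each
  # isotopologue-mode compound
  iso <- compounds[compounds$quant_mode == "isotopologue", ]
  is_spikes <- data.frame(
    is_name = c("IS_injection", iso$isotopologue_partner),
    spike_pmol = c(100, rep(100, nrow(iso))), stringsAsFactors = FALSE)
  is_rf <- c(IS_injection = 800,
             stats::setNames(rf[iso$name] * suppr[iso$name],
                             iso$isotopologue_partner))
  is_rows <- lapply(seq_len(nrow(is_spikes)), function(k) {
    nm <- is_spikes$is_name[k]
    data.frame(is_name = nm, sample_id = samples$sample_id,
               area = is_spikes$spike_pmol[k] * is_rf[[nm]] * inj,
               stringsAsFactors = FALSE)
  })
  is_areas <- do.call(rbind, is_rows)
  rownames(is_areas) <- NULL

  # calibration inputs (run without injection variance: calibration curves
  # are acquired in dedicated runs and normalized to their own standards)
  pooled_pmol <- rowMeans(exp_conc[, field, drop = FALSE]) *
    design$volume_filtered
  ext <- compounds$name[compounds$quant_mode == "matrix_external"]
  spk <- pmax(pooled_pmol[ext], 1)
  external_cal <- data.frame(
    compound = ext,
    rf_water = rf[ext],
    area_matrix_unspiked = pooled_pmol[ext] * rf[ext] * suppr[ext],
    area_matrix_spiked = (pooled_pmol[ext] + spk) * rf[ext] * suppr[ext],
    spike_pmol = spk, stringsAsFactors = FALSE)
  rownames(external_cal) <- NULL
  sa <- compounds$name[compounds$quant_mode == "std_addition"]
  std_addition <- do.call(rbind, lapply(sa, function(cn) {
    lev <- pmax(pooled_pmol[cn], 1) * c(0, 1, 2, 3)
    data.frame(compound = cn, added_pmol = lev,
               response = (pooled_pmol[cn] + lev) * rf[cn] * suppr[cn],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(std_addition)) rownames(std_addition) <- NULL

  # covariates on the field time grid: POC with a modest dusk-peaking diel
  # cycle (daily fold change 1.2), PN in Redfield-like proportion, and cell
  # abundance / carbon biomass for the two quota-attribution taxa
  tp <- unique(samples[field, c("t_hours", "clock_hour", "period")])
  cov_sig <- function(base, fc, pk)
    diel_signal(tp$t_hours,
                signal_truth("cov", baseline = base, fold_change = fc,
                             peak_hour = pk), design) *
      rlnorm_cv(nrow(tp), covariate_noise_cv)
  covariates <- data.frame(
    tp,
    poc_umol = cov_sig(2.0, 1.2, 18),
    pn_umol = cov_sig(0.30, 1.15, 18),
    croco_cells_per_L = cov_sig(1.6e5, 2.0, 18),
    prochloro_cells_per_L = cov_sig(2.0e8, 1.3, 18),
    stringsAsFactors = FALSE)
  covariates$croco_ugC_per_L <- covariates$croco_cells_per_L * 1.5e-6  # ~1.5 pg C per cell
  covariates$prochloro_ugC_per_L <- covariates$prochloro_cells_per_L * 6e-8  # ~60 fg C per cell
  rownames(covariates) <- NULL

  # transcripts: one observation per time point (replicate 1 sample ids)
  transcripts <- NULL
  if (!is.null(transcript_truths) && nrow(transcript_truths) > 0) {
    rep1 <- samples[field & samples$replicate == 1, ]
    transcripts <- do.call(rbind, lapply(seq_len(nrow(transcript_truths)),
                                         function(i) {
      tr <- transcript_truths[i, ]
      ab <- diel_signal(rep1$t_hours, tr, design) *
        rlnorm_cv(nrow(rep1), tr$noise_cv)
      data.frame(taxon = tr$taxon, ko = tr$ko, domain = tr$domain,
                 sample_id = rep1$sample_id, abundance = ab,
                 stringsAsFactors = FALSE)
    }))
    rownames(transcripts) <- NULL
  }

  structure(list(design = design, samples = samples, areas = areas,
                 is_areas = is_areas, compounds = compounds,
                 calibration = list(is_spikes = is_spikes,
                                    external_cal = external_cal,
                                    std_addition = std_addition),
                 covariates = covariates, transcripts = transcripts,
                 transcript_truth = transcript_truths, truth = truths,
                 model = model, seed = seed),
            class = "diel_study")
}

#' Simulate a batch of arrhythmic (null) signals
#'
#' Every generated signal is flat (fold change 1) plus replicate noise; used
#' to calibrate the type-I error of the rhythm test.
#'
#' @param design A \code{\link{study_design}}.
#' @param n_signals Number of null signals (>= 1).
#' @param noise_cv Replicate noise CV (default 0.2).
#' @param seed Integer seed.
#' @param ... Passed on to \code{\link{simulate_study}}.
#' @return A \code{diel_study}; its truth table has no diel rows.
#' @export
simulate_null_batch <- function(design, n_signals, noise_cv = 0.2, seed = 1L,
                                ...) {
  if (n_signals < 1) stop("n_signals must be >= 1")
  set.seed(seed)
  base <- exp(stats::runif(n_signals, log(10), log(200)))
  truths <- do.call(rbind, lapply(seq_len(n_signals), function(i)
    signal_truth(sprintf("null_%04d", i), baseline = base[i], is_diel = FALSE,
                 fold_change = 1, peak_hour = 0, noise_cv = noise_cv)))
  compounds <- default_compound_info(truths)
  compounds$quant_mode <- "matrix_external"
  compounds$isotopologue_partner <- NA_character_
  simulate_study(design, truths, seed = seed + 1L, compounds = compounds, ...)
}
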