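#' Stoichiometric constants for the diazotroph energy budget
#'
#' Constants linking trehalose catabolism to nitrogen fixation in a
#' unicellular diazotroph: each trehalose yields two glucose equivalents;
#' respiring one glucose yields \code{atp_per_glucose} ATP and
#' \code{electrons_per_glucose} reducing-equivalent electrons; fixing one
#' N2 costs \code{atp_per_n2} ATP and \code{electrons_per_n2} electrons;
#' and a fraction \code{f_o2_drawdown} of dark respiration is diverted to
#' intracellular oxygen removal rather than directly powering nitrogenase.
#'
#' @param glucose_equiv_per_trehalose mol glucose per mol trehalose (2).
#' @param atp_per_glucose mol ATP per mol glucose respired (default 30;
#'   an assumption, not a measured value -- configurable).
#' @param electrons_per_glucose mol electrons per mol glucose (default 24).
#' @param atp_per_n2 mol ATP per mol N2 fixed (16).
#' @param electrons_per_n2 mol electrons per mol N2 fixed (8).
#' @param f_o2_drawdown Fraction of dark respiration used for oxygen
#'   drawdown (default 0.60).
#' @return List of class \code{stoichiometry_params}.
#' @export
stoichiometry_params <- function(glucose_equiv_per_trehalose = 2,
                                 atp_per_glucose = 30,
                                 electrons_per_glucose = 24,
                                 atp_per_n2 = 16, electrons_per_n2 = 8,
                                 f_o2_drawdown = 0.60) {
  vals <- c(glucose_equiv_per_trehalose, atp_per_glucose,
            electrons_per_glucose, atp_per_n2, electrons_per_n2,
            f_o2_drawdown)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("stoichiometry parameters must be finite and >= 0")
  if (f_o2_drawdown >= 1) stop("f_o2_drawdown must be in [0, 1)")
  structure(list(glucose_equiv_per_trehalose = glucose_equiv_per_trehalose,
                 atp_per_glucose = atp_per_glucose,
                 electrons_per_glucose = electrons_per_glucose,
                 atp_per_n2 = atp_per_n2, electrons_per_n2 = electrons_per_n2,
                 f_o2_drawdown = f_o2_drawdown),
            class = "stoichiometry_params")
}

#' Metabolite carbon and nitrogen as a percentage of POC and PN
#'
#' \code{\%POC = 100 * conc * n_carbon / (poc * 1e6)} with concentration in
#' pmol per liter and POC in umol C per liter (the 1e6 reconciles pmol and
#' umol); \code{\%PN} analogously.  Fractions are additive across
#' compounds.
#'
#' @param conc_pmol_per_L Metabolite concentration(s), pmol per liter.
#' @param n_carbon,n_nitrogen Atoms per molecule.
#' @param poc_umol POC, umol C per liter (> 0).
#' @param pn_umol PN, umol N per liter (> 0 required only when
#'   \code{n_nitrogen} > 0).
#' @return List: \code{pct_poc}, \code{pct_pn} (0 when the compound has no
#'   nitrogen).
#' @export
composition_fraction <- function(conc_pmol_per_L, n_carbon, n_nitrogen,
                                 poc_umol, pn_umol = NA_real_) {
  if (any(poc_umol <= 0)) stop("POC must be > 0")
  pct_poc <- 100 * conc_pmol_per_L * n_carbon / (poc_umol * 1e6)
  if (any(n_nitrogen > 0)) {
    if (any(!is.finite(pn_umol)) || any(pn_umol <= 0))
      stop("PN must be > 0 for nitrogen-containing compounds")
    pct_pn <- 100 * conc_pmol_per_L * n_nitrogen / (pn_umol * 1e6)
  } else {
    pct_pn <- rep(0, length(conc_pmol_per_L))
  }
  list(pct_poc = pct_poc, pct_pn = ifelse(n_nitrogen > 0, pct_pn, 0))
}

#' Net daily turnover flux through the particulate pool
#'
#' The mean daily swing (maximum minus minimum of per-time-point medians
#' within each complete 24-h window, averaged across windows) is the net
#' production-and-degradation rate; elemental fluxes follow from the atom
#' counts.  These are conservative minima of the instantaneous flux.
#'
#' @param medians Long data.frame: \code{compound}, \code{t_hours},
#'   \code{clock_hour}, \code{period}, \code{median_pmol_per_L}.
#' @param compounds Compound table with \code{name}, \code{n_carbon},
#'   \code{n_nitrogen}.
#' @param include Character vector of compounds to total over (typically
#'   the diel-flagged set); default all.
#' @param window_start_hour,interval Passed to the window partition.
#' @return List: \code{flux} (per-compound data.frame with
#'   \code{swing_pmol_per_L_d}, \code{carbon_pmol_per_L_d},
#'   \code{nitrogen_pmol_per_L_d}, \code{n_windows}),
#'   \code{total_carbon_nmol_per_L_d}, \code{total_nitrogen_nmol_per_L_d}
#'   (sums over \code{include}).
#' @export
net_turnover <- function(medians, compounds, include = NULL,
                         window_start_hour = NULL, interval = NULL) {
  cmp <- unique(medians$compound)
  rows <- vector("list", length(cmp))
  for (k in seq_along(cmp)) {
    sub <- medians[medians$compound == cmp[k], ]
    swings <- c(); nw <- 0
    for (p in unique(sub$period)) {
      m <- sub[sub$period == p, ]
      m <- m[order(m$t_hours), ]
      fc <- tryCatch(
        daily_fold_change(m$t_hours, m$median_pmol_per_L,
                          start_clock_hour = m$clock_hour[1] - m$t_hours[1],
                          window_start_hour = window_start_hour,
                          interval = interval),
        error = function(e) NULL)
      if (is.null(fc)) next
      swings <- c(swings, fc$per_window$max - fc$per_window$min)
      nw <- nw + nrow(fc$per_window)
    }
    if (nw == 0) {
      message("net_turnover: no complete window for ", cmp[k], "; skipped")
      next
    }
    i <- match(cmp[k], compounds$name)
    sw <- mean(swings)
    rows[[k]] <- data.frame(compound = cmp[k], swing_pmol_per_L_d = sw,
                            carbon_pmol_per_L_d = sw * compounds$n_carbon[i],
                            nitrogen_pmol_per_L_d = sw * compounds$n_nitrogen[i],
                            n_windows = nw, stringsAsFactors = FALSE)
  }
  flux <- do.call(rbind, rows)
  rownames(flux) <- NULL
  inc <- if (is.null(include)) flux$compound else
    intersect(include, flux$compound)
  sel <- flux$compound %in% inc
  list(flux = flux,
       total_carbon_nmol_per_L_d = sum(flux$carbon_pmol_per_L_d[sel]) / 1000,
       total_nitrogen_nmol_per_L_d = sum(flux$nitrogen_pmol_per_L_d[sel]) / 1000,
       included = inc)
}

#' Attribute a metabolite pool to a taxon via cell quotas
#'
#' Predicts the particulate pool a taxon would account for given its cell
#' abundance and culture-measured per-cell quotas at the light-end and
#' dark-end of the photoperiod, and inverts the field pool into an apparent
#' per-cell quota and carbon-normalized content.
#'
#' @param pool_pmol_per_L Measured pool, pmol per liter (vector over time).
#' @param cells_per_L Cell abundance series (same length; > 0 where quotas
#'   are computed, else flagged NA).
#' @param quota_light_fmol,quota_dark_fmol Per-cell quotas, fmol per cell.
#' @param molar_mass_g Optional molar mass (g per mol) for the
#'   carbon-normalized output.
#' @param ugC_per_L Optional taxon carbon biomass series, ug C per liter.
#' @return List: \code{predicted_light_pmol_per_L},
#'   \code{predicted_dark_pmol_per_L}, \code{predicted_range_pmol_per_L},
#'   \code{field_quota_fmol_per_cell}, \code{mg_per_g_cell_carbon} (NA
#'   when inputs are missing), \code{zero_abundance} index vector.
#' @export
quota_attribution <- function(pool_pmol_per_L, cells_per_L,
                              quota_light_fmol, quota_dark_fmol,
                              molar_mass_g = NULL, ugC_per_L = NULL) {
  if (any(quota_light_fmol < 0, quota_dark_fmol < 0))
    stop("quotas must be >= 0")
  zero <- which(!(cells_per_L > 0))
  # fmol cell^-1 * cells L^-1 = fmol L^-1; /1000 -> pmol L^-1
  pred_l <- cells_per_L * quota_light_fmol / 1000
  pred_d <- cells_per_L * quota_dark_fmol / 1000
  fq <- ifelse(cells_per_L > 0, pool_pmol_per_L * 1000 / cells_per_L,
               NA_real_)
  mgg <- NULL
  if (!is.null(molar_mass_g) && !is.null(ugC_per_L)) {
    # pmol L^-1 * g mol^-1 = 1e-12 g L^-1 = 1e-6 ug L^-1; / (ugC L^-1) g/g;
    # * 1000 -> mg per g cell carbon
    mgg <- ifelse(ugC_per_L > 0,
                  pool_pmol_per_L * molar_mass_g * 1e-6 / ugC_per_L * 1000,
                  NA_real_)
  }
  list(predicted_light_pmol_per_L = pred_l,
       predicted_dark_pmol_per_L = pred_d,
       predicted_range_pmol_per_L = range(c(pred_l, pred_d)),
       field_quota_fmol_per_cell = fq,
       mg_per_g_cell_carbon = mgg,
       zero_abundance = zero)
}

#' Fraction of nighttime nitrogen fixation fuelable by trehalose catabolism
#'
#' The daily trehalose swing is converted to glucose equivalents, then to
#' the N2 fixation it could support under whichever of the ATP and
#' electron budgets is limiting.  The adjusted value discounts the
#' fraction of dark respiration used to draw down intracellular oxygen.
#'
#' @param trehalose_swing Daily net trehalose swing, mol per liter per day.
#' @param n2_fixation_rate Measured fixation, mol N2 per liter per day
#'   (> 0).
#' @param params \code{\link{stoichiometry_params}}.
#' @return List: \code{unadjusted_pct}, \code{adjusted_pct},
#'   \code{limiting} ("atp" or "electrons").
#' @export
n2_fixation_fraction <- function(trehalose_swing, n2_fixation_rate,
                                 params = stoichiometry_params()) {
  if (any(n2_fixation_rate <= 0)) stop("nitrogen fixation rate must be > 0")
  if (any(trehalose_swing < 0)) stop("trehalose swing must be >= 0")
  glc <- trehalose_swing * params$glucose_equiv_per_trehalose
  by_atp <- glc * params$atp_per_glucose / params$atp_per_n2
  by_e <- glc * params$electrons_per_glucose / params$electrons_per_n2
  n2 <- pmin(by_atp, by_e)
  unadj <- 100 * n2 / n2_fixation_rate
  list(unadjusted_pct = unadj,
       adjusted_pct = adjust_o2_drawdown(unadj, params$f_o2_drawdown),
       limiting = ifelse(by_atp <= by_e, "atp", "electrons"))
}

#' Apply the oxygen-drawdown adjustment to a fuelable-fixation percentage
#'
#' @param unadjusted_pct Percentage before adjustment.
#' @param f_o2_drawdown Fraction of dark respiration spent on oxygen
#'   drawdown (default 0.60).
#' @return \code{unadjusted_pct * (1 - f_o2_drawdown)}.
#' @export
#' @examples
#' adjust_o2_drawdown(9)   # 3.6
#' adjust_o2_drawdown(28)  # 11.2
adjust_o2_drawdown <- function(unadjusted_pct, f_o2_drawdown = 0.60) {
  if (f_o2_drawdown < 0 || f_o2_drawdown >= 1)
    stop("f_o2_drawdown must be in [0, 1)")
  unadjusted_pct * (1 - f_o2_drawdown)
}

#' Type II (reduced major axis) regression
#'
#' Geometric-mean regression used to calibrate one proxy against another
#' when both carry error: \code{slope = sign(r) * sd(y) / sd(x)}, line
#' through the means, with the Pearson correlation reported.
#'
#' @param x,y Numeric vectors (>= 3 points, both with variance).
#' @return List: \code{slope}, \code{intercept}, \code{r}.
#' @export
type2_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("type II regression needs >= 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("type II regression needs variance in both axes")
  r <- stats::cor(x, y)
  slope <- sign(r) * stats::sd(y) / stats::sd(x)
  if (r == 0) slope <- stats::sd(y) / stats::sd(x)  # degenerate sign choice
  list(slope = slope, intercept = mean(y) - slope * mean(x), r = r)
}
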