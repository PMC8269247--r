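# Table schemas: required columns and coercions for every table the
# pipeline reads or writes.  All files are delimited UTF-8 with a header
# row; missing values are empty fields.

#' @noRd
table_schemas <- list(
  samples = list(required = c("sample_id", "t_hours", "period",
                              "replicate", "volume_L", "sample_class"),
                 numeric = c("t_hours", "clock_hour", "volume_L")),
  areas = list(required = c("compound", "sample_id", "area"),
               numeric = "area"),
  is_areas = list(required = c("is_name", "sample_id", "area"),
                  numeric = "area"),
  compounds = list(required = c("name", "n_carbon", "n_nitrogen",
                                "quant_mode"),
                   numeric = c("n_carbon", "n_nitrogen")),
  transcripts = list(required = c("taxon", "ko", "sample_id", "abundance"),
                     numeric = "abundance"),
  covariates = list(required = c("t_hours", "poc_umol"),
                    numeric = c("t_hours", "clock_hour", "poc_umol")),
  truth = list(required = c("signal_id", "baseline", "is_diel",
                            "fold_change", "peak_hour"),
               numeric = c("baseline", "fold_change", "peak_hour",
                           "noise_cv")),
  links = list(required = c("metabolite", "ko_id", "role"),
               numeric = character(0)),
  concentrations = list(required = c("compound", "sample_id", "pmol_per_L"),
                        numeric = "pmol_per_L"),
  rhythm_results = list(required = c("signal_id", "scope", "p_raw", "q_fdr",
                                     "is_diel"),
                        numeric = c("p_raw", "q_fdr", "peak_hour",
                                    "amplitude", "mesor", "fold_change")))

#' Read and validate a pipeline table
#'
#' Checks required columns by name, coerces declared numeric columns, and
#' derives \code{clock_hour} from \code{datetime_iso} when absent (with a
#' row-numbered error on unparseable timestamps).
#'
#' @param path File path (CSV, or TSV for \code{schema = "links"}).
#' @param schema One of \code{"samples"}, \code{"areas"}, \code{"is_areas"},
#'   \code{"compounds"}, \code{"transcripts"}, \code{"covariates"},
#'   \code{"truth"}, \code{"links"}, \code{"concentrations"},
#'   \code{"rhythm_results"}.
#' @return Validated data.frame.
#' @export
read_table <- function(path, schema) {
  if (!schema %in% names(table_schemas)) stop("unknown schema: ", schema)
  sc <- table_schemas[[schema]]
  sep <- if (schema == "links" && grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          na.strings = c("", "NA"), encoding = "UTF-8")
  miss <- setdiff(sc$required, names(df))
  if (length(miss) > 0)
    stop("missing column ", paste(miss, collapse = ", "), " in ", path)
  if ("clock_hour" %in% sc$numeric && !"clock_hour" %in% names(df) &&
      "datetime_iso" %in% names(df)) {
    tt <- as.POSIXct(df$datetime_iso, format = "%Y-%m-%dT%H:%M:%S",
                     tz = "UTC")
    bad <- which(is.na(tt) & !is.na(df$datetime_iso))
    if (length(bad) > 0)
      stop("unparseable datetime at row ", bad[1], " of ", path)
    df$clock_hour <- as.numeric(format(tt, "%H")) +
      as.numeric(format(tt, "%M")) / 60
  }
  for (cn in intersect(sc$numeric, names(df)))
    df[[cn]] <- as.numeric(df[[cn]])
  message(sprintf("read %s: %d rows, %d columns", basename(path),
                  nrow(df), ncol(df)))
  df
}

#' @noRd
write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
}

#' Write a simulated study to a directory of delimited tables
#'
#' Emits samples.csv, areas.csv, is_areas.csv, compounds.csv,
#' covariates.csv, truth.csv, the calibration tables, and (when present)
#' transcripts.csv and transcript_truth.csv, plus design.cfg.
#'
#' @param study A \code{diel_study}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_csv_plain(study$samples, p("samples.csv"))
  write_csv_plain(study$areas, p("areas.csv"))
  write_csv_plain(study$is_areas, p("is_areas.csv"))
  write_csv_plain(study$compounds, p("compounds.csv"))
  write_csv_plain(study$covariates, p("covariates.csv"))
  write_csv_plain(study$truth, p("truth.csv"))
  write_csv_plain(study$calibration$is_spikes, p("is_spikes.csv"))
  write_csv_plain(study$calibration$external_cal, p("external_cal.csv"))
  if (!is.null(study$calibration$std_addition))
    write_csv_plain(study$calibration$std_addition, p("std_addition.csv"))
  if (!is.null(study$transcripts)) {
    write_csv_plain(study$transcripts, p("transcripts.csv"))
    write_csv_plain(study$transcript_truth, p("transcript_truth.csv"))
  }
  dg <- study$design
  write_config(list(start_clock_hour = dg$start_clock_hour,
                    sampling_interval = dg$sampling_interval,
                    n_days_per_period = paste(dg$n_days_per_period,
                                              collapse = " "),
                    gap_between_periods = dg$gap_between_periods,
                    n_replicates = dg$n_replicates,
                    volume_filtered = dg$volume_filtered,
                    start_date = dg$start_date,
                    seed = study$seed),
               p("design.cfg"))
  invisible(dir)
}

#' Read a study directory back into a \code{diel_study}
#'
#' Inverse of \code{\link{write_study}}; the round trip is lossless for all
#' tables.
#'
#' @param dir Directory written by \code{\link{write_study}}.
#' @return A \code{diel_study} list.
#' @export
read_study <- function(dir) {
  p <- function(f) file.path(dir, f)
  cfg <- read_config(p("design.cfg"))
  design <- study_design(
    start_clock_hour = cfg$start_clock_hour,
    sampling_interval = cfg$sampling_interval,
    n_days_per_period = as.numeric(strsplit(as.character(
      cfg$n_days_per_period), " ")[[1]]),
    gap_between_periods = cfg$gap_between_periods,
    n_replicates = cfg$n_replicates,
    volume_filtered = cfg$volume_filtered,
    start_date = as.character(cfg$start_date))
  std_add <- if (file.exists(p("std_addition.csv")))
    utils::read.csv(p("std_addition.csv"), stringsAsFactors = FALSE)
  transcripts <- if (file.exists(p("transcripts.csv")))
    read_table(p("transcripts.csv"), "transcripts")
  tr_truth <- if (file.exists(p("transcript_truth.csv")))
    utils::read.csv(p("transcript_truth.csv"), stringsAsFactors = FALSE)
  structure(list(
    design = design,
    samples = read_table(p("samples.csv"), "samples"),
    areas = read_table(p("areas.csv"), "areas"),
    is_areas = read_table(p("is_areas.csv"), "is_areas"),
    compounds = read_table(p("compounds.csv"), "compounds"),
    calibration = list(
      is_spikes = utils::read.csv(p("is_spikes.csv"),
                                  stringsAsFactors = FALSE),
      external_cal = utils::read.csv(p("external_cal.csv"),
                                     stringsAsFactors = FALSE),
      std_addition = std_add),
    covariates = read_table(p("covariates.csv"), "covariates"),
    transcripts = transcripts, transcript_truth = tr_truth,
    truth = read_table(p("truth.csv"), "truth"),
    model = NULL, seed = cfg$seed), class = "diel_study")
}

#' Read a flat key-value configuration file
#'
#' Lines of the form \code{key = value}; blank lines and \code{#} comments
#' ignored; values that parse as numbers are returned numeric.  Dotted keys
#' (e.g. \code{stoichiometry.atp_per_glucose}) are kept flat.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a flat key-value configuration file
#'
#' @param config Named list of scalars.
#' @param path Destination path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  writeLines(paste(names(config), unlist(config), sep = " = "), path)
  invisible(path)
}
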