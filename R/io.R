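#' Read a beat-level R-R CSV
#'
#' Expects a header `time_s,rr_ms` (extra columns are kept). Malformed
#' rows — non-numeric fields, non-positive R-R, non-increasing timestamps —
#' abort with the offending file line number.
#'
#' @param path CSV path.
#' @return A [beat_series()].
#' @export
read_beat_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "rr_ms") %in% names(df))) {
    stop("beat CSV must have columns time_s, rr_ms", call. = FALSE)
  }
  if (nrow(df) == 0L) return(beat_series(numeric(0), numeric(0)))
  line <- function(i) i + 1L  # header occupies line 1
  tnum <- suppressWarnings(as.numeric(df$time_s))
  rnum <- suppressWarnings(as.numeric(df$rr_ms))
  bad <- which(is.na(tnum) | is.na(rnum))
  if (length(bad)) {
    stop(sprintf("malformed row at line %d of %s", line(bad[1]), path),
         call. = FALSE)
  }
  bad <- which(rnum <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive R-R at line %d of %s", line(bad[1]), path),
         call. = FALSE)
  }
  bad <- which(diff(tnum) <= 0)
  if (length(bad)) {
    stop(sprintf("non-monotone timestamp at line %d of %s",
                 line(bad[1] + 1L), path), call. = FALSE)
  }
  out <- beat_series(tnum, rnum)
  extra <- setdiff(names(df), c("time_s", "rr_ms"))
  for (nm in extra) out[[nm]] <- df[[nm]]
  out
}

#' @rdname read_beat_csv
#' @param beats A [beat_series()].
#' @param path Output CSV path.
#' @export
write_beat_csv <- function(beats, path) {
  utils::write.csv(as.data.frame(beats)[c("time_s", "rr_ms")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a binned R-R CSV
#'
#' Columns `bin_start_h,rr_ms`; missing bins are empty fields.
#'
#' @param path CSV path.
#' @param calving_time Optional calving time attached on read.
#' @return A [binned_series()].
#' @export
read_binned_csv <- function(path, calving_time = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("bin_start_h", "rr_ms") %in% names(df))) {
    stop("binned CSV must have columns bin_start_h, rr_ms", call. = FALSE)
  }
  binned_series(as.numeric(df$bin_start_h),
                suppressWarnings(as.numeric(df$rr_ms)),
                bin_width = if (nrow(df) > 1) {
                  df$bin_start_h[2] - df$bin_start_h[1]
                } else 0.5,
                calving_time = calving_time)
}

#' @rdname read_binned_csv
#' @param binned A [binned_series()].
#' @export
write_binned_csv <- function(binned, path) {
  utils::write.csv(as.data.frame(binned), path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}

#' Read/write a components CSV
#'
#' Columns `bin_start_h,observed_ms,trend_ms,seasonal_ms,remainder_ms`.
#'
#' @param dec An `rr_decomposition` from [stl_decompose()].
#' @param path CSV path.
#' @export
write_components_csv <- function(dec, path) {
  stopifnot(inherits(dec, "rr_decomposition"))
  utils::write.csv(data.frame(
    bin_start_h = dec$time, observed_ms = dec$observed,
    trend_ms = dec$trend, seasonal_ms = dec$seasonal,
    remainder_ms = dec$remainder), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_components_csv
#' @return `read_components_csv()` returns a data frame of the five
#'   columns.
#' @export
read_components_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("bin_start_h", "observed_ms", "trend_ms", "seasonal_ms",
            "remainder_ms")
  if (!all(need %in% names(df))) {
    stop("components CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write an indicator panel CSV
#'
#' One column per indicator on the shared bin grid, empty fields during
#' warm-up.
#'
#' @param panel Named list of [indicator_series()] on one grid.
#' @param path CSV path.
#' @export
write_indicator_csv <- function(panel, path) {
  stopifnot(length(panel) > 0)
  df <- data.frame(bin_start_h = panel[[1]]$time)
  for (nm in names(panel)) df[[tolower(nm)]] <- panel[[nm]]$value
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Write a signals CSV
#'
#' Columns `subject_id,indicator,mode,found,signal_time_h,peak_value,
#' remaining_h`.
#'
#' @param signals Data frame with those columns.
#' @param path CSV path.
#' @export
write_signals_csv <- function(signals, path) {
  utils::write.csv(signals, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every stage parameter with its default. Unknown keys are
#' rejected, so configs round-trip exactly.
#'
#' @param ... Overrides of the defaults listed below.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    subject_id = "subject",
    calving_time = NA_real_,       # hours from recording start
    outlier_threshold = 0.30,
    outlier_window = 60L,
    bin_width = 0.5,
    min_beats = 30L,
    max_gap = 48L,
    stl_period = 48L,
    stl_s_window = "periodic",
    stl_t_window = NULL,
    stl_robust = FALSE,
    sma_n = 12L,
    mad_n = 12L,
    macd_short = 12L,
    macd_long = 26L,
    rsi_n = 14L,
    indicator_mode = "percent",
    detector_mode = "retrospective",
    online_k = 3L,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(over)] <- over
  cfg <- structure(defaults, class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!(config$outlier_threshold > 0 && config$outlier_threshold < 1)) {
    stop("outlier_threshold must be in (0, 1)", call. = FALSE)
  }
  if (config$macd_short >= config$macd_long) {
    stop("macd_short must be smaller than macd_long", call. = FALSE)
  }
  if (!config$indicator_mode %in% c("percent", "difference")) {
    stop("indicator_mode must be 'percent' or 'difference'", call. = FALSE)
  }
  if (!config$detector_mode %in% c("retrospective", "online")) {
    stop("detector_mode must be 'retrospective' or 'online'", call. = FALSE)
  }
  if (config$bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  invisible(config)
}

#' Read/write a pipeline config as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))],
                   path)
  invisible(path)
}

#' Run the whole analysis pipeline on one recording
#'
#' Chains preprocessing (outlier filter, binning, imputation), STL
#' decomposition, the indicator panel, and turning-point detection, and
#' writes each stage's artifact plus a run log under `out_dir`. With a
#' fixed config the data artifacts are byte-identical across reruns.
#'
#' @param beats A [beat_series()] or path to a beat CSV.
#' @param config A [pipeline_config()]; `calving_time` must be set to get
#'   remaining hours.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return Invisibly, a list with `binned`, `decomposition`, `panel`,
#'   `signals` (data frame, one row per indicator), and `log` (character
#'   vector of stage records).
#' @export
run_pipeline <- function(beats, config = pipeline_config(), out_dir = NULL) {
  validate_pipeline_config(config)
  if (is.character(beats)) beats <- read_beat_csv(beats)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  note("stage=input subject=%s beats=%d seed=%d", config$subject_id,
       nrow(beats), config$seed)

  filt <- filter_outliers(beats, threshold = config$outlier_threshold,
                          window = config$outlier_window)
  note("stage=filter_outliers threshold=%g window=%d removed=%d",
       config$outlier_threshold, as.integer(config$outlier_window),
       length(filt$removed))

  binned <- bin_series(filt$beats, bin_width = config$bin_width,
                       min_beats = config$min_beats,
                       calving_time = config$calving_time)
  note("stage=bin_series bin_width=%g min_beats=%d bins=%d missing=%d",
       config$bin_width, as.integer(config$min_beats), nrow(binned),
       sum(is.na(binned$rr_ms)))

  binned <- impute_gaps(binned, max_gap = config$max_gap)
  note("stage=impute_gaps max_gap=%d imputed=%d",
       as.integer(config$max_gap), length(attr(binned, "imputed")))

  dec <- stl_decompose(binned, period = config$stl_period,
                       s_window = config$stl_s_window,
                       t_window = config$stl_t_window,
                       robust = config$stl_robust)
  note("stage=stl_decompose period=%d s_window=%s",
       as.integer(config$stl_period), as.character(config$stl_s_window))

  panel <- indicator_panel(dec, sma_n = config$sma_n, mad_n = config$mad_n,
                           macd_short = config$macd_short,
                           macd_long = config$macd_long,
                           rsi_n = config$rsi_n,
                           mode = config$indicator_mode)

  sig_rows <- lapply(names(panel), function(nm) {
    sig <- if (config$detector_mode == "retrospective") {
      detect_peak_retrospective(panel[[nm]])
    } else {
      detect_peak_online(panel[[nm]], k = config$online_k)
    }
    rem <- if (sig$found && !is.na(config$calving_time)) {
      config$calving_time - sig$signal_time
    } else NA_real_
    data.frame(subject_id = config$subject_id, indicator = nm,
               mode = config$detector_mode, found = sig$found,
               signal_time_h = if (sig$found) sig$signal_time else NA_real_,
               peak_value = if (sig$found) sig$peak_value else NA_real_,
               remaining_h = rem)
  })
  signals <- do.call(rbind, sig_rows)
  note("stage=detect mode=%s found=%d/%d", config$detector_mode,
       sum(signals$found), nrow(signals))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_binned_csv(binned, file.path(out_dir, "binned.csv"))
    write_components_csv(dec, file.path(out_dir, "components.csv"))
    write_indicator_csv(panel, file.path(out_dir, "indicators.csv"))
    write_signals_csv(signals, file.path(out_dir, "signals.csv"))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  invisible(list(binned = binned, decomposition = dec, panel = panel,
                 signals = signals, log = log))
}

#' Write a synthetic record's ground truth and metadata
#'
#' Truth CSV columns: `bin_start_h,trend_ms,seasonal_ms,remainder_ms`;
#' metadata is a key=value text file echoing the generating spec.
#'
#' @param record An `rr_record`.
#' @param truth_path Truth CSV path.
#' @param meta_path Optional metadata path.
#' @export
write_truth_csv <- function(record, truth_path, meta_path = NULL) {
  stopifnot(inherits(record, "rr_record"))
  utils::write.csv(record$components, truth_path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(meta_path)) {
    sp <- record$spec
    flat <- vapply(names(sp), function(nm) {
      v <- sp[[nm]]
      if (is.list(v)) v <- unlist(v)
      paste0(nm, "=", paste(format(v, digits = 15), collapse = ";"))
    }, character(1))
    writeLines(c(flat,
                 sprintf("true_turning_time=%g", record$true_turning_time),
                 sprintf("calving_time=%g", record$calving_time)),
               meta_path)
  }
  invisible(truth_path)
}
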