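# File formats and configuration.
#
# All interchange files are header-rowed UTF-8 CSV with "." decimals, time
# in seconds from recording start, and empty fields for missing values.
# Region ids are opaque integers; no image-space coordinates are stored.

#' Default pipeline configuration
#'
#' Collects every tunable of the pipeline with its default: frame rates,
#' POS window, HR windowing and search band, jump threshold, segment
#' length, LF/HF band edges, NN bounds, cross-validation folds and the
#' master seed. The object round-trips losslessly through JSON or YAML.
#'
#' @return named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    fps_rgb = 30, fps_thermal = 8,
    pos_window_s = 1.6,
    hr_win_s = 6, hr_hop_s = 1, hr_band_hz = c(0.65, 4.0),
    max_jump_bpm = 25,
    segment_s = 120,
    lf_band_hz = c(0.04, 0.15), hf_band_hz = c(0.15, 0.40),
    nn_bounds_ms = c(300, 2000),
    thermal_min_coverage = 0.5, thermal_ref_roi = 58,
    cv_folds = 5, seed = 1,
    roi_include = NULL
  ), class = "pipeline_config")
}

validate_config <- function(cfg) {
  assert_scalar_num(cfg$fps_rgb, "fps_rgb", lower = 10)
  assert_scalar_num(cfg$fps_thermal, "fps_thermal", lower = 0.5)
  assert_scalar_num(cfg$pos_window_s, "pos_window_s", lower = 0.5, upper = 10)
  assert_scalar_num(cfg$hr_win_s, "hr_win_s", lower = 2, upper = 30)
  assert_scalar_num(cfg$hr_hop_s, "hr_hop_s", lower = 1 / cfg$fps_rgb)
  if (length(cfg$hr_band_hz) != 2L || cfg$hr_band_hz[1L] >= cfg$hr_band_hz[2L])
    pt_validation_error("hr_band_hz must be an increasing pair")
  assert_scalar_num(cfg$max_jump_bpm, "max_jump_bpm", lower = 1)
  assert_scalar_num(cfg$segment_s, "segment_s", lower = 30)
  assert_scalar_num(cfg$cv_folds, "cv_folds", lower = 2, upper = 20)
  assert_scalar_num(cfg$seed, "seed", lower = 0, upper = 2^31 - 1)
  invisible(cfg)
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return validated `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) pt_validation_error(paste("no such config file:", path))
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- default_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    pt_validation_error(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg[names(raw)] <- raw
  validate_config(structure(cfg, class = "pipeline_config"))
}

#' Write a pipeline configuration
#'
#' @param cfg a `pipeline_config`.
#' @param path output path (`.json`, `.yaml` or `.yml`).
#' @export
write_config <- function(cfg, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    yaml::write_yaml(unclass(cfg), path)
  }
  invisible(path)
}

csv_dialects <- list(
  rgb = c("time_s", "roi_id", "R", "G", "B"),
  thermal = c("time_s", "roi_id", "temp_c"),
  beats = "beat_time_s",
  hr = c("t_center_s", "roi_id", "hr_bpm"),
  features = c("subject_id", "label")
)

#' Read a typed pipeline CSV
#'
#' Parses and validates one of the pipeline's CSV dialects into its typed
#' object; malformed content is reported with row numbers.
#'
#' @param path CSV file path.
#' @param kind one of `"rgb"`, `"thermal"`, `"beats"`, `"hr"`,
#'   `"features"`.
#' @param fps frame rate for `rgb`/`thermal` (inferred from the median
#'   time step when omitted).
#' @return a [roi_trace_set()], [thermal_trace_set()], [beat_series()],
#'   list of [hr_series()] (named by roi id, `"agg"` for the aggregate), or
#'   [fusion_dataset()].
#' @export
read_trace_csv <- function(path, kind = c("rgb", "thermal", "beats", "hr", "features"),
                           fps = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) pt_validation_error(paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- csv_dialects[[kind]]
  miss <- setdiff(need, names(df))
  if (length(miss))
    pt_validation_error(sprintf("%s: missing column(s) %s", path,
                                paste(miss, collapse = ", ")))
  if (kind %in% c("rgb", "thermal", "beats", "hr")) {
    extra <- setdiff(names(df), need)
    if (length(extra))
      pt_validation_error(sprintf("%s: unknown column(s) %s", path,
                                  paste(extra, collapse = ", ")))
  }
  check_monotone <- function(tcol, by = NULL) {
    groups <- if (is.null(by)) list(seq_len(nrow(df))) else split(seq_len(nrow(df)), by)
    for (g in groups) {
      bad <- g[which(diff(df[[tcol]][g]) <= 0) + 1L]
      if (length(bad))
        pt_validation_error(sprintf("%s: non-monotone %s at row(s) %s", path,
                                    tcol, paste(utils::head(bad + 1L, 5L), collapse = ", ")))
    }
  }
  switch(kind,
    rgb = {
      check_monotone("time_s", df$roi_id)
      if (is.null(fps)) fps <- 1 / stats::median(diff(sort(unique(df$time_s))))
      roi_trace_set(df, fps = fps)
    },
    thermal = {
      check_monotone("time_s", df$roi_id)
      bad <- which(!df$roi_id %in% thermal_rois()$roi_id)
      if (length(bad))
        pt_validation_error(sprintf("%s: roi_id not in the 22-region set at row(s) %s",
                                    path, paste(utils::head(bad + 1L, 5L), collapse = ", ")))
      if (is.null(fps)) fps <- 1 / stats::median(diff(sort(unique(df$time_s))))
      thermal_trace_set(df, fps = fps)
    },
    beats = {
      check_monotone("beat_time_s")
      beat_series(df$beat_time_s, duration_s = max(df$beat_time_s))
    },
    hr = {
      out <- lapply(split(df, df$roi_id), function(sub) {
        id <- sub$roi_id[1L]
        hr_series(sub$t_center_s, sub$hr_bpm,
                  roi_id = if (identical(as.character(id), "agg")) NULL else id)
      })
      out
    },
    features = {
      feats <- setdiff(names(df), c("subject_id", "label"))
      modality <- ifelse(grepl("^thermal", feats), "thermal", "rppg")
      fusion_dataset(df, stats::setNames(modality, feats))
    })
}

#' Write a typed pipeline object to CSV
#'
#' Inverse of [read_trace_csv()]: serialises the object into its CSV
#' dialect so that reading it back reconstructs an equal object.
#'
#' @param x a `roi_trace_set`, `thermal_trace_set`, `beat_series`, list of
#'   `hr_series`, or `fusion_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  df <- if (inherits(x, "roi_trace_set")) {
    x$traces
  } else if (inherits(x, "thermal_trace_set")) {
    x$traces
  } else if (inherits(x, "beat_series")) {
    data.frame(beat_time_s = x$beat_times)
  } else if (inherits(x, "fusion_dataset")) {
    as.data.frame(x)
  } else if (is.list(x) && all(vapply(x, inherits, logical(1L), "hr_series"))) {
    do.call(rbind, lapply(x, function(s) {
      id <- attr(s, "roi_id")
      data.frame(t_center_s = s$t_center_s,
                 roi_id = if (is.null(id)) "agg" else id,
                 hr_bpm = s$hr_bpm)
    }))
  } else {
    pt_validation_error("unsupported object for write_trace_csv")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
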