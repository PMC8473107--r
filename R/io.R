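# CSV and JSON interchange. All CSVs are UTF-8, '.' decimal, with headers:
#   RRI:      t_sec,rri_ms
#   EEG:      t_sec,attention,meditation
#   clicks:   t_sec,polarity
#   aligned:  t_sec,arousal_raw,valence_raw
#   estimates t_sec,valence,arousal,label,intensity_raw,intensity_level
#   dataset:  t_sec,x_arousal,x_valence,y

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) {
    ra_stop(sprintf("input file not found: %s", path), "roboaffect_io_error",
            path = path)
  }
  df <- utils::read.csv(path)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    ra_stop(sprintf("%s: missing column(s) %s", path,
                    paste(missing, collapse = ", ")),
            "roboaffect_io_error", path = path)
  }
  df
}

#' Read biosignal and click CSV files
#'
#' `read_rri_csv()` expects columns `t_sec,rri_ms` and returns an
#' [rri_series()]; `read_eeg_csv()` expects `t_sec,attention,meditation`;
#' `read_clicks_csv()` expects `t_sec,polarity` with polarity `like` /
#' `dislike`.
#'
#' @param path file path.
#' @return A data frame (an `rri_series` for `read_rri_csv()`).
#' @export
read_rri_csv <- function(path) {
  df <- read_checked_csv(path, c("t_sec", "rri_ms"))
  rri_series(df$t_sec, df$rri_ms)
}

#' @rdname read_rri_csv
#' @export
read_eeg_csv <- function(path) {
  df <- read_checked_csv(path, c("t_sec", "attention", "meditation"))
  arousal_index(df$attention, df$meditation)  # range validation
  df[order(df$t_sec), c("t_sec", "attention", "meditation")]
}

#' @rdname read_rri_csv
#' @export
read_clicks_csv <- function(path) {
  df <- read_checked_csv(path, c("t_sec", "polarity"))
  if (!all(df$polarity %in% c("like", "dislike"))) {
    ra_stop(sprintf("%s: polarity must be 'like' or 'dislike'", path),
            "roboaffect_io_error", path = path)
  }
  df[order(df$t_sec), c("t_sec", "polarity")]
}

#' Write a simulated session to CSV files plus a manifest
#'
#' Writes `rri.csv`, `eeg.csv`, `clicks.csv`, `expressions.csv` and
#' `manifest.json` (specs, condition, seed) into `dir`. Output is
#' deterministic for a fixed session object.
#'
#' @param session an `affect_session` from [generate_session()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_session_csv <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("rri.csv", "eeg.csv", "clicks.csv",
                            "expressions.csv", "manifest.json"))
  utils::write.csv(session$rri[, c("t_sec", "rri_ms")], paths[1],
                   row.names = FALSE)
  utils::write.csv(session$eeg, paths[2], row.names = FALSE)
  utils::write.csv(session$clicks, paths[3], row.names = FALSE)
  utils::write.csv(session$expressions, paths[4], row.names = FALSE)
  manifest <- list(
    condition = session$condition, seed = session$seed,
    baseline_s = session$baseline_s, stimulus_s = session$stimulus_s,
    tick_interval = session$tick_interval,
    participant = unclass(session$participant),
    signal = unclass(session$signal),
    baseline_signal = unclass(session$baseline_signal),
    package_version = as.character(utils::packageVersion("roboaffect"))
  )
  jsonlite::write_json(manifest, paths[5], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Write a fitted preference model to JSON
#'
#' @param model a `preference_model`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
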