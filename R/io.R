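# write a data frame as CSV with numeric columns at 9 significant digits
.write_csv9 <- function(df, path) {
  out <- as.data.frame(df)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 9, format = "g")
      out[[col]][out[[col]] %in% c("NA", " NA")] <- NA
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write joint-angle series as tidy CSV
#'
#' Long layout, one sample per row: `time_s`, `joint`, `side`
#' (`left`/`right`/`none`), `angle_deg`.
#'
#' @param angles Wide `joint_angle_set` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tidy_angles <- function(angles, path) {
  long <- tidyr::pivot_longer(
    as_tibble(angles), -dplyr::all_of("time_s"),
    names_to = "series", values_to = "angle_deg"
  )
  long$joint <- sub("_(left|right)$", "", long$series)
  long$side <- ifelse(grepl("_left$", long$series), "left",
    ifelse(grepl("_right$", long$series), "right", "none")
  )
  .write_csv9(long[c("time_s", "joint", "side", "angle_deg")], path)
}

#' Read tidy joint-angle CSV into the wide layout
#'
#' Expects columns `time_s`, `joint`, `side`, `angle_deg` (as written by
#' [write_tidy_angles()]).
#'
#' @param path CSV file.
#' @param rate,onset_time,halt_time Optional metadata attached as
#'   attributes (rate inferred from `time_s` when absent).
#' @return A wide `joint_angle_set` tibble.
#' @export
read_trial_angles <- function(path, rate = NULL, onset_time = 0,
                              halt_time = NULL) {
  long <- as_tibble(utils::read.csv(path))
  long$series <- ifelse(long$side == "none", long$joint,
    paste(long$joint, long$side, sep = "_")
  )
  wide <- tidyr::pivot_wider(long[c("time_s", "series", "angle_deg")],
    names_from = "series", values_from = "angle_deg"
  )
  wide <- wide[order(wide$time_s), ]
  structure(wide,
    class = c("joint_angle_set", class(wide)),
    rate = rate %||% 1 / stats::median(diff(wide$time_s)),
    onset_time = onset_time, halt_time = halt_time
  )
}

#' Write EMG channels as tidy CSV
#'
#' Long layout: `time_s`, `channel`, `mv`.
#'
#' @param emg Wide `emg_recording` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tidy_emg <- function(emg, path) {
  long <- tidyr::pivot_longer(
    as_tibble(emg), -dplyr::all_of("time_s"),
    names_to = "channel", values_to = "mv"
  )
  .write_csv9(long, path)
}

#' Read tidy EMG CSV plus an MVC reference CSV
#'
#' @param path CSV with columns `time_s`, `channel`, `mv`.
#' @param mvc_path Optional CSV with columns `muscle`, `mvc_mv`.
#' @param rate,onset_time,halt_time Optional metadata.
#' @return A wide `emg_recording` tibble.
#' @export
read_trial_emg <- function(path, mvc_path = NULL, rate = NULL,
                           onset_time = 0, halt_time = NULL) {
  long <- as_tibble(utils::read.csv(path))
  wide <- tidyr::pivot_wider(long,
    names_from = "channel", values_from = "mv"
  )
  wide <- wide[order(wide$time_s), ]
  mvc <- NULL
  if (!is.null(mvc_path)) {
    m <- utils::read.csv(mvc_path)
    mvc <- setNames(m$mvc_mv, m$muscle)
  }
  structure(wide,
    class = c("emg_recording", class(wide)),
    rate = rate %||% 1 / stats::median(diff(wide$time_s)),
    mvc_mv = mvc, onset_time = onset_time, halt_time = halt_time
  )
}

#' Read a force-plate COP export
#'
#' Expects columns `time_s`, `ap_cm`, `ml_cm`.
#'
#' @param path CSV file.
#' @param condition Optional condition label (attached as attribute).
#' @return A `cop_trace` tibble.
#' @export
read_cop_csv <- function(path, condition = NULL) {
  df <- as_tibble(utils::read.csv(path))
  structure(df,
    class = c("cop_trace", class(df)),
    condition = condition,
    rate = 1 / stats::median(diff(df$time_s))
  )
}

#' Write / read the subject-level feature table
#'
#' One CSV row per subject; floats carry 9 significant digits.
#'
#' @param features Feature tibble (see [build_feature_table()]).
#' @param path CSV file.
#' @return `path` invisibly (write) or the feature tibble (read).
#' @export
write_feature_csv <- function(features, path) {
  .write_csv9(features, path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  as_tibble(utils::read.csv(path))
}

#' Read or write an analysis config as JSON or YAML
#'
#' The format is chosen from the file extension (`.json` vs
#' `.yaml`/`.yml`).
#'
#' @param path Config file.
#' @return The config list (read) or `path` invisibly (write).
#' @export
read_analysis_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
}

#' @rdname read_analysis_config
#' @param config Config list to write.
#' @export
write_analysis_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(config, path)
  } else {
    jsonlite::write_json(config, path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
    )
  }
  invisible(path)
}

#' Write an analysis report to a directory
#'
#' Writes the feature table, univariate comparisons, coefficient report and
#' permutation points as CSV, model summaries and the resolved config as
#' JSON, plus a manifest listing every file.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param out_dir Target directory (created if needed).
#' @return The manifest (named list of paths), invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  .write_csv9(report$features, p("features.csv"))
  .write_csv9(report$univariate, p("univariate.csv"))
  .write_csv9(report$coefficients, p("coefficients.csv"))
  .write_csv9(report$permutation$points, p("permutation_points.csv"))
  summaries <- list(
    base_models = lapply(report$base_models, function(m) {
      list(r2 = sum(m$R2), q2 = m$Q2, n_components = m$n_components)
    }),
    top_model = list(
      r2y = report$top_model$R2Y, q2 = report$top_model$Q2,
      n_orth = report$top_model$n_orth,
      positive = report$top_model$positive
    ),
    permutation = list(
      r2y_intercept = report$permutation$r2y_intercept,
      q2_intercept = report$permutation$q2_intercept,
      prop_q2_ge = report$permutation$prop_q2_ge,
      verdict = report$permutation$verdict
    ),
    multiple_testing = "none applied"
  )
  jsonlite::write_json(summaries, p("model_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  write_analysis_config(report$config, p("config_resolved.json"))
  files <- c(
    "features.csv", "univariate.csv", "coefficients.csv",
    "permutation_points.csv", "model_summary.json", "config_resolved.json"
  )
  manifest <- list(files = files, created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, p("manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
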