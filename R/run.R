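#' Run the full video-analysis workflow
#'
#' Classifies a frame sequence against a calibration, applies optional
#' manual overrides, segments closure events, computes windowed indicators
#' and the session summary, and writes the indicator CSV, summary CSV,
#' charts and a reproducibility manifest to `out_dir`.
#'
#' @param frames A list of grayscale frame matrices, or a path to a PNG
#'   frame directory.
#' @param calibration A `calibration_set`, or a path to a YAML calibration
#'   file (resolved against the frames).
#' @param landmarks Landmark provider (see [classify_sequence()]).
#' @param overrides Optional override tibble or CSV path
#'   (see [apply_overrides()]).
#' @param fps Frames per second (default 60).
#' @param thresholds A [threshold_config()].
#' @param out_dir Output directory (created if needed).
#' @param source_id Identifier recorded in outputs.
#' @return Invisibly, a list with `series`, `events`, `windows`, `summary`
#'   and the written file paths.
#' @export
run_analysis <- function(frames, calibration, landmarks,
                         overrides = NULL, fps = 60,
                         thresholds = threshold_config(),
                         out_dir = ".", source_id = "session") {
  if (is.character(frames)) frames <- read_frame_dir(frames)
  if (is.character(calibration)) {
    cal <- read_calibration(calibration)
    calibration <- build_templates(frames, cal$selections,
                                   threshold = cal$threshold)
  }
  series <- classify_sequence(frames, calibration, landmarks,
                              fps = fps, source_id = source_id)
  if (!is.null(overrides)) series <- apply_overrides(series, overrides)
  config <- segmentation_config(fps = fps)
  events <- label_events(segment_events(series), config)
  windows <- window_indicators(series, events, thresholds, config)
  summary <- session_summary(windows)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    indicators = file.path(out_dir, "indicators.csv"),
    summary = file.path(out_dir, "session_summary.csv"),
    series_chart = file.path(out_dir, "eye_states.png"),
    indicator_chart = file.path(out_dir, "indicators.png"),
    manifest = file.path(out_dir, "manifest.json")
  )
  export_indicator_table(windows, paths$indicators)
  readr::write_csv(summary, paths$summary, na = "")
  ggplot2::ggsave(paths$series_chart, ggplot2::autoplot(series),
                  width = 8, height = 4, dpi = 120)
  ggplot2::ggsave(paths$indicator_chart, ggplot2::autoplot(windows),
                  width = 8, height = 6, dpi = 120)
  write_manifest(paths$manifest, list(
    workflow = "analyze", source_id = source_id, fps = fps,
    n_frames = length(frames), thresholds = thresholds,
    calibration = list(n_pairs = length(calibration$pairs),
                       patch_size = calibration$patch_size,
                       threshold = calibration$threshold)
  ))
  invisible(list(series = series, events = events, windows = windows,
                 summary = summary, paths = paths))
}

#' Run the synthetic-session workflow
#'
#' Generates a ground-truthed aperture session, optionally renders it to PNG
#' frames, and writes the ground-truth JSON, the expected indicator CSV
#' (computed from the thresholded aperture mask) and a manifest — enough to
#' run [run_analysis()] end-to-end offline.
#'
#' @param profile A [drowsiness_profile()].
#' @param duration_s Session length in seconds.
#' @param fps Frames per second.
#' @param out_dir Output directory.
#' @param render Also write rendered PNG frames (default `FALSE`; slow for
#'   long sessions).
#' @param thresholds A [threshold_config()].
#' @return Invisibly, a list with `session`, `windows` and file paths.
#' @export
run_simulation <- function(profile, duration_s, fps = 60, out_dir = ".",
                           render = FALSE,
                           thresholds = threshold_config()) {
  session <- generate_session(profile, duration_s, fps)
  series <- session_to_series(session)
  windows <- window_indicators(series, thresholds = thresholds)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    ground_truth = file.path(out_dir, "ground_truth.json"),
    indicators = file.path(out_dir, "expected_indicators.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  jsonlite::write_json(
    list(fps = session$fps, total_frames = session$total_frames,
         closed_threshold = profile$closed_threshold,
         events = session$events),
    paths$ground_truth, auto_unbox = TRUE, digits = NA
  )
  export_indicator_table(windows, paths$indicators)
  if (render) {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("Package 'png' is required to render frames.")
    }
    frame_dir <- file.path(out_dir, "frames")
    dir.create(frame_dir, showWarnings = FALSE)
    rendered <- render_frames(session$aperture, seed = profile$seed)
    for (i in seq_along(rendered$frames)) {
      png::writePNG(rendered$frames[[i]],
                    file.path(frame_dir, sprintf("frame_%06d.png", i - 1L)))
    }
    paths$frames <- frame_dir
  }
  write_manifest(paths$manifest, list(
    workflow = "simulate", profile = unclass(profile),
    duration_s = duration_s, fps = fps, render = render
  ))
  invisible(list(session = session, windows = windows, paths = paths))
}

#' Run the multilevel statistical-evaluation workflow
#'
#' Fits the nested model sequence — M1 intercepts only, M2 adding the time
#' variable, then one model per eye-closure indicator column added to M2 —
#' and writes a comparison table (AIC, -2 log L, df, likelihood-ratio
#' chi-squared against M2), the intercept-model ICCs, per-model marginal and
#' conditional R-squared, and per-level delta R-squared against M2.
#'
#' @param data A data frame (or CSV path) with columns `subject`,
#'   `condition`, `occasion`, `fss_s` and at least one indicator column.
#' @param indicators Indicator column names to test one at a time; defaults
#'   to whichever of `perclos`, `ecd`, `fec`, `indicator` are present.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `fits`, `comparison`, `icc`, `r2`,
#'   `delta_r2` and file paths.
#' @export
run_stats <- function(data, indicators = NULL, out_dir = ".") {
  if (is.character(data)) data <- readr::read_csv(data, show_col_types = FALSE)
  data <- as_tibble(data)
  need <- c("subject", "condition", "occasion", "fss_s")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Data is missing required columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "perclosr_schema_error")
  }
  indicators <- indicators %||%
    intersect(c("perclos", "ecd", "fec", "indicator"), names(data))
  if (length(indicators) == 0) {
    abort("No indicator columns found or specified.",
          class = "perclosr_schema_error")
  }

  m1 <- fit_three_level(data, character(), label = "M1 Intercepts only")
  m2 <- fit_three_level(data, "time", label = "M2 Time variable")
  ind_fits <- purrr::imap(setNames(indicators, indicators), function(col, nm) {
    fit_three_level(data, c("time", "indicator"), indicator = col,
                    label = paste0("M", 2 + which(indicators == col),
                                   " Final (", toupper(nm), ")"))
  })
  fits <- c(list(m1, m2), unname(ind_fits))
  reference <- c(NA, 1, rep(2L, length(ind_fits)))
  comparison <- compare_models(fits, reference)

  icc_tbl <- icc(m1)
  r2_tbl <- purrr::map_dfr(fits, function(f) {
    dplyr::bind_cols(tibble(model = f$label), r2_nakagawa(f))
  })
  d_r2 <- purrr::map_dfr(ind_fits, function(f) {
    dplyr::bind_cols(tibble(model = f$label), delta_r2(m2, f))
  })

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    comparison = file.path(out_dir, "model_comparison.csv"),
    r2 = file.path(out_dir, "model_r2.csv"),
    delta_r2 = file.path(out_dir, "delta_r2.csv"),
    report = file.path(out_dir, "stats_report.txt"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_csv(comparison, paths$comparison, na = "")
  readr::write_csv(r2_tbl, paths$r2, na = "")
  readr::write_csv(d_r2, paths$delta_r2, na = "")

  rpt <- c(
    "Multilevel model comparison for subjective fatigue",
    "==================================================",
    utils::capture.output(print(as.data.frame(comparison), digits = 5)),
    "",
    sprintf("Intercept-only model ICC: level 2 (task conditions) %.3f, level 3 (subjects) %.3f",
            icc_tbl$icc_level2, icc_tbl$icc_level3),
    "",
    "Marginal / conditional R2:",
    utils::capture.output(print(as.data.frame(r2_tbl), digits = 3)),
    "",
    "Per-level delta R2 vs M2:",
    utils::capture.output(print(as.data.frame(d_r2), digits = 3))
  )
  writeLines(rpt, paths$report)
  write_manifest(paths$manifest, list(
    workflow = "stats", indicators = indicators, n_rows = nrow(data),
    models = purrr::map_chr(fits, "label")
  ))
  invisible(list(fits = fits, comparison = comparison, icc = icc_tbl,
                 r2 = r2_tbl, delta_r2 = d_r2, paths = paths))
}

# Machine-readable record of a run: config + versions, for reproducibility.
write_manifest <- function(path, config) {
  jsonlite::write_json(
    c(config, list(
      package = "perclosr",
      package_version = as.character(utils::packageVersion("perclosr")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )),
    path, auto_unbox = TRUE, digits = NA, force = TRUE
  )
  invisible(path)
}
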