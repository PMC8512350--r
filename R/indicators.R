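#' Fatigue-threshold configuration for windowed indicators
#'
#' Defaults follow the conventional values for camera-based drowsiness
#' monitoring: 30-s analysis windows; PERCLOS above 0.15 indicates fatigue;
#' mean eye-closure duration (ECD) above 400 ms (24 frames at 60 fps)
#' indicates fatigue; more than 5 qualifying closures per window (FEC)
#' may indicate fatigue. All flag comparisons are strict ("above").
#'
#' @param window_s Window length in seconds (default 30).
#' @param perclos_fatigue PERCLOS fatigue threshold, proportion (default 0.15).
#' @param ecd_fatigue_ms ECD fatigue threshold in milliseconds (default 400).
#' @param fec_fatigue FEC fatigue threshold, count per window (default 5).
#' @param low_confidence_frac Fraction of unclassified frames above which a
#'   window is flagged low-confidence (default 0.10).
#' @return A named list of thresholds.
#' @export
threshold_config <- function(window_s = 30, perclos_fatigue = 0.15,
                             ecd_fatigue_ms = 400, fec_fatigue = 5,
                             low_confidence_frac = 0.10) {
  stopifnot(window_s > 0, perclos_fatigue > 0, ecd_fatigue_ms > 0,
            fec_fatigue > 0)
  list(window_s = window_s, perclos_fatigue = perclos_fatigue,
       ecd_fatigue_ms = ecd_fatigue_ms, fec_fatigue = fec_fatigue,
       low_confidence_frac = low_confidence_frac)
}

#' Windowed PERCLOS, ECD and FEC indicators
#'
#' Tiles the series into consecutive non-overlapping windows of
#' `round(window_s * fps)` frames (half-open in frames) and computes, per
#' window, the three eye-closure indicators from the qualifying (longer than
#' blink) events only:
#'
#' * `perclos = closed_frames_qualifying / n_frames` — the fraction of window
#'   time with the eyes closed; an event spanning a window boundary
#'   contributes its per-window frame counts.
#' * `ecd_frames = total qualifying duration / n_clusters` — the mean
#'   qualifying-cluster duration; each event is assigned wholly (with its
#'   full duration) to the window containing its start frame. Missing
#'   (`NA`), not 0, when a window has no qualifying clusters.
#' * `fec = n_clusters` — the count of qualifying closures assigned to the
#'   window.
#'
#' A trailing partial window is reported with its true frame count and
#' `complete = FALSE`. Unclassified frames stay in the denominator (the
#' window length is fixed) and are counted in `unclassified_frames`;
#' windows with many unclassified frames are flagged `low_confidence`.
#'
#' @param series An `eye_state_series`.
#' @param events Labelled events from [label_events()]; if `NULL`, computed
#'   from `series` with `config`.
#' @param thresholds A [threshold_config()].
#' @param config A [segmentation_config()]; defaults to the series fps.
#' @return A tibble of class `window_indicators`, one row per window:
#'   `window_index`, `start_frame`, `n_frames`, `complete`,
#'   `closed_frames_qualifying`, `n_clusters`, `perclos`, `ecd_frames`,
#'   `ecd_ms`, `fec`, `unclassified_frames`, `low_confidence`, and fatigue
#'   flags `perclos_fatigue`, `ecd_fatigue`, `fec_fatigue`.
#' @examples
#' mask <- rep(FALSE, 1800); mask[101:280] <- TRUE # one 180-frame closure
#' s <- as_eye_state_series(mask)
#' window_indicators(s)[, c("perclos", "ecd_frames", "fec")]
#' @export
window_indicators <- function(series, events = NULL,
                              thresholds = threshold_config(),
                              config = NULL) {
  fps <- series_fps(series)
  config <- config %||% segmentation_config(fps = fps)
  if (is.null(events)) {
    events <- label_events(segment_events(series), config)
  }
  n_total <- nrow(series)
  win_n <- as.integer(round(thresholds$window_s * fps))
  if (n_total < 1) {
    abort("Series is empty.", class = "perclosr_config_error")
  }
  if (n_total < win_n) {
    warn("Series is shorter than one full window; only a partial window is reported.")
  }
  n_windows <- ceiling(n_total / win_n)
  qual <- dplyr::filter(events, .data$label == "qualifying")

  # Per-window frame counts of qualifying events (frame-split across windows).
  closed_in_window <- integer(n_windows)
  if (nrow(qual) > 0) {
    for (i in seq_len(nrow(qual))) {
      a <- qual$start_frame[i]
      b <- a + qual$duration_frames[i] - 1L
      for (w in (a %/% win_n):(b %/% win_n)) {
        lo <- max(a, w * win_n)
        hi <- min(b, (w + 1L) * win_n - 1L)
        closed_in_window[w + 1L] <- closed_in_window[w + 1L] + (hi - lo + 1L)
      }
    }
  }
  # Event-level stats: whole event assigned to the window of its start frame.
  ev_window <- if (nrow(qual) > 0) qual$start_frame %/% win_n else integer()
  n_clusters <- tabulate(ev_window + 1L, nbins = n_windows)
  dur_by_window <- vapply(seq_len(n_windows) - 1L, function(w) {
    sum(qual$duration_frames[ev_window == w])
  }, numeric(1))

  unclassified <- vapply(seq_len(n_windows), function(w) {
    idx <- ((w - 1L) * win_n + 1L):min(w * win_n, n_total)
    sum(is.na(series$combined_closed[idx]))
  }, numeric(1))

  n_frames <- pmin(win_n, n_total - (seq_len(n_windows) - 1L) * win_n)
  out <- tibble(
    window_index = seq_len(n_windows) - 1L,
    start_frame = (seq_len(n_windows) - 1L) * win_n,
    n_frames = as.integer(n_frames),
    complete = n_frames == win_n,
    closed_frames_qualifying = as.integer(closed_in_window),
    n_clusters = as.integer(n_clusters),
    perclos = closed_in_window / n_frames,
    ecd_frames = ifelse(n_clusters > 0, dur_by_window / n_clusters, NA_real_),
    fec = as.integer(n_clusters),
    unclassified_frames = as.integer(unclassified)
  )
  out$ecd_ms <- out$ecd_frames * 1000 / fps
  out$low_confidence <- out$unclassified_frames >
    thresholds$low_confidence_frac * out$n_frames
  out <- fatigue_flags(out, thresholds)
  out <- out[, c("window_index", "start_frame", "n_frames", "complete",
                 "closed_frames_qualifying", "n_clusters", "perclos",
                 "ecd_frames", "ecd_ms", "fec", "unclassified_frames",
                 "low_confidence", "perclos_fatigue", "ecd_fatigue",
                 "fec_fatigue")]
  attr(out, "fps") <- fps
  attr(out, "window_frames") <- win_n
  attr(out, "thresholds") <- thresholds
  class(out) <- c("window_indicators", class(out))
  out
}

#' Apply fatigue thresholds to window indicators
#'
#' Flags fire strictly above their thresholds: PERCLOS > 0.15, ECD > 400 ms,
#' FEC > 5 by default. A window with no qualifying clusters has no defined
#' ECD and its ECD flag is `FALSE`.
#'
#' @param windows A window-indicator tibble (rows with `perclos`, `ecd_ms`,
#'   `fec` columns).
#' @param thresholds A [threshold_config()].
#' @return `windows` with logical columns `perclos_fatigue`, `ecd_fatigue`,
#'   `fec_fatigue`.
#' @export
fatigue_flags <- function(windows, thresholds = threshold_config()) {
  dplyr::mutate(
    windows,
    perclos_fatigue = .data$perclos > thresholds$perclos_fatigue,
    ecd_fatigue = !is.na(.data$ecd_ms) &
      .data$ecd_ms > thresholds$ecd_fatigue_ms,
    fec_fatigue = .data$fec > thresholds$fec_fatigue
  )
}

#' Session summary: first-10 / last-10 window means
#'
#' Computes the arithmetic means of PERCLOS, ECD and FEC over the first
#' `min(10, k)` and last `min(10, k)` complete windows (k complete windows in
#' total), the summary used in a pre-test/post-test design where the window
#' means stand in for the session's start and end state. Windows without a
#' defined ECD are excluded from the ECD mean, with the count used reported.
#'
#' @param windows A `window_indicators` tibble.
#' @return A tibble with one row per indicator (`perclos`, `ecd_ms`, `fec`):
#'   `mean_first10`, `mean_last10`, `windows_used_first`, `windows_used_last`.
#' @examples
#' mask <- rep(FALSE, 1800 * 20)
#' s <- as_eye_state_series(mask)
#' session_summary(window_indicators(s))
#' @export
session_summary <- function(windows) {
  complete <- dplyr::filter(windows, .data$complete)
  k <- nrow(complete)
  if (k == 0) {
    abort("No complete windows: cannot summarise the session.",
          class = "perclosr_config_error")
  }
  m <- min(10L, k)
  first <- head(complete, m)
  last <- tail(complete, m)
  one <- function(block, col) {
    x <- block[[col]]
    x <- x[!is.na(x)]
    list(mean = if (length(x)) mean(x) else NA_real_, n = length(x))
  }
  purrr::map_dfr(c(perclos = "perclos", ecd_ms = "ecd_ms", fec = "fec"),
                 function(col) {
    f <- one(first, col); l <- one(last, col)
    tibble(mean_first10 = f$mean, mean_last10 = l$mean,
           windows_used_first = f$n, windows_used_last = l$n)
  }, .id = "indicator")
}

#' Export window indicators to CSV
#'
#' Writes one row per window with a fixed column order; missing ECD values
#' are serialized as empty fields, never as 0. Comma separator, dot decimal,
#' UTF-8, header row.
#'
#' @param windows A `window_indicators` tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_indicator_table <- function(windows, path) {
  if (nrow(windows) == 0) {
    abort("No windows to export.", class = "perclosr_io_error")
  }
  cols <- c("window_index", "start_frame", "n_frames", "complete",
            "closed_frames_qualifying", "n_clusters", "perclos",
            "ecd_frames", "ecd_ms", "fec", "unclassified_frames",
            "low_confidence", "perclos_fatigue", "ecd_fatigue", "fec_fatigue")
  readr::write_csv(as_tibble(windows)[, cols], path, na = "")
  invisible(path)
}
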