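#' Segmentation configuration: blink/closure boundary
#'
#' A closure lasting at most `blink_max_ms` is an ordinary blink and is
#' excluded from all fatigue indicators. The millisecond value is primary and
#' the frame cutoff is derived from the frame rate, so non-60-fps recordings
#' rescale correctly: 200 ms is 12 frames at 60 fps but 6 frames at 30 fps.
#'
#' @param blink_max_ms Longest blink duration in milliseconds (default 200).
#' @param fps Frames per second (default 60).
#' @return A list with `blink_max_ms`, `fps` and the derived
#'   `blink_max_frames` (`round(blink_max_ms * fps / 1000)`, at least 1).
#' @examples
#' segmentation_config()$blink_max_frames        # 12
#' segmentation_config(fps = 30)$blink_max_frames # 6
#' @export
segmentation_config <- function(blink_max_ms = 200, fps = 60) {
  stopifnot(blink_max_ms > 0, fps > 0)
  frames <- max(1L, as.integer(round(blink_max_ms * fps / 1000)))
  list(blink_max_ms = blink_max_ms, fps = fps, blink_max_frames = frames)
}

#' Segment a combined eye-state series into maximal closure events
#'
#' A closure event (cluster) is a maximal run of consecutive frames in which
#' both eyes are classified as closed. Unclassified frames never bridge two
#' runs: they terminate the run and mark the adjacent event(s) `truncated`,
#' as do the series boundaries, since the true extent of such events is
#' unknown.
#'
#' @param series An `eye_state_series` (or anything with a `combined_closed`
#'   logical column and an fps attribute).
#' @return A tibble with one row per event: `start_frame` (0-based),
#'   `duration_frames`, `duration_ms` and `truncated`.
#' @examples
#' s <- as_eye_state_series(c(0, 0, 0, 1, 1, 1, 1, 0, 0, 1, 1, 0) == 1)
#' segment_events(s)
#' @export
segment_events <- function(series) {
  closed <- series$combined_closed
  fps <- series_fps(series)
  n <- length(closed)
  if (n == 0) {
    return(tibble(start_frame = integer(), duration_frames = integer(),
                  duration_ms = double(), truncated = logical()))
  }
  # Code frames as "1" closed / "0" open / "x" unclassified and run-length
  # encode; unclassified acts as a run terminator.
  code <- ifelse(is.na(closed), "x", ifelse(closed, "1", "0"))
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == "1"
  if (!any(keep)) {
    return(tibble(start_frame = integer(), duration_frames = integer(),
                  duration_ms = double(), truncated = logical()))
  }
  i <- which(keep)
  start_frame <- starts[i] - 1L
  len <- r$lengths[i]
  prev_val <- ifelse(i == 1L, "edge", r$values[pmax(i - 1L, 1L)])
  next_val <- ifelse(i == length(r$values), "edge",
                     r$values[pmin(i + 1L, length(r$values))])
  truncated <- prev_val %in% c("edge", "x") | next_val %in% c("edge", "x")
  tibble(
    start_frame = as.integer(start_frame),
    duration_frames = as.integer(len),
    duration_ms = len * 1000 / fps,
    truncated = truncated
  )
}

#' Label closure events as ordinary blinks or qualifying closures
#'
#' Events lasting at most the blink cutoff are labelled `blink`; strictly
#' longer events are `qualifying` and are the only events that enter the
#' PERCLOS, ECD and FEC indicators.
#'
#' @param events Event tibble from [segment_events()].
#' @param config A [segmentation_config()].
#' @return The events with a `label` column (`"blink"`/`"qualifying"`).
#' @examples
#' ev <- tibble::tibble(start_frame = c(0L, 100L),
#'                      duration_frames = c(12L, 13L),
#'                      duration_ms = c(200, 13000 / 60),
#'                      truncated = FALSE)
#' label_events(ev, segmentation_config())$label
#' @export
label_events <- function(events, config = segmentation_config()) {
  dplyr::mutate(
    events,
    label = ifelse(.data$duration_frames <= config$blink_max_frames,
                   "blink", "qualifying")
  )
}
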