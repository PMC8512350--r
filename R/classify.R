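#' Normalized-correlation match score between an image patch and a template
#'
#' Computes the Pearson-type normalized correlation coefficient between two
#' equal-sized grayscale patches and clamps negative values to zero, so the
#' score lies in \[0, 1\]: 1 for a perfect match, 0 for uncorrelated or
#' anti-correlated content. Anti-correlated patches carry no evidence of a
#' match, which is why the negative branch is folded to "no match" rather
#' than kept signed.
#'
#' @param patch,template Equal-sized numeric matrices with finite values and
#'   nonzero intensity variance.
#' @return A single score in \[0, 1\].
#' @examples
#' a <- matrix(runif(64), 8, 8)
#' match_score(a, a) # 1
#' @export
match_score <- function(patch, template) {
  if (!all(dim(patch) == dim(template))) {
    abort("`patch` and `template` must have identical dimensions.",
          class = "perclosr_degenerate_input")
  }
  p <- as.vector(patch)
  t <- as.vector(template)
  if (!all(is.finite(p)) || !all(is.finite(t))) {
    abort("Patches must contain only finite intensities.",
          class = "perclosr_degenerate_input")
  }
  if (sd(p) == 0 || sd(t) == 0) {
    abort("Zero-variance patch or template: region is uninformative.",
          class = "perclosr_degenerate_input")
  }
  max(0, cor(p, t))
}

#' Classify one frame's eye states from per-template match scores
#'
#' Scores are examined sequentially and the search stops at the first score
#' at or above the threshold, in which case the eye is open; an eye whose
#' scores all fall below the threshold is closed. The eyes are treated as
#' closed jointly only when both eyes are closed.
#'
#' @param scores_left,scores_right Numeric vectors of match scores (one per
#'   template pair, in matching order).
#' @param threshold Acceptance threshold in (0, 1].
#' @return A list with `left_state`, `right_state` (`"open"`/`"closed"`),
#'   `combined_closed` (logical), and `best_score_left`, `best_score_right`
#'   (the largest score examined before the search stopped).
#' @examples
#' classify_frame(c(0.5, 0.6, 0.4), c(0.3, 0.2, 0.1), 0.68)
#' @export
classify_frame <- function(scores_left, scores_right, threshold = 0.68) {
  if (length(scores_left) == 0 || length(scores_right) == 0) {
    abort("Score lists must be non-empty.",
          class = "perclosr_classification_error")
  }
  if (!(threshold > 0 && threshold <= 1)) {
    abort("`threshold` must lie in (0, 1].",
          class = "perclosr_classification_error")
  }
  eye <- function(scores) {
    best <- -Inf
    for (s in scores) {
      best <- max(best, s)
      if (s >= threshold) return(list(state = "open", best = best))
    }
    list(state = "closed", best = best)
  }
  l <- eye(scores_left)
  r <- eye(scores_right)
  list(
    left_state = l$state, right_state = r$state,
    combined_closed = l$state == "closed" && r$state == "closed",
    best_score_left = l$best, best_score_right = r$best
  )
}

new_eye_state_series <- function(frames, fps, source_id = "") {
  stopifnot(fps > 0)
  out <- as_tibble(frames)
  attr(out, "fps") <- fps
  attr(out, "source_id") <- source_id
  class(out) <- c("eye_state_series", class(out))
  out
}

#' Frame rate of an eye-state series
#' @param series An `eye_state_series`.
#' @return Frames per second.
#' @export
series_fps <- function(series) attr(series, "fps") %||% 60

#' Build an eye-state series directly from a combined closed/open mask
#'
#' Convenience constructor used when the per-frame combined eye state is
#' already known (e.g. from a thresholded synthetic aperture signal) and the
#' per-eye matching detail is not needed. `TRUE` means both eyes closed,
#' `FALSE` open, `NA` unclassified.
#'
#' @param closed Logical vector (may contain `NA`).
#' @param fps Frames per second (default 60).
#' @param source_id Free-text identifier carried through to outputs.
#' @return An `eye_state_series` tibble with one row per frame.
#' @examples
#' as_eye_state_series(c(FALSE, TRUE, TRUE, FALSE), fps = 60)
#' @export
as_eye_state_series <- function(closed, fps = 60, source_id = "") {
  closed <- as.logical(closed)
  state <- dplyr::case_when(
    is.na(closed) ~ "unclassified",
    closed ~ "closed",
    TRUE ~ "open"
  )
  new_eye_state_series(
    tibble(
      frame = seq_along(closed) - 1L,
      landmark_found = !is.na(closed),
      left_state = state, right_state = state,
      best_score_left = NA_real_, best_score_right = NA_real_,
      padded = FALSE,
      combined_closed = closed
    ),
    fps = fps, source_id = source_id
  )
}

#' Classify every frame of a sequence by template matching
#'
#' For each frame, an eye-sized patch is cut around each eye center reported
#' by the landmark provider and matched sequentially against the calibration
#' templates; frames whose landmarks are not found, or whose patches are
#' degenerate (flat intensity), are retained as unclassified rather than
#' dropped. Patches that extend past the frame border are zero-padded and
#' flagged in the `padded` column.
#'
#' @param frames List of grayscale frame matrices (frame 0 first).
#' @param calibration A `calibration_set` from [build_templates()].
#' @param landmarks A landmark provider: `function(frame_index)` returning
#'   `list(left = c(x, y), right = c(x, y))` eye-center pixel coordinates
#'   (0-based, `x` = column) or `NULL` when no face/landmarks are found.
#' @param fps Frames per second of the recording (default 60).
#' @param source_id Free-text identifier carried through to outputs.
#' @return An `eye_state_series` tibble with one row per frame: `frame`,
#'   `landmark_found`, `left_state`, `right_state`, `best_score_left`,
#'   `best_score_right`, `padded`, and `combined_closed` (`NA` when either
#'   eye is unclassified).
#' @export
classify_sequence <- function(frames, calibration, landmarks,
                              fps = 60, source_id = "") {
  if (!inherits(calibration, "calibration_set")) {
    abort("`calibration` must be a calibration_set.",
          class = "perclosr_config_error")
  }
  if (length(frames) > 0) {
    d <- dim(frames[[1]])
    if (any(calibration$patch_size > d)) {
      abort("Calibration patch size exceeds the frame size.",
            class = "perclosr_config_error")
    }
  }
  ph <- calibration$patch_size[1]
  pw <- calibration$patch_size[2]
  thr <- calibration$threshold

  rows <- purrr::map(seq_along(frames), function(i) {
    lm <- landmarks(i - 1L)
    if (is.null(lm) || anyNA(c(lm$left, lm$right))) {
      return(list(frame = i - 1L, landmark_found = FALSE,
                  left_state = "unclassified", right_state = "unclassified",
                  best_score_left = NA_real_, best_score_right = NA_real_,
                  padded = FALSE, combined_closed = NA))
    }
    img <- frames[[i]]
    le <- extract_centered(img, lm$left, ph, pw)
    re <- extract_centered(img, lm$right, ph, pw)

    sl <- eye_scores(le$patch, calibration$pairs, "left", thr)
    sr <- eye_scores(re$patch, calibration$pairs, "right", thr)
    if (is.null(sl) || is.null(sr)) {
      return(list(frame = i - 1L, landmark_found = TRUE,
                  left_state = if (is.null(sl)) "unclassified" else sl$state,
                  right_state = if (is.null(sr)) "unclassified" else sr$state,
                  best_score_left = if (is.null(sl)) NA_real_ else sl$best,
                  best_score_right = if (is.null(sr)) NA_real_ else sr$best,
                  padded = le$padded || re$padded, combined_closed = NA))
    }
    list(frame = i - 1L, landmark_found = TRUE,
         left_state = sl$state, right_state = sr$state,
         best_score_left = sl$best, best_score_right = sr$best,
         padded = le$padded || re$padded,
         combined_closed = sl$state == "closed" && sr$state == "closed")
  })

  new_eye_state_series(dplyr::bind_rows(rows), fps = fps,
                       source_id = source_id)
}

# Sequential early-stopping match of one patch against all template pairs.
# Returns NULL if every score was degenerate (flat patch or template).
eye_scores <- function(patch, pairs, side, threshold) {
  best <- -Inf
  any_valid <- FALSE
  for (p in pairs) {
    s <- tryCatch(match_score(patch, p[[side]]),
                  perclosr_degenerate_input = function(e) NA_real_)
    if (is.na(s)) next
    any_valid <- TRUE
    best <- max(best, s)
    if (s >= threshold) return(list(state = "open", best = best))
  }
  if (!any_valid) return(NULL)
  list(state = "closed", best = best)
}

# Fixed-size patch centered on a 0-based (x, y) pixel; zero-pads outside.
extract_centered <- function(img, center, ph, pw) {
  cx <- round(center[1]) + 1L  # column, 1-based
  cy <- round(center[2]) + 1L  # row, 1-based
  r0 <- cy - (ph %/% 2L)
  c0 <- cx - (pw %/% 2L)
  rows <- r0:(r0 + ph - 1L)
  cols <- c0:(c0 + pw - 1L)
  inside_r <- rows >= 1L & rows <= nrow(img)
  inside_c <- cols >= 1L & cols <= ncol(img)
  patch <- matrix(0, ph, pw)
  if (any(inside_r) && any(inside_c)) {
    patch[which(inside_r), which(inside_c)] <-
      img[rows[inside_r], cols[inside_c], drop = FALSE]
  }
  list(patch = patch, padded = !(all(inside_r) && all(inside_c)))
}

#' Apply manual frame-state overrides to an eye-state series
#'
#' File-based replacement for interactive manual correction: each override
#' sets both eyes of an inclusive frame range to a given state. Overrides are
#' applied in order, so later rows win where ranges overlap.
#'
#' @param series An `eye_state_series`.
#' @param overrides A data frame with columns `frame_start`, `frame_end`
#'   (inclusive, 0-based) and `state` (`"open"` or `"closed"`); or a path to
#'   a CSV file with those columns.
#' @return The corrected `eye_state_series`.
#' @examples
#' s <- as_eye_state_series(rep(FALSE, 20))
#' ov <- tibble::tibble(frame_start = 10, frame_end = 19, state = "closed")
#' sum(apply_overrides(s, ov)$combined_closed)
#' @export
apply_overrides <- function(series, overrides) {
  if (is.character(overrides)) overrides <- read_overrides(overrides)
  overrides <- as_tibble(overrides)
  if (nrow(overrides) == 0) return(series)
  n <- nrow(series)
  for (i in seq_len(nrow(overrides))) {
    a <- overrides$frame_start[i]
    b <- overrides$frame_end[i]
    st <- overrides$state[i]
    if (!st %in% c("open", "closed")) {
      abort(sprintf("Override state must be 'open' or 'closed', got '%s'.", st),
            class = "perclosr_override_error")
    }
    if (is.na(a) || is.na(b) || a < 0 || b >= n || a > b) {
      abort(sprintf("Override range [%s, %s] lies outside the series (0..%d).",
                    a, b, n - 1L),
            class = "perclosr_override_error")
    }
    idx <- (a + 1):(b + 1)
    series$left_state[idx] <- st
    series$right_state[idx] <- st
    series$combined_closed[idx] <- st == "closed"
  }
  series
}

#' @param path Path to an override CSV with columns `frame_start`,
#'   `frame_end`, `state`.
#' @rdname apply_overrides
#' @export
read_overrides <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Override file not found: %s", path),
          class = "perclosr_io_error")
  }
  readr::read_csv(path, col_types = readr::cols(
    frame_start = readr::col_integer(),
    frame_end = readr::col_integer(),
    state = readr::col_character()
  ))
}
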