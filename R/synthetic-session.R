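#' Generative profile for a synthetic drowsiness session
#'
#' Describes the eye-closure process of one simulated driving session: short
#' frequent blinks, rarer and heavy-tailed drowsy closures, and an optional
#' within-session drift that ramps the closure process up towards the end of
#' the drive. Closure durations are modelled as the blink cutoff (200 ms)
#' plus a lognormal excess, so every closure is strictly longer than a blink;
#' blink durations are a normal truncated to (0, 200\] ms.
#'
#' Two presets bracket the typical observed range: `"rested"` targets a mean
#' session PERCLOS in the 0.03-0.07 band with 3-4 qualifying closures per
#' 30-s window, `"drowsy"` a 0.08-0.15 band with 7-9 per window; both ramp up
#' over the session (drift) so the last windows run higher than the first,
#' emulating fatigue building up during a monotonous drive.
#'
#' @param preset `"rested"` or `"drowsy"`, or `NULL` for fully manual values.
#' @param blink_rate Blinks per minute (session average).
#' @param blink_dur_ms `c(mean, sd)` of the truncated-normal blink duration.
#' @param closure_rate Qualifying closures per minute at session start.
#' @param closure_dur_ms `c(log_mean, log_sd)` of the lognormal closure
#'   duration excess over the 200 ms blink cutoff.
#' @param drift Multiplier on closure rate and duration-excess reached at the
#'   session end (linear ramp from 1 at the start); 1 means no drift.
#' @param closed_threshold Aperture below this fraction of full opening is
#'   closed (default 0.25, i.e. at least 75% lid coverage).
#' @param seed Integer seed; every stochastic operation derives from it.
#' @return A `drowsiness_profile` list.
#' @examples
#' drowsiness_profile("drowsy", seed = 1)$closure_rate
#' @export
drowsiness_profile <- function(preset = NULL,
                               blink_rate = 15,
                               blink_dur_ms = c(120, 40),
                               closure_rate = 6,
                               closure_dur_ms = c(log(60), 0.6),
                               drift = 1.6,
                               closed_threshold = 0.25,
                               seed = 1L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("rested", "drowsy"))
    if (preset == "rested") {
      blink_rate <- 15; blink_dur_ms <- c(120, 40)
      closure_rate <- 5.5; closure_dur_ms <- c(log(60), 0.6); drift <- 1.8
    } else {
      blink_rate <- 20; blink_dur_ms <- c(130, 40)
      closure_rate <- 12; closure_dur_ms <- c(log(120), 0.7); drift <- 1.8
    }
  }
  stopifnot(blink_rate >= 0, closure_rate >= 0, drift > 0,
            blink_dur_ms[1] > 0, closed_threshold > 0, closed_threshold < 1)
  structure(
    list(preset = preset %||% "custom",
         blink_rate = blink_rate, blink_dur_ms = blink_dur_ms,
         closure_rate = closure_rate, closure_dur_ms = closure_dur_ms,
         drift = drift, closed_threshold = closed_threshold,
         seed = as.integer(seed)),
    class = "drowsiness_profile"
  )
}

#' Expected qualifying closed-time fraction of a profile
#'
#' The analytic expectation of the session-wide PERCLOS implied by a
#' profile: mean closure rate times mean closure duration. Used as the
#' reference value in Monte-Carlo recovery checks.
#'
#' @param profile A [drowsiness_profile()].
#' @return Expected fraction of session time inside qualifying closures.
#' @export
expected_closed_fraction <- function(profile) {
  mean_factor <- (1 + profile$drift) / 2
  mean_rate <- profile$closure_rate * mean_factor # per minute
  mean_excess_ms <- exp(profile$closure_dur_ms[1] +
                          profile$closure_dur_ms[2]^2 / 2) * mean_factor
  mean_dur_ms <- 200 + mean_excess_ms
  mean_rate * mean_dur_ms / 60000
}

#' Generate a ground-truthed synthetic eye-aperture session
#'
#' Draws blink and closure events from inhomogeneous Poisson processes
#' (closure rate and duration excess ramp linearly by the profile's drift),
#' rejects overlapping or adjacent placements so events map one-to-one onto
#' closed runs, and emits a per-frame aperture signal in \[0, 1\]: open
#' frames fluctuate near full opening, event frames sit below the closed
#' threshold. The returned ground truth lists every event with its kind.
#'
#' @param profile A [drowsiness_profile()].
#' @param duration_s Session length in seconds (at least one window, 30 s).
#' @param fps Frames per second (default 60).
#' @return A list of class `synthetic_session`: `aperture` (numeric vector,
#'   one value per frame), `events` (tibble `start_frame`,
#'   `duration_frames`, `kind`), `fps`, `total_frames`, `profile`.
#' @examples
#' s <- generate_session(drowsiness_profile("rested", seed = 7), 60)
#' head(s$events)
#' @export
generate_session <- function(profile, duration_s, fps = 60) {
  if (duration_s < 30) {
    abort("`duration_s` must cover at least one 30-s window.",
          class = "perclosr_generator_error")
  }
  total_frames <- as.integer(round(duration_s * fps))
  dur_min <- duration_s / 60
  blink_max_frames <- segmentation_config(fps = fps)$blink_max_frames

  withr::with_seed(profile$seed, {
    # Drift factor at relative session time u in [0, 1].
    factor_at <- function(u) 1 + (profile$drift - 1) * u
    mean_factor <- (1 + profile$drift) / 2

    # Closure starts: inhomogeneous Poisson, density proportional to the
    # linear ramp; sampled by inverse CDF.
    n_clo <- rpois(1, profile$closure_rate * dur_min * mean_factor)
    u_clo <- sample_linear_ramp(n_clo, profile$drift)
    clo_excess <- rlnorm(n_clo, profile$closure_dur_ms[1],
                         profile$closure_dur_ms[2]) * factor_at(u_clo)
    clo_frames <- pmax(blink_max_frames + 1L,
                       as.integer(round((200 + clo_excess) * fps / 1000)))

    n_bli <- rpois(1, profile$blink_rate * dur_min)
    u_bli <- runif(n_bli)
    bli_ms <- rnorm_trunc(n_bli, profile$blink_dur_ms[1],
                          profile$blink_dur_ms[2], lo = 1, hi = 200)
    bli_frames <- pmin(blink_max_frames,
                       pmax(1L, as.integer(round(bli_ms * fps / 1000))))

    kinds <- c(rep("closure", n_clo), rep("blink", n_bli))
    rel <- c(u_clo, u_bli)
    lens <- c(clo_frames, bli_frames)

    events <- place_events(rel, lens, kinds, total_frames)

    aperture <- runif(total_frames, 0.85, 1)
    if (nrow(events) > 0) {
      for (i in seq_len(nrow(events))) {
        idx <- (events$start_frame[i] + 1L):
          (events$start_frame[i] + events$duration_frames[i])
        aperture[idx] <- runif(length(idx), 0.02, 0.18)
      }
    }

    structure(
      list(aperture = aperture, events = events, fps = fps,
           total_frames = total_frames, profile = profile),
      class = "synthetic_session"
    )
  })
}

# Inverse-CDF sample of n points with density proportional to a linear ramp
# rising from 1 to `drift` over [0, 1].
sample_linear_ramp <- function(n, drift) {
  if (n == 0) return(numeric())
  u <- runif(n)
  if (abs(drift - 1) < 1e-12) return(u)
  a <- drift - 1
  # CDF F(x) = (x + a x^2 / 2) / (1 + a / 2); solve quadratic for x.
  c0 <- -u * (1 + a / 2)
  (-1 + sqrt(1 - 2 * a * c0)) / a
}

# Truncated-normal sample by rejection with a uniform fallback.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(numeric())
  out <- numeric(n)
  todo <- seq_len(n)
  for (it in 1:50) {
    draw <- rnorm(length(todo), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
    if (length(todo) == 0) return(out)
  }
  out[todo] <- runif(length(todo), lo, hi)
  out
}

# Place events at relative times without overlap; at least one open frame
# between events so closed runs map one-to-one onto events. Bounded retries.
place_events <- function(rel, lens, kinds, total_frames) {
  ord <- order(rel)
  rel <- rel[ord]; lens <- lens[ord]; kinds <- kinds[ord]
  occupied <- logical(total_frames)
  rows <- vector("list", length(rel))
  for (i in seq_along(rel)) {
    len <- lens[i]
    if (len >= total_frames - 2L) {
      abort("Event longer than the session; lower the duration parameters.",
            class = "perclosr_generator_error")
    }
    placed <- FALSE
    start0 <- min(total_frames - len, max(1L, as.integer(round(
      rel[i] * (total_frames - len - 1L)))))
    for (attempt in 1:60) {
      start <- if (attempt == 1) start0 else
        sample.int(total_frames - len - 1L, 1)
      span <- max(1L, start - 1L):min(total_frames, start + len)
      if (!any(occupied[span])) {
        occupied[start:(start + len - 1L)] <- TRUE
        rows[[i]] <- list(start_frame = start - 1L,
                          duration_frames = as.integer(len),
                          kind = kinds[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort("Could not place events without overlap; rates too high for the session length.",
            class = "perclosr_generator_error")
    }
  }
  ev <- dplyr::bind_rows(rows)
  if (nrow(ev) == 0) {
    return(tibble(start_frame = integer(), duration_frames = integer(),
                  kind = character()))
  }
  dplyr::arrange(ev, .data$start_frame)
}

#' Threshold a synthetic aperture signal into an eye-state series
#'
#' Frames whose aperture falls below the profile's closed threshold (default
#' 0.25 of full opening, i.e. at least 75% lid coverage) are combined-closed.
#'
#' @param session A `synthetic_session` from [generate_session()].
#' @param closed_threshold Override for the profile's closed threshold.
#' @return An `eye_state_series`.
#' @export
session_to_series <- function(session, closed_threshold = NULL) {
  thr <- closed_threshold %||% session$profile$closed_threshold
  as_eye_state_series(session$aperture < thr, fps = session$fps,
                      source_id = paste0("synthetic-", session$profile$preset))
}

#' Render a synthetic eye-region frame sequence
#'
#' Draws, per frame, two dark elliptical "eyes" on a light background whose
#' vertical opening scales with the aperture signal (a closed eye collapses
#' to a thin lid line), adds Gaussian pixel noise, and returns both the
#' frames and a perfect landmark provider for the rendered eye centers —
#' a stand-in for camera input plus a face-landmark engine.
#'
#' @param aperture Numeric vector in \[0, 1\], one value per frame.
#' @param image_size `c(height, width)` in pixels (default `c(48, 72)`).
#' @param noise_sd Gaussian pixel-noise standard deviation (default 0.02).
#' @param seed Integer seed for the noise.
#' @return A list: `frames` (list of matrices in \[0, 1\]), `landmarks`
#'   (provider `function(frame_index)`), `centers` (left/right `c(x, y)`,
#'   0-based), `eye_box` (`c(height, width)` of the eye bounding box, a
#'   sensible template patch size).
#' @examples
#' r <- render_frames(c(1, 1, 0, 1), seed = 1)
#' length(r$frames)
#' @export
render_frames <- function(aperture, image_size = c(48, 72),
                          noise_sd = 0.02, seed = 1L) {
  if (any(aperture < 0 | aperture > 1)) {
    abort("`aperture` values must lie in [0, 1].",
          class = "perclosr_config_error")
  }
  h <- image_size[1]; w <- image_size[2]
  a_semi <- round(w / 9)        # eye half-width, px
  b_max <- round(h / 6)         # full-open eye half-height, px
  cy <- round(h / 2)
  cxl <- round(w * 0.3); cxr <- round(w * 0.7)
  if (h < 4 * b_max + 4 || cxl - a_semi < 2 || cxr + a_semi > w - 1) {
    abort("Image too small for the eye geometry.",
          class = "perclosr_config_error")
  }
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  base_bg <- 0.85
  eye_dark <- 0.15

  draw <- function(ap) {
    img <- matrix(base_bg, h, w)
    b <- ap * b_max
    for (cx in c(cxl, cxr)) {
      if (b >= 0.5) {
        inside <- ((cols - cx) / a_semi)^2 + ((rows - cy) / b)^2 <= 1
        img[inside] <- eye_dark
      }
      # Lid line is always present; dominates when the eye is (near) closed.
      lid <- abs(rows - cy) <= 0.6 & abs(cols - cx) <= a_semi
      img[lid] <- eye_dark + 0.15 * ap
    }
    img
  }

  withr::with_seed(seed, {
    frames <- purrr::map(aperture, function(ap) {
      img <- draw(ap)
      if (noise_sd > 0) {
        img <- img + matrix(rnorm(h * w, 0, noise_sd), h, w)
      }
      pmin(pmax(img, 0), 1)
    })
  })

  centers <- list(left = c(cxl - 1, cy - 1), right = c(cxr - 1, cy - 1))
  list(
    frames = frames,
    landmarks = function(frame_index) centers,
    centers = centers,
    eye_box = c(2L * b_max + 5L, 2L * a_semi + 5L)
  )
}

#' Template selections for a rendered synthetic sequence
#'
#' Builds the calibration-selection table ([build_templates()] input) whose
#' rectangles are the rendered eye bounding boxes, for the given (open-eye)
#' template frames.
#'
#' @param rendered Output of [render_frames()].
#' @param template_frames 0-based indices of the frames to template from.
#' @return A selections tibble.
#' @export
render_selection <- function(rendered, template_frames) {
  eb <- rendered$eye_box
  ctr <- rendered$centers
  tibble(
    frame = as.integer(template_frames),
    left_x = ctr$left[1] - eb[2] %/% 2,
    left_y = ctr$left[2] - eb[1] %/% 2,
    left_w = eb[2], left_h = eb[1],
    right_x = ctr$right[1] - eb[2] %/% 2,
    right_y = ctr$right[2] - eb[1] %/% 2,
    right_w = eb[2], right_h = eb[1]
  )
}
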