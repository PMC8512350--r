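# Build a 60 fps mask with closures at given (start_frame, duration) pairs.
event_mask <- function(n, events) {
  mask <- rep(FALSE, n)
  for (ev in events) mask[(ev[1] + 1):(ev[1] + ev[2])] <- TRUE
  mask
}

test_that("window indicators reproduce the definitional worked examples", {
  # one qualifying 180-frame event inside one 1800-frame window
  s <- as_eye_state_series(event_mask(1800, list(c(100, 180))))
  w <- window_indicators(s)
  expect_equal(nrow(w), 1)
  expect_equal(w$perclos, 0.1)
  expect_equal(w$fec, 1L)
  expect_equal(w$ecd_frames, 180)
  expect_equal(w$ecd_ms, 3000)
  expect_equal(w$closed_frames_qualifying, w$perclos * w$n_frames)

  # a window of only blinks: five 8-frame events
  blinks <- purrr::map(0:4, ~ c(.x * 300, 8))
  wb <- window_indicators(as_eye_state_series(event_mask(1800, blinks)))
  expect_equal(wb$perclos, 0)
  expect_equal(wb$fec, 0L)
  expect_true(is.na(wb$ecd_frames))

  # two qualifying events of 30 and 60 frames
  w2 <- window_indicators(
    as_eye_state_series(event_mask(1800, list(c(100, 30), c(900, 60)))))
  expect_equal(w2$ecd_frames, 45)
  expect_equal(w2$ecd_ms, 750)
  expect_equal(w2$fec, 2L)
  expect_equal(w2$perclos, 90 / 1800)
})

test_that("fatigue flags fire strictly above their thresholds", {
  w <- tibble::tibble(
    perclos = c(0.15, 0.151, 0.1),
    ecd_ms = c(400, 401, NA),
    fec = c(5L, 6L, 0L)
  )
  f <- fatigue_flags(w)
  expect_equal(f$perclos_fatigue, c(FALSE, TRUE, FALSE))
  expect_equal(f$ecd_fatigue, c(FALSE, TRUE, FALSE))
  expect_equal(f$fec_fatigue, c(FALSE, TRUE, FALSE))
})

test_that("events are frame-split for PERCLOS but start-assigned for ECD/FEC", {
  # 100-frame event straddling the window boundary at frame 1800:
  # starts at 1750, so 50 frames in window 0 and 50 in window 1
  s <- as_eye_state_series(event_mask(3600, list(c(1750, 100))))
  w <- window_indicators(s)
  expect_equal(w$closed_frames_qualifying, c(50L, 50L))
  expect_equal(w$fec, c(1L, 0L))          # whole event in its start window
  expect_equal(w$ecd_frames, c(100, NA))  # full duration, not the split part
})

test_that("trailing partial windows are flagged and use their true length", {
  s <- as_eye_state_series(event_mask(2700, list(c(2000, 90))))
  w <- window_indicators(s)
  expect_equal(w$complete, c(TRUE, FALSE))
  expect_equal(w$n_frames, c(1800L, 900L))
  expect_equal(w$perclos[2], 90 / 900)
  expect_warning(window_indicators(as_eye_state_series(rep(FALSE, 100))),
                 "partial window")
})

test_that("unclassified frames stay in the denominator and flag low confidence", {
  closed <- event_mask(1800, list(c(100, 60)))
  closed[501:800] <- NA # 300 unclassified frames > 10%
  w <- window_indicators(as_eye_state_series(closed))
  expect_equal(w$unclassified_frames, 300L)
  expect_true(w$low_confidence)
  expect_equal(w$perclos, 60 / 1800)
})

test_that("session summary averages the first and last 10 complete windows", {
  # 20 windows with constant perclos
  w <- window_indicators(as_eye_state_series(
    event_mask(1800 * 20, purrr::map(0:19, ~ c(.x * 1800 + 10, 180)))))
  expect_equal(nrow(w), 20)
  s <- session_summary(w)
  expect_equal(s$mean_first10[s$indicator == "perclos"], 0.1)
  expect_equal(s$mean_last10[s$indicator == "perclos"], 0.1)
  expect_equal(s$windows_used_first, c(10L, 10L, 10L))

  # perclos ramp 0.00, 0.01, ..., 0.19: first-10 mean 0.045, last-10 0.145
  ramp <- purrr::map(0:19, ~ c(.x * 1800 + 10, .x * 18))
  ramp <- ramp[purrr::map_dbl(ramp, 2) > 12] # drop empty/blink-short ones
  wr <- window_indicators(as_eye_state_series(event_mask(1800 * 20, ramp)))
  pr <- wr$perclos
  expect_equal(mean(pr[1:10]), 0.045)
  expect_equal(mean(pr[11:20]), 0.145)
  sr <- session_summary(wr)
  expect_equal(sr$mean_first10[sr$indicator == "perclos"], 0.045)
  expect_equal(sr$mean_last10[sr$indicator == "perclos"], 0.145)

  # fewer than 10 windows: means over what exists
  w8 <- window_indicators(as_eye_state_series(
    event_mask(1800 * 8, purrr::map(0:7, ~ c(.x * 1800 + 10, 90)))))
  s8 <- session_summary(w8)
  expect_equal(unique(s8$windows_used_first), 8L)
  expect_equal(s8$mean_first10, s8$mean_last10)

  expect_error(session_summary(w8[0, ]), class = "perclosr_config_error")
})

test_that("ECD means skip windows without qualifying clusters", {
  # windows 0 and 2 have a qualifying closure, window 1 does not
  w <- window_indicators(as_eye_state_series(
    event_mask(1800 * 3, list(c(10, 30), c(3610, 60)))))
  expect_true(is.na(w$ecd_frames[2]))
  s <- session_summary(w)
  row <- s[s$indicator == "ecd_ms", ]
  expect_equal(row$windows_used_first, 2L)
  expect_equal(row$mean_first10, mean(c(30, 60)) * 1000 / 60)
})

test_that("indicator CSV export is deterministic and keeps NA empty", {
  w <- window_indicators(as_eye_state_series(
    event_mask(1800 * 3, list(c(10, 30), c(3610, 60)))))
  f <- withr::local_tempfile(fileext = ".csv")
  export_indicator_table(w, f)
  lines <- readLines(f)
  expect_length(lines, 4) # header + 3 windows
  # missing ecd serialized as empty, not 0
  expect_match(lines[3], ",,")
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(back$perclos, w$perclos, tolerance = 1e-9)
  expect_equal(back$ecd_ms, w$ecd_ms, tolerance = 1e-9)
  expect_true(is.na(back$ecd_ms[2]))
  expect_error(export_indicator_table(w[0, ], f), class = "perclosr_io_error")
})

test_that("windowed conservation and FEC bounds hold on random masks", {
  cfg <- segmentation_config()
  withr::with_seed(31, {
    for (i in 1:30) {
      mask <- random_mask(1800 * 4, p_closed = runif(1, 0.05, 0.3))
      s <- as_eye_state_series(mask)
      ev <- label_events(segment_events(s), cfg)
      w <- window_indicators(s, ev)
      qual <- ev[ev$label == "qualifying", ]
      expect_equal(sum(w$closed_frames_qualifying),
                   sum(qual$duration_frames))
      expect_equal(sum(w$fec), nrow(qual))
      # each qualifying event is at least blink_max + 1 frames long
      dur_assigned <- w$fec * ifelse(is.na(w$ecd_frames), 0, w$ecd_frames)
      expect_true(all(w$fec * (cfg$blink_max_frames + 1) <=
                        dur_assigned + 1e-9))
    }
  })
})

test_that("adding a qualifying closure never decreases PERCLOS or FEC", {
  withr::with_seed(77, {
    for (i in 1:20) {
      mask <- event_mask(1800, list(c(sample(1500, 1), 30)))
      w0 <- window_indicators(as_eye_state_series(mask))
      # insert an extra qualifying closure in a free stretch
      free <- which(!mask)
      start <- free[free < 1700][sample(sum(free < 1700), 1)]
      mask2 <- mask
      mask2[start:(start + 20)] <- TRUE
      w1 <- window_indicators(as_eye_state_series(mask2))
      expect_gte(w1$perclos[1], w0$perclos[1])
      expect_gte(w1$fec[1], w0$fec[1])
    }
  })
})

test_that("pipeline indicators equal the brute-force oracle on random masks", {
  withr::with_seed(555, {
    for (i in 1:50) {
      mask <- random_mask(sample(c(2000, 4000, 5400), 1),
                          p_closed = runif(1, 0.05, 0.4))
      w <- window_indicators(as_eye_state_series(mask))
      o <- oracle_indicators(mask)
      expect_equal(w$perclos, o$perclos)
      expect_equal(w$ecd_frames, o$ecd_frames)
      expect_equal(w$fec, o$fec)
    }
  })
})
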