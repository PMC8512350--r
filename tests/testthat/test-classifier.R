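make_frames <- function(n = 5, h = 48, w = 72, seed = 1) {
  withr::with_seed(seed, replicate(n, matrix(runif(h * w), h, w),
                                   simplify = FALSE))
}

std_selection <- function(frames = c(0, 2, 4)) {
  tibble::tibble(
    frame = frames,
    left_x = 10, left_y = 14, left_w = 18, left_h = 12,
    right_x = 44, right_y = 14, right_w = 18, right_h = 12
  )
}

test_that("match_score is a clamped normalized correlation", {
  withr::with_seed(42, {
    a <- matrix(runif(64), 8, 8)
    b <- matrix(runif(64), 8, 8)
  })
  expect_equal(match_score(a, a), 1.0)
  # intensities negated about the mean: correlation -1, clamped to 0
  inv <- matrix(2 * mean(a) - a, 8, 8)
  expect_equal(match_score(a, inv), 0)
  # direct Pearson formula oracle on two fixed random patches
  av <- as.vector(a); bv <- as.vector(b)
  r_oracle <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  expect_equal(match_score(a, b), max(0, r_oracle), tolerance = 1e-10)
  # symmetry
  expect_equal(match_score(a, b), match_score(b, a))
  # degenerate inputs
  expect_error(match_score(matrix(1, 8, 8), a),
               class = "perclosr_degenerate_input")
  expect_error(match_score(a, matrix(0.5, 8, 8)),
               class = "perclosr_degenerate_input")
  expect_error(match_score(a, matrix(runif(36), 6, 6)),
               class = "perclosr_degenerate_input")
})

test_that("match_score stays in [0, 1] for random patch pairs", {
  withr::with_seed(7, {
    for (i in 1:50) {
      a <- matrix(rnorm(25), 5, 5)
      b <- matrix(rnorm(25), 5, 5)
      s <- match_score(a, b)
      expect_gte(s, 0)
      expect_lte(s, 1)
    }
  })
})

test_that("build_templates cuts one equal-sized pair per selection", {
  frames <- make_frames()
  cal <- build_templates(frames, std_selection())
  expect_s3_class(cal, "calibration_set")
  expect_length(cal$pairs, 3)
  expect_equal(cal$threshold, 0.68)
  expect_equal(cal$patch_size, c(12L, 18L))
  expect_equal(purrr::map_int(cal$pairs, "source_frame"), c(0L, 2L, 4L))
  # template content is the selected rectangle (0-based half-open)
  expect_equal(cal$pairs[[1]]$left, frames[[1]][15:26, 11:28])

  # a single pair is allowed
  cal1 <- build_templates(frames, std_selection(frames = 1))
  expect_length(cal1$pairs, 1)
})

test_that("build_templates rejects bad selections", {
  frames <- make_frames()
  bad <- std_selection(frames = 0)
  bad$right_x <- 60 # 60 + 18 > 72
  expect_error(build_templates(frames, bad),
               class = "perclosr_calibration_error")
  expect_error(build_templates(frames, std_selection(frames = 99)),
               class = "perclosr_calibration_error")
  expect_error(build_templates(frames, std_selection()[0, ]),
               class = "perclosr_calibration_error")
})

test_that("classify_frame applies the sequential acceptance rule", {
  r <- classify_frame(c(0.9), c(0.9), 0.68)
  expect_equal(r$left_state, "open")
  expect_false(r$combined_closed)

  # all scores below threshold on both eyes -> combined closed
  r <- classify_frame(c(0.5, 0.6, 0.4), c(0.3, 0.2, 0.1), 0.68)
  expect_equal(c(r$left_state, r$right_state), c("closed", "closed"))
  expect_true(r$combined_closed)
  expect_equal(r$best_score_left, 0.6)

  # acceptance begins at exactly the threshold and the search stops there
  r <- classify_frame(c(0.67, 0.68, 0.0), c(0.2, 0.2, 0.9), 0.68)
  expect_equal(c(r$left_state, r$right_state), c("open", "open"))
  expect_false(r$combined_closed)
  expect_equal(r$best_score_left, 0.68)

  expect_error(classify_frame(numeric(), c(0.5), 0.68),
               class = "perclosr_classification_error")
})

test_that("sequential early stop is equivalent to max-score acceptance", {
  grid <- seq(0, 1, by = 0.25)
  combos <- expand.grid(a = grid, b = grid, c = grid)
  for (i in seq_len(nrow(combos))) {
    s <- as.numeric(combos[i, ])
    r <- classify_frame(s, s, 0.68)
    expect_equal(r$left_state == "open", max(s) >= 0.68)
  }
})

test_that("raising one score never flips an eye from open to closed", {
  withr::with_seed(11, {
    for (rep in 1:30) {
      s <- runif(3)
      before <- classify_frame(s, s, 0.68)$left_state
      j <- sample(3, 1)
      s2 <- s
      s2[j] <- min(1, s[j] + runif(1, 0, 1 - s[j]))
      after <- classify_frame(s2, s2, 0.68)$left_state
      if (before == "open") expect_equal(after, "open")
    }
  })
})

test_that("classify_sequence marks landmark-failed frames unclassified", {
  aperture <- rep(1, 40)
  r <- render_frames(aperture, seed = 5)
  cal <- build_templates(r$frames, render_selection(r, 0:2))
  flaky <- function(i) if (i >= 10 && i <= 19) NULL else r$landmarks(i)
  ser <- classify_sequence(r$frames, cal, flaky)
  expect_equal(nrow(ser), 40)
  expect_equal(which(!ser$landmark_found) - 1L, 10:19)
  expect_equal(sum(ser$left_state == "unclassified"), 10)
  expect_true(all(is.na(ser$combined_closed[11:20])))
  # all other frames are open: fully open sequence, matching templates
  expect_true(all(ser$combined_closed[-(11:20)] == FALSE))
})

test_that("classification agrees with rendered ground truth", {
  withr::with_seed(21, {
    aperture <- rep(1, 200)
    closed_at <- c(40:60, 120:150)
    aperture[closed_at + 1] <- runif(length(closed_at), 0.02, 0.18)
  })
  ser <- classify_rendered(aperture, seed = 3)
  truth <- aperture < 0.25
  expect_equal(sum(is.na(ser$combined_closed)), 0)
  expect_gte(mean(ser$combined_closed == truth), 0.99)
})

test_that("calibration patch larger than the frame is a config error", {
  aperture <- rep(1, 5)
  r <- render_frames(aperture, seed = 5)
  cal <- build_templates(r$frames, render_selection(r, 0))
  tiny <- purrr::map(r$frames, ~ .x[1:10, 1:10])
  expect_error(classify_sequence(tiny, cal, r$landmarks),
               class = "perclosr_config_error")
})

test_that("apply_overrides replaces states, later overrides winning", {
  s <- as_eye_state_series(rep(FALSE, 30))
  ov <- tibble::tibble(frame_start = 10, frame_end = 19, state = "closed")
  out <- apply_overrides(s, ov)
  expect_equal(sum(out$combined_closed), 10)
  expect_equal(which(out$combined_closed) - 1L, 10:19)

  expect_identical(apply_overrides(s, ov[0, ]), s)

  ov2 <- tibble::tibble(frame_start = c(0, 5), frame_end = c(9, 9),
                        state = c("closed", "open"))
  out2 <- apply_overrides(s, ov2)
  expect_equal(which(out2$combined_closed) - 1L, 0:4)

  expect_error(
    apply_overrides(s, tibble::tibble(frame_start = 25, frame_end = 35,
                                      state = "closed")),
    class = "perclosr_override_error")
  expect_error(
    apply_overrides(s, tibble::tibble(frame_start = 1, frame_end = 2,
                                      state = "shut")),
    class = "perclosr_override_error")
})

test_that("calibration YAML and override CSV round-trip", {
  sel <- std_selection()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_calibration(sel, f, threshold = 0.7)
  back <- read_calibration(f)
  expect_equal(back$threshold, 0.7)
  expect_equal(as.data.frame(back$selections), as.data.frame(sel))

  ov <- tibble::tibble(frame_start = c(0L, 5L), frame_end = c(4L, 9L),
                       state = c("closed", "open"))
  g <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ov, g)
  expect_equal(as.data.frame(read_overrides(g)), as.data.frame(ov))
})
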