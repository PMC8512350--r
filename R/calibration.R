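#' Build an eye-template calibration set from selected frames
#'
#' Cuts matched left/right open-eye patches out of user-selected frames and
#' bundles them with the match-score threshold used to accept an eye as open.
#' One or more template pairs may be used; three pairs is the conventional
#' choice, trading detection robustness against matching cost.
#'
#' @param frames A list of grayscale frames (numeric matrices), indexed from
#'   frame 0 (i.e. `frames[[1]]` is frame 0).
#' @param selections A data frame with one row per template pair and columns
#'   `frame` (0-based frame index) and, for each eye `left`/`right`, rectangle
#'   columns `<eye>_x`, `<eye>_y`, `<eye>_w`, `<eye>_h` giving a 0-based,
#'   top-left-origin, half-open pixel rectangle (`x` = column, `y` = row).
#' @param threshold Match-score cutoff in (0, 1]; a template match at or above
#'   this score classifies the eye as open. Default 0.68.
#'
#' @return An object of class `calibration_set`: a list with `pairs` (each a
#'   list with `left`, `right` patch matrices and `source_frame`), `threshold`
#'   and `patch_size` (`c(height, width)` in pixels).
#' @examples
#' frames <- replicate(5, matrix(runif(48 * 72), 48, 72), simplify = FALSE)
#' sel <- tibble::tibble(
#'   frame = c(0, 2, 4),
#'   left_x = 10, left_y = 14, left_w = 18, left_h = 12,
#'   right_x = 44, right_y = 14, right_w = 18, right_h = 12
#' )
#' cal <- build_templates(frames, sel)
#' length(cal$pairs)
#' @export
build_templates <- function(frames, selections, threshold = 0.68) {
  selections <- as_tibble(selections)
  if (nrow(selections) == 0) {
    abort("`selections` must contain at least one template selection.",
          class = "perclosr_calibration_error")
  }
  needed <- c("frame", paste0(rep(c("left_", "right_"), each = 4),
                              c("x", "y", "w", "h")))
  missing_cols <- setdiff(needed, names(selections))
  if (length(missing_cols) > 0) {
    abort(paste0("`selections` is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "perclosr_calibration_error")
  }
  if (!(threshold > 0 && threshold <= 1)) {
    abort("`threshold` must lie in (0, 1].",
          class = "perclosr_calibration_error")
  }

  pairs <- purrr::pmap(selections, function(frame, ...) {
    rect <- list(...)
    if (frame < 0 || frame >= length(frames)) {
      abort(sprintf("Selected frame %d does not exist (0..%d).",
                    frame, length(frames) - 1L),
            class = "perclosr_calibration_error")
    }
    img <- frames[[frame + 1L]]
    list(
      left  = extract_rect(img, rect$left_x, rect$left_y,
                           rect$left_w, rect$left_h, frame),
      right = extract_rect(img, rect$right_x, rect$right_y,
                           rect$right_w, rect$right_h, frame),
      source_frame = as.integer(frame)
    )
  })

  sizes <- purrr::map(pairs, ~ rbind(dim(.x$left), dim(.x$right)))
  size0 <- sizes[[1]][1, ]
  ok <- purrr::every(sizes, ~ all(t(.x) == size0))
  if (!ok) {
    abort("All template patches must share one size within a calibration set.",
          class = "perclosr_calibration_error")
  }

  structure(
    list(pairs = pairs, threshold = threshold,
         patch_size = as.integer(size0)),
    class = "calibration_set"
  )
}

# Half-open, 0-based rectangle -> matrix patch; errors if out of bounds.
extract_rect <- function(img, x, y, w, h, frame) {
  if (w < 1 || h < 1 ||
      x < 0 || y < 0 || x + w > ncol(img) || y + h > nrow(img)) {
    abort(sprintf(
      "Template region (x=%s, y=%s, w=%s, h=%s) exceeds frame %d (%dx%d px).",
      x, y, w, h, frame, ncol(img), nrow(img)),
      class = "perclosr_calibration_error")
  }
  img[(y + 1):(y + h), (x + 1):(x + w), drop = FALSE]
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("<calibration_set> %d template pair(s), patch %dx%d px, threshold %.2f\n",
              length(x$pairs), x$patch_size[1], x$patch_size[2], x$threshold))
  cat("source frames:", paste(purrr::map_int(x$pairs, "source_frame"),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Read and write calibration selections
#'
#' The calibration file is a YAML document recording which frames and which
#' eye rectangles the templates are built from (not the pixel data itself),
#' so a calibration can be re-applied to the original video. Rectangles are
#' 0-based, top-left origin, half-open.
#'
#' @param path Path to a YAML calibration file.
#' @return `read_calibration()` returns a list with `threshold` and
#'   `selections` (a tibble suitable for [build_templates()]).
#' @examples
#' sel <- tibble::tibble(
#'   frame = 0, left_x = 2, left_y = 2, left_w = 4, left_h = 3,
#'   right_x = 10, right_y = 2, right_w = 4, right_h = 3
#' )
#' f <- tempfile(fileext = ".yaml")
#' write_calibration(sel, f)
#' read_calibration(f)$selections
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Calibration file not found: %s", path),
          class = "perclosr_io_error")
  }
  doc <- yaml::read_yaml(path)
  sel <- purrr::map_dfr(doc$templates, function(t) {
    tibble(
      frame = t$frame,
      left_x = t$left$x, left_y = t$left$y,
      left_w = t$left$width, left_h = t$left$height,
      right_x = t$right$x, right_y = t$right$y,
      right_w = t$right$width, right_h = t$right$height
    )
  })
  list(threshold = doc$threshold %||% 0.68, selections = sel)
}

#' @param selections Selections tibble (see [build_templates()]).
#' @param threshold Match-score threshold stored with the file.
#' @rdname read_calibration
#' @export
write_calibration <- function(selections, path, threshold = 0.68) {
  selections <- as_tibble(selections)
  doc <- list(
    threshold = threshold,
    templates = purrr::pmap(selections, function(frame, ...) {
      r <- list(...)
      list(
        frame = as.integer(frame),
        left = list(x = r$left_x, y = r$left_y,
                    width = r$left_w, height = r$left_h),
        right = list(x = r$right_x, y = r$right_y,
                     width = r$right_w, height = r$right_h)
      )
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read an ordered directory of PNG frames
#'
#' Frames are read in lexicographic filename order and converted to grayscale
#' matrices (mean over channels for RGB input). Frame 0 is the first file.
#'
#' @param dir Directory containing `.png` frames.
#' @return A list of numeric matrices.
#' @export
read_frame_dir <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("Package 'png' is required to read PNG frame directories.")
  }
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) {
    abort(sprintf("No PNG frames found in %s", dir),
          class = "perclosr_io_error")
  }
  purrr::map(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                        c(1, 2), mean)
    a
  })
}
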