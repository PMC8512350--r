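#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an eye-state series as open/closed bars
#'
#' Static reproduction of the result-visualisation chart: per-frame bars,
#' green for open, red for closed, gaps where frames are unclassified.
#'
#' @param object An `eye_state_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eye_state_series <- function(object, ...) {
  d <- tidyr::pivot_longer(
    as_tibble(object)[, c("frame", "left_state", "right_state")],
    cols = c("left_state", "right_state"),
    names_to = "eye", values_to = "state"
  )
  d <- dplyr::filter(d, .data$state != "unclassified")
  d$eye <- ifelse(d$eye == "left_state", "left eye", "right eye")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame, y = 1,
                                  fill = .data$state)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~eye, ncol = 1) +
    ggplot2::scale_fill_manual(values = c(open = "#2e7d32",
                                          closed = "#c62828")) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "frame", y = NULL, fill = "eye state",
                  title = "Per-frame eye-state classification") +
    ggplot2::theme_minimal()
}

#' Plot windowed fatigue indicators with threshold lines
#'
#' One panel per indicator (PERCLOS, ECD in ms, FEC) over window index, with
#' the fatigue threshold drawn as a dashed line.
#'
#' @param object A `window_indicators` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.window_indicators <- function(object, ...) {
  thr <- attr(object, "thresholds") %||% threshold_config()
  d <- tidyr::pivot_longer(
    as_tibble(object)[, c("window_index", "perclos", "ecd_ms", "fec")],
    cols = c("perclos", "ecd_ms", "fec"),
    names_to = "indicator", values_to = "value"
  )
  d$indicator <- factor(d$indicator, levels = c("perclos", "ecd_ms", "fec"),
                        labels = c("PERCLOS", "ECD (ms)", "FEC"))
  lines <- tibble(
    indicator = factor(c("PERCLOS", "ECD (ms)", "FEC"),
                       levels = levels(d$indicator)),
    threshold = c(thr$perclos_fatigue, thr$ecd_fatigue_ms, thr$fec_fatigue)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window_index, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::geom_hline(data = lines,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed", colour = "#c62828") +
    ggplot2::facet_wrap(~indicator, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "30-s window", y = NULL,
                  title = "Eye closure-associated fatigue indicators") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `perclos_roc` from [roc_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perclos_roc <- function(object, ...) {
  d <- object$curve
  ggplot2::ggplot(d, ggplot2::aes(x = 1 - .data$specificity,
                                  y = .data$sensitivity)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, colour = "#c62828") +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("ROC curve (AUC = %.3f, %g%% CI %.3f-%.3f)",
                      object$auc, 100 * object$conf_level,
                      object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}
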