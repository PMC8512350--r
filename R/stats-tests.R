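#' Paired t-test with a dependent-samples effect size
#'
#' Runs a paired Student's t-test on pre/post measurements (differences taken
#' as `post - pre`) and computes Cohen's d for paired samples. The default
#' effect size is the correlation-corrected repeated-measures form
#' `d_rm = mean(diff) * sqrt(2 * (1 - r)) / sd(diff)` with `r` the pre/post
#' correlation; `"av"` divides the mean difference by the average of the two
#' SDs, and `"z"` is the plain standardized mean difference of the
#' differences. When the pre/post correlation is undefined (a constant
#' margin), the `"rm"` form falls back to `"z"`.
#'
#' @param pre,post Paired numeric vectors (same subjects, same order),
#'   length at least 2.
#' @param d_method `"rm"` (default), `"av"`, or `"z"`.
#' @return A one-row tibble: `t`, `df`, `p_value`, `cohens_d`, `mean_diff`,
#'   `n`, `d_method`.
#' @examples
#' paired_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
paired_test <- function(pre, post, d_method = c("rm", "av", "z")) {
  d_method <- match.arg(d_method)
  if (length(pre) != length(post)) {
    abort("`pre` and `post` must have equal lengths.",
          class = "perclosr_degenerate_input")
  }
  n <- length(pre)
  if (n < 2) {
    abort("Paired test needs at least 2 pairs (df = n - 1 >= 1).",
          class = "perclosr_degenerate_input")
  }
  diff <- post - pre
  if (sd(diff) == 0) {
    if (all(diff == 0)) {
      return(tibble(t = 0, df = n - 1L, p_value = 1, cohens_d = 0,
                    mean_diff = 0, n = n, d_method = d_method))
    }
    abort("Differences have zero variance but nonzero mean; t is undefined.",
          class = "perclosr_degenerate_input")
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  r <- suppressWarnings(cor(pre, post))
  d <- switch(
    d_method,
    rm = if (is.na(r)) mean(diff) / sd(diff)
         else mean(diff) * sqrt(2 * (1 - r)) / sd(diff),
    av = mean(diff) / mean(c(sd(pre), sd(post))),
    z = mean(diff) / sd(diff)
  )
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, cohens_d = d, mean_diff = mean(diff),
         n = n, d_method = d_method)
}

#' ROC analysis with stratified bootstrap confidence interval
#'
#' Computes the area under the ROC curve by the rank (Mann-Whitney) formula
#' — equivalent to the proportion of positive/negative pairs ordered
#' correctly, ties counting one half — together with a stratified
#' (within-class) percentile bootstrap confidence interval and the optimal
#' operating point maximizing Youden's J, placed at the midpoint between
#' adjacent distinct scores. Higher scores are taken to indicate the
#' positive class.
#'
#' @param scores Numeric classifier scores.
#' @param labels Class labels coercible to logical (`TRUE`/second factor
#'   level = positive class); both classes must be present.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `perclos_roc`: a list with `auc`, `ci_low`,
#'   `ci_high`, `optimal_threshold`, `sensitivity`, `specificity`, `n_pos`,
#'   `n_neg`, `n_boot`, `conf_level`, and `curve` (a tibble of the full
#'   sensitivity/specificity path).
#' @examples
#' roc_analysis(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3),
#'              n_boot = 50, seed = 1)$auc
#' @export
roc_analysis <- function(scores, labels, n_boot = 2000, seed = 1L,
                         conf_level = 0.95) {
  labels <- as_positive(labels)
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal lengths.",
          class = "perclosr_degenerate_input")
  }
  if (!any(labels) || all(labels)) {
    abort("Both classes must be present for ROC analysis.",
          class = "perclosr_degenerate_input")
  }
  if (n_boot < 1) abort("`n_boot` must be at least 1.")
  pos <- scores[labels]
  neg <- scores[!labels]
  auc <- auc_rank(pos, neg)

  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      auc_rank(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha), type = 7))

  # Candidate thresholds: midpoints between adjacent distinct scores,
  # bracketed by -Inf/Inf.
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2, Inf)
  sens <- vapply(thr, function(t) mean(pos > t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg <= t), numeric(1))
  j <- sens + spec - 1
  best <- which.max(j)

  structure(
    list(auc = auc, ci_low = ci[1], ci_high = ci[2],
         optimal_threshold = thr[best],
         sensitivity = sens[best], specificity = spec[best],
         n_pos = length(pos), n_neg = length(neg),
         n_boot = n_boot, conf_level = conf_level,
         curve = tibble(threshold = thr, sensitivity = sens,
                        specificity = spec)),
    class = "perclos_roc"
  )
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) {
      abort("Factor labels must have exactly 2 levels.",
            class = "perclosr_degenerate_input")
    }
    return(labels == levels(labels)[2])
  }
  if (is.numeric(labels)) return(labels != 0)
  f <- factor(labels)
  as_positive(f)
}

# Mann-Whitney AUC: mean rank of positives among all scores, ties averaged.
auc_rank <- function(pos, neg) {
  n1 <- length(pos); n0 <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.perclos_roc <- function(x, ...) {
  cat(sprintf("<perclos_roc> AUC = %.3f (%g%% bootstrap CI %.3f-%.3f, %d reps)\n",
              x$auc, 100 * x$conf_level, x$ci_low, x$ci_high, x$n_boot))
  cat(sprintf("optimal threshold %.3g: sensitivity %.3f, specificity %.3f\n",
              x$optimal_threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
tidy.perclos_roc <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
         optimal_threshold = x$optimal_threshold,
         sensitivity = x$sensitivity, specificity = x$specificity,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
glance.perclos_roc <- function(x, ...) tidy(x)
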