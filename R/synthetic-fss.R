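#' Configuration for the three-level subjective-fatigue simulator
#'
#' Describes a pre-test/post-test repeated-measures design: two measurement
#' occasions nested in two experimental conditions (rested/drowsy sessions)
#' nested in subjects, with random intercepts for subject (level 3) and
#' condition-within-subject (level 2), a residual at the occasion level
#' (level 1), and fixed effects of time (occasion) and a standardized
#' eye-closure indicator.
#'
#' @param n_subjects Number of subjects.
#' @param fixed_intercept Grand-mean subjective-fatigue score.
#' @param fixed_time_slope Fixed effect of occasion (0 = pre, 1 = post).
#' @param fixed_indicator_slope Fixed effect of the (standardized) indicator.
#' @param var_subject,var_condition,var_residual Variances of the level-3
#'   and level-2 random intercepts and the level-1 residual.
#' @param indicator_mean,indicator_sd Distribution of the simulated
#'   indicator values.
#' @param seed Integer seed.
#' @return An `fss_sim_config` list.
#' @export
fss_sim_config <- function(n_subjects = 8,
                           fixed_intercept = 30,
                           fixed_time_slope = 5,
                           fixed_indicator_slope = 10,
                           var_subject = 237,
                           var_condition = 217,
                           var_residual = 178,
                           indicator_mean = 0,
                           indicator_sd = 1,
                           seed = 1L) {
  stopifnot(n_subjects >= 1, var_subject >= 0, var_condition >= 0,
            var_residual >= 0, indicator_sd >= 0)
  structure(
    list(n_subjects = as.integer(n_subjects),
         fixed_intercept = fixed_intercept,
         fixed_time_slope = fixed_time_slope,
         fixed_indicator_slope = fixed_indicator_slope,
         var_subject = var_subject, var_condition = var_condition,
         var_residual = var_residual,
         indicator_mean = indicator_mean, indicator_sd = indicator_sd,
         seed = as.integer(seed)),
    class = "fss_sim_config"
  )
}

#' Simulate a three-level subjective-fatigue dataset
#'
#' Generates one row per subject x condition x occasion with
#' `fss_s = intercept + time_slope * occasion + indicator_slope * indicator
#' + u_subject + u_condition + epsilon`, where `u_subject` and `u_condition`
#' are mean-zero normal random intercepts at levels 3 and 2 and `epsilon` is
#' the level-1 residual. The drawn random effects are attached as the
#' `"components"` attribute for variance-recovery checks.
#'
#' @param config An [fss_sim_config()].
#' @return A tibble with columns `subject` (factor), `condition`
#'   (`"rested"`/`"drowsy"`), `occasion` (0 pre / 1 post), `indicator`,
#'   `fss_s`.
#' @examples
#' d <- generate_fss_dataset(fss_sim_config(n_subjects = 4, seed = 2))
#' nrow(d) # 4 subjects x 2 conditions x 2 occasions
#' @export
generate_fss_dataset <- function(config) {
  n <- config$n_subjects
  withr::with_seed(config$seed, {
    u_subject <- rnorm(n, 0, sqrt(config$var_subject))
    u_condition <- rnorm(2 * n, 0, sqrt(config$var_condition))
    grid <- tidyr::expand_grid(
      subject = seq_len(n),
      condition = c("rested", "drowsy"),
      occasion = c(0L, 1L)
    )
    cond_id <- (grid$subject - 1L) * 2L + ifelse(grid$condition == "drowsy", 2L, 1L)
    eps <- rnorm(nrow(grid), 0, sqrt(config$var_residual))
    indicator <- rnorm(nrow(grid), config$indicator_mean, config$indicator_sd)
    out <- dplyr::mutate(
      grid,
      subject = factor(.data$subject),
      indicator = indicator,
      fss_s = config$fixed_intercept +
        config$fixed_time_slope * .data$occasion +
        config$fixed_indicator_slope * indicator +
        u_subject[as.integer(as.character(.data$subject))] +
        u_condition[cond_id] + eps
    )
    attr(out, "components") <- list(u_subject = u_subject,
                                    u_condition = u_condition,
                                    residual = eps)
    out
  })
}
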