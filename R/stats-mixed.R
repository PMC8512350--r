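#' Construct a three-level model-fit record
#'
#' Container for one fitted (or externally reported) three-level linear
#' mixed model: fixed effects, the variance components at the subject
#' (level 3), condition-within-subject (level 2) and residual (level 1)
#' levels, and the likelihood bookkeeping. `compare_models()`, [icc()],
#' [r2_nakagawa()] and [delta_r2()] all operate on this record, so model
#' summaries printed elsewhere (e.g. a published comparison table) can be
#' re-analysed by constructing records from their `-2 log L` values.
#'
#' @param fixed_effects Tibble with columns `term`, `estimate`, `std_error`
#'   (may be empty for externally reported fits).
#' @param var_subject,var_condition,var_residual Variance components.
#' @param loglik Maximized log-likelihood.
#' @param n_params Number of estimated parameters (fixed effects +
#'   variance components).
#' @param n_obs Number of observations.
#' @param converged Logical convergence flag.
#' @param label Model label used in comparison tables.
#' @param var_fixed Variance of the fixed-effect linear predictor (needed by
#'   [r2_nakagawa()]; `NA` if unknown).
#' @return An object of class `perclos_model_fit`.
#' @examples
#' m1 <- model_fit(loglik = -289.46 / 2, n_params = 4, label = "M1")
#' m2 <- model_fit(loglik = -287.44 / 2, n_params = 5, label = "M2")
#' compare_models(list(m1, m2))
#' @export
model_fit <- function(fixed_effects = tibble(term = character(),
                                             estimate = double(),
                                             std_error = double()),
                      var_subject = NA_real_, var_condition = NA_real_,
                      var_residual = NA_real_,
                      loglik, n_params, n_obs = NA_integer_,
                      converged = TRUE, label = "model",
                      var_fixed = NA_real_) {
  for (v in c(var_subject, var_condition, var_residual)) {
    if (!is.na(v) && v < 0) abort("Variance components must be >= 0.")
  }
  structure(
    list(fixed_effects = as_tibble(fixed_effects),
         var_subject = var_subject, var_condition = var_condition,
         var_residual = var_residual,
         loglik = loglik, n_params = as.integer(n_params),
         aic = 2 * n_params - 2 * loglik,
         n_obs = n_obs, converged = converged, label = label,
         var_fixed = var_fixed, lmer_fit = NULL),
    class = "perclos_model_fit"
  )
}

#' Fit a three-level linear mixed model for subjective fatigue
#'
#' Fits, by maximum likelihood, the model
#' `fss_s ~ 1 [+ occasion] [+ indicator] + (1 | subject / condition)`:
#' random intercepts for subject (level 3) and for the experimental
#' condition nested within subject (level 2), with the measurement occasion
#' as the level-1 unit. The indicator predictor is z-standardized over all
#' rows before entry ("scaled") so its slope is per indicator-SD. Estimation
#' delegates to [lme4::lmer()] with deterministic optimizer settings; the
#' model specification and all derived quantities (ICC, R-squared,
#' delta R-squared, comparisons) live here.
#'
#' @param data A data frame with columns `subject`, `condition`, `occasion`
#'   (0/1), the response, and an indicator column when requested.
#' @param predictors Character subset of `c("time", "indicator")`; empty for
#'   the intercept-only model.
#' @param response Response column name (default `"fss_s"`).
#' @param indicator Indicator column name (default `"indicator"`).
#' @param scale_indicator Standardize the indicator before entry
#'   (default `TRUE`).
#' @param label Model label for comparison tables.
#' @return A `perclos_model_fit`; `converged` is `FALSE` when lme4 reports
#'   convergence problems (the fit is still returned, never silently
#'   discarded).
#' @export
fit_three_level <- function(data, predictors = character(),
                            response = "fss_s", indicator = "indicator",
                            scale_indicator = TRUE,
                            label = NULL) {
  bad <- setdiff(predictors, c("time", "indicator"))
  if (length(bad) > 0) {
    abort(paste0("Unknown predictors: ", paste(bad, collapse = ", ")),
          class = "perclosr_config_error")
  }
  need <- c("subject", "condition", "occasion", response,
            if ("indicator" %in% predictors) indicator)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Data is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "perclosr_schema_error")
  }
  d <- as_tibble(data)
  if (sd(d[[response]]) == 0) {
    abort("Response is constant; the model is degenerate.",
          class = "perclosr_degenerate_input")
  }
  d$.y <- d[[response]]
  terms <- c("1")
  if ("time" %in% predictors) terms <- c(terms, "occasion")
  if ("indicator" %in% predictors) {
    d$.ind <- if (scale_indicator) as.numeric(scale(d[[indicator]]))
              else d[[indicator]]
    terms <- c(terms, ".ind")
  }
  fml <- stats::as.formula(paste(
    ".y ~", paste(terms, collapse = " + "), "+ (1 | subject / condition)"))

  fit <- lme4::lmer(fml, data = d, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v) == 1) v else NA_real_
  }
  co <- summary(fit)$coefficients
  term_names <- rownames(co)
  term_names[term_names == ".ind"] <- indicator
  fe <- tibble(term = term_names,
               estimate = co[, "Estimate"],
               std_error = co[, "Std. Error"])
  ll <- logLik(fit)
  conv <- length(fit@optinfo$conv$lme4$messages %||% character()) == 0 &&
    (fit@optinfo$conv$opt %||% 0) == 0

  out <- model_fit(
    fixed_effects = fe,
    var_subject = pick("subject"),
    var_condition = pick("condition:subject"),
    var_residual = pick("Residual"),
    loglik = as.numeric(ll),
    n_params = attr(ll, "df"),
    n_obs = nrow(d),
    converged = conv,
    label = label %||% paste0("fss_s ~ ", paste(terms, collapse = " + ")),
    var_fixed = var(predict(fit, re.form = NA))
  )
  out$lmer_fit <- fit
  out
}

#' @export
print.perclos_model_fit <- function(x, ...) {
  cat(sprintf("<perclos_model_fit> %s\n", x$label))
  cat(sprintf("  logLik %.3f  AIC %.2f  params %d  converged %s\n",
              x$loglik, x$aic, x$n_params, x$converged))
  cat(sprintf("  variances: subject %.2f | condition %.2f | residual %.2f\n",
              x$var_subject, x$var_condition, x$var_residual))
  if (nrow(x$fixed_effects) > 0) {
    print(x$fixed_effects)
  }
  invisible(x)
}

#' @export
tidy.perclos_model_fit <- function(x, ...) {
  fixed <- dplyr::mutate(x$fixed_effects, effect = "fixed", .before = 1)
  ran <- tibble(
    effect = "random",
    term = c("var_subject (level 3)", "var_condition (level 2)",
             "var_residual (level 1)"),
    estimate = c(x$var_subject, x$var_condition, x$var_residual),
    std_error = NA_real_
  )
  dplyr::bind_rows(fixed, ran)
}

#' @export
glance.perclos_model_fit <- function(x, ...) {
  tibble(nobs = x$n_obs, logLik = x$loglik, AIC = x$aic,
         n_params = x$n_params, converged = x$converged,
         var_subject = x$var_subject, var_condition = x$var_condition,
         var_residual = x$var_residual)
}

#' Intraclass correlations of a three-level intercept model
#'
#' The ICC at a grouping level is that level's variance share of the total:
#' `icc_k = var_k / (var_subject + var_condition + var_residual)`. Level 2
#' is the condition (task repetition) level, level 3 the subject (person)
#' level. Meaningful for the intercept-only model.
#'
#' @param fit A `perclos_model_fit`.
#' @return A one-row tibble: `icc_level2` (condition), `icc_level3`
#'   (subject).
#' @examples
#' f <- model_fit(var_subject = 4, var_condition = 4, var_residual = 2,
#'                loglik = 0, n_params = 4)
#' icc(f)
#' @export
icc <- function(fit) {
  total <- fit$var_subject + fit$var_condition + fit$var_residual
  if (is.na(total) || total == 0) {
    abort("All variance components are zero or missing; ICC is undefined.",
          class = "perclosr_degenerate_input")
  }
  tibble(icc_level2 = fit$var_condition / total,
         icc_level3 = fit$var_subject / total)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-explained summaries for mixed models: the marginal R-squared is
#' the fixed-effect share `var_f / (var_f + var_subject + var_condition +
#' var_residual)`; the conditional R-squared adds the random-intercept
#' variances to the numerator, summarizing the entire model. `var_f` is the
#' variance of the fixed-effect linear predictor.
#'
#' @param fit A `perclos_model_fit`.
#' @param var_fixed Variance of the fixed-effect linear predictor; defaults
#'   to the value stored in the fit.
#' @return A one-row tibble: `r2_marginal`, `r2_conditional`.
#' @export
r2_nakagawa <- function(fit, var_fixed = NULL) {
  vf <- var_fixed %||% fit$var_fixed
  if (is.na(vf)) {
    abort("Fixed-effect predictor variance is unknown for this fit.",
          class = "perclosr_config_error")
  }
  denom <- vf + fit$var_subject + fit$var_condition + fit$var_residual
  if (is.na(denom) || denom == 0) {
    abort("Total variance is zero; R-squared is undefined.",
          class = "perclosr_degenerate_input")
  }
  tibble(
    r2_marginal = vf / denom,
    r2_conditional = (vf + fit$var_subject + fit$var_condition) / denom
  )
}

#' Per-level proportional variance change (delta R-squared)
#'
#' For each level, the proportion of the reference model's variance
#' component removed by the richer model:
#' `(var_ref - var_new) / var_ref`. A variance increase yields a negative
#' value (reported, not clipped); a zero reference variance yields `NA` for
#' that level.
#'
#' @param fit_ref,fit_new `perclos_model_fit`s of nested models on the same
#'   data (`fit_ref` the smaller model).
#' @return A tibble with one row per level (`subject`, `condition`,
#'   `residual`): `var_ref`, `var_new`, `delta_r2`.
#' @examples
#' a <- model_fit(var_subject = 100, var_condition = 100, var_residual = 100,
#'                loglik = 0, n_params = 4)
#' b <- model_fit(var_subject = 63, var_condition = 100, var_residual = 100,
#'                loglik = 0, n_params = 5)
#' delta_r2(a, b)
#' @export
delta_r2 <- function(fit_ref, fit_new) {
  ref <- c(subject = fit_ref$var_subject, condition = fit_ref$var_condition,
           residual = fit_ref$var_residual)
  new <- c(subject = fit_new$var_subject, condition = fit_new$var_condition,
           residual = fit_new$var_residual)
  tibble(
    level = names(ref),
    var_ref = unname(ref),
    var_new = unname(new),
    delta_r2 = unname(ifelse(ref == 0, NA_real_, (ref - new) / ref))
  )
}

#' Likelihood-ratio comparison table for a set of nested models
#'
#' Builds the usual model-comparison table — AIC, -2 log-likelihood, df, and
#' the likelihood-ratio chi-squared of each model against its designated
#' reference — for a sequence of nested fits on the same data. By default
#' each model is compared to the previous one; pass `reference` to compare
#' several rivals to a common base (e.g. each indicator model against the
#' time-only model).
#'
#' @param fits List of `perclos_model_fit`s.
#' @param reference Integer vector, per fit, giving the index of its
#'   reference model (`NA` for none). Default: `c(NA, 1, 2, 3, ...)`.
#' @return A tibble: `model`, `aic`, `minus2ll`, `df`, `reference`, `chisq`,
#'   `df_diff`, `p_value`.
#' @examples
#' m1 <- model_fit(loglik = -289.46 / 2, n_params = 4, label = "M1")
#' m2 <- model_fit(loglik = -287.44 / 2, n_params = 5, label = "M2")
#' compare_models(list(m1, m2))$chisq
#' @export
compare_models <- function(fits, reference = NULL) {
  k <- length(fits)
  if (k < 1) abort("Need at least one fit.")
  reference <- reference %||% c(NA, seq_len(k - 1))
  if (length(reference) != k) {
    abort("`reference` must have one entry per fit.",
          class = "perclosr_config_error")
  }
  nobs <- purrr::map_int(fits, ~ .x$n_obs %||% NA_integer_)
  if (length(unique(nobs[!is.na(nobs)])) > 1) {
    abort("Models were fitted to different numbers of observations.",
          class = "perclosr_config_error")
  }
  rows <- purrr::map(seq_len(k), function(i) {
    f <- fits[[i]]
    ref <- reference[i]
    if (!is.na(ref)) {
      fr <- fits[[ref]]
      df_diff <- f$n_params - fr$n_params
      if (df_diff <= 0) {
        abort("Each model must have more parameters than its reference (nesting).",
              class = "perclosr_config_error")
      }
      chisq <- (-2 * fr$loglik) - (-2 * f$loglik)
      p <- pchisq(max(0, chisq), df_diff, lower.tail = FALSE)
    } else {
      chisq <- NA_real_; df_diff <- NA_integer_; p <- NA_real_
    }
    tibble(model = f$label, aic = f$aic, minus2ll = -2 * f$loglik,
           df = f$n_params,
           reference = if (is.na(ref)) NA_character_ else fits[[ref]]$label,
           chisq = chisq, df_diff = df_diff, p_value = p)
  })
  dplyr::bind_rows(rows)
}
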