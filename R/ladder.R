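# Polynomial mixed-model comparison ladders. Blur grade always enters as
# an orthogonal second-order polynomial (poly(blur_grade, 2)), so the
# linear and quadratic terms are decorrelated. All likelihood-ratio tests
# compare maximum-likelihood (not REML) fits, the validity condition for
# LRTs on fixed effects.

fit_mixed <- function(formula, data, family = "gaussian") {
  f <- as.formula(formula)
  if (family == "gaussian") {
    lme4::lmer(f, data = data, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  } else {
    fam <- switch(family,
                  poisson = stats::poisson(),
                  gamma_log = stats::Gamma(link = "log"),
                  stop("unsupported family: ", family))
    lme4::glmer(f, data = data, family = fam,
                control = lme4::glmerControl(check.conv.singular = "ignore"))
  }
}

lrt <- function(null_fit, full_fit) {
  chi <- as.numeric(2 * (logLik(full_fit) - logLik(null_fit)))
  df <- attr(logLik(full_fit), "df") - attr(logLik(null_fit), "df")
  list(chi_square = max(chi, 0), df = df,
       p = pchisq(max(chi, 0), df, lower.tail = FALSE))
}

is_singular <- function(fit) tryCatch(lme4::isSingular(fit, tol = 1e-4),
                                      error = function(e) TRUE)

#' Choose the random-effects structure
#'
#' Starts from nested dyad/participant random intercepts, tests adding a
#' gesture-type intercept by likelihood-ratio test, and falls back to a
#' single (global) participant factor when the nested structure is
#' singular or fails to converge.
#'
#' @param data long table with `dyad_id`, `participant_id` and optionally
#'   `gesture_type` columns plus the response.
#' @param response response column name.
#' @param family `"gaussian"`, `"poisson"` or `"gamma_log"`.
#' @param alpha level for the gesture-type LRT.
#' @return list: `formula` (random-effects part as a string),
#'   `gesture_type_kept`, `nested_ok`, `diagnostics`.
#' @export
build_random_effects <- function(data, response, family = "gaussian",
                                 alpha = 0.05) {
  if (length(unique(data$participant_id)) < 2)
    stop("need at least 2 participants")
  nested <- "(1 | dyad_id / participant_id)"
  flat <- "(1 | participant_id)"
  base_fit <- tryCatch(
    fit_mixed(paste(response, "~ 1 +", nested), data, family),
    error = function(e) NULL, warning = function(w) NULL)
  nested_ok <- !is.null(base_fit) && !is_singular(base_fit)
  re <- if (nested_ok) nested else flat
  if (!nested_ok)
    base_fit <- fit_mixed(paste(response, "~ 1 +", flat), data, family)
  gesture_type_kept <- FALSE
  diag_p <- NA_real_
  if ("gesture_type" %in% names(data) &&
      length(unique(data$gesture_type)) > 1) {
    with_gt <- tryCatch(
      fit_mixed(paste(response, "~ 1 +", re, "+ (1 | gesture_type)"),
                data, family),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(with_gt) && !is_singular(with_gt)) {
      cmp <- lrt(base_fit, with_gt)
      diag_p <- cmp$p
      if (cmp$p < alpha) {
        gesture_type_kept <- TRUE
        re <- paste(re, "+ (1 | gesture_type)")
      }
    }
  }
  list(formula = re, gesture_type_kept = gesture_type_kept,
       nested_ok = nested_ok,
       diagnostics = list(gesture_type_p = diag_p))
}

#' Pseudo-R-squared for a mixed-model comparison
#'
#' Conditional R-squared (variance explained by fixed plus random
#' effects) via the variance-components decomposition, its change from
#' the null model, and the likelihood-ratio R-squared
#' `1 - exp(-LR / n)`.
#'
#' The distribution-specific residual variance on the link scale is
#' `sigma^2` (gaussian), `log(1 + 1/lambda-bar)` (poisson, log link) and
#' `trigamma(1/dispersion)` (gamma, log link).
#'
#' @param full_fit,null_fit `merMod` fits on the same data (ML).
#' @param n number of observations (defaults to `nobs(full_fit)`).
#' @return list: `r2c`, `delta_r2c`, `r2lr`.
#' @export
pseudo_r2 <- function(full_fit, null_fit, n = stats::nobs(full_fit)) {
  r2c_one <- function(fit) {
    X <- model.matrix(fit)
    var_fix <- var(as.numeric(X %*% lme4::fixef(fit)))
    # random part via conditional minus marginal prediction: covers
    # random slopes as well as intercepts
    var_ran <- var(predict(fit, re.form = NULL) -
                     predict(fit, re.form = NA))
    var_res <- resid_variance(fit)
    (var_fix + var_ran) / (var_fix + var_ran + var_res)
  }
  lr <- as.numeric(2 * (logLik(full_fit) - logLik(null_fit)))
  r2c <- r2c_one(full_fit)
  list(r2c = r2c, delta_r2c = r2c - r2c_one(null_fit),
       r2lr = 1 - exp(-max(lr, 0) / n))
}

resid_variance <- function(fit) {
  if (inherits(fit, "glmerMod")) {
    fam <- stats::family(fit)
    if (fam$family == "poisson") {
      lambda_bar <- mean(stats::fitted(fit))
      log(1 + 1 / lambda_bar)
    } else if (fam$family == "Gamma") {
      disp <- stats::sigma(fit)^2
      trigamma(1 / disp)
    } else stats::sigma(fit)^2
  } else stats::sigma(fit)^2
}

#' Polynomial model-comparison ladder
#'
#' Fits the random-effects-only null, the linear and the quadratic
#' (orthogonal polynomial) blur-grade models and reports the two
#' likelihood-ratio comparisons the procedure rests on: quadratic vs null
#' (the headline model test) and quadratic vs linear (guarding against a
#' purely linear trend masquerading as a quadratic one). The quadratic
#' effect is declared only when both pass `alpha`.
#'
#' @param data long table with the response, `blur_grade` and the
#'   grouping columns named by `random`.
#' @param response response column name.
#' @param family `"gaussian"`, `"poisson"` or `"gamma_log"`.
#' @param random random-effects part as a string, e.g.
#'   `"(1 | dyad_id / participant_id)"`; `NULL` selects it via
#'   [build_random_effects()].
#' @param alpha significance level applied to both comparisons.
#' @return object of class `ladder_result`: `chi_square`, `df`, `p`
#'   (quadratic vs null), `quad_vs_linear` (list), `significant`
#'   (both comparisons below `alpha`), `coefficients` (fixed-effect table
#'   of the quadratic model), `r2c`, `delta_r2c`, `r2lr`, `converged`,
#'   `singular`, `fits`.
#' @export
ladder_test <- function(data, response, family = "gaussian",
                        random = NULL, alpha = 0.05) {
  if (is.null(random))
    random <- build_random_effects(data, response, family)$formula
  data$blur_grade <- as.numeric(data$blur_grade)
  forms <- list(
    null = paste(response, "~ 1 +", random),
    linear = paste(response, "~ poly(blur_grade, 1) +", random),
    quad = paste(response, "~ poly(blur_grade, 2) +", random))
  fits <- lapply(forms, function(f)
    tryCatch(fit_mixed(f, data, family), error = function(e) NULL))
  conv <- !vapply(fits, is.null, logical(1))
  if (!all(conv)) {
    return(structure(list(chi_square = NA_real_, df = NA_integer_,
                          p = NA_real_, quad_vs_linear = NULL,
                          significant = NA, coefficients = NULL,
                          r2c = NA_real_, delta_r2c = NA_real_,
                          r2lr = NA_real_, converged = FALSE,
                          singular = NA, fits = fits, alpha = alpha),
                     class = "ladder_result"))
  }
  main <- lrt(fits$null, fits$quad)
  qvl <- lrt(fits$linear, fits$quad)
  r2 <- pseudo_r2(fits$quad, fits$null)
  cf <- coef(summary(fits$quad))
  structure(list(chi_square = main$chi_square, df = main$df, p = main$p,
                 quad_vs_linear = qvl,
                 significant = main$p < alpha && qvl$p < alpha,
                 coefficients = cf, r2c = r2$r2c,
                 delta_r2c = r2$delta_r2c, r2lr = r2$r2lr,
                 converged = TRUE, singular = is_singular(fits$quad),
                 fits = fits, alpha = alpha),
            class = "ladder_result")
}

#' @export
print.ladder_result <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<ladder_result: model did not converge>\n")
    return(invisible(x))
  }
  cat(sprintf("Quadratic vs null:   chi2(%d) = %.3f, p = %.4g\n",
              x$df, x$chi_square, x$p))
  cat(sprintf("Quadratic vs linear: chi2(%d) = %.3f, p = %.4g\n",
              x$quad_vs_linear$df, x$quad_vs_linear$chi_square,
              x$quad_vs_linear$p))
  cat(sprintf("R2C = %.3f, dR2C = %.3f, R2LR = %.3f%s\n", x$r2c,
              x$delta_r2c, x$r2lr,
              if (isTRUE(x$singular)) " (singular fit)" else ""))
  cat(if (isTRUE(x$significant)) "Quadratic effect supported\n"
      else "No quadratic effect\n")
  invisible(x)
}

#' Modality main-effect and interaction ladder for speech acoustics
#'
#' Sequential likelihood-ratio tests on per-grade, per-modality acoustic
#' means: (1) a speech-with-gesture vs speech-only main effect, (2) the
#' blur-grade polynomial on top of modality, (3) the blur x modality
#' interaction. The modality coefficient reported is the
#' speech-with-gesture minus speech-only fixed effect from the main-effect
#' model, i.e. the adjusted mean difference.
#'
#' @param acoustic_table output of [acoustics_by_grade()] (stacked over
#'   participants), containing `blur_grade`, `modality`, `dyad_id`,
#'   `participant_id` and the response column.
#' @param response response column, e.g. `"mean_intensity_db"`.
#' @param alpha significance level per step.
#' @return object of class `modality_ladder`: `steps` (named list of LRT
#'   results), `modality_coef`, `modality_se`, `coefficients` (final
#'   model), `significant` (per step), `fits`.
#' @export
modality_interaction_ladder <- function(acoustic_table, response,
                                        alpha = 0.05) {
  d <- acoustic_table[is.finite(acoustic_table[[response]]), ]
  d$modality <- factor(d$modality,
                       levels = c("speech_only", "speech_with_gesture"))
  d$blur_grade <- as.numeric(d$blur_grade)
  re <- "(1 | dyad_id / participant_id)"
  f0 <- paste(response, "~ 1 +", re)
  f1 <- paste(response, "~ modality +", re)
  f2 <- paste(response, "~ modality + poly(blur_grade, 2) +", re)
  f3 <- paste(response,
              "~ modality * poly(blur_grade, 2) +", re)
  fits <- lapply(list(f0, f1, f2, f3), function(f)
    fit_mixed(f, d, "gaussian"))
  names(fits) <- c("null", "modality", "blur", "interaction")
  steps <- list(modality = lrt(fits$null, fits$modality),
                blur = lrt(fits$modality, fits$blur),
                interaction = lrt(fits$blur, fits$interaction))
  cf1 <- coef(summary(fits$modality))
  structure(list(steps = steps,
                 modality_coef = cf1["modalityspeech_with_gesture",
                                     "Estimate"],
                 modality_se = cf1["modalityspeech_with_gesture",
                                   "Std. Error"],
                 coefficients = coef(summary(fits$interaction)),
                 significant = vapply(steps, function(s) s$p < alpha,
                                      logical(1)),
                 fits = fits, alpha = alpha),
            class = "modality_ladder")
}

#' @export
print.modality_ladder <- function(x, ...) {
  for (nm in names(x$steps)) {
    s <- x$steps[[nm]]
    cat(sprintf("%-12s chi2(%d) = %.3f, p = %.4g%s\n", nm, s$df,
                s$chi_square, s$p,
                if (s$p < x$alpha) " *" else ""))
  }
  cat(sprintf("Modality effect (with-gesture - speech-only): %.3f +/- %.3f\n",
              x$modality_coef, x$modality_se))
  invisible(x)
}

#' Kinetic-confound test for speech acoustics
#'
#' Tests whether a kinetic covariate (gesture peak velocity, or head /
#' hand / torso motion energy) explains the blur-grade effect on speech
#' acoustics: likelihood-ratio test of the blur-only model against the
#' model additionally containing the covariate. A significant result
#' means biomechanical coupling cannot be excluded.
#'
#' @param acoustic_table table with the response, `blur_grade`,
#'   `dyad_id`, `participant_id` and the covariate column.
#' @param response response column name.
#' @param covariate kinetic covariate column name.
#' @param alpha significance level.
#' @return list: `chi_square`, `df`, `p`, `significant`, `coef`
#'   (covariate estimate and SE).
#' @export
kinetic_confound_test <- function(acoustic_table, response, covariate,
                                  alpha = 0.05) {
  d <- acoustic_table[is.finite(acoustic_table[[response]]), ]
  if (length(unique(d[[covariate]])) < 2)
    stop("degenerate covariate: '", covariate, "' is constant")
  d$blur_grade <- as.numeric(d$blur_grade)
  re <- "(1 | dyad_id / participant_id)"
  m0 <- fit_mixed(paste(response, "~ poly(blur_grade, 2) +", re), d,
                  "gaussian")
  m1 <- fit_mixed(paste(response, "~ poly(blur_grade, 2) +", covariate,
                        "+", re), d, "gaussian")
  cmp <- lrt(m0, m1)
  cf <- coef(summary(m1))
  list(chi_square = cmp$chi_square, df = cmp$df, p = cmp$p,
       significant = cmp$p < alpha,
       coef = cf[covariate, c("Estimate", "Std. Error")])
}

#' Correlation-adjusted Bonferroni alpha
#'
#' Bonferroni-type correction that accounts for the mean pairwise
#' correlation among the family's outcome measures:
#' `alpha_adj = alpha / k^(1 - r_bar)`. With `k = 1` or perfectly
#' correlated outcomes (`r_bar = 1`) the nominal alpha is returned; for
#' independent outcomes it reduces to the plain Bonferroni level.
#'
#' @param k number of tests in the family (>= 1).
#' @param r_bar mean pairwise correlation among the outcomes, in
#'   `[0, 1]`.
#' @param alpha nominal level (default 0.05).
#' @param digits decimals for reporting (default 3); `NULL` for the
#'   unrounded value.
#' @return adjusted alpha.
#' @export
adjusted_alpha <- function(k, r_bar, alpha = 0.05, digits = 3) {
  if (k < 1 || k != round(k)) stop("k must be a positive integer")
  if (r_bar < 0 || r_bar > 1) stop("r_bar must be in [0, 1]")
  a <- alpha / k^(1 - r_bar)
  if (!is.null(digits)) round(a, digits) else a
}
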