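#' Fit a linear mixed-effects model (maximum likelihood)
#'
#' Thin wrapper around [lme4::lmer()] with `REML = FALSE` (maximum
#' likelihood, so nested models are comparable by likelihood ratio).
#' Fixed-effect tests are conditional t-tests with residual degrees of
#' freedom (`n_obs - rank(X)`); the df method is recorded in the fit
#' metadata. Singular fits (a variance component estimated at zero) are
#' flagged, not fatal. If a categorical fixed effect has a single level it
#' is dropped with a warning.
#'
#' @param data a data.frame containing the response, covariates and the
#'   grouping column.
#' @param response name of the response column.
#' @param fixed character vector of fixed-effect terms (e.g.
#'   `c("time_index", "video_type")`); may be empty for a zero model.
#' @param random one of `"intercept"`, `"slope_uncorrelated"`,
#'   `"slope_correlated"`.
#' @param group name of the grouping (participant) column.
#' @param time_var name of the time covariate used in random slopes.
#' @return An object of class `icuvr_lmem`: list with `model` (the merMod),
#'   `beta` (estimate, se, t, df, p per fixed effect), `varcor`,
#'   `residual_sd`, `loglik`, `n_obs`, `r2` (Nakagawa pair), `singular`,
#'   `df_method`, `formula`.
#' @examples
#' d <- study_design(n_participants = 8)
#' v <- simulate_vitals(d, ages = rep(50, 8), seed = 1)
#' f <- fit_lmem(v, "map", fixed = "time_index")
#' f$beta
#' @export
fit_lmem <- function(data, response, fixed = c("time_index", "video_type"),
                     random = c("intercept", "slope_uncorrelated",
                                "slope_correlated"),
                     group = "participant_id", time_var = "time_index") {
  random <- match.arg(random)
  if (!response %in% names(data))
    stop(sprintf("response '%s' not found in data", response), call. = FALSE)
  if (length(unique(data[[group]])) < 2)
    stop("need at least 2 participants", call. = FALSE)
  data <- data[stats::complete.cases(data[c(response, fixed, group)]), ,
               drop = FALSE]
  keep <- vapply(fixed, function(f) {
    v <- data[[f]]
    ok <- length(unique(v)) > 1
    if (!ok) warning(sprintf("fixed effect '%s' is constant; dropped", f),
                     call. = FALSE)
    ok
  }, TRUE)
  fixed <- fixed[keep]
  fe <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  re <- switch(random,
               intercept = sprintf("(1 | %s)", group),
               slope_uncorrelated = sprintf("(1 | %s) + (0 + %s | %s)",
                                            group, time_var, group),
               slope_correlated = sprintf("(1 + %s | %s)", time_var, group))
  fml <- as.formula(paste(response, "~", fe, "+", re))
  model <- lme4::lmer(fml, data = data, REML = FALSE,
                      control = lme4::lmerControl(
                        optimizer = "bobyqa",
                        check.conv.singular =
                          lme4::.makeCC(action = "ignore", tol = 1e-4)))
  est <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  n_obs <- stats::nobs(model)
  df <- n_obs - length(est)
  tval <- est / se
  beta <- data.frame(term = names(est), estimate = unname(est),
                     se = unname(se), t = unname(tval), df = df,
                     p = unname(2 * pt(-abs(tval), df)))
  fit <- structure(list(model = model, beta = beta,
                        varcor = lme4::VarCorr(model),
                        residual_sd = stats::sigma(model),
                        loglik = as.numeric(logLik(model)),
                        n_obs = n_obs,
                        singular = lme4::isSingular(model),
                        df_method = "residual",
                        formula = fml, response = response,
                        random = random),
                   class = "icuvr_lmem")
  fit$r2 <- nakagawa_r2(fit)
  fit
}

#' @export
print.icuvr_lmem <- function(x, ...) {
  cat(sprintf("LMEM (ML): %s   [random: %s%s]\n",
              deparse(x$formula), x$random,
              if (x$singular) ", singular fit" else ""))
  print(x$beta, row.names = FALSE, digits = 4)
  cat(sprintf("logLik %.2f | n %d | R2 marginal %.4f conditional %.4f\n",
              x$loglik, x$n_obs, x$r2["marginal"], x$r2["conditional"]))
  invisible(x)
}

#' Nakagawa marginal and conditional R-squared
#'
#' Variance-decomposition effect sizes for a mixed model: the marginal R2
#' is the variance of the fixed-effect predictions over the total variance
#' (fixed + summed random-effect variances + residual); the conditional R2
#' additionally credits the random effects. Random-slope terms contribute
#' their mean observation-level variance `mean_i(z_i' Sigma z_i)`.
#'
#' @param fit an `icuvr_lmem` object or a fitted `merMod`.
#' @return Named numeric `c(marginal =, conditional =)`; `NA` (with a
#'   warning) when the total variance is zero.
#' @export
nakagawa_r2 <- function(fit) {
  model <- if (inherits(fit, "icuvr_lmem")) fit$model else fit
  X <- lme4::getME(model, "X")
  var_f <- as.numeric(var(as.vector(X %*% lme4::fixef(model))))
  if (ncol(X) == 1 && all(X == X[1])) var_f <- 0  # intercept-only: exact zero
  vc <- lme4::VarCorr(model)
  mm <- lme4::getME(model, "mmList")
  var_r <- 0
  for (k in seq_along(mm)) {
    Z <- mm[[k]]
    S <- as.matrix(Matrix::bdiag(vc[[k]]))
    var_r <- var_r + mean(rowSums((Z %*% S) * Z))
  }
  var_e <- stats::sigma(model)^2
  tot <- var_f + var_r + var_e
  if (tot <= 0) {
    warning("total variance is zero; R2 undefined", call. = FALSE)
    return(c(marginal = NA_real_, conditional = NA_real_))
  }
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

#' Random-effects model ladder for a vital sign
#'
#' Fits the three-rung ladder — model 1: random participant intercept;
#' model 2: plus an uncorrelated random time slope; model 3: intercepts
#' and slopes correlated — all by maximum likelihood with the same fixed
#' effects, and keeps each extension only when its likelihood-ratio test
#' against the previous rung is significant at `alpha`. The ladder stops
#' at model 1 when the slope variance is not supported. The naive
#' chi-squared reference is used for these boundary tests (conservative
#' for variance components). Non-convergence at a rung falls back to the
#' last converged rung with a message.
#'
#' @param data analysis table (e.g. from [to_analysis_grid()] or
#'   [simulate_vitals()]).
#' @param response signal column name.
#' @param fixed fixed-effect terms.
#' @param alpha significance level for the likelihood-ratio tests.
#' @inheritParams fit_lmem
#' @return A list of class `icuvr_ladder`: `chosen` (`icuvr_lmem`),
#'   `chosen_model` (1, 2 or 3), and `ladder` (per rung: loglik, LRT
#'   statistic, df, p, kept).
#' @export
select_vitals_model <- function(data, response,
                                fixed = c("time_index", "video_type"),
                                alpha = 0.05, group = "participant_id",
                                time_var = "time_index") {
  rungs <- c("intercept", "slope_uncorrelated", "slope_correlated")
  fits <- list()
  for (k in 1:3) {
    fits[[k]] <- tryCatch(
      fit_lmem(data, response, fixed, random = rungs[k], group = group,
               time_var = time_var),
      error = function(e) {
        message(sprintf("model %d (%s) failed to converge: %s", k, rungs[k],
                        conditionMessage(e)))
        NULL
      })
  }
  ll <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$loglik,
               0)
  lrt_stat <- c(NA, 2 * (ll[2] - ll[1]), 2 * (ll[3] - ll[2]))
  lrt_df <- c(NA, 1, 1)
  lrt_p <- c(NA, stats::pchisq(lrt_stat[2], 1, lower.tail = FALSE),
             stats::pchisq(lrt_stat[3], 1, lower.tail = FALSE))
  chosen <- 1L
  kept <- c(TRUE, FALSE, FALSE)
  if (!is.null(fits[[2]]) && is.finite(lrt_p[2]) && lrt_p[2] < alpha) {
    chosen <- 2L; kept[2] <- TRUE
    if (!is.null(fits[[3]]) && is.finite(lrt_p[3]) && lrt_p[3] < alpha) {
      chosen <- 3L; kept[3] <- TRUE
    }
  }
  ladder <- data.frame(model = 1:3, random = rungs, loglik = ll,
                       lrt_stat = lrt_stat, lrt_df = lrt_df, lrt_p = lrt_p,
                       kept = kept)
  structure(list(chosen = fits[[chosen]], chosen_model = chosen,
                 ladder = ladder, response = response),
            class = "icuvr_ladder")
}

#' @export
print.icuvr_ladder <- function(x, ...) {
  cat(sprintf("Model ladder for '%s': chose model %d\n", x$response,
              x$chosen_model))
  print(x$ladder, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Add questionnaire-rating fixed effects with Holm adjustment
#'
#' Adds each per-participant rating scale, one at a time, as a fixed
#' effect to a chosen vitals model, collects the conditional t-test
#' p-value of the scale coefficient, and Holm-adjusts the p-values across
#' scales. Constant rating columns are excluded with a warning.
#'
#' @param selection an `icuvr_ladder` (or `icuvr_lmem`) for the chosen
#'   model.
#' @param ratings data.frame `participant_id` plus one column per scale
#'   (one score per participant).
#' @param data the analysis table the model was fitted on.
#' @return A data.frame `scale, estimate, se, t, df, p, p_holm`.
#' @export
add_rating_effects <- function(selection, ratings, data) {
  fit <- if (inherits(selection, "icuvr_ladder")) selection$chosen
         else selection
  scales <- setdiff(names(ratings), "participant_id")
  const <- vapply(scales, function(s)
    length(unique(ratings[[s]])) < 2, TRUE)
  if (any(const))
    warning(sprintf("constant rating column(s) excluded: %s",
                    paste(scales[const], collapse = ", ")), call. = FALSE)
  scales <- scales[!const]
  # recover the fixed terms from the fitted formula (factor terms keep
  # their original names there)
  fe_terms <- attr(stats::terms(lme4::nobars(fit$formula)), "term.labels")
  rows <- lapply(scales, function(s) {
    d <- merge(data, ratings[c("participant_id", s)], by = "participant_id")
    f <- fit_lmem(d, fit$response, fixed = c(fe_terms, s),
                  random = fit$random)
    b <- f$beta[f$beta$term == s, , drop = FALSE]
    data.frame(scale = s, estimate = b$estimate, se = b$se, t = b$t,
               df = b$df, p = b$p)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- p.adjust(out$p, method = "holm")
  out
}

#' Eight-model suite for a windowed oculomotor feature
#'
#' Fits, by maximum likelihood with a random participant intercept, the
#' eight fixed-effect configurations used to size effects on windowed
#' oculomotor features: a zero model (no fixed effects), a full model
#' (time + target + video type), one single-predictor model per fixed
#' effect, and the three leave-one-out models. Effect sizes are Nakagawa
#' marginal/conditional R2; the increase in explained variance credited to
#' a predictor is `delta_R2m = R2m(full) - R2m(full without it)`.
#'
#' @param features feature table with columns `participant_id`,
#'   the response, and the three predictors.
#' @param response feature column name (e.g. `"fix_sacc_ratio"`).
#' @param time_var,target_var,video_var predictor column names.
#' @return A list of class `icuvr_suite`: `models` (per model: name, fixed
#'   effects, loglik, R2m, R2c), `delta_r2` (per predictor), `fits` (the
#'   eight `icuvr_lmem` objects).
#' @export
oculomotor_model_suite <- function(features, response,
                                   time_var = "time_global",
                                   target_var = "target",
                                   video_var = "video_type") {
  specs <- list(
    zero = character(0),
    full = c(time_var, target_var, video_var),
    time = time_var,
    target = target_var,
    video = video_var,
    full_minus_time = c(target_var, video_var),
    full_minus_target = c(time_var, video_var),
    full_minus_video = c(time_var, target_var))
  fits <- lapply(specs, function(fx)
    fit_lmem(features, response, fixed = fx, random = "intercept",
             time_var = time_var))
  models <- data.frame(
    model = names(specs),
    fixed_effects = vapply(specs, function(s)
      if (length(s)) paste(s, collapse = " + ") else "(none)", ""),
    loglik = vapply(fits, function(f) f$loglik, 0),
    R2m = vapply(fits, function(f) unname(f$r2["marginal"]), 0),
    R2c = vapply(fits, function(f) unname(f$r2["conditional"]), 0))
  delta <- data.frame(
    term = c("time", "target", "video"),
    delta_R2m = models$R2m[models$model == "full"] -
      models$R2m[match(c("full_minus_time", "full_minus_target",
                         "full_minus_video"), models$model)])
  structure(list(models = models, delta_r2 = delta, fits = fits,
                 response = response),
            class = "icuvr_suite")
}

#' @export
print.icuvr_suite <- function(x, ...) {
  cat(sprintf("Oculomotor LMEM suite for '%s'\n", x$response))
  print(x$models, row.names = FALSE, digits = 4)
  cat("Increase in explained variance (delta marginal R2):\n")
  print(x$delta_r2, row.names = FALSE, digits = 4)
  invisible(x)
}
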