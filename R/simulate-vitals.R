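#' Ground-truth parameters for synthetic vital-sign series
#'
#' Per-signal linear mixed-effects structure: for participant i at
#' measurement index k,
#' `value = baseline + b0_i + (beta_time + b1_i + beta_age_time * (age_i -
#' mean(age))) * k + noise`, with `(b0_i, b1_i)` bivariate normal with the
#' stated SDs and correlation. A negative intercept-slope correlation makes
#' the downward time trend steeper for participants with higher baselines.
#' SpO2 has a zero time slope by default (it is expected to stay constant)
#' and is clipped to `[0, 100]`. The within-participant noise SDs are plain
#' configuration values chosen to look like two-minute-median vital signs;
#' nothing pins them down externally.
#'
#' @param baseline named per-signal means (`hf` beats/min, `map` mmHg, `rf`
#'   breaths/min, `spo2` %).
#' @param beta_time fixed time slope per measurement index.
#' @param beta_age_time age x time interaction (per year, age mean-centred).
#' @param intercept_sd,slope_sd random-effect SDs per participant.
#' @param intercept_slope_corr correlation between random intercepts and
#'   slopes, in `[-1, 1]`.
#' @param residual_sd within-participant noise SD.
#' @return A validated list of class `icuvr_vital_truth`.
#' @export
vital_truth_params <- function(
    baseline = c(hf = 68, map = 87, rf = 21, spo2 = 97),
    beta_time = c(hf = -0.25, map = -0.3, rf = -0.2, spo2 = 0),
    beta_age_time = c(hf = 0, map = -0.01, rf = 0, spo2 = 0),
    intercept_sd = c(hf = 12, map = 12, rf = 4, spo2 = 1.5),
    slope_sd = c(hf = 0.3, map = 0.25, rf = 0.15, spo2 = 0),
    intercept_slope_corr = c(hf = -0.4, map = -0.4, rf = -0.4, spo2 = 0),
    residual_sd = c(hf = 2, map = 3, rf = 1.5, spo2 = 0.5)) {
  sig <- c("hf", "map", "rf", "spo2")
  for (nm in c("baseline", "beta_time", "beta_age_time", "intercept_sd",
               "slope_sd", "intercept_slope_corr", "residual_sd")) {
    v <- get(nm)
    if (!all(sig %in% names(v)))
      stop(sprintf("'%s' needs named entries %s", nm,
                   paste(sig, collapse = ", ")), call. = FALSE)
  }
  if (any(intercept_sd < 0) || any(slope_sd < 0) || any(residual_sd < 0))
    stop("random-effect and residual SDs must be non-negative",
         call. = FALSE)
  if (any(abs(intercept_slope_corr) > 1))
    stop("'intercept_slope_corr' must lie in [-1, 1]", call. = FALSE)
  structure(list(baseline = baseline, beta_time = beta_time,
                 beta_age_time = beta_age_time, intercept_sd = intercept_sd,
                 slope_sd = slope_sd,
                 intercept_slope_corr = intercept_slope_corr,
                 residual_sd = residual_sd),
            class = "icuvr_vital_truth")
}

#' Simulate vital-sign records
#'
#' Emits one record per participant per `vital_interval` seconds of
#' stimulation (the two-minute-median grid), with values following the
#' mixed-effects structure in [vital_truth_params()]. With
#' `raw_interval_s` set, a dense raw stream is emitted instead, whose
#' samples scatter around the interval value so that downstream
#' [two_minute_medians()] recovers it.
#'
#' @param design an [study_design()] object.
#' @param truth a [vital_truth_params()] object.
#' @param ages numeric vector of participant ages (years), length
#'   `n_participants`.
#' @param raw_interval_s if non-`NULL`, spacing of raw samples in seconds.
#' @param raw_noise_sd extra SD of raw samples around the interval value.
#' @param seed integer seed.
#' @return A data.frame `participant_id, t, time_index, hf, map, rf, spo2`
#'   with attribute `"random_effects"` (per-participant, per-signal drawn
#'   intercepts and slopes).
#' @examples
#' d <- study_design(n_participants = 3)
#' v <- simulate_vitals(d, ages = c(30, 50, 70), seed = 2)
#' head(v)
#' @export
simulate_vitals <- function(design, truth = vital_truth_params(), ages,
                            raw_interval_s = NULL, raw_noise_sd = 1,
                            seed = design$seed) {
  stopifnot(inherits(design, "icuvr_design"))
  stopifnot(inherits(truth, "icuvr_vital_truth"))
  if (length(ages) != design$n_participants)
    stop("'ages' must have one entry per participant", call. = FALSE)
  set.seed(as.integer(seed))
  total <- design$n_videos * design$video_duration
  n_idx <- floor(total / design$vital_interval)
  sig <- c("hf", "map", "rf", "spo2")
  np <- design$n_participants
  agec <- ages - mean(ages)

  re <- list()
  for (s in sig) {
    rho <- truth$intercept_slope_corr[[s]]
    b0 <- rnorm(np, 0, truth$intercept_sd[[s]])
    z <- rnorm(np)
    if (truth$intercept_sd[[s]] > 0) {
      b1 <- truth$slope_sd[[s]] *
        (rho * b0 / truth$intercept_sd[[s]] + sqrt(1 - rho^2) * z)
    } else b1 <- truth$slope_sd[[s]] * z
    re[[s]] <- cbind(intercept = b0, slope = b1)
  }

  rows <- expand.grid(time_index = seq_len(n_idx), participant_id = seq_len(np))
  rows <- rows[, c("participant_id", "time_index")]
  rows$t <- rows$time_index * design$vital_interval
  for (s in sig) {
    b <- re[[s]]
    mu <- truth$baseline[[s]] + b[rows$participant_id, "intercept"] +
      (truth$beta_time[[s]] + b[rows$participant_id, "slope"] +
         truth$beta_age_time[[s]] * agec[rows$participant_id]) *
      rows$time_index
    rows[[s]] <- mu + rnorm(nrow(rows), 0, truth$residual_sd[[s]])
  }
  rows$spo2 <- clip(rows$spo2, 0, 100)

  if (!is.null(raw_interval_s)) {
    raw_t <- seq(raw_interval_s, total, by = raw_interval_s)
    raw_idx <- pmin(ceiling(raw_t / design$vital_interval), n_idx)
    raw <- expand.grid(t = raw_t, participant_id = seq_len(np))
    raw$time_index <- raw_idx[match(raw$t, raw_t)]
    key <- paste(rows$participant_id, rows$time_index)
    for (s in sig) {
      base <- rows[[s]][match(paste(raw$participant_id, raw$time_index), key)]
      raw[[s]] <- base + rnorm(nrow(raw), 0, raw_noise_sd)
    }
    raw$spo2 <- clip(raw$spo2, 0, 100)
    raw <- raw[, c("participant_id", "t", "time_index", sig)]
    attr(raw, "random_effects") <- re
    return(raw)
  }
  out <- rows[, c("participant_id", "t", "time_index", sig)]
  attr(out, "random_effects") <- re
  out
}
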