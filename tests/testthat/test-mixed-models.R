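sim_grouped <- function(n_g, m, beta, sd_b0, sd_e, seed,
                        sd_b1 = 0, corr = 0) {
  set.seed(seed)
  d <- expand.grid(obs = seq_len(m), participant_id = seq_len(n_g))
  d$time_index <- d$obs
  b0 <- rnorm(n_g, 0, sd_b0)
  b1 <- if (sd_b0 > 0)
    sd_b1 * (corr * b0 / sd_b0 + sqrt(1 - corr^2) * rnorm(n_g))
  else rnorm(n_g, 0, sd_b1)
  d$y <- 50 + (beta + b1[d$participant_id]) * d$time_index +
    b0[d$participant_id] + rnorm(nrow(d), 0, sd_e)
  d
}

test_that("ML fits recover a known fixed slope within 3 SE", {
  d <- sim_grouped(100, 9, beta = -0.5, sd_b0 = 5, sd_e = 1.5, seed = 1)
  f <- fit_lmem(d, "y", fixed = "time_index")
  b <- f$beta[f$beta$term == "time_index", ]
  expect_lt(abs(b$estimate - (-0.5)), 3 * b$se)
  expect_equal(f$df_method, "residual")
  expect_equal(b$df, f$n_obs - 2)
})

test_that("fixed effects match an independent mixed-model implementation", {
  skip_if_not_installed("nlme")
  d <- sim_grouped(30, 6, beta = -0.3, sd_b0 = 3, sd_e = 1, seed = 4)
  f <- fit_lmem(d, "y", fixed = "time_index")
  g <- nlme::lme(y ~ time_index, random = ~ 1 | participant_id, data = d,
                 method = "ML")
  expect_equal(f$beta$estimate, unname(nlme::fixef(g)), tolerance = 1e-4)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-4)
})

test_that("null slopes are declared nonsignificant at close to nominal rate", {
  hits <- 0
  for (k in 1:40) {
    d <- sim_grouped(20, 6, beta = 0, sd_b0 = 3, sd_e = 2, seed = 100 + k)
    f <- fit_lmem(d, "y", fixed = "time_index")
    p <- f$beta$p[f$beta$term == "time_index"]
    hits <- hits + (p < 0.05)
  }
  expect_lte(hits, 40 * 0.05 + 4)  # <= ~15% of 40 replicates
})

test_that("the model ladder keeps extensions only when the data support them", {
  # no slope variance -> model 1
  d0 <- sim_grouped(40, 7, beta = -0.3, sd_b0 = 6, sd_e = 1.5, seed = 11)
  s0 <- select_vitals_model(d0, "y", fixed = "time_index")
  expect_equal(s0$chosen_model, 1L)
  expect_true(all(diff(s0$ladder$loglik) >= -1e-6))  # nesting monotonicity

  # strong slope variance, no correlation -> model 2
  d2 <- sim_grouped(60, 7, beta = -0.5, sd_b0 = 6, sd_e = 1, seed = 12,
                    sd_b1 = 0.8)
  s2 <- select_vitals_model(d2, "y", fixed = "time_index")
  expect_equal(s2$chosen_model, 2L)

  # strong negative intercept-slope correlation at large n -> model 3,
  # with a negative estimated correlation
  d3 <- sim_grouped(200, 9, beta = -0.5, sd_b0 = 8, sd_e = 1, seed = 13,
                    sd_b1 = 0.8, corr = -0.8)
  s3 <- select_vitals_model(d3, "y", fixed = "time_index")
  expect_equal(s3$chosen_model, 3L)
  vc <- lme4::VarCorr(s3$chosen$model)$participant_id
  expect_lt(attr(vc, "correlation")[1, 2], 0)
})

test_that("degenerate slope variance is recovered near zero under model 2", {
  d <- sim_grouped(40, 7, beta = -0.3, sd_b0 = 5, sd_e = 1, seed = 21)
  f2 <- fit_lmem(d, "y", fixed = "time_index", random = "slope_uncorrelated")
  vc <- lme4::VarCorr(f2$model)
  slope_sd <- sqrt(unlist(lapply(vc, function(m) diag(m)))[["participant_id.1.time_index"]])
  expect_lt(slope_sd, 0.1)
})

test_that("a single-level categorical fixed effect is dropped with a warning", {
  d <- sim_grouped(10, 6, beta = -0.3, sd_b0 = 2, sd_e = 1, seed = 31)
  d$video_type <- factor("v1")
  expect_warning(f <- fit_lmem(d, "y", fixed = c("time_index", "video_type")),
                 "video_type")
  expect_false(any(grepl("video_type", f$beta$term)))
})

test_that("Nakagawa R2 matches constructed variance partitions", {
  # fixed 2.0 / random 1.0 / residual 1.0 -> (0.50, 0.75)
  set.seed(5)
  ng <- 150; m <- 40
  d <- data.frame(participant_id = rep(seq_len(ng), each = m),
                  x = rnorm(ng * m))
  b0 <- rnorm(ng, 0, 1)
  d$y <- sqrt(2) * d$x + b0[d$participant_id] + rnorm(ng * m)
  f <- fit_lmem(d, "y", fixed = "x", time_var = "x")
  expect_equal(unname(f$r2["marginal"]), 0.50, tolerance = 0.05)
  expect_equal(unname(f$r2["conditional"]), 0.75, tolerance = 0.05)

  # no fixed effects -> marginal exactly zero
  f0 <- fit_lmem(d, "y", fixed = character(0), time_var = "x")
  expect_identical(unname(f0$r2["marginal"]), 0)

  # zero random variance -> marginal equals conditional
  d2 <- data.frame(participant_id = rep(1:20, each = 20), x = rnorm(400))
  d2$y <- d2$x + rnorm(400)
  f2 <- fit_lmem(d2, "y", fixed = "x", time_var = "x")
  expect_equal(unname(f2$r2["marginal"]), unname(f2$r2["conditional"]),
               tolerance = 0.02)
})

test_that("R2 ordering invariant holds across the eight-model suite", {
  d <- study_design(n_participants = 3, n_videos = 2, video_duration = 60,
                    seed = 6)
  gs <- simulate_gaze_study(d, seed = 6)
  ft <- extract_gaze_features(gs$samples, window_s = 20, step_s = 1)
  ft$time_global <- (ft$video - 1) * 60 + ft$t
  ft$video_type <- factor(ft$video)
  suite <- oculomotor_model_suite(ft, "fix_dur_ms_per_s")
  expect_equal(nrow(suite$models), 8)
  expect_setequal(suite$models$model,
                  c("zero", "full", "time", "target", "video",
                    "full_minus_time", "full_minus_target",
                    "full_minus_video"))
  expect_true(all(suite$models$R2m >= -1e-12))
  expect_true(all(suite$models$R2c <= 1 + 1e-12))
  expect_true(all(suite$models$R2c >= suite$models$R2m - 1e-12))
  expect_identical(suite$models$R2m[suite$models$model == "zero"], 0)
  expect_equal(nrow(suite$delta_r2), 3)
})

test_that("Holm adjustment follows the step-down definition", {
  # raw (0.01, 0.04), m = 2 -> adjusted (0.02, 0.04)
  expect_equal(p.adjust(c(0.01, 0.04), method = "holm"), c(0.02, 0.04))
  d <- sim_grouped(25, 6, beta = -0.3, sd_b0 = 3, sd_e = 1, seed = 41)
  sel <- select_vitals_model(d, "y", fixed = "time_index")
  set.seed(42)
  ratings <- data.frame(participant_id = 1:25,
                        usability = runif(25, 3, 5),
                        sickness = runif(25, 1, 2),
                        presence = runif(25, 2, 4))
  eff <- add_rating_effects(sel, ratings, d)
  expect_equal(nrow(eff), 3)
  expect_true(all(eff$p_holm >= eff$p - 1e-12))
  expect_equal(order(eff$p), order(eff$p_holm))
  # single scale: adjusted = raw
  eff1 <- add_rating_effects(sel, ratings[c("participant_id", "presence")],
                             d)
  expect_equal(eff1$p_holm, eff1$p)
  # constant column excluded with warning
  ratings$flat <- 3
  expect_warning(add_rating_effects(sel, ratings, d), "flat")
})

test_that("rating effects on independent vitals are rarely significant", {
  sig <- 0
  n_rep <- 20
  for (k in seq_len(n_rep)) {
    d <- sim_grouped(25, 6, beta = -0.2, sd_b0 = 3, sd_e = 1.5,
                     seed = 500 + k)
    sel <- select_vitals_model(d, "y", fixed = "time_index")
    set.seed(600 + k)
    ratings <- data.frame(participant_id = 1:25, r1 = rnorm(25),
                          r2 = rnorm(25))
    eff <- add_rating_effects(sel, ratings, d)
    sig <- sig + sum(eff$p_holm < 0.05)
  }
  expect_lte(sig / (2 * n_rep), 0.10)
})
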