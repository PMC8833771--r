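static_world <- function(n, seed) {
  cohort_config(
    n_patients = n, seed = seed,
    baseline_covariates = list(age = list(dist = "normal", mean = 0, sd = 1),
                               z = list(dist = "bernoulli", prob = 0.4)),
    markers = list(m = list(kind = "continuous", init_mean = 0, init_sd = 1,
                            drift = 0, noise_sd = 0)),
    effects = list(m = c(0.5)), theta = c(age = 0.3, z = -0.4),
    baseline_hazard_rate = 0.1, censoring_rate = 0.05, admin_censoring = 24,
    landmark_faithful = TRUE
  )
}

test_that("single landmark + constant basis reproduces the reference Cox fit", {
  co <- simulate_cohort(static_world(150, seed = 31))
  lm0 <- build_landmark_dataset(co, landmarks = 0)
  fit <- fit_dpm(lm0, robust = FALSE)
  X <- as.matrix(as.data.frame(lm0)[, c("m", "age", "z")])
  or <- oracle_coxph(start = rep(0, nrow(lm0)), stop = lm0$observed_time,
                     event = lm0$event_indicator, X = X)
  expect_equal(unname(fit$coef), unname(or$coef), tolerance = 1e-6)
  # model-based covariance agrees with the inverse information
  expect_equal(unname(fit$covariance), unname(or$vcov), tolerance = 1e-6)
  bh <- fit$baselines[["0"]]
  expect_equal(bh$time, or$baseline$time)
  expect_equal(bh$increment, or$baseline$increment, tolerance = 1e-8)
})

test_that("null data give no spurious effects (all |z| < 4)", {
  cfg <- cohort_config(
    n_patients = 2000, seed = 57,
    baseline_covariates = list(z = list(dist = "bernoulli", prob = 0.5)),
    markers = list(m = list(kind = "continuous", init_mean = 0, init_sd = 1,
                            drift = 0, noise_sd = 0.5)),
    effects = list(m = c(0)), theta = c(z = 0),
    baseline_hazard_rate = 0.08, censoring_rate = 0.02, admin_censoring = 36,
    landmark_faithful = TRUE
  )
  co <- simulate_cohort(cfg)
  lmd <- build_landmark_dataset(co, landmarks = 0:12)
  fit <- fit_dpm(lmd)
  zscores <- fit$coef / sqrt(diag(fit$covariance))
  expect_true(all(abs(zscores) < 4))
})

test_that("Breslow baseline closed forms and hand enumeration", {
  # one event at t1, all linear predictors 0, m at risk -> increment 1/m
  bh <- landmarkDPM:::breslow_cumhaz(start = rep(0, 5), stop = c(2, 3, 4, 5, 6),
                                     event = c(1, 0, 0, 0, 0), explp = rep(1, 5))
  expect_equal(bh$increment, 1 / 5)
  expect_equal(bh$time, 2)
  # no events -> H = 0 everywhere
  bh0 <- landmarkDPM:::breslow_cumhaz(start = rep(0, 3), stop = 1:3,
                                      event = rep(0, 3), explp = rep(1, 3))
  expect_equal(nrow(bh0), 0L)
  expect_equal(landmarkDPM:::eval_cumhaz(bh0, c(0, 10)), c(0, 0))
  # 5-row set with lp in {0, log 2}: hand-computed risk sums
  # times 1..5, events at 1, 3, 4; exp(lp) = (1, 2, 1, 2, 1)
  bh5 <- landmarkDPM:::breslow_cumhaz(start = rep(0, 5), stop = 1:5,
                                      event = c(1, 0, 1, 1, 0),
                                      explp = c(1, 2, 1, 2, 1))
  expect_equal(bh5$time, c(1, 3, 4))
  expect_equal(bh5$increment, c(1 / 7, 1 / 4, 1 / 3))
  expect_equal(bh5$cumhaz, cumsum(c(1 / 7, 1 / 4, 1 / 3)))
  # left truncation shrinks early risk sets: subject entering at 2 misses t = 1
  bh_lt <- landmarkDPM:::breslow_cumhaz(start = c(0, 0, 2), stop = c(1, 3, 4),
                                        event = c(1, 1, 1), explp = rep(1, 3))
  expect_equal(bh_lt$increment, c(1 / 2, 1 / 2, 1))
})

test_that("dynamic coefficient: constant basis is flat; zero alpha gives HR 1", {
  co <- simulate_cohort(static_world(200, seed = 5))
  lmd <- build_landmark_dataset(co, landmarks = 0:4)
  fit <- fit_dpm(lmd, basis = basis_spec(numeric(0), 1, include_constant = TRUE))
  dc <- dynamic_coefficient(fit, "m", c(0, 2, 4))
  expect_equal(dc$estimate, rep(dc$estimate[1], 3))
  expect_equal(dc$se, rep(dc$se[1], 3))
  # zeroed coefficients -> log-HR 0, HR 1 at every s
  fit0 <- fit
  fit0$alpha[] <- 0
  fit0$coef[] <- 0
  dc0 <- dynamic_coefficient(fit0, "m", c(0, 3))
  expect_equal(dc0$estimate, c(0, 0))
  expect_equal(dc0$hr, c(1, 1))
  expect_error(dynamic_coefficient(fit, "nope", 0), "nope")
  expect_warning(dynamic_coefficient(fit, "m", 99), "extrapolat")
})

test_that("Wald statistic is exactly zero when non-constant coefficients vanish", {
  co <- simulate_cohort(design_constant_effect(400, seed = 13))
  lmd <- build_landmark_dataset(co, landmarks = 0:6)
  fit <- fit_dpm(lmd)
  fit0 <- fit
  nc <- grep("\\.w\\d+$", names(fit0$coef))
  fit0$coef[nc] <- 0
  fit0$alpha[, -1] <- 0
  w <- wald_test_time_varying(fit0, "biomarker")
  expect_equal(unname(w$statistic), 0)
  expect_equal(w$p.value, 1)
  expect_equal(unname(w$parameter), fit$basis$k - 1)
  # constant-only basis cannot be tested
  fitc <- fit_dpm(lmd, basis = basis_spec(numeric(0), 1))
  expect_error(wald_test_time_varying(fitc, "biomarker"), "constant",
               class = "landmarkDPM_config_error")
})

test_that("predicted survival: boundary, zero-lp and monotonicity properties", {
  co <- simulate_cohort(static_world(300, seed = 23))
  lmd <- build_landmark_dataset(co, landmarks = 0:4)
  fit <- fit_dpm(lmd)
  rows <- lmd[lmd$landmark_s == 2, ][1:5, ]
  expect_equal(predict_survival(fit, rows, s = 2, horizon = 0), rep(1, 5))
  # zero linear predictor: survival is exp(-H)
  nd <- data.frame(m = 0, age = 0, z = 0)
  H <- landmarkDPM:::eval_cumhaz(fit$baselines[["2"]], 2 + 1.5)
  expect_equal(predict_survival(fit, nd, s = 2, horizon = 1.5), exp(-H))
  # nonincreasing in horizon, strictly decreasing across event times
  hs <- seq(0, 6, by = 0.25)
  p <- vapply(hs, function(h) predict_survival(fit, rows[1, ], 2, h), numeric(1))
  expect_true(all(diff(p) <= 0))
  ev <- fit$baselines[["2"]]$time
  p_lo <- predict_survival(fit, rows[1, ], 2, ev[1] - 2 - 1e-9)
  p_hi <- predict_survival(fit, rows[1, ], 2, ev[1] - 2 + 1e-9)
  expect_lt(p_hi, p_lo)
  expect_error(predict_survival(fit, data.frame(m = 1), 2, 1), "age",
               class = "landmarkDPM_data_error")
  expect_warning(predict_survival(fit, rows, s = 2.4, horizon = 1), "nearest")
})

test_that("predicted survival matches the exponential closed form", {
  # constant world: hazard h0 * exp(b * x); prediction at x = 0 is exp(-h0 * t)
  co <- simulate_cohort(design_constant_effect(5000, seed = 71))
  lmd <- build_landmark_dataset(co, landmarks = 0)
  fit <- fit_dpm(lmd)
  nd <- data.frame(biomarker = 0)
  p1 <- predict_survival(fit, nd, s = 0, horizon = 1)
  expect_equal(p1, exp(-0.08), tolerance = 0.02)
})

test_that("fitted trajectories and predictions are invariant to basis reparameterization", {
  co <- simulate_cohort(design_faithful_linear(500, seed = 37))
  lmd <- build_landmark_dataset(co, landmarks = 0:8)
  b1 <- basis_spec(nodes = c(0, 4, 8), support_radius = 8)
  set.seed(99)
  A <- diag(4) + matrix(rnorm(16, sd = 0.2), 4, 4)
  b2 <- basis_spec(nodes = c(0, 4, 8), support_radius = 8, transform = A)
  f1 <- fit_dpm(lmd, basis = b1)
  f2 <- fit_dpm(lmd, basis = b2)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  s <- c(0, 3, 6, 8)
  expect_equal(dynamic_coefficient(f1, "biomarker", s)$estimate,
               dynamic_coefficient(f2, "biomarker", s)$estimate,
               tolerance = 1e-6)
  rows <- lmd[lmd$landmark_s == 4, ][1:10, ]
  expect_equal(predict_survival(f1, rows, 4, 2), predict_survival(f2, rows, 4, 2),
               tolerance = 1e-6)
})

test_that("sandwich covariance approaches the model-based one for singleton clusters", {
  co <- simulate_cohort(static_world(1000, seed = 43))
  lm0 <- build_landmark_dataset(co, landmarks = 0)
  fr <- fit_dpm(lm0, robust = TRUE)
  fn <- fit_dpm(lm0, robust = FALSE)
  expect_equal(fr$coef, fn$coef, tolerance = 1e-10)
  rel <- norm(fr$covariance - fn$covariance, "F") / norm(fn$covariance, "F")
  expect_lt(rel, 0.25)
})

test_that("a finite window censors events beyond s + window within each stratum", {
  co <- simulate_cohort(static_world(300, seed = 11))
  lmd <- build_landmark_dataset(co, landmarks = 0:4)
  fit1 <- fit_dpm(lmd, window = 1)
  fitI <- fit_dpm(lmd)
  expect_lt(fit1$n_events, fitI$n_events)
  for (s in names(fit1$baselines)) {
    bh <- fit1$baselines[[s]]
    if (nrow(bh)) expect_true(all(bh$time <= as.numeric(s) + 1 + 1e-12))
  }
})

test_that("JSON serialization round-trips the fit", {
  co <- simulate_cohort(static_world(250, seed = 3))
  lmd <- build_landmark_dataset(co, landmarks = 0:4)
  fit <- fit_dpm(lmd)
  f <- withr::local_tempfile(fileext = ".json")
  write_dpm(fit, f)
  back <- read_dpm(f)
  expect_equal(back$coef, fit$coef, tolerance = 1e-12)
  expect_equal(back$alpha, fit$alpha, tolerance = 1e-12)
  expect_equal(back$covariance, fit$covariance, tolerance = 1e-12)
  rows <- lmd[lmd$landmark_s == 3, ][1:8, ]
  expect_equal(predict_survival(back, rows, 3, 2),
               predict_survival(fit, rows, 3, 2), tolerance = 1e-12)
  dc1 <- dynamic_coefficient(fit, "m", c(0, 2, 4))
  dc2 <- dynamic_coefficient(back, "m", c(0, 2, 4))
  expect_equal(dc1, dc2, tolerance = 1e-12)
})

test_that("degenerate fitting inputs raise informative errors", {
  co <- simulate_cohort(static_world(50, seed = 2))
  lmd <- build_landmark_dataset(co, landmarks = 0:2)
  empty <- lmd[0, ]
  expect_error(fit_dpm(empty), "empty", class = "landmarkDPM_data_error")
  # all-censored data: no events in any stratum
  lmd2 <- lmd
  lmd2$event_indicator <- 0L
  expect_error(fit_dpm(lmd2), "no events", class = "landmarkDPM_data_error")
  expect_error(fit_dpm(lmd, window = 0), "window", class = "landmarkDPM_config_error")
})
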