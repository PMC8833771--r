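test_that("covariate-free censoring model equals the Kaplan-Meier of censoring", {
  set.seed(1)
  n <- 120
  time <- rexp(n, 0.1)
  event <- rbinom(n, 1, 0.6)
  pat <- data.frame(patient_id = as.character(1:n), observed_time = time,
                    event_indicator = event)
  cm <- fit_censoring_model(pat, covariates = NULL)
  km <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  ts <- sort(unique(time[event == 0]))
  mine <- censoring_survival(cm, NULL, t = ts)
  # exact: exp(-Nelson-Aalen) using survfit's independent risk-set counting
  H_na <- cumsum(km$n.event / km$n.risk)
  expect_equal(mine, exp(-H_na[match(ts, km$time)]), tolerance = 1e-12)
  # and equal to the KM product-limit up to its first-order approximation
  km_s <- summary(km, times = ts)$surv
  expect_equal(mine, km_s, tolerance = 0.02)
})

test_that("all patients censored at one time: S_C = 1 before it", {
  pat <- data.frame(patient_id = as.character(1:8),
                    observed_time = rep(5, 8), event_indicator = 0L)
  cm <- fit_censoring_model(pat, covariates = NULL)
  expect_equal(censoring_survival(cm, NULL, t = c(1, 4.999)), c(1, 1))
  expect_lt(censoring_survival(cm, NULL, t = 5), 1)
  # no censored observations at all -> informative error
  pat2 <- transform(pat, event_indicator = 1L)
  expect_error(fit_censoring_model(pat2, NULL), "no censored",
               class = "landmarkDPM_data_error")
})

test_that("censoring-covariate effect is recovered within 3 SE", {
  set.seed(33)
  n <- 2000
  gender <- rbinom(n, 1, 0.5)
  cens_t <- rexp(n, 0.05 * exp(0.5 * gender))
  death_t <- rexp(n, 0.08)
  pat <- data.frame(patient_id = as.character(1:n),
                    observed_time = pmin(cens_t, death_t),
                    event_indicator = as.integer(death_t <= cens_t),
                    gender = gender)
  cm <- fit_censoring_model(pat, covariates = "gender")
  se <- sqrt(cm$vcov["gender", "gender"])
  expect_lt(abs(cm$coef[["gender"]] - 0.5), 3 * se)
  # conditioning renormalizes: S(t | > s) = S(t) / S(s)
  nd <- data.frame(gender = 1)
  s_t <- censoring_survival(cm, nd, t = 10)
  s_s <- censoring_survival(cm, nd, t = 4)
  expect_equal(censoring_survival(cm, nd, t = 10, condition_time = 4), s_t / s_s)
})

test_that("degenerate AUC identities: complete ties and perfect anti-ranking", {
  time <- c(0.5, 0.7, 2, 3, 4, 5)
  event <- c(1, 1, 0, 1, 0, 0)
  tied <- rep(0.4, 6)
  r <- ipcw_auc(tied, time, event, s = 0, horizon = 1)
  expect_identical(r$auc, 0.5)
  # lower predicted survival for the two early deaths -> AUC 1
  perfect <- c(0.1, 0.2, 0.8, 0.9, 0.7, 0.6)
  expect_identical(ipcw_auc(perfect, time, event, 0, 1)$auc, 1)
  # reversing the ranking flips the AUC
  expect_identical(ipcw_auc(1 - perfect, time, event, 0, 1)$auc, 0)
})

test_that("AUC is invariant to strictly increasing transforms and anti-symmetric", {
  set.seed(7)
  n <- 150
  pred <- round(runif(n), 2)          # forces some ties
  time <- rexp(n, 0.3)
  event <- rbinom(n, 1, 0.7)
  time <- time + 0.01
  a <- ipcw_auc(pred, time, event, s = 0, horizon = 2)$auc
  trans <- function(p) p^3 / (1 + p^3)  # strictly increasing on [0, 1]
  expect_equal(ipcw_auc(trans(pred), time, event, 0, 2)$auc, a, tolerance = 1e-12)
  # with no ties, anti-ranking gives 1 - AUC
  pred2 <- runif(n)
  a2 <- ipcw_auc(pred2, time, event, 0, 2)$auc
  expect_equal(ipcw_auc(1 - pred2, time, event, 0, 2)$auc, 1 - a2,
               tolerance = 1e-12)
})

test_that("sensitivity/specificity curves are monotone and consistent with counts", {
  set.seed(9)
  n <- 80
  pred <- round(runif(n), 1)
  time <- rexp(n, 0.4) + 0.01
  event <- rbinom(n, 1, 0.8)
  r <- ipcw_auc(pred, time, event, s = 0, horizon = 1)
  expect_true(all(diff(r$curves$sensitivity) >= 0))   # nondecreasing in cutoff
  expect_true(all(diff(r$curves$specificity) <= 0))
  expect_equal(max(r$curves$sensitivity), 1)
  expect_equal(min(r$curves$specificity), 0)
  expect_equal(r$n_cases + r$n_controls +
                 sum(time <= 1 & event == 0), n)
})

test_that("AUC precondition violations raise the documented errors", {
  expect_error(ipcw_auc(c(0.5, 0.6), c(1, 2), c(1, 1), s = 1.5, horizon = 1),
               "at risk", class = "landmarkDPM_data_error")
  expect_error(ipcw_auc(c(0.5, 1.4), c(1, 2), c(1, 1), s = 0, horizon = 1),
               "probabilities")
  # no controls beyond the horizon
  expect_error(ipcw_auc(c(0.5, 0.6), c(0.2, 0.4), c(1, 1), 0, 1),
               "controls", class = "landmarkDPM_auc_undefined")
  # no cases
  expect_error(ipcw_auc(c(0.5, 0.6), c(2, 3), c(1, 1), 0, 1),
               "cases", class = "landmarkDPM_auc_undefined")
})

test_that("patient-wise bootstrap: determinism, identical-model p-value, skips", {
  set.seed(15)
  n <- 100
  pred <- runif(n)
  time <- rexp(n, 0.5) + 0.01
  event <- rbinom(n, 1, 0.8)
  b1 <- bootstrap_auc(list(a = pred, b = pred), time, event, 0, 1,
                      n_boot = 50, seed = 4)
  b2 <- bootstrap_auc(list(a = pred, b = pred), time, event, 0, 1,
                      n_boot = 50, seed = 4)
  expect_identical(b1$boot, b2$boot)
  expect_equal(b1$ci["a", ], b1$ci["b", ])
  expect_equal(b1$p_value, 1)      # identical models never differ
  expect_error(bootstrap_auc(pred, time, event, 0, 1, n_boot = 1), "n_boot",
               class = "landmarkDPM_config_error")
})

test_that("evaluate_grid aligns models and flags undefined cells", {
  co <- simulate_cohort(design_faithful_linear(400, seed = 91))
  sp <- split_patients(co, 2 / 3, seed = 1)
  train <- subset_cohort(co, sp$train)
  valid <- subset_cohort(co, sp$validation)
  lm_tr <- build_landmark_dataset(train, landmarks = 0:6)
  lm_va <- build_landmark_dataset(valid, landmarks = 0:6)
  fit <- fit_dpm(lm_tr)
  tab <- evaluate_grid(list(m1 = fit, m2 = fit), lm_va,
                       landmarks = c(0, 3, 6), horizons = c(1, 3))
  expect_equal(nrow(tab), 2 * 3 * 2)
  # identical model passed twice -> identical AUC columns
  expect_equal(tab$auc[tab$model == "m1"], tab$auc[tab$model == "m2"])
  # a landmark beyond everyone's follow-up yields an undefined cell, others intact
  tab2 <- evaluate_grid(list(m1 = fit), lm_va, landmarks = c(3, 40), horizons = 1)
  expect_true(is.na(tab2$auc[tab2$landmark == 40]))
  expect_match(tab2$note[tab2$landmark == 40], "no patients")
  expect_false(is.na(tab2$auc[tab2$landmark == 3]))
})

test_that("a dynamic model outranks the static baseline when markers drift strongly", {
  # current marker value dominates; baseline value is nearly uninformative
  wins <- 0L
  for (seed in 1:10) {
    cfg <- cohort_config(
      n_patients = 1500, seed = 500 + seed,
      baseline_covariates = list(z = list(dist = "bernoulli", prob = 0.5)),
      markers = list(biomarker = list(kind = "continuous", init_mean = 0,
                                      init_sd = 0.3, drift = 0, noise_sd = 1)),
      effects = list(biomarker = c(log(2))), theta = c(z = 0.2),
      baseline_hazard_rate = 0.08, censoring_rate = 0.02, admin_censoring = 36,
      landmark_faithful = TRUE
    )
    co <- simulate_cohort(cfg)
    sp <- split_patients(co, 2 / 3, seed = seed)
    lm_tr <- build_landmark_dataset(subset_cohort(co, sp$train), landmarks = 0:8)
    lm_va <- build_landmark_dataset(subset_cohort(co, sp$validation), landmarks = 0:8)
    dyn <- fit_dpm(lm_tr)
    rows0 <- lm_tr[lm_tr$landmark_s == 0, ]
    attr(rows0, "td_vars") <- attr(lm_tr, "td_vars")
    attr(rows0, "fixed_vars") <- attr(lm_tr, "fixed_vars")
    sta <- fit_dpm(rows0, basis = basis_spec(numeric(0), 1))
    tab <- evaluate_grid(list(dyn = dyn, sta = sta), lm_va,
                         landmarks = 6, horizons = 1)
    if (tab$auc[tab$model == "dyn"] > tab$auc[tab$model == "sta"]) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
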