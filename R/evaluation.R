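#' Fit a Cox model for the censoring distribution
#'
#' Treats censoring as the event of interest (deaths become censored
#' observations) and fits a Cox proportional hazards model on the supplied
#' covariates -- by default age and gender -- from which the censoring
#' survival function \eqn{\hat S_C(t \mid x)} is obtained via the Breslow
#' baseline. With no covariates the estimate reduces to the Kaplan-Meier /
#' Nelson-Aalen estimate of the censoring distribution.
#'
#' @param patients A cohort object or patient table containing
#'   `observed_time`, `event_indicator` and the covariates.
#' @param covariates Character vector of covariate names; `NULL` or empty
#'   fits the covariate-free model.
#' @return Object of class `censoring_model`.
#' @export
fit_censoring_model <- function(patients, covariates = c("age", "gender")) {
  if (inherits(patients, "cohort")) patients <- patients$patients
  if (!all(c("observed_time", "event_indicator") %in% names(patients))) {
    abort_data("patient table must contain observed_time and event_indicator")
  }
  cens <- 1L - patients$event_indicator
  if (sum(cens) < 1L) {
    abort_data(paste("no censored observations: cannot fit a censoring model;",
                     "with complete follow-up IPCW weights are not needed",
                     "(pass cens_model = NULL)"))
  }
  covariates <- covariates %||% character(0)
  miss <- setdiff(covariates, names(patients))
  if (length(miss)) {
    abort_data("censoring covariate(s) absent: %s", paste(miss, collapse = ", "))
  }
  if (length(covariates)) {
    df <- data.frame(.time = patients$observed_time, .cens = cens,
                     patients[, covariates, drop = FALSE], check.names = FALSE)
    fml <- stats::as.formula(paste(
      "survival::Surv(.time, .cens) ~",
      paste(sprintf("`%s`", covariates), collapse = " + ")))
    fit <- survival::coxph(fml, data = df, ties = "breslow")
    cf <- stats::setNames(stats::coef(fit), covariates)
    vc <- stats::vcov(fit)
    dimnames(vc) <- list(covariates, covariates)
    lp <- drop(as.matrix(patients[, covariates, drop = FALSE]) %*% cf)
  } else {
    cf <- stats::setNames(numeric(0), character(0))
    vc <- NULL
    lp <- rep(0, nrow(patients))
  }
  bh <- breslow_cumhaz(start = rep(0, nrow(patients)),
                       stop = patients$observed_time,
                       event = cens, explp = exp(lp))
  structure(list(coef = cf, vcov = vc, covariates = covariates, baseline = bh,
                 n = nrow(patients), n_censored = sum(cens)),
            class = "censoring_model")
}

#' Censoring survival probabilities
#'
#' \eqn{\hat S_C(t \mid x)}, optionally conditioned on being uncensored at
#' a landmark by the renormalization
#' \eqn{\hat S_C(t \mid x) / \hat S_C(s \mid x)}.
#'
#' @param model A [fit_censoring_model()] result.
#' @param newdata data.frame with the model's covariates (ignored for the
#'   covariate-free model); recycled against `t`.
#' @param t Times (months, on the baseline scale).
#' @param condition_time Conditioning time `s` (default 0: unconditional).
#' @return Vector of probabilities in (0, 1].
#' @export
censoring_survival <- function(model, newdata = NULL, t, condition_time = 0) {
  stopifnot(inherits(model, "censoring_model"))
  if (length(model$covariates)) {
    miss <- setdiff(model$covariates, names(newdata))
    if (length(miss)) abort_data("newdata is missing censoring covariate(s): %s",
                                 paste(miss, collapse = ", "))
    lp <- drop(as.matrix(newdata[, model$covariates, drop = FALSE]) %*% model$coef)
  } else {
    lp <- 0
  }
  H_t <- eval_cumhaz(model$baseline, t)
  H_s <- eval_cumhaz(model$baseline, condition_time)
  exp(-(H_t - H_s) * exp(lp))
}

abort_auc_undefined <- function(side) {
  stop(errorCondition(
    sprintf("IPCW AUC undefined: no %s at this (landmark, horizon)", side),
    class = c("landmarkDPM_auc_undefined", "landmarkDPM_data_error", "landmarkDPM_error")))
}

# Weighted pairwise AUC with half-credit for tied predictions. Cases carry
# individual weights w_case, controls w_ctrl; equals the brute-force
# double-loop sum over (case, control) pairs.
weighted_pair_auc <- function(pred, is_case, is_ctrl, w_case, w_ctrl) {
  u <- sort(unique(pred))
  lev <- match(pred, u)
  Wc <- numeric(length(u)); Wn <- numeric(length(u))
  if (any(is_case)) {
    agg <- rowsum(w_case[is_case], lev[is_case])
    Wc[as.integer(rownames(agg))] <- agg[, 1L]
  }
  if (any(is_ctrl)) {
    agg <- rowsum(w_ctrl[is_ctrl], lev[is_ctrl])
    Wn[as.integer(rownames(agg))] <- agg[, 1L]
  }
  tot_c <- sum(Wc); tot_n <- sum(Wn)
  if (tot_c <= 0 || tot_n <= 0) return(NA_real_)
  ctrl_gt <- tot_n - cumsum(Wn)           # control weight strictly above each value
  sum(Wc * (ctrl_gt + 0.5 * Wn)) / (tot_c * tot_n)
}

#' IPCW time-dependent AUC at a (landmark, horizon) pair
#'
#' Implements the inverse-probability-of-censoring-weighted AUC for
#' predicting an event within `horizon` months after landmark `s`, over
#' the patients at risk at `s`. Cases are patients observed to die by
#' `s + horizon` and are weighted by `1 / S_C(observed time)`; controls
#' are patients still under observation beyond `s + horizon`, weighted by
#' `1 / S_C(s + horizon)`; censoring survival is conditioned on being
#' uncensored at `s`. A (case, control) pair scores 1 when the case's
#' predicted survival is lower than the control's, 1/2 on ties, and the
#' AUC is the weighted pair-score sum over the product of total case and
#' control weights. Without a censoring model all weights are 1 and the
#' estimator reduces to the classical Mann-Whitney AUC.
#'
#' @param pred Predicted survival probabilities \eqn{\hat S_s(horizon)}
#'   for the at-risk patients (lower = higher predicted risk).
#' @param time,event Observed times (months, baseline scale; all `> s`)
#'   and event indicators for the same patients.
#' @param s Landmark time (months).
#' @param horizon Horizon `t` (months, > 0).
#' @param cens_model Optional [fit_censoring_model()] result; `NULL`
#'   disables weighting.
#' @param cens_data data.frame of censoring covariates for the at-risk
#'   patients (required when the censoring model has covariates).
#' @param weight_cap_quantile Optional quantile in (0, 1] at which the
#'   IPCW weights are capped (off by default).
#' @return Object of class `auc_result`: `auc`, counts, and the
#'   sensitivity/specificity curves over prediction cutoffs.
#' @export
ipcw_auc <- function(pred, time, event, s, horizon,
                     cens_model = NULL, cens_data = NULL,
                     weight_cap_quantile = NULL) {
  n <- length(pred)
  if (length(time) != n || length(event) != n) {
    abort_data("pred, time and event must have equal length")
  }
  if (any(time <= s)) abort_data("all patients must be at risk at the landmark (time > s)")
  if (any(pred < -1e-12 | pred > 1 + 1e-12)) {
    abort_data("predictions must be survival probabilities in [0, 1]")
  }
  tau <- s + horizon
  is_case <- time <= tau & event == 1
  is_ctrl <- time > tau
  if (!any(is_case)) abort_auc_undefined("cases")
  if (!any(is_ctrl)) abort_auc_undefined("controls")

  if (is.null(cens_model)) {
    w_case <- rep(1, n); w_ctrl <- rep(1, n)
  } else {
    sc_case <- censoring_survival(cens_model, cens_data, t = time, condition_time = s)
    sc_ctrl <- censoring_survival(cens_model, cens_data, t = rep(tau, n), condition_time = s)
    if (any(sc_case[is_case] <= 0) || any(sc_ctrl[is_ctrl] <= 0)) {
      if (is.null(weight_cap_quantile)) {
        abort_numerical(paste("zero censoring-survival weight encountered;",
                              "consider weight_cap_quantile"))
      }
      sc_case <- pmax(sc_case, .Machine$double.eps)
      sc_ctrl <- pmax(sc_ctrl, .Machine$double.eps)
    }
    w_case <- 1 / sc_case
    w_ctrl <- 1 / sc_ctrl
    if (!is.null(weight_cap_quantile)) {
      cap <- stats::quantile(c(w_case[is_case], w_ctrl[is_ctrl]),
                             weight_cap_quantile, names = FALSE)
      w_case <- pmin(w_case, cap)
      w_ctrl <- pmin(w_ctrl, cap)
    }
  }

  auc <- weighted_pair_auc(pred, is_case, is_ctrl, w_case, w_ctrl)

  # sensitivity / specificity over cutoffs u (predicted event iff pred < u)
  u <- c(sort(unique(pred)), Inf)
  Wcase_tot <- sum(w_case[is_case]); Wctrl_tot <- sum(w_ctrl[is_ctrl])
  se <- vapply(u, function(cut) sum(w_case[is_case & pred < cut]) / Wcase_tot, numeric(1))
  sp <- vapply(u, function(cut) sum(w_ctrl[is_ctrl & pred >= cut]) / Wctrl_tot, numeric(1))
  curves <- data.frame(cutoff = u, sensitivity = se, specificity = sp)

  structure(
    list(landmark_s = s, horizon_t = horizon, auc = auc,
         n_at_risk = n, n_cases = sum(is_case), n_controls = sum(is_ctrl),
         case_weight_total = Wcase_tot, control_weight_total = Wctrl_tot,
         curves = curves),
    class = "auc_result"
  )
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("IPCW AUC at landmark %s, horizon %s months: %.4f (%d at risk, %d cases, %d controls)\n",
              format(x$landmark_s), format(x$horizon_t), x$auc,
              x$n_at_risk, x$n_cases, x$n_controls))
  invisible(x)
}

#' Patient-wise bootstrap for the IPCW AUC
#'
#' Resamples the at-risk validation patients with replacement and
#' recomputes the IPCW AUC of each model on every resample (predictions
#' and censoring model are held fixed, as models are built on the training
#' set). Percentile confidence intervals are reported per model; with
#' exactly two models, a two-sided bootstrap p-value for the AUC
#' difference is added, computed as twice the smaller tail fraction of
#' bootstrap differences and floored at `1 / n_boot`.
#'
#' @param preds Named list of prediction vectors (one per model), or a
#'   single vector.
#' @param time,event,s,horizon,cens_model,cens_data As in [ipcw_auc()].
#' @param n_boot Number of bootstrap iterations (default 100).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return List with `auc` (point estimates), `ci` (matrix model x
#'   lower/upper), `p_value` (two models only), `n_skipped`, and the
#'   bootstrap draws.
#' @export
bootstrap_auc <- function(preds, time, event, s, horizon,
                          cens_model = NULL, cens_data = NULL,
                          n_boot = 100, seed = 1L, level = 0.95) {
  if (!is.list(preds)) preds <- list(model = preds)
  if (n_boot < 2) abort_config("n_boot must be >= 2")
  n <- length(time)
  tau <- s + horizon
  is_case <- time <= tau & event == 1
  is_ctrl <- time > tau
  if (is.null(cens_model)) {
    w_case <- rep(1, n); w_ctrl <- rep(1, n)
  } else {
    w_case <- 1 / censoring_survival(cens_model, cens_data, t = time, condition_time = s)
    w_ctrl <- 1 / censoring_survival(cens_model, cens_data, t = rep(tau, n), condition_time = s)
  }
  point <- vapply(preds, weighted_pair_auc, numeric(1),
                  is_case = is_case, is_ctrl = is_ctrl,
                  w_case = w_case, w_ctrl = w_ctrl)

  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, length(preds),
                 dimnames = list(NULL, names(preds)))
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (!any(is_case[idx]) || !any(is_ctrl[idx])) {
      skipped <- skipped + 1L
      next
    }
    for (m in seq_along(preds)) {
      boot[b, m] <- weighted_pair_auc(preds[[m]][idx], is_case[idx], is_ctrl[idx],
                                      w_case[idx], w_ctrl[idx])
    }
  }
  if (skipped > 0L) {
    warning(sprintf("%d bootstrap iteration(s) skipped (no cases or no controls)", skipped))
  }
  if (skipped > n_boot / 2) {
    abort_data("more than half of the bootstrap iterations were degenerate")
  }
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- t(apply(boot, 2L, stats::quantile, probs = pr, na.rm = TRUE, names = FALSE))
  colnames(ci) <- c("lower", "upper")
  p_value <- NULL
  if (length(preds) == 2L) {
    d <- boot[, 1L] - boot[, 2L]
    d <- d[!is.na(d)]
    p_value <- max(2 * min(mean(d <= 0), mean(d >= 0)), 1 / n_boot)
    p_value <- min(p_value, 1)
  }
  list(auc = point, ci = ci, p_value = p_value, n_skipped = skipped, boot = boot)
}

#' Evaluate models over a landmark x horizon grid
#'
#' Computes the IPCW AUC of each fitted model at every (landmark, horizon)
#' cell on the validation landmark dataset, with aligned comparisons: a
#' single-landmark (static) fit is evaluated on the same at-risk patients
#' using its baseline covariate values and the shifted horizon `s + t`
#' from its own landmark, so all models predict the same events for the
#' same people.
#'
#' @param fits Named list of [fit_dpm()] results. A fit with a single
#'   landmark stratum is treated as a static baseline model.
#' @param validation A [build_landmark_dataset()] built on the validation
#'   cohort (its grid must contain the requested landmarks, and the static
#'   model's landmark if any static fit is supplied).
#' @param cens_model Optional censoring model (fit on training patients).
#' @param landmarks Landmarks to evaluate (default: the validation grid).
#' @param horizons Horizons in months (default `c(0.5, 1, 3, 6)`).
#' @param n_boot Bootstrap iterations for per-cell CIs (0 disables).
#' @param seed Seed for the bootstrap.
#' @return data.frame with one row per (model, landmark, horizon):
#'   `auc`, `ci_low`, `ci_high`, `n_at_risk`, `n_cases`, `n_controls`,
#'   `note` (reason when a cell is undefined).
#' @export
evaluate_grid <- function(fits, validation, cens_model = NULL,
                          landmarks = NULL, horizons = c(0.5, 1, 3, 6),
                          n_boot = 0, seed = 1L) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  landmarks <- landmarks %||% attr(validation, "landmarks")
  cens_cov <- if (!is.null(cens_model)) cens_model$covariates else character(0)
  rows <- list()
  for (mi in seq_along(fits)) {
    fit <- fits[[mi]]
    mname <- names(fits)[mi]
    static <- length(fit$landmarks) == 1L
    s0 <- fit$landmarks[1L]
    base_rows <- if (static) {
      validation[validation$landmark_s == s0, , drop = FALSE]
    } else NULL
    for (s in landmarks) {
      at_s <- validation[validation$landmark_s == s, , drop = FALSE]
      for (h in horizons) {
        note <- ""
        res <- NULL
        if (nrow(at_s) == 0L) {
          note <- "no patients at risk"
        } else {
          if (static) {
            m <- match(at_s$patient_id, base_rows$patient_id)
            ok <- !is.na(m)
            dat <- at_s[ok, , drop = FALSE]
            nd <- base_rows[m[ok], , drop = FALSE]
            pred <- predict_survival(fit, nd, s = s0, horizon = (s - s0) + h)
          } else {
            dat <- at_s
            pred <- predict_survival(fit, at_s, s = s, horizon = h)
          }
          cd <- if (length(cens_cov)) dat[, cens_cov, drop = FALSE] else NULL
          res <- tryCatch(
            ipcw_auc(pred, dat$observed_time, dat$event_indicator,
                     s = s, horizon = h, cens_model = cens_model, cens_data = cd),
            landmarkDPM_auc_undefined = function(e) {
              note <<- conditionMessage(e); NULL
            })
          if (!is.null(res) && n_boot > 0) {
            bs <- tryCatch(
              suppressWarnings(bootstrap_auc(
                pred, dat$observed_time, dat$event_indicator,
                s = s, horizon = h, cens_model = cens_model,
                cens_data = cd, n_boot = n_boot,
                seed = seed + round(1000 * s) + round(10 * h))),
              landmarkDPM_data_error = function(e) {
                note <<- paste("bootstrap:", conditionMessage(e)); NULL
              })
            ci <- if (is.null(bs)) c(NA_real_, NA_real_) else bs$ci[1L, ]
          } else ci <- c(NA_real_, NA_real_)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          model = mname, landmark = s, horizon = h,
          auc = if (is.null(res)) NA_real_ else res$auc,
          ci_low = if (is.null(res)) NA_real_ else unname(ci[1L]),
          ci_high = if (is.null(res)) NA_real_ else unname(ci[2L]),
          n_at_risk = if (is.null(res)) nrow(at_s) else res$n_at_risk,
          n_cases = if (is.null(res)) NA_integer_ else res$n_cases,
          n_controls = if (is.null(res)) NA_integer_ else res$n_controls,
          note = note, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
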