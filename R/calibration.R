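#' Expected events and martingale residuals at a landmark
#'
#' For each patient at risk at landmark `s`, the model-expected number of
#' events over their own follow-up is
#' \eqn{e_{i,s} = H_{s,0}(\tilde T_i) \exp(x_i'\hat\beta(s) + z_i'\hat\theta)},
#' with the Breslow cumulative baseline of the landmark's stratum
#' evaluated at the patient's observed time; the martingale residual is
#' \eqn{m_{i,s} = \delta_i - e_{i,s}}. On the training data these residuals
#' sum to zero within every landmark stratum (the Breslow score-equation
#' identity). If the fit used a finite per-stratum `window`, follow-up and
#' events are capped at `s + window` for consistency with the fit.
#'
#' @param fit A [fit_dpm()] result.
#' @param data Landmark rows (e.g. one stratum of a
#'   [build_landmark_dataset()]); all rows must satisfy
#'   `observed_time > s`.
#' @param s Landmark time; default: taken from the rows' `landmark_s`
#'   (which must then be constant).
#' @return data.frame with columns `patient_id`, `expected`, `observed`,
#'   `martingale`.
#' @export
expected_events <- function(fit, data, s = NULL) {
  stopifnot(inherits(fit, "dpm_fit"))
  if (is.null(s)) {
    s <- unique(data$landmark_s)
    if (length(s) != 1L) abort_data("rows span several landmarks; supply s")
  }
  if (any(data$observed_time <= s)) {
    abort_data("some patients are not at risk at landmark %s (observed_time <= s)", format(s))
  }
  bh <- fit$baselines[[format_landmark(s)]]
  if (is.null(bh)) abort_data("no fitted stratum at landmark %s", format(s))
  B <- evaluate_basis(fit$basis, s)
  lp <- rep(0, nrow(data))
  for (v in fit$td_vars) lp <- lp + data[[v]] * drop(B %*% fit$alpha[v, ])
  if (length(fit$fixed_vars)) {
    lp <- lp + drop(as.matrix(data[, fit$fixed_vars, drop = FALSE]) %*% fit$theta)
  }
  t_end <- pmin(data$observed_time, s + fit$window)
  delta <- as.integer(data$event_indicator == 1 & data$observed_time <= s + fit$window)
  e <- eval_cumhaz(bh, t_end) * exp(lp)
  data.frame(patient_id = data$patient_id, expected = e, observed = delta,
             martingale = delta - e, stringsAsFactors = FALSE)
}

#' Risk groups from predicted survival
#'
#' Partitions patients into `q` groups by quantiles of predicted survival
#' at a fixed horizon (the grouping variable of the model-based
#' calibration test). With fewer distinct prediction values than groups,
#' groups are collapsed with a warning; ties between equal predictions are
#' broken by stable input order.
#'
#' @param pred Predicted survival probabilities.
#' @param q Number of groups (default 10).
#' @return Integer vector of group labels in `1..q` (group 1 = lowest
#'   predicted survival, i.e. highest risk).
#' @export
group_by_predicted_survival <- function(pred, q = 10L) {
  n <- length(pred)
  if (q < 2L) abort_config("q must be >= 2")
  if (n < q) abort_data("need at least q patients to form q groups")
  nu <- length(unique(pred))
  if (nu < q) {
    q_eff <- max(nu, 1L)
    warning(sprintf("only %d distinct prediction value(s); collapsing to %d group(s)",
                    nu, q_eff))
    if (q_eff == 1L) return(rep(1L, n))
    return(as.integer(cut(pred, breaks = stats::quantile(unique(pred),
                                                         probs = seq(0, 1, length.out = q_eff + 1L)),
                          include.lowest = TRUE)))
  }
  r <- rank(pred, ties.method = "first")
  as.integer(ceiling(r * q / n))
}

#' Offset Poisson calibration test
#'
#' The model-based calibration endpoint: a Poisson regression of the
#' observed event indicator on `q` risk-group indicators with the log
#' expected count as a fixed-coefficient-1 offset and no intercept,
#' \deqn{E(\delta_i) = \exp\{\gamma_1 g_{1i} + \ldots + \gamma_q g_{qi} +
#' \log e_{i,s}\}.}
#' The maximum-likelihood solution is available in closed form,
#' \eqn{\hat\gamma_g = \log(O_g / E_g)} with information \eqn{O_g}, and a
#' global Wald test of \eqn{H_0: \gamma_1 = \ldots = \gamma_q = 0}
#' (statistic \eqn{\sum_g O_g \hat\gamma_g^2}, df = number of groups with
#' observed events) examines whether any group's observed events deviate
#' from the model's expectation.
#'
#' @param observed 0/1 event indicators \eqn{\delta_i}.
#' @param expected Model-expected events \eqn{e_{i,s}} (> 0 summed within
#'   every group).
#' @param groups Group labels (from [group_by_predicted_survival()]).
#' @param solver `"closed_form"` (default) or `"glm"` (iterative fit via
#'   [stats::glm()]; identical to the closed form, kept for
#'   cross-checking).
#' @param level Confidence level for the per-group intervals.
#' @return Object of class `calibration_result`: per-group table
#'   (`group`, `n`, `observed`, `expected`, `gamma`, `ci_low`, `ci_high`)
#'   and the global Wald `statistic`, `df`, `p_value`. Groups with zero
#'   observed events get `gamma = -Inf` with a one-sided upper limit and
#'   are excluded from the Wald statistic (df reduced, with a warning).
#' @export
poisson_calibration <- function(observed, expected, groups,
                                solver = c("closed_form", "glm"),
                                level = 0.95) {
  solver <- match.arg(solver)
  n <- length(observed)
  if (length(expected) != n || length(groups) != n) {
    abort_data("observed, expected and groups must have equal length")
  }
  gl <- sort(unique(groups))
  O <- as.numeric(rowsum(as.numeric(observed), groups)[, 1L])
  E <- as.numeric(rowsum(as.numeric(expected), groups)[, 1L])
  ng <- as.numeric(table(factor(groups, levels = gl)))
  if (any(E <= 0)) abort_data("every group must have positive total expected events")

  z <- stats::qnorm(1 - (1 - level) / 2)
  if (solver == "glm") {
    gf <- factor(groups, levels = gl)
    fit <- stats::glm(observed ~ 0 + gf + offset(log(expected)),
                      family = stats::poisson(),
                      control = stats::glm.control(epsilon = 1e-14, maxit = 100))
    gamma <- unname(stats::coef(fit))
    se <- sqrt(diag(stats::vcov(fit)))
  } else {
    gamma <- log(O / E)
    se <- ifelse(O > 0, 1 / sqrt(O), NA_real_)
  }
  ci_low <- gamma - z * se
  ci_high <- gamma + z * se
  # zero-event groups: gamma = -Inf; exact one-sided Poisson upper bound
  zero <- O == 0
  if (any(zero)) {
    warning(sprintf("%d group(s) with zero observed events excluded from the Wald test",
                    sum(zero)))
    gamma[zero] <- -Inf
    ci_low[zero] <- -Inf
    ci_high[zero] <- log(-log(1 - level) / E[zero])  # from P(O = 0) = exp(-E e^gamma)
  }
  keep <- !zero
  stat <- sum(O[keep] * log(O[keep] / E[keep])^2)
  df <- sum(keep)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)

  structure(
    list(table = data.frame(group = gl, n = ng, observed = O, expected = E,
                            gamma = gamma, ci_low = ci_low, ci_high = ci_high),
         statistic = stat, df = df, p_value = p, solver = solver),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Model-based calibration: Wald X^2 = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' One-call calibration of a fitted DPM at a landmark
#'
#' Groups the validation patients at risk at `s` by their predicted
#' survival at `grouping_horizon` months, computes per-patient expected
#' events over their own follow-up, and runs the offset Poisson test.
#'
#' @param fit A [fit_dpm()] result.
#' @param validation A validation [build_landmark_dataset()].
#' @param s Landmark (must be a fitted stratum present in `validation`).
#' @param grouping_horizon Horizon used only to build the risk groups
#'   (months, default 1).
#' @param q Number of risk groups (default 10).
#' @param level Confidence level.
#' @return A `calibration_result` with an extra `landmark_s` field.
#' @export
calibrate_dpm <- function(fit, validation, s, grouping_horizon = 1, q = 10L,
                          level = 0.95) {
  rows <- validation[validation$landmark_s == s, , drop = FALSE]
  if (nrow(rows) == 0L) abort_data("no validation patients at landmark %s", format(s))
  pred <- predict_survival(fit, rows, s = s, horizon = grouping_horizon)
  grp <- group_by_predicted_survival(pred, q = q)
  ee <- expected_events(fit, rows, s = s)
  out <- poisson_calibration(ee$observed, ee$expected, grp, level = level)
  out$landmark_s <- s
  out$grouping_horizon <- grouping_horizon
  out
}
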