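#' Fit the spline-smoothed landmark Cox supermodel
#'
#' Maximizes a single stacked Cox partial likelihood over all landmark
#' rows, stratified by landmark (a separate nonparametric baseline hazard
#' per landmark), with each time-dependent covariate `x` entering through
#' the interaction columns `x * phi_i(s)` of the basis, so its log hazard
#' ratio varies smoothly over landmark time as
#' \eqn{\beta(s) = \sum_i \alpha_i \phi_i(s)}. Fixed covariates enter with
#' time-constant coefficients `theta`. Each stratum is left-truncated at
#' its landmark; because patients contribute rows to many landmarks, the
#' default variance is the cluster-robust sandwich estimator with score
#' contributions aggregated within patient.
#'
#' With a single landmark and a constant-only basis the model reduces
#' exactly to an ordinary Cox model: a static prediction model is the
#' special case of the dynamic one.
#'
#' @param data A [build_landmark_dataset()] result (or a data.frame with
#'   the same columns and attributes supplied via `td_vars`/`fixed_vars`).
#' @param basis A [basis_spec()]; default [default_basis()] on the data's
#'   landmark grid.
#' @param td_vars,fixed_vars Covariate roles; default taken from the
#'   dataset attributes. `fixed_vars` may be empty.
#' @param window Optional per-stratum follow-up cap (months): events and
#'   follow-up beyond `s + window` are administratively censored within
#'   stratum `s`. Default `Inf` uses full residual follow-up, so one fit
#'   serves every prediction horizon.
#' @param ties Tie handling in the partial likelihood, `"breslow"`
#'   (default, consistent with the Breslow baseline) or `"efron"`.
#' @param robust Use the cluster-robust (by patient) sandwich covariance
#'   (default `TRUE`); `FALSE` keeps the model-based covariance.
#' @return An object of class `dpm_fit`: spline coefficient matrix
#'   `alpha` (time-dependent covariates x basis functions), fixed-effect
#'   vector `theta`, full coefficient vector `coef`, `covariance` (robust
#'   or model-based per `robust`), `naive_covariance`, per-landmark Breslow
#'   baseline cumulative hazards `baselines`, the basis, and fit metadata.
#' @export
fit_dpm <- function(data, basis = NULL, td_vars = NULL, fixed_vars = NULL,
                    window = Inf, ties = c("breslow", "efron"),
                    robust = TRUE) {
  ties <- match.arg(ties)
  if (!is.data.frame(data) || nrow(data) == 0L) {
    abort_data("landmark dataset is empty")
  }
  td_vars <- td_vars %||% attr(data, "td_vars")
  fixed_vars <- fixed_vars %||% attr(data, "fixed_vars")
  landmarks <- attr(data, "landmarks") %||% sort(unique(data$landmark_s))
  if (is.null(td_vars)) abort_config("td_vars must be supplied")
  basis <- basis %||% default_basis(landmarks)
  if (!is.finite(window) && !identical(window, Inf)) {
    abort_config("window must be a positive number or Inf")
  }
  if (window <= 0) abort_config("window must be > 0")

  s <- data$landmark_s
  stop_t <- pmin(data$observed_time, s + window)
  event <- as.integer(data$event_indicator == 1 & data$observed_time <= s + window)

  ev_per_stratum <- tapply(event, s, sum)
  if (all(ev_per_stratum == 0)) abort_data("no events in any landmark stratum")
  if (any(ev_per_stratum == 0)) {
    warning(sprintf("landmark stratum(s) with zero events: %s",
                    paste(names(ev_per_stratum)[ev_per_stratum == 0], collapse = ", ")))
  }

  B <- evaluate_basis(basis, s)
  cn_td <- as.vector(outer(basis$names, td_vars, function(b, v) paste(v, b, sep = ".")))
  X <- matrix(0, nrow(data), length(cn_td), dimnames = list(NULL, cn_td))
  j <- 0L
  for (v in td_vars) {
    for (bi in seq_len(basis$k)) {
      j <- j + 1L
      X[, j] <- data[[v]] * B[, bi]
    }
  }
  if (length(fixed_vars)) {
    miss <- setdiff(fixed_vars, names(data))
    if (length(miss)) abort_data("fixed covariate(s) missing from data: %s",
                                 paste(miss, collapse = ", "))
    Xf <- as.matrix(data[, fixed_vars, drop = FALSE])
    X <- cbind(X, Xf)
  }
  coef_names <- colnames(X)

  df <- data.frame(.start = s, .stop = stop_t, .event = event,
                   .strat = factor(s, levels = sort(unique(s))),
                   .id = data$patient_id, check.names = FALSE)
  df <- cbind(df, as.data.frame(X))
  fml <- stats::as.formula(paste(
    "survival::Surv(.start, .stop, .event) ~",
    paste(sprintf("`%s`", coef_names), collapse = " + "),
    "+ survival::strata(.strat)"))
  fit <- tryCatch(
    if (robust) {
      survival::coxph(fml, data = df, ties = ties, cluster = .id,
                      control = survival::coxph.control(iter.max = 50))
    } else {
      survival::coxph(fml, data = df, ties = ties,
                      control = survival::coxph.control(iter.max = 50))
    },
    error = function(e) abort_numerical("partial-likelihood fit failed: %s",
                                        conditionMessage(e)))
  cf <- stats::coef(fit)
  names(cf) <- coef_names
  if (any(is.na(cf))) {
    abort_numerical("partial-likelihood fit did not converge (NA coefficients: %s)",
                    paste(coef_names[is.na(cf)], collapse = ", "))
  }

  alpha <- matrix(cf[cn_td], nrow = length(td_vars), ncol = basis$k,
                  byrow = TRUE, dimnames = list(td_vars, basis$names))
  theta <- if (length(fixed_vars)) cf[fixed_vars] else stats::setNames(numeric(0), character(0))

  covariance <- fit$var
  dimnames(covariance) <- list(coef_names, coef_names)
  naive <- fit$naive.var %||% fit$var
  dimnames(naive) <- list(coef_names, coef_names)

  lp <- drop(X %*% cf)   # uncentered: baselines refer to covariates == 0
  baselines <- list()
  for (sv in sort(unique(s))) {
    idx <- s == sv
    baselines[[format_landmark(sv)]] <- breslow_cumhaz(
      start = df$.start[idx], stop = df$.stop[idx],
      event = df$.event[idx], explp = exp(lp[idx]))
  }

  structure(
    list(alpha = alpha, theta = theta, coef = cf,
         covariance = covariance, naive_covariance = naive,
         baselines = baselines, basis = basis,
         td_vars = td_vars, fixed_vars = fixed_vars,
         landmarks = sort(unique(s)), window = window, ties = ties,
         robust = robust, n_rows = nrow(data),
         n_patients = length(unique(data$patient_id)),
         n_events = sum(event), loglik = fit$loglik[2L],
         iterations = fit$iter),
    class = "dpm_fit"
  )
}

format_landmark <- function(s) format(s, trim = TRUE, digits = 12)

# Breslow cumulative baseline hazard for one left-truncated stratum:
# increments d_j / sum_{start < t_j <= stop} exp(lp) at each event time.
breslow_cumhaz <- function(start, stop, event, explp) {
  ev_times <- sort(unique(stop[event == 1]))
  if (length(ev_times) == 0L) {
    return(data.frame(time = numeric(0), increment = numeric(0), cumhaz = numeric(0)))
  }
  o_stop <- order(stop)
  sorted_stop <- stop[o_stop]
  cum_stop <- cumsum(explp[o_stop])
  total <- cum_stop[length(cum_stop)]
  o_start <- order(start)
  sorted_start <- start[o_start]
  cum_start <- cumsum(explp[o_start])

  n_stop_lt <- findInterval(ev_times, sorted_stop, left.open = TRUE)
  sum_stop_ge <- total - c(0, cum_stop)[n_stop_lt + 1L]
  n_start_lt <- findInterval(ev_times, sorted_start, left.open = TRUE)
  sum_start_ge <- total - c(0, cum_start)[n_start_lt + 1L]
  risk <- sum_stop_ge - sum_start_ge

  d <- as.numeric(rowsum(rep(1, sum(event == 1)), stop[event == 1])[, 1L])
  inc <- d / risk
  data.frame(time = ev_times, increment = inc, cumhaz = cumsum(inc))
}

#' Dynamic coefficient trajectory
#'
#' Evaluates the fitted log hazard ratio \eqn{\hat\beta(s) = \phi(s)'
#' \hat\alpha_{var}} of a time-dependent covariate at landmark times `s`,
#' with delta-method standard errors from the (cluster-robust) covariance
#' and normal-quantile confidence limits.
#'
#' @param fit A [fit_dpm()] result.
#' @param var Name of a fitted time-dependent covariate.
#' @param s Landmark times (months); values outside the fitted grid are
#'   extrapolations and trigger a warning.
#' @param level Confidence level (default 0.95).
#' @return data.frame with columns `s`, `estimate`, `se`, `lower`,
#'   `upper`, `hr`, `hr_lower`, `hr_upper`.
#' @export
dynamic_coefficient <- function(fit, var, s, level = 0.95) {
  stopifnot(inherits(fit, "dpm_fit"))
  if (!var %in% fit$td_vars) {
    abort_data("'%s' is not a fitted time-dependent covariate", var)
  }
  s <- as.numeric(s)
  rng <- range(fit$landmarks)
  if (any(s < rng[1] | s > rng[2])) {
    warning("some landmark times lie outside the fitted grid; extrapolating")
  }
  B <- evaluate_basis(fit$basis, s)
  idx <- paste(var, fit$basis$names, sep = ".")
  a <- fit$alpha[var, ]
  V <- fit$covariance[idx, idx, drop = FALSE]
  est <- drop(B %*% a)
  se <- sqrt(pmax(rowSums((B %*% V) * B), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(s = s, estimate = est, se = se,
             lower = est - z * se, upper = est + z * se,
             hr = exp(est), hr_lower = exp(est - z * se),
             hr_upper = exp(est + z * se))
}

#' Wald test of a time-varying effect
#'
#' Tests whether the effect of a time-dependent covariate is constant over
#' landmark time: under the null all non-constant basis coefficients are
#' zero, and the quadratic form in the cluster-robust covariance is
#' chi-squared with k - 1 degrees of freedom.
#'
#' @param fit A [fit_dpm()] result whose basis includes the constant
#'   function plus at least one kernel.
#' @param var Name of a fitted time-dependent covariate.
#' @return A list of class `htest` with `statistic`, `parameter` (df),
#'   `p.value`.
#' @export
wald_test_time_varying <- function(fit, var) {
  stopifnot(inherits(fit, "dpm_fit"))
  if (!fit$basis$include_constant || fit$basis$k < 2L) {
    abort_config("test requires a basis with the constant function plus >= 1 kernel")
  }
  if (!is.null(fit$basis$transform)) {
    abort_config("test requires the untransformed basis (constant component identifiable)")
  }
  if (!var %in% fit$td_vars) {
    abort_data("'%s' is not a fitted time-dependent covariate", var)
  }
  nc <- setdiff(fit$basis$names, "const")
  idx <- paste(var, nc, sep = ".")
  a <- fit$coef[idx]
  V <- fit$covariance[idx, idx, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    abort_numerical("covariance block is singular; consider fewer basis functions"))
  stat <- drop(t(a) %*% Vi %*% a)
  df <- length(idx)
  structure(
    list(statistic = c(`X-squared` = stat), parameter = c(df = df),
         p.value = stats::pchisq(stat, df, lower.tail = FALSE),
         method = "Wald test of time-varying effect (cluster-robust)",
         data.name = var),
    class = "htest"
  )
}

#' Predicted survival from a landmark
#'
#' Computes \eqn{\hat S_s(t_h \mid X(s), Z) = \exp\{-H_{s,0}(s + t_h)
#' \exp(x'\hat\beta(s) + z'\hat\theta)\}} using the Breslow cumulative
#' baseline hazard of the landmark's stratum, evaluated as a
#' right-continuous step function. `H_{s,0}(s) = 0`, so the probability at
#' horizon 0 is 1.
#'
#' @param fit A [fit_dpm()] result.
#' @param newdata data.frame with one row per patient holding the
#'   time-dependent covariate values current at `s` and the fixed
#'   covariates.
#' @param s Landmark time (months); the nearest fitted stratum's baseline
#'   is used (with a warning if not an exact match).
#' @param horizon Prediction horizon(s) `t_h >= 0` (months); either a
#'   single value or one per row of `newdata`.
#' @return Vector of survival probabilities in \[0, 1\].
#' @export
predict_survival <- function(fit, newdata, s, horizon) {
  stopifnot(inherits(fit, "dpm_fit"), length(s) == 1L)
  if (any(horizon < 0)) abort_data("horizon must be >= 0")
  need <- c(fit$td_vars, fit$fixed_vars)
  miss <- setdiff(need, names(newdata))
  if (length(miss)) {
    abort_data("newdata is missing covariate(s): %s", paste(miss, collapse = ", "))
  }
  ds <- abs(fit$landmarks - s)
  s_strat <- fit$landmarks[which.min(ds)]
  if (min(ds) > 1e-8) {
    warning(sprintf("no stratum at landmark %s; using nearest stratum %s",
                    format(s), format(s_strat)))
  }
  bh <- fit$baselines[[format_landmark(s_strat)]]
  B <- evaluate_basis(fit$basis, s)
  lp <- rep(0, nrow(newdata))
  for (v in fit$td_vars) {
    lp <- lp + newdata[[v]] * drop(B %*% fit$alpha[v, ])
  }
  if (length(fit$fixed_vars)) {
    lp <- lp + drop(as.matrix(newdata[, fit$fixed_vars, drop = FALSE]) %*% fit$theta)
  }
  H <- eval_cumhaz(bh, s + horizon)
  unname(pmin(pmax(exp(-H * exp(lp)), 0), 1))
}

#' @export
coef.dpm_fit <- function(object, ...) object$coef

#' @export
vcov.dpm_fit <- function(object, ...) object$covariance

#' @export
print.dpm_fit <- function(x, ...) {
  cat(sprintf(
    "Landmark DPM fit: %d rows, %d patients, %d events, %d strata\n",
    x$n_rows, x$n_patients, x$n_events, length(x$landmarks)))
  cat(sprintf("  time-dependent: %s (basis k = %d); fixed: %s\n",
              paste(x$td_vars, collapse = ", "), x$basis$k,
              if (length(x$fixed_vars)) paste(x$fixed_vars, collapse = ", ") else "none"))
  cat(sprintf("  log partial likelihood %.3f; %s ties; %s covariance\n",
              x$loglik, x$ties, if (x$robust) "cluster-robust" else "model-based"))
  invisible(x)
}

#' Serialize / restore a fitted DPM as JSON
#'
#' Writes basis specification, coefficients, covariance and per-landmark
#' baseline hazard step functions to a JSON document; `read_dpm()`
#' restores a `dpm_fit` usable for prediction, testing and calibration.
#'
#' @param fit A [fit_dpm()] result.
#' @param file Path to the JSON file.
#' @return `write_dpm()` the path invisibly; `read_dpm()` a `dpm_fit`.
#' @export
write_dpm <- function(fit, file) {
  stopifnot(inherits(fit, "dpm_fit"))
  doc <- list(
    package = "landmarkDPM", object = "dpm_fit",
    basis = list(family = fit$basis$family, nodes = fit$basis$nodes,
                 support_radius = fit$basis$support_radius,
                 include_constant = fit$basis$include_constant,
                 transform = fit$basis$transform),
    td_vars = fit$td_vars, fixed_vars = fit$fixed_vars,
    coef_names = names(fit$coef), coef = unname(fit$coef),
    covariance = fit$covariance, naive_covariance = fit$naive_covariance,
    landmarks = fit$landmarks, window = if (is.finite(fit$window)) fit$window else "Inf",
    ties = fit$ties, robust = fit$robust,
    n_rows = fit$n_rows, n_patients = fit$n_patients,
    n_events = fit$n_events, loglik = fit$loglik, iterations = fit$iterations,
    baselines = lapply(names(fit$baselines), function(nm) {
      bh <- fit$baselines[[nm]]
      list(landmark = nm, time = bh$time, increment = bh$increment)
    })
  )
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_dpm
#' @export
read_dpm <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(doc$object, "dpm_fit")) abort_data("'%s' is not a serialized dpm_fit", file)
  basis <- basis_spec(nodes = as.numeric(doc$basis$nodes),
                      support_radius = doc$basis$support_radius,
                      include_constant = doc$basis$include_constant,
                      family = doc$basis$family,
                      transform = if (length(doc$basis$transform)) {
                        as.matrix(doc$basis$transform)
                      })
  cf <- stats::setNames(as.numeric(doc$coef), doc$coef_names)
  td <- as.character(doc$td_vars)
  fx <- as.character(doc$fixed_vars %||% character(0))
  alpha <- matrix(cf[as.vector(outer(basis$names, td,
                                     function(b, v) paste(v, b, sep = ".")))],
                  nrow = length(td), ncol = basis$k, byrow = TRUE,
                  dimnames = list(td, basis$names))
  covariance <- matrix(as.numeric(unlist(doc$covariance)), length(cf), length(cf),
                       dimnames = list(doc$coef_names, doc$coef_names))
  naive <- matrix(as.numeric(unlist(doc$naive_covariance)), length(cf), length(cf),
                  dimnames = list(doc$coef_names, doc$coef_names))
  if (is.data.frame(doc$baselines)) {
    bl_list <- lapply(seq_len(nrow(doc$baselines)), function(i) {
      list(landmark = doc$baselines$landmark[i],
           time = doc$baselines$time[[i]],
           increment = doc$baselines$increment[[i]])
    })
  } else {
    bl_list <- doc$baselines
  }
  baselines <- list()
  for (b in bl_list) {
    tm <- as.numeric(b$time); inc <- as.numeric(b$increment)
    baselines[[as.character(b$landmark)]] <-
      data.frame(time = tm, increment = inc, cumhaz = cumsum(inc))
  }
  structure(
    list(alpha = alpha,
         theta = if (length(fx)) cf[fx] else stats::setNames(numeric(0), character(0)),
         coef = cf, covariance = covariance, naive_covariance = naive,
         baselines = baselines, basis = basis, td_vars = td, fixed_vars = fx,
         landmarks = as.numeric(doc$landmarks),
         window = if (identical(doc$window, "Inf")) Inf else as.numeric(doc$window),
         ties = doc$ties, robust = doc$robust, n_rows = doc$n_rows,
         n_patients = doc$n_patients, n_events = doc$n_events,
         loglik = doc$loglik, iterations = doc$iterations),
    class = "dpm_fit"
  )
}
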