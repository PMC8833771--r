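#' Configuration for the longitudinal cohort simulator
#'
#' Describes the data-generating world: fixed baseline covariates,
#' irregularly measured time-dependent markers, a visit process, dynamic
#' log hazard ratios, and independent censoring. Defaults emulate an
#' advanced-cancer cohort followed from start of first-line therapy: an
#' albumin-like continuous marker (g/dL) that drifts downward, an ordinal
#' performance-status-like marker on 0--4, roughly monthly clinic visits,
#' and covariate effects whose magnitude strengthens over the disease
#' course. Time is in months throughout.
#'
#' The hazard for patient i at time t is
#' \deqn{h_i(t) = h_0 \exp\{x_i(t)' \beta(t) + z_i' \theta\}}
#' where \eqn{x_i(t)} carries forward the latest recorded marker values
#' (a step function) and each component of \eqn{\beta(t)} is a polynomial
#' in t. Event times are drawn exactly by piecewise-exponential inversion
#' over the segments on which the hazard is constant (marker changes, and a
#' fine time grid when \eqn{\beta(t)} is non-constant).
#'
#' With `landmark_faithful = TRUE` visits fall exactly on integer months,
#' markers are constant within each month, and \eqn{\beta(t)} is evaluated
#' at the floor month, so the hazard is exactly constant on every month
#' interval. On such data a landmark model whose per-stratum follow-up is
#' capped at one month is correctly specified with estimand
#' \eqn{\beta(s)} -- the configuration used by the parameter-recovery tests.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer seed; the same (config, seed) pair reproduces the
#'   cohort exactly.
#' @param baseline_covariates Named list of distribution specs, each
#'   `list(dist = "normal", mean=, sd=)` or `list(dist = "bernoulli", prob=)`.
#' @param markers Named list of marker specs. Continuous:
#'   `list(kind = "continuous", init_mean=, init_sd=, drift=, noise_sd=)`
#'   giving value `init + drift * t + noise` at each visit. Ordinal:
#'   `list(kind = "ordinal", init_mean=, init_sd=, drift=, step_sd=,
#'   bounds = c(lo, hi))`, a latent Gaussian random walk rounded and
#'   clipped to `bounds`.
#' @param visit_gap_mean Mean of the exponential inter-visit gap (months);
#'   first visit at time 0.
#' @param effects Named list (one entry per marker) of polynomial
#'   coefficients for the dynamic log hazard ratio,
#'   `c(b0, b1, ...)` meaning `beta(s) = b0 + b1 s + ...`.
#' @param theta Named log hazard ratios for (a subset of) the baseline
#'   covariates.
#' @param baseline_hazard_rate Baseline hazard `h0` (events/month, > 0) at
#'   covariate value zero.
#' @param censoring_rate Independent exponential censoring rate
#'   (events/month, >= 0; 0 disables random censoring).
#' @param admin_censoring Administrative cutoff (months; `Inf` disables).
#' @param landmark_faithful Logical; see Details.
#' @param max_time Horizon for covariate paths when `admin_censoring` is
#'   infinite; beyond it the hazard is held at its last value.
#' @param beta_time_step Grid step (months) used to discretize a
#'   non-constant `beta(t)` in the general (non-faithful) mode.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 1000,
                          seed = 1L,
                          baseline_covariates = list(
                            age    = list(dist = "normal", mean = 68.2, sd = 9.6),
                            gender = list(dist = "bernoulli", prob = 0.463)
                          ),
                          markers = list(
                            albumin = list(kind = "continuous", init_mean = 3.7,
                                           init_sd = 0.5, drift = -0.02,
                                           noise_sd = 0.15),
                            ecog = list(kind = "ordinal", init_mean = 0.9,
                                        init_sd = 0.8, drift = 0.05,
                                        step_sd = 0.35, bounds = c(0, 4))
                          ),
                          visit_gap_mean = 1,
                          effects = list(
                            albumin = c(-log(1.72), -(log(2.33) - log(1.72)) / 12),
                            ecog    = c(log(1.38), (log(1.70) - log(1.38)) / 12)
                          ),
                          theta = c(age = 0.01, gender = -0.15),
                          baseline_hazard_rate = 0.206,
                          censoring_rate = 0.02,
                          admin_censoring = 36,
                          landmark_faithful = FALSE,
                          max_time = 60,
                          beta_time_step = 0.25) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1) {
    abort_config("n_patients must be a single integer >= 1")
  }
  for (nm in names(baseline_covariates)) {
    sp <- baseline_covariates[[nm]]
    if (is.null(sp$dist) || !sp$dist %in% c("normal", "bernoulli")) {
      abort_config("baseline covariate '%s': dist must be 'normal' or 'bernoulli'", nm)
    }
    if (sp$dist == "normal" && (is.null(sp$mean) || is.null(sp$sd) || sp$sd < 0)) {
      abort_config("baseline covariate '%s': normal spec needs mean and sd >= 0", nm)
    }
    if (sp$dist == "bernoulli" &&
        (is.null(sp$prob) || sp$prob < 0 || sp$prob > 1)) {
      abort_config("baseline covariate '%s': bernoulli spec needs prob in [0,1]", nm)
    }
  }
  for (nm in names(markers)) {
    sp <- markers[[nm]]
    if (is.null(sp$kind) || !sp$kind %in% c("continuous", "ordinal")) {
      abort_config("marker '%s': kind must be 'continuous' or 'ordinal'", nm)
    }
    if (sp$kind == "ordinal") {
      if (is.null(sp$bounds) || length(sp$bounds) != 2L || sp$bounds[1] >= sp$bounds[2]) {
        abort_config("marker '%s': ordinal bounds must be c(lo, hi) with lo < hi", nm)
      }
    }
  }
  if (!all(names(effects) %in% names(markers))) {
    bad <- setdiff(names(effects), names(markers))
    abort_config("effects given for unknown marker(s): %s", paste(bad, collapse = ", "))
  }
  if (length(theta) && !all(names(theta) %in% names(baseline_covariates))) {
    bad <- setdiff(names(theta), names(baseline_covariates))
    abort_config("theta given for unknown baseline covariate(s): %s",
                 paste(bad, collapse = ", "))
  }
  if (baseline_hazard_rate <= 0) abort_config("baseline_hazard_rate must be > 0")
  if (censoring_rate < 0) abort_config("censoring_rate must be >= 0")
  if (visit_gap_mean <= 0) abort_config("visit_gap_mean must be > 0")
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         baseline_covariates = baseline_covariates, markers = markers,
         visit_gap_mean = visit_gap_mean, effects = effects, theta = theta,
         baseline_hazard_rate = baseline_hazard_rate,
         censoring_rate = censoring_rate, admin_censoring = admin_censoring,
         landmark_faithful = isTRUE(landmark_faithful), max_time = max_time,
         beta_time_step = beta_time_step),
    class = "cohort_config"
  )
}

polyval <- function(coefs, s) {
  out <- 0
  for (j in rev(seq_along(coefs))) out <- out * s + coefs[j]
  out
}

#' Simulate a longitudinal survival cohort
#'
#' Draws fixed covariates, visit times, marker trajectories and survival /
#' censoring times from a [cohort_config()]. Both the observable data
#' (measurements truncated at the observed time) and the latent truth
#' (true event and censoring times) are retained so that downstream
#' estimators can be validated against the generating mechanism.
#'
#' @param config A [cohort_config()].
#' @return An object of class `c("simulated_cohort", "cohort")` with
#'   elements `patients` (one row per patient: fixed covariates,
#'   `true_event_time`, `censoring_time`, `observed_time`,
#'   `event_indicator`), `measurements` (long table `patient_id`,
#'   `time_months`, `variable`, `value`), `markers`, `fixed`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  h0 <- config$baseline_hazard_rate
  t_max <- if (is.finite(config$admin_censoring)) config$admin_censoring else config$max_time
  faithful <- config$landmark_faithful

  # fixed covariates
  zn <- names(config$baseline_covariates)
  Z <- matrix(0, n, length(zn), dimnames = list(NULL, zn))
  for (nm in zn) {
    sp <- config$baseline_covariates[[nm]]
    Z[, nm] <- if (sp$dist == "normal") stats::rnorm(n, sp$mean, sp$sd)
               else stats::rbinom(n, 1L, sp$prob)
  }
  theta_lp <- if (length(config$theta)) {
    drop(Z[, names(config$theta), drop = FALSE] %*% config$theta)
  } else rep(0, n)

  mk <- names(config$markers)
  beta_const <- all(vapply(mk, function(v) {
    length(config$effects[[v]] %||% 0) <= 1L
  }, logical(1)))

  ids <- sprintf("P%05d", seq_len(n))

  if (faithful) {
    # all patients share the integer-month visit grid: simulate as matrices
    M <- ceiling(t_max)
    months <- 0:M
    vals <- list()
    for (v in mk) {
      sp <- config$markers[[v]]
      if (sp$kind == "continuous") {
        x0 <- stats::rnorm(n, sp$init_mean, sp$init_sd)
        vals[[v]] <- outer(x0, (sp$drift %||% 0) * months, `+`) +
          matrix(stats::rnorm(n * (M + 1L), 0, sp$noise_sd %||% 0), n)
      } else {
        lat <- matrix(0, n, M + 1L)
        lat[, 1L] <- stats::rnorm(n, sp$init_mean, sp$init_sd %||% 0)
        steps <- matrix((sp$drift %||% 0) +
                          stats::rnorm(n * M, 0, sp$step_sd %||% 0), n, M)
        lat[, -1L] <- lat[, 1L] + t(apply(steps, 1L, cumsum))
        vals[[v]] <- pmin(pmax(round(lat), sp$bounds[1]), sp$bounds[2])
      }
    }
    # hazard constant on [m, m+1): uses marker value and beta at month m
    lp_td <- matrix(0, n, M + 1L)
    for (v in mk) {
      bcoef <- config$effects[[v]] %||% 0
      lp_td <- lp_td + vals[[v]] *
        matrix(polyval(bcoef, months), n, M + 1L, byrow = TRUE)
    }
    lambda <- h0 * exp(lp_td + theta_lp)        # n x (M + 1)
    cumh <- t(apply(lambda[, seq_len(M), drop = FALSE], 1L, cumsum))
    e_draw <- stats::rexp(n)
    seg <- rowSums(cumh < e_draw)               # segments fully traversed
    before <- ifelse(seg == 0L, 0, cumh[cbind(seq_len(n), pmax(seg, 1L))])
    rate <- lambda[cbind(seq_len(n), pmin(seg, M) + 1L)]
    t_event <- pmin(seg, M) + (e_draw - before) / rate
    c_rand <- if (config$censoring_rate > 0) stats::rexp(n, config$censoring_rate) else rep(Inf, n)
    t_cens <- pmin(c_rand, config$admin_censoring)
    obs <- pmin(t_event, t_cens)
    delta <- as.integer(t_event <= t_cens)

    nv <- pmin(floor(obs), M) + 1L              # visits at months 0..floor(obs)
    row_rep <- rep(seq_len(n), nv)
    time_m <- sequence(nv) - 1L
    meas_list <- lapply(mk, function(v) data.frame(
      patient_id = ids[row_rep], time_months = as.numeric(time_m),
      variable = v, value = vals[[v]][cbind(row_rep, time_m + 1L)],
      stringsAsFactors = FALSE))
    measurements <- do.call(rbind, meas_list)
    measurements <- measurements[order(measurements$patient_id,
                                       measurements$variable,
                                       measurements$time_months), , drop = FALSE]
    rownames(measurements) <- NULL
    patients <- cbind(data.frame(patient_id = ids, stringsAsFactors = FALSE),
                      as.data.frame(Z),
                      data.frame(true_event_time = t_event, censoring_time = t_cens,
                                 observed_time = obs, event_indicator = delta))
    return(structure(
      list(patients = patients, measurements = measurements,
           markers = mk, fixed = zn, config = config),
      class = c("simulated_cohort", "cohort")))
  }

  pat_rows <- vector("list", n)
  meas_rows <- vector("list", n)

  for (i in seq_len(n)) {
    # visit times
    if (faithful) {
      visits <- seq(0, ceiling(t_max))
    } else {
      gaps <- numeric(0)
      tt <- 0
      repeat {
        g <- stats::rexp(1, rate = 1 / config$visit_gap_mean)
        if (tt + g > t_max) break
        tt <- tt + g
        gaps <- c(gaps, g)
      }
      visits <- c(0, cumsum(gaps))
    }
    nv <- length(visits)

    # marker values at visits (step-function paths drive the hazard)
    vals <- matrix(0, nv, length(mk), dimnames = list(NULL, mk))
    for (v in mk) {
      sp <- config$markers[[v]]
      if (sp$kind == "continuous") {
        x0 <- stats::rnorm(1, sp$init_mean, sp$init_sd)
        vals[, v] <- x0 + (sp$drift %||% 0) * visits +
          stats::rnorm(nv, 0, sp$noise_sd %||% 0)
      } else {
        lat <- numeric(nv)
        lat[1] <- stats::rnorm(1, sp$init_mean, sp$init_sd %||% 0)
        if (nv > 1L) {
          dgap <- diff(visits)
          steps <- (sp$drift %||% 0) * dgap +
            stats::rnorm(nv - 1L, 0, (sp$step_sd %||% 0) * sqrt(dgap))
          lat[-1] <- lat[1] + cumsum(steps)
        }
        vals[, v] <- pmin(pmax(round(lat), sp$bounds[1]), sp$bounds[2])
      }
    }

    # hazard segments: constant between breakpoints
    if (faithful || beta_const) {
      breaks <- visits
    } else {
      breaks <- sort(unique(c(visits, seq(0, t_max, by = config$beta_time_step))))
    }
    idx <- findInterval(breaks, visits)           # latest visit at or before break
    s_eval <- if (faithful) floor(breaks + 1e-9) else breaks
    lp_td <- rep(0, length(breaks))
    for (v in mk) {
      bcoef <- config$effects[[v]] %||% 0
      lp_td <- lp_td + vals[idx, v] * polyval(bcoef, s_eval)
    }
    lambda <- h0 * exp(lp_td + theta_lp[i])
    dur <- diff(c(breaks, max(t_max, breaks[length(breaks)])))
    cumhaz <- cumsum(lambda * dur)
    e_draw <- stats::rexp(1)
    if (e_draw <= cumhaz[length(cumhaz)]) {
      m <- which(e_draw <= cumhaz)[1L]
      before <- if (m == 1L) 0 else cumhaz[m - 1L]
      t_event <- breaks[m] + (e_draw - before) / lambda[m]
    } else {
      # constant tail hazard beyond the path horizon
      t_event <- t_max + (e_draw - cumhaz[length(cumhaz)]) / lambda[length(lambda)]
    }

    c_rand <- if (config$censoring_rate > 0) stats::rexp(1, config$censoring_rate) else Inf
    t_cens <- min(c_rand, config$admin_censoring)
    obs <- min(t_event, t_cens)
    delta <- as.integer(t_event <= t_cens)

    keep <- visits <= obs
    meas_rows[[i]] <- data.frame(
      patient_id = rep(ids[i], sum(keep) * length(mk)),
      time_months = rep(visits[keep], times = length(mk)),
      variable = rep(mk, each = sum(keep)),
      value = as.vector(vals[keep, mk, drop = FALSE]),
      stringsAsFactors = FALSE
    )
    pat_rows[[i]] <- c(true_event_time = t_event, censoring_time = t_cens,
                       observed_time = obs, event_indicator = delta)
  }

  pat <- as.data.frame(do.call(rbind, pat_rows))
  patients <- cbind(data.frame(patient_id = ids, stringsAsFactors = FALSE),
                    as.data.frame(Z), pat)
  measurements <- do.call(rbind, meas_rows)
  rownames(measurements) <- NULL
  structure(
    list(patients = patients, measurements = measurements,
         markers = mk, fixed = zn, config = config),
    class = c("simulated_cohort", "cohort")
  )
}

#' @export
print.cohort <- function(x, ...) {
  ev <- mean(x$patients$event_indicator)
  cat(sprintf("Cohort: %d patients, %d measurements (%s), %.0f%% events\n",
              nrow(x$patients), nrow(x$measurements),
              paste(x$markers, collapse = ", "), 100 * ev))
  invisible(x)
}

#' Write / read a cohort as a pair of CSV files
#'
#' The patient table holds one row per patient (`patient_id`, fixed
#' covariates, `observed_time`, `event_indicator`, plus latent truth
#' columns when present); the measurement table is long format
#' (`patient_id`, `time_months`, `variable`, `value`). `read_cohort()`
#' accepts files produced by [write_cohort()] or user data with the same
#' schema; `read_cohort(write_cohort(x))` reproduces `x`'s tables exactly.
#'
#' @param cohort A cohort object.
#' @param patients_file,measurements_file CSV paths.
#' @param markers Optional character vector of expected marker names; an
#'   unexpected `variable` in the measurement table raises a schema error.
#' @return `write_cohort()` returns the two paths invisibly;
#'   `read_cohort()` returns an object of class `cohort`.
#' @export
write_cohort <- function(cohort, patients_file, measurements_file) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.csv(cohort$patients, patients_file, row.names = FALSE)
  utils::write.csv(cohort$measurements, measurements_file, row.names = FALSE)
  invisible(c(patients_file, measurements_file))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(patients_file, measurements_file, markers = NULL) {
  patients <- utils::read.csv(patients_file, stringsAsFactors = FALSE)
  measurements <- utils::read.csv(measurements_file, stringsAsFactors = FALSE)
  need_p <- c("patient_id", "observed_time", "event_indicator")
  miss <- setdiff(need_p, names(patients))
  if (length(miss)) {
    abort_data("patient table is missing required column(s): %s",
               paste(miss, collapse = ", "))
  }
  need_m <- c("patient_id", "time_months", "variable", "value")
  miss <- setdiff(need_m, names(measurements))
  if (length(miss)) {
    abort_data("measurement table is missing required column(s): %s",
               paste(miss, collapse = ", "))
  }
  seen <- unique(measurements$variable)
  if (!is.null(markers)) {
    unknown <- setdiff(seen, markers)
    if (length(unknown)) {
      abort_data("measurement table contains unknown variable(s): %s",
                 paste(unknown, collapse = ", "))
    }
  }
  patients$patient_id <- as.character(patients$patient_id)
  measurements$patient_id <- as.character(measurements$patient_id)
  reserved <- c(need_p, "true_event_time", "censoring_time")
  structure(
    list(patients = patients, measurements = measurements,
         markers = markers %||% seen,
         fixed = setdiff(names(patients), reserved),
         config = NULL),
    class = "cohort"
  )
}
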