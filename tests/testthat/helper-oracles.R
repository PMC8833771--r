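# Independent reference implementations used as oracles. These are kept
# deliberately naive (explicit loops over risk sets / pairs) and share no
# code with the package internals they check.

# Newton-Raphson maximizer of the left-truncated Cox partial likelihood
# with Breslow tie handling, plus the Breslow baseline and the inverse
# information as model-based covariance.
oracle_coxph <- function(start, stop, event, X, iter = 30, tol = 1e-12) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- rep(0, p)
  ev_times <- sort(unique(stop[event == 1]))
  I <- diag(p)
  for (it in seq_len(iter)) {
    elp <- exp(drop(X %*% beta))
    U <- rep(0, p)
    I <- matrix(0, p, p)
    for (tj in ev_times) {
      risk <- which(start < tj & stop >= tj)
      dset <- which(stop == tj & event == 1)
      w <- elp[risk]
      sw <- sum(w)
      xbar <- colSums(X[risk, , drop = FALSE] * w) / sw
      d <- length(dset)
      U <- U + colSums(X[dset, , drop = FALSE]) - d * xbar
      xx <- crossprod(X[risk, , drop = FALSE] * sqrt(w)) / sw
      I <- I + d * (xx - tcrossprod(xbar))
    }
    step <- solve(I, U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  elp <- exp(drop(X %*% beta))
  inc <- vapply(ev_times, function(tj) {
    sum(stop == tj & event == 1) / sum(elp[start < tj & stop >= tj])
  }, numeric(1))
  list(coef = beta, vcov = solve(I),
       baseline = data.frame(time = ev_times, increment = inc,
                             cumhaz = cumsum(inc)))
}

# Brute-force double-loop IPCW AUC over (case, control) pairs: cases are
# subjects with time <= s + horizon and an event, weighted by the inverse
# censoring survival at their own time; controls have time > s + horizon,
# weighted by the inverse censoring survival at s + horizon. Pairs score
# 1 / 0.5 / 0 by comparing predicted survival, lower = riskier.
oracle_ipcw_auc <- function(pred, time, event, s, horizon, sc_at_T, sc_at_tau) {
  tau <- s + horizon
  n <- length(pred)
  num <- 0
  w_case_tot <- 0
  w_ctrl_tot <- 0
  for (i in seq_len(n)) {
    if (time[i] <= tau && event[i] == 1) {
      wi <- 1 / sc_at_T[i]
      w_case_tot <- w_case_tot + wi
      for (j in seq_len(n)) {
        if (time[j] > tau) {
          wj <- 1 / sc_at_tau[j]
          sc <- as.numeric(pred[i] < pred[j]) + 0.5 * as.numeric(pred[i] == pred[j])
          num <- num + wi * wj * sc
        }
      }
    }
  }
  for (j in seq_len(n)) if (time[j] > tau) w_ctrl_tot <- w_ctrl_tot + 1 / sc_at_tau[j]
  num / (w_case_tot * w_ctrl_tot)
}

# Unweighted Mann-Whitney AUC with half credit for ties (classical
# empirical AUC), brute force.
oracle_mann_whitney <- function(pred, is_case, is_ctrl) {
  num <- 0
  for (i in which(is_case)) {
    for (j in which(is_ctrl)) {
      num <- num + as.numeric(pred[i] < pred[j]) + 0.5 * as.numeric(pred[i] == pred[j])
    }
  }
  num / (sum(is_case) * sum(is_ctrl))
}

# Brute-force landmark row count: double loop over landmarks and patients.
oracle_landmark_rows <- function(cohort, landmarks, td_vars, max_staleness = Inf) {
  n <- 0L
  for (s in landmarks) {
    for (i in seq_len(nrow(cohort$patients))) {
      if (cohort$patients$observed_time[i] <= s) next
      pid <- cohort$patients$patient_id[i]
      ok <- TRUE
      for (v in td_vars) {
        m <- cohort$measurements
        tms <- m$time_months[m$patient_id == pid & m$variable == v & m$time_months <= s]
        if (length(tms) == 0L || s - max(tms) > max_staleness) ok <- FALSE
      }
      if (ok) n <- n + 1L
    }
  }
  n
}
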