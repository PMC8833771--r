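#' Build the stacked landmark dataset
#'
#' For every landmark `s` in `landmarks` and every patient still at risk
#' (`observed_time > s`), emits one row carrying the patient's fixed
#' covariates and, for each time-dependent variable, the most recent
#' measurement taken at or before `s` (last observation carried forward).
#' When several measurements fall within the month ending at `s`, the
#' latest is used -- a consequence of taking the most recent value overall.
#' Patients with no measurement of some requested variable at or before
#' `s`, or whose most recent value is staler than `max_staleness`, are
#' omitted from that landmark.
#'
#' @param cohort A cohort object ([simulate_cohort()] or [read_cohort()]).
#' @param landmarks Increasing vector of nonnegative landmark times
#'   (months); default `0:12`.
#' @param td_vars Time-dependent variables to carry (default: all markers
#'   in the cohort).
#' @param fixed_vars Fixed covariates to carry (default: all).
#' @param max_staleness Maximum age (months) of a carried-forward value;
#'   `Inf` (default) never drops stale values.
#' @return A data.frame of class `landmark_dataset` with columns
#'   `patient_id`, `landmark_s`, `observed_time`, `event_indicator`, the
#'   fixed covariates, the time-dependent values current at `s`, and one
#'   `staleness_<var>` column per time-dependent variable. Attributes
#'   `landmarks`, `td_vars`, `fixed_vars` record the construction.
#' @export
build_landmark_dataset <- function(cohort, landmarks = 0:12, td_vars = NULL,
                                   fixed_vars = NULL, max_staleness = Inf) {
  stopifnot(inherits(cohort, "cohort"))
  landmarks <- as.numeric(landmarks)
  if (length(landmarks) == 0L) abort_config("landmark grid must be nonempty")
  if (any(landmarks < 0) || is.unsorted(landmarks, strictly = TRUE)) {
    abort_config("landmarks must be nonnegative and strictly increasing")
  }
  td_vars <- td_vars %||% cohort$markers
  fixed_vars <- fixed_vars %||% cohort$fixed
  miss <- setdiff(fixed_vars, names(cohort$patients))
  if (length(miss)) {
    abort_data("fixed covariate(s) absent from patient table: %s",
               paste(miss, collapse = ", "))
  }
  for (v in td_vars) {
    if (!any(cohort$measurements$variable == v)) {
      abort_data("time-dependent variable '%s' has no measurements for any patient", v)
    }
  }

  pat <- cohort$patients
  # per-variable measurement tables sorted by (patient, time); the latest
  # value at or before s is then the last non-duplicated patient row of the
  # time-filtered table
  series <- lapply(td_vars, function(v) {
    mv <- cohort$measurements[cohort$measurements$variable == v, , drop = FALSE]
    mv[order(mv$patient_id, mv$time_months), c("patient_id", "time_months", "value")]
  })
  names(series) <- td_vars

  out <- vector("list", length(landmarks))
  for (li in seq_along(landmarks)) {
    s <- landmarks[li]
    at_risk <- pat[pat$observed_time > s, , drop = FALSE]
    if (nrow(at_risk) == 0L) next
    vals <- matrix(NA_real_, nrow(at_risk), length(td_vars),
                   dimnames = list(NULL, td_vars))
    stal <- vals
    for (v in td_vars) {
      mv <- series[[v]]
      sub <- mv[mv$time_months <= s, , drop = FALSE]
      if (nrow(sub) == 0L) next
      last <- sub[!duplicated(sub$patient_id, fromLast = TRUE), , drop = FALSE]
      m <- match(at_risk$patient_id, last$patient_id)
      ok <- !is.na(m)
      vals[ok, v] <- last$value[m[ok]]
      stal[ok, v] <- s - last$time_months[m[ok]]
    }
    keep <- rowSums(is.na(vals)) == 0L & rowSums(stal > max_staleness, na.rm = TRUE) == 0L
    if (!any(keep)) next
    block <- data.frame(
      patient_id = at_risk$patient_id[keep],
      landmark_s = s,
      observed_time = at_risk$observed_time[keep],
      event_indicator = at_risk$event_indicator[keep],
      stringsAsFactors = FALSE
    )
    for (v in fixed_vars) block[[v]] <- at_risk[[v]][keep]
    for (v in td_vars) block[[v]] <- vals[keep, v]
    for (v in td_vars) block[[paste0("staleness_", v)]] <- stal[keep, v]
    out[[li]] <- block
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    abort_data("no patient is at risk (with usable measurements) at any landmark")
  }
  rownames(res) <- NULL
  structure(res, landmarks = landmarks, td_vars = td_vars,
            fixed_vars = fixed_vars, max_staleness = max_staleness,
            class = c("landmark_dataset", "data.frame"))
}

#' Patient-level train/validation split
#'
#' @param cohort A cohort object.
#' @param train_fraction Fraction of patients assigned to the training set
#'   (default 2/3); the training size is `round(train_fraction * n)`.
#' @param seed Integer seed; the same seed reproduces the partition.
#' @return A list with character vectors `train` and `validation`
#'   (disjoint, exhaustive).
#' @export
split_patients <- function(cohort, train_fraction = 2 / 3, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort_config("train_fraction must be strictly between 0 and 1")
  }
  ids <- cohort$patients$patient_id
  n <- length(ids)
  if (n < 2L) abort_data("need at least 2 patients to split")
  set.seed(seed)
  n_train <- round(train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  train <- sort(sample(ids, n_train))
  list(train = train, validation = sort(setdiff(ids, train)))
}

#' Restrict a cohort to a set of patients
#'
#' @param cohort A cohort object.
#' @param ids Patient identifiers to keep.
#' @return A cohort of the same class containing only those patients.
#' @export
subset_cohort <- function(cohort, ids) {
  stopifnot(inherits(cohort, "cohort"))
  out <- cohort
  out$patients <- cohort$patients[cohort$patients$patient_id %in% ids, , drop = FALSE]
  out$measurements <- cohort$measurements[
    cohort$measurements$patient_id %in% ids, , drop = FALSE]
  rownames(out$patients) <- rownames(out$measurements) <- NULL
  out
}

#' Write a landmark dataset to CSV
#'
#' @param data A `landmark_dataset`.
#' @param file Output path.
#' @export
write_landmark_dataset <- function(data, file) {
  stopifnot(inherits(data, "landmark_dataset"))
  utils::write.csv(as.data.frame(data), file, row.names = FALSE)
  invisible(file)
}
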