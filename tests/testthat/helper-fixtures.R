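# Hand-built cohort objects for exactly controlled landmarking tests.
make_cohort <- function(patients, measurements, markers = NULL, fixed = NULL) {
  structure(
    list(patients = patients, measurements = measurements,
         markers = markers %||% unique(measurements$variable),
         fixed = fixed %||% setdiff(names(patients),
                                    c("patient_id", "observed_time",
                                      "event_indicator", "true_event_time",
                                      "censoring_time")),
         config = NULL),
    class = "cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

meas <- function(pid, times, values, var = "m") {
  data.frame(patient_id = pid, time_months = times, variable = var,
             value = values, stringsAsFactors = FALSE)
}
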