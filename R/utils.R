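# Internal condition constructors. The CLI maps these classes onto exit
# codes (config -> 2, data -> 3, numerical -> 4), so raise them instead of
# bare stop() wherever a user-facing cause is identifiable.

abort_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("landmarkDPM_config_error", "landmarkDPM_error")))
}

abort_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("landmarkDPM_data_error", "landmarkDPM_error")))
}

abort_numerical <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("landmarkDPM_numerical_error", "landmarkDPM_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Step-function evaluation of a cumulative hazard stored as
# data.frame(time, cumhaz): right-continuous, 0 before the first event.
eval_cumhaz <- function(bh, t) {
  if (is.null(bh) || nrow(bh) == 0L) return(rep(0, length(t)))
  idx <- findInterval(t, bh$time)
  c(0, bh$cumhaz)[idx + 1L]
}
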