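# Clinical alarm policy: 0.5 probability threshold, three-consecutive-window
# confirmation, 30-minute refractory period, lead-time validation (alarms
# under 5 minutes before onset are discarded as giving insufficient
# intervention time; 20 minutes or more counts as a successful early
# warning) and false-alarms-per-hour reporting.

#' Build a window probability trace
#'
#' @param window_start_s ascending window start times, seconds.
#' @param p_preictal predicted preictal probabilities in \[0, 1\].
#' @param step_s sliding step between windows (default 32).
#' @return a `probability_trace` data frame.
#' @export
probability_trace <- function(window_start_s, p_preictal, step_s = 32) {
  stopifnot(length(window_start_s) == length(p_preictal),
            all(p_preictal >= 0 & p_preictal <= 1))
  if (length(window_start_s) > 1 && any(diff(window_start_s) <= 0)) {
    stop("window starts must be strictly ascending", call. = FALSE)
  }
  structure(data.frame(window_start_s = window_start_s,
                       p_preictal = p_preictal),
            step_s = step_s, class = c("probability_trace", "data.frame"))
}

#' Raise alarms from a probability trace
#'
#' An alarm fires when `confirm` consecutive windows reach the threshold
#' (boundary inclusive); its timestamp is the decision-availability time,
#' the end of the confirming window (`start + window_s`). After an alarm no
#' further alarm fires for `refractory_s` seconds, and the consecutive count
#' restarts. The policy is pure: the same trace always yields the same
#' alarms.
#'
#' @param trace a [probability_trace()] (or data frame with
#'   `window_start_s`, `p_preictal`).
#' @param threshold probability threshold (default 0.5).
#' @param confirm consecutive suprathreshold windows required (default 3).
#' @param refractory_s refractory period in seconds (default 1800).
#' @param window_s window length in seconds (default 64).
#' @return numeric vector of alarm times in seconds.
#' @export
raise_alarms <- function(trace, threshold = 0.5, confirm = 3,
                         refractory_s = 1800, window_s = 64) {
  if (nrow(trace) == 0) return(numeric(0))
  alarms <- numeric(0)
  run <- 0L
  blocked_until <- -Inf
  for (i in seq_len(nrow(trace))) {
    t_dec <- trace$window_start_s[i] + window_s
    if (trace$p_preictal[i] >= threshold) {
      run <- run + 1L
      if (run >= confirm && t_dec >= blocked_until) {
        alarms <- c(alarms, t_dec)
        blocked_until <- t_dec + refractory_s
        run <- 0L
      }
    } else {
      run <- 0L
    }
  }
  alarms
}

#' Categorise alarms against seizure onsets
#'
#' For each alarm, the lead time is the interval to the next onset at or
#' after it. Leads under 5 minutes are discarded (insufficient intervention
#' time); leads of at least 20 minutes that fall within the association
#' horizon are early warnings; leads in between are late warnings; alarms
#' with no onset inside the horizon are false alarms.
#'
#' @param alarms alarm times in seconds (sorted).
#' @param onsets seizure onset times in seconds (sorted).
#' @param discard_s lower lead-time cutoff (default 300).
#' @param early_s successful early-warning lead (default 1200).
#' @param horizon_s maximum lead for which an alarm is associated with an
#'   onset at all; default 3000 (the 20-minute labelling horizon plus the
#'   30-minute refractory period).
#' @return list with `events` (data frame `time_s`, `lead_time_s`,
#'   `category`) and `summary` (category counts).
#' @export
score_alarms <- function(alarms, onsets, discard_s = 300, early_s = 1200,
                         horizon_s = 3000) {
  category <- character(length(alarms))
  lead <- numeric(length(alarms))
  for (i in seq_along(alarms)) {
    nxt <- onsets[onsets >= alarms[i]]
    lead[i] <- if (length(nxt)) min(nxt) - alarms[i] else Inf
    category[i] <-
      if (lead[i] > horizon_s) "false_alarm"
      else if (lead[i] < discard_s) "discarded"
      else if (lead[i] < early_s) "late_warning"
      else "early_warning"
  }
  events <- data.frame(time_s = alarms, lead_time_s = lead,
                       category = category)
  summary <- c(n_alarms = length(alarms),
               n_early = sum(category == "early_warning"),
               n_late = sum(category == "late_warning"),
               n_false = sum(category == "false_alarm"),
               n_discarded = sum(category == "discarded"))
  list(events = events, summary = summary)
}

#' False alarms per hour
#'
#' @param events the `events` data frame from [score_alarms()].
#' @param interictal_hours monitored interictal duration in hours (> 0).
#' @return false alarms per hour.
#' @export
false_alarm_rate <- function(events, interictal_hours) {
  if (!is.numeric(interictal_hours) || interictal_hours <= 0) {
    stop("interictal_hours must be positive", call. = FALSE)
  }
  sum(events$category == "false_alarm") / interictal_hours
}
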