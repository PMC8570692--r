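#' Detect stimulus-locked spikes after light pulses
#'
#' For each pulse, finds the latency of the first spike inside the
#' response window after pulse onset. Reliability is the fraction of
#' pulses followed by at least one spike in the window.
#'
#' @param spike_times sorted spike timestamps, s.
#' @param pulse_times sorted pulse-onset timestamps, s.
#' @param response_window_ms response window after pulse onset, ms
#'   (default `c(0, 15)`).
#' @param check_overlap error if consecutive pulses are closer than the
#'   window length (ambiguous attribution); disabled for spike-triggered
#'   collision pulses, which are attributed individually.
#' @return An object of class `evoked_spikes`: data frame with
#'   `pulse_time` and `latency_ms` (`NA` when no spike fell in the
#'   window); attribute `reliability`.
#' @examples
#' pulses <- (1:100) * 0.5
#' spikes <- pulses + 0.005
#' ev <- detect_evoked_spikes(spikes, pulses)
#' attr(ev, "reliability")  # 1
#' @export
detect_evoked_spikes <- function(spike_times, pulse_times,
                                 response_window_ms = c(0, 15),
                                 check_overlap = TRUE) {
  check_window(response_window_ms, "response_window_ms")
  check_sorted_times(spike_times, "spike_times")
  check_sorted_times(pulse_times, "pulse_times")
  w <- response_window_ms / 1000
  if (check_overlap && length(pulse_times) > 1L &&
      min(diff(pulse_times)) < (w[2] - w[1]) - 1e-12) {
    stop_invalid("pulses overlap given the response window; shorten the window")
  }
  lat <- rep(NA_real_, length(pulse_times))
  if (length(spike_times) > 0L && length(pulse_times) > 0L) {
    first_after <- findInterval(pulse_times + w[1], spike_times,
                                left.open = TRUE) + 1L
    has <- first_after <= length(spike_times)
    t_first <- ifelse(has, spike_times[pmin(first_after, length(spike_times))],
                      Inf)
    hit <- (t_first - pulse_times) < w[2]
    lat[hit] <- (t_first[hit] - pulse_times[hit]) * 1000
  }
  out <- data.frame(pulse_time = pulse_times, latency_ms = lat)
  attr(out, "reliability") <- if (length(pulse_times) > 0L) mean(!is.na(lat))
    else NA_real_
  class(out) <- c("evoked_spikes", "data.frame")
  out
}

#' Collision test for antidromic activation
#'
#' When terminal stimulation is triggered immediately after a spontaneous
#' spike, a genuine antidromic spike collides with the outgoing
#' orthodromic spike in the axon and never reaches the soma — so an
#' identified projection neuron shows no stimulus-locked spikes on
#' spike-triggered pulses. A unit passes when the fraction of triggered
#' pulses that still evoke a spike is at or below `max_evoked_fraction`
#' (default 10%, a chance-level allowance for coincident spontaneous
#' spikes).
#'
#' @param spike_times sorted spike timestamps, s.
#' @param triggered_pulse_times pulse onsets that were triggered by
#'   spontaneous spikes, s.
#' @param response_window_ms evoked-spike window, ms.
#' @param max_evoked_fraction pass bound on the evoked fraction.
#' @return List: `tested` (FALSE when no triggered pulses were delivered),
#'   `pass`, `evoked_fraction`, `n_pulses`, and the per-pulse
#'   `evoked` outcomes.
#' @export
collision_test <- function(spike_times, triggered_pulse_times,
                           response_window_ms = c(0, 15),
                           max_evoked_fraction = 0.10) {
  check_number(max_evoked_fraction, "max_evoked_fraction", lower = 0, upper = 1)
  if (length(triggered_pulse_times) == 0L) {
    return(list(tested = FALSE, pass = NA, evoked_fraction = NA_real_,
                n_pulses = 0L, evoked = logical(0)))
  }
  ev <- detect_evoked_spikes(spike_times, sort(triggered_pulse_times),
                             response_window_ms, check_overlap = FALSE)
  evoked <- !is.na(ev$latency_ms)
  frac <- mean(evoked)
  list(tested = TRUE, pass = frac <= max_evoked_fraction,
       evoked_fraction = frac, n_pulses = length(evoked), evoked = evoked)
}

#' Optotag inclusion decision
#'
#' A unit is identified as a projection neuron when its median first-spike
#' latency over the identification protocol is strictly below
#' `max_latency_ms` (15 ms), it spiked in response to at least
#' `min_reliability` (70%) of all pulses, and — when a collision test was
#' performed — it passed that test. Units without a collision test are
#' decided on latency and reliability alone.
#'
#' @param median_latency_ms median first-spike latency, ms.
#' @param reliability fraction of pulses with an evoked spike.
#' @param collision_tested was a collision test performed?
#' @param collision_pass did the unit pass it (ignored when untested)?
#' @param max_latency_ms,min_reliability identification thresholds.
#' @return Logical: tagged?
#' @examples
#' tag_decision(5, 0.90, TRUE, TRUE)    # TRUE
#' tag_decision(20, 0.95, FALSE, NA)    # FALSE: too slow
#' tag_decision(5, 0.69, FALSE, NA)     # FALSE: unreliable
#' @export
tag_decision <- function(median_latency_ms, reliability,
                         collision_tested = FALSE, collision_pass = NA,
                         max_latency_ms = 15, min_reliability = 0.70) {
  if (is.na(reliability)) return(FALSE)
  if (reliability > 0 && is.na(median_latency_ms)) return(FALSE)
  ok <- reliability >= min_reliability &&
    !is.na(median_latency_ms) && median_latency_ms < max_latency_ms
  if (ok && isTRUE(collision_tested)) ok <- isTRUE(collision_pass)
  ok
}

#' Full optotag characterization of one unit
#'
#' Runs evoked-spike detection on the identification protocol (the
#' untriggered pulses), the collision test on spike-triggered pulses, and
#' the tag decision.
#'
#' The collision test looks for the stimulus-locked spike in a narrow
#' window centered on the unit's own median evoked latency (half-width
#' the larger of 1.5 ms and three times the measured latency jitter,
#' clipped to the response window), not the full response window. The
#' evoked latency is known from the identification protocol, so a
#' collided (absent) antidromic spike is distinguished from chance
#' spontaneous spikes elsewhere in the window; with the full window,
#' baseline firing alone (rate x 15 ms) would approach the pass bound.
#'
#' @param spike_times sorted spike timestamps, s.
#' @param pulses data frame with `pulse_time`, `triggered` (logical), and
#'   `trigger_spike_time` — as produced by [simulate_unit()], or read from
#'   `pulses.csv`.
#' @param response_window_ms evoked-spike window, ms.
#' @param max_evoked_fraction collision-test pass bound.
#' @param ... thresholds passed to [tag_decision()].
#' @return One-row data frame of class `optotag_result`:
#'   `median_latency_ms`, `latency_jitter_ms` (SD of first-spike
#'   latencies), `reliability`, `n_pulses`, `collision_tested`,
#'   `collision_pass`, `tagged`.
#' @export
optotag_unit <- function(spike_times, pulses,
                         response_window_ms = c(0, 15),
                         max_evoked_fraction = 0.10, ...) {
  if (!all(c("pulse_time", "triggered") %in% names(pulses))) {
    stop_invalid("`pulses` must have columns pulse_time and triggered")
  }
  proto <- sort(pulses$pulse_time[!pulses$triggered])
  ev <- detect_evoked_spikes(spike_times, proto, response_window_ms)
  lat <- ev$latency_ms[!is.na(ev$latency_ms)]
  reliability <- attr(ev, "reliability")
  med_lat <- if (length(lat) > 0L) stats::median(lat) else NA_real_
  jitter <- if (length(lat) > 1L) stats::sd(lat) else NA_real_
  col_window <- if (!is.na(med_lat)) {
    half <- max(1.5, if (is.na(jitter)) 0 else 3 * jitter)
    c(max(response_window_ms[1], med_lat - half),
      min(response_window_ms[2], med_lat + half))
  } else {
    response_window_ms
  }
  col <- collision_test(spike_times, pulses$pulse_time[pulses$triggered],
                        col_window, max_evoked_fraction)
  tagged <- tag_decision(med_lat, reliability,
                         collision_tested = col$tested,
                         collision_pass = col$pass, ...)
  out <- data.frame(
    median_latency_ms = med_lat, latency_jitter_ms = jitter,
    reliability = reliability, n_pulses = length(proto),
    collision_tested = col$tested,
    collision_pass = if (col$tested) col$pass else NA,
    tagged = tagged
  )
  class(out) <- c("optotag_result", "data.frame")
  out
}
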