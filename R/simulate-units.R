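#' Specification of a synthetic single unit
#'
#' Parameters of one simulated neuron: an inhomogeneous Poisson spike train
#' whose rate is `baseline_rate` outside cue periods and
#' `baseline_rate * (1 + cue_gain * sucrose_prop) * group_gain` during the
#' odor + trace-delay window of sucrose/denatonium/mixture trials
#' (`group_gain` applies only in the air-puff group; odors C and D leave
#' the rate at baseline). Optionally the unit responds to the optogenetic
#' identification protocol with short-latency stimulus-locked spikes, and
#' behaves antidromically in collision tests: a light pulse falling within
#' `collision_window_ms` after a spontaneous spike evokes nothing, because
#' the antidromic spike collides with the orthodromic one in the axon.
#'
#' @param unit_id integer unit identifier (also seeds the unit's private
#'   RNG stream).
#' @param baseline_rate spontaneous firing rate, spikes/s (> 0).
#' @param cue_gain slope of the multiplicative cue modulation in the
#'   sucrose-odor proportion (0 = unresponsive; may be negative for
#'   suppressed units, the rate is clamped at 0).
#' @param group_gain multiplicative cue-period factor applied in the
#'   air-puff group (hyperactivity of an aversive history when > 1).
#' @param tagged does the unit emit stimulus-locked spikes to light?
#' @param tag_latency_ms mean first-spike latency after a pulse, ms (> 0).
#' @param tag_jitter_ms Gaussian SD of the evoked latency, ms.
#' @param tag_reliability probability that a pulse evokes a spike, in
#'   [0, 1].
#' @param antidromic collision behavior: `TRUE` suppresses evoked spikes
#'   whenever a spontaneous spike precedes the pulse within the collision
#'   window (a genuine projection neuron); `FALSE` mimics orthodromic
#'   activation through local synapses, which survives the collision test.
#' @param refractory absolute refractory period, s (default 0.0025): spikes
#'   closer than this to the preceding spike are removed, and the
#'   generating intensity is dead-time corrected (`lambda = r / (1 - r *
#'   refractory)`) so the observed rate still equals the configured rate.
#' @param collision_window_ms collision window, ms; default
#'   `tag_latency_ms + 3` (the antidromic and orthodromic spikes must meet
#'   within roughly the conduction latency).
#' @param n_collision_trials number of spike-triggered pulses delivered in
#'   the collision-test epoch (0 = collision test not performed).
#' @return A list of class `unit_spec`.
#' @export
unit_spec <- function(unit_id,
                      baseline_rate = 5.0,
                      cue_gain = 0.0,
                      group_gain = 1.0,
                      tagged = FALSE,
                      tag_latency_ms = 4.0,
                      tag_jitter_ms = 0.5,
                      tag_reliability = 0.9,
                      antidromic = TRUE,
                      collision_window_ms = NULL,
                      n_collision_trials = 100L,
                      refractory = 0.0025) {
  if (missing(unit_id) || !is.numeric(unit_id) || length(unit_id) != 1L) {
    stop_invalid("`unit_id` must be a single integer")
  }
  check_number(baseline_rate, "baseline_rate", positive = TRUE)
  check_number(cue_gain, "cue_gain")
  check_number(group_gain, "group_gain", lower = 0)
  check_number(tag_latency_ms, "tag_latency_ms", positive = TRUE)
  check_number(tag_jitter_ms, "tag_jitter_ms", lower = 0)
  check_number(tag_reliability, "tag_reliability", lower = 0, upper = 1)
  if (is.null(collision_window_ms)) collision_window_ms <- tag_latency_ms + 3
  check_number(collision_window_ms, "collision_window_ms", positive = TRUE)
  check_number(refractory, "refractory", lower = 0)
  if (!is.numeric(n_collision_trials) || n_collision_trials < 0 ||
      n_collision_trials != round(n_collision_trials)) {
    stop_invalid("`n_collision_trials` must be a non-negative integer")
  }
  structure(
    list(unit_id = as.integer(unit_id), baseline_rate = baseline_rate,
         cue_gain = cue_gain, group_gain = group_gain,
         tagged = isTRUE(tagged), tag_latency_ms = tag_latency_ms,
         tag_jitter_ms = tag_jitter_ms, tag_reliability = tag_reliability,
         antidromic = isTRUE(antidromic),
         collision_window_ms = collision_window_ms,
         n_collision_trials = as.integer(n_collision_trials),
         refractory = refractory),
    class = "unit_spec"
  )
}

# Expected cue-period rate per trial row for a unit spec.
unit_cue_rate <- function(trials, spec) {
  p <- trials$sucrose_prop
  rate <- rep(spec$baseline_rate, nrow(trials))
  cue <- !is.na(p)
  mod <- spec$baseline_rate * (1 + spec$cue_gain * p[cue])
  if (any(trials$group[cue] == "air_puff")) {
    mod <- mod * ifelse(trials$group[cue] == "air_puff", spec$group_gain, 1)
  }
  rate[cue] <- pmax(mod, 0)
  rate
}

#' Simulate one unit's spike train and light-pulse protocol
#'
#' Generates an inhomogeneous Poisson spike train over one session: the
#' rate is piecewise constant, at baseline between trials and at the
#' cue-modulated rate during each trial's odor + trace-delay window. After
#' the session the optogenetic identification epoch is appended: 10 trains
#' of 10 pulses at 10 Hz with 10 s between train onsets (100 pulses
#' total), each pulse evoking a stimulus-locked spike at
#' `tag_latency_ms` plus Gaussian jitter with probability
#' `tag_reliability` for tagged units. If `n_collision_trials > 0`, a
#' collision-test epoch follows in which single pulses are triggered 1 ms
#' after spontaneous spikes; for antidromic units these pulses evoke
#' nothing (the orthodromic spike collides with the antidromic one),
#' whereas orthodromic-like units keep responding.
#'
#' @param trials trial table rows of a single session (the spike clock is
#'   the session clock).
#' @param spec a [unit_spec()].
#' @param seed optional integer seed; the default derives a per-unit seed
#'   from the trial table's configuration seed and `unit_id`, so a unit's
#'   spikes do not depend on which other units are simulated.
#' @return A list of class `unit_recording`: `unit_id`, `spikes` (sorted
#'   timestamps, s), `pulses` (data frame `pulse_time`, `triggered`,
#'   `trigger_spike_time`), `session`, and the `spec`.
#' @examples
#' trials <- generate_trial_table(task_config(n_conditioning = 1, n_reversal = 0))
#' rec <- simulate_unit(trials, unit_spec(1, cue_gain = 1, tagged = TRUE))
#' sum(!rec$pulses$triggered)  # 100-pulse identification protocol
#' @export
simulate_unit <- function(trials, spec, seed = NULL) {
  if (!inherits(spec, "unit_spec")) stop_invalid("`spec` must be a unit_spec")
  if (nrow(trials) == 0L) stop_invalid("`trials` must be non-empty")
  if (length(unique(trials$session)) != 1L) {
    stop_invalid(paste("`trials` must contain a single session:",
                       "spike timestamps share the session clock"))
  }
  cfg <- attr(trials, "config")
  cue_len <- if (!is.null(cfg)) cfg$odor_duration + cfg$trace_delay else 2.0
  tail_s <- if (!is.null(cfg)) cfg$vacuum_time + cfg$post_vacuum_delay else 7.0
  if (is.null(seed)) {
    master <- if (!is.null(cfg)) cfg$seed else 0L
    seed <- derive_unit_seed(master, spec$unit_id)
  }

  ord <- order(trials$odor_on)
  cue_on <- trials$odor_on[ord]
  cue_off <- cue_on + cue_len
  cue_rate <- unit_cue_rate(trials, spec)[ord]
  session_end <- max(cue_on) + tail_s

  # dead-time-corrected intensity: a Poisson stream at lambda followed by
  # sequential refractory thinning is a renewal process with mean interval
  # refractory + 1/lambda, so lambda = r / (1 - r * refractory) makes the
  # observed rate equal the configured rate r
  tau <- spec$refractory
  adj <- function(r) {
    if (r * tau >= 1) {
      stop_invalid("rate %.3g/s is unattainable with a %.4g s refractory",
                   r, tau)
    }
    r / (1 - r * tau)
  }

  with_seed(seed, {
    # piecewise-constant rate: baseline segments interleaved with cue windows
    spikes <- poisson_events(adj(spec$baseline_rate), 0, cue_on[1])
    for (i in seq_along(cue_on)) {
      spikes <- c(spikes, poisson_events(adj(cue_rate[i]), cue_on[i], cue_off[i]))
      nxt <- if (i < length(cue_on)) cue_on[i + 1] else session_end
      spikes <- c(spikes, poisson_events(adj(spec$baseline_rate), cue_off[i], nxt))
    }

    # identification epoch: 10 trains x 10 pulses at 10 Hz, 10 s between
    # train onsets -> 100 pulses
    id_start <- session_end + 10
    train_starts <- id_start + (0:9) * 10
    pulse_times <- as.vector(outer((0:9) * 0.1, train_starts, `+`))
    pulse_times <- sort(pulse_times)
    id_end <- max(pulse_times) + 1

    spikes <- c(spikes, poisson_events(adj(spec$baseline_rate), session_end,
                                       id_end))
    spikes <- enforce_refractory(sort(spikes), tau)

    evoke <- function(pulses, spontaneous) {
      if (!spec$tagged || length(pulses) == 0L) return(numeric(0))
      hit <- stats::runif(length(pulses)) < spec$tag_reliability
      if (spec$antidromic && length(spontaneous) > 0L) {
        cw <- spec$collision_window_ms / 1000
        prev <- findInterval(pulses, spontaneous)
        collided <- prev >= 1L & (pulses - spontaneous[pmax(prev, 1L)]) < cw
        hit <- hit & !collided
      }
      lat <- pmax(spec$tag_latency_ms +
                    stats::rnorm(length(pulses), 0, spec$tag_jitter_ms), 0.5)
      (pulses + lat / 1000)[hit]
    }

    spikes <- sort(c(spikes, evoke(pulse_times, spikes)))
    pulses <- data.frame(pulse_time = pulse_times, triggered = FALSE,
                         trigger_spike_time = NA_real_)

    # collision-test epoch: pulses triggered 1 ms after spontaneous spikes
    if (spec$n_collision_trials > 0L) {
      col_start <- id_end + 10
      col_len <- spec$n_collision_trials * (0.5 + 3 / spec$baseline_rate) + 10
      spont <- enforce_refractory(
        poisson_events(adj(spec$baseline_rate), col_start, col_start + col_len),
        tau)
      triggers <- numeric(0)
      last <- -Inf
      for (t in spont) {
        if (t - last >= 0.5) {
          triggers <- c(triggers, t)
          last <- t
          if (length(triggers) >= spec$n_collision_trials) break
        }
      }
      spikes <- sort(c(spikes, spont))
      if (length(triggers) > 0L) {
        trig_pulses <- triggers + 0.001
        spikes <- sort(c(spikes, evoke(trig_pulses, spikes)))
        pulses <- rbind(pulses, data.frame(
          pulse_time = trig_pulses, triggered = TRUE,
          trigger_spike_time = triggers
        ))
      }
    }

    structure(
      list(unit_id = spec$unit_id,
           spikes = enforce_refractory(spikes, tau),
           pulses = pulses,
           session = trials$session[1], spec = spec),
      class = "unit_recording"
    )
  })
}

#' @export
print.unit_recording <- function(x, ...) {
  cat(sprintf("Unit %d: %d spikes, %d pulses (%d triggered), session %d\n",
              x$unit_id, length(x$spikes), nrow(x$pulses),
              sum(x$pulses$triggered), x$session))
  invisible(x)
}
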