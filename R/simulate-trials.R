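#' Sample truncated-exponential inter-trial intervals
#'
#' Draws inter-trial intervals from an exponential distribution right-
#' truncated at `iti_max`. Truncation is realized by resampling draws that
#' exceed the bound, which keeps the within-support shape exactly
#' exponential (memoryless, flat hazard) rather than piling an atom at the
#' bound as clipping would. The resulting mean is
#' `1/rate - iti_max * exp(-rate * iti_max) / (1 - exp(-rate * iti_max))`
#' (about 3.33 s at the default rate 0.3/s and bound 30 s).
#'
#' @param n number of draws.
#' @param rate exponential rate parameter, events/s (> 0).
#' @param iti_max right truncation bound, s (> 0).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return Numeric vector of `n` intervals, each in (0, `iti_max`].
#' @examples
#' itis <- sample_iti(1000, rate = 0.3, iti_max = 30, seed = 1)
#' max(itis) <= 30
#' @export
sample_iti <- function(n, rate = 0.3, iti_max = 30.0, seed = NULL) {
  check_number(rate, "rate", positive = TRUE)
  check_number(iti_max, "iti_max", positive = TRUE)
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    stop_invalid("`n` must be a non-negative integer")
  }
  with_seed(seed, {
    out <- stats::rexp(n, rate)
    bad <- which(out > iti_max)
    while (length(bad) > 0L) {
      out[bad] <- stats::rexp(length(bad), rate)
      bad <- bad[out[bad] > iti_max]
    }
    out
  })
}

# Distribution function of the truncated exponential, for KS checks.
#' Cumulative distribution of the truncated exponential ITI
#'
#' @param q quantiles, s.
#' @param rate exponential rate, events/s.
#' @param iti_max truncation bound, s.
#' @return `P(ITI <= q)` under the right-truncated exponential law.
#' @export
ptrunc_exp <- function(q, rate = 0.3, iti_max = 30.0) {
  check_number(rate, "rate", positive = TRUE)
  check_number(iti_max, "iti_max", positive = TRUE)
  p <- (1 - exp(-rate * pmin(pmax(q, 0), iti_max))) / (1 - exp(-rate * iti_max))
  ifelse(q >= iti_max, 1, ifelse(q <= 0, 0, p))
}

# Build the shuffled odor sequence for one session.
session_odor_plan <- function(config, phase) {
  if (phase %in% c("conditioning", "reversal")) {
    odor <- rep(c("A", "B", "C", "D"), each = config$trials_per_odor_conditioning)
    prop <- rep(NA_real_, length(odor))
  } else {
    odor <- c(rep(c("A", "B", "C", "D"), each = config$trials_per_odor_probe),
              rep("mix", config$probe_mixture_repeats * length(config$mixtures)))
    prop <- c(rep(NA_real_, 4L * config$trials_per_odor_probe),
              rep(config$mixtures, each = config$probe_mixture_repeats))
  }
  ord <- sample.int(length(odor))
  list(odor = odor[ord], mixture_prop = prop[ord])
}

#' Generate the trial table for a full experimental timeline
#'
#' Builds the event schedule of every session in `config`: randomized odor
#' order within session, odor on/off times, outcome times on reinforced
#' trials, and truncated-exponential inter-trial intervals. Odor A predicts
#' sucrose and odor B denatonium during conditioning; their contingencies
#' are swapped during reversal sessions and the second probe test. Odor C
#' is never reinforced; odor D predicts an air puff in the `air_puff` group
#' and nothing otherwise. Probe-session mixture trials are unreinforced.
#'
#' The `sucrose_prop` column codes each trial's stimulus as the proportion
#' of the currently sucrose-predicting odor: 1 for the sucrose cue, 0 for
#' the denatonium cue, the configured mixture proportions for probe
#' mixtures, and `NA` for odors C and D. Times are on a per-session clock,
#' in seconds.
#'
#' @param config a [task_config()].
#' @return A data frame of class `trial_table` with columns `trial_id`,
#'   `session`, `phase`, `odor`, `sucrose_prop`, `outcome`, `odor_on`,
#'   `odor_off`, `outcome_time`, `laser`, `group`; the configuration is
#'   attached as attribute `"config"`.
#' @examples
#' trials <- generate_trial_table(task_config(n_conditioning = 1, n_reversal = 0))
#' table(trials$phase)
#' @export
generate_trial_table <- function(config) {
  if (!inherits(config, "task_config")) {
    stop_invalid("`config` must be a task_config object")
  }
  phases <- config$phases
  if (length(phases) == 0L) {
    out <- empty_trial_table(config)
    return(out)
  }
  with_seed(config$seed, {
    sessions <- vector("list", length(phases))
    for (s in seq_along(phases)) {
      phase <- phases[s]
      reversed <- phase == "reversal" ||
        (phase == "probe" && s > config$n_conditioning + 1L)
      plan <- session_odor_plan(config, phase)
      n <- length(plan$odor)

      sucrose_prop <- plan$mixture_prop
      a_prop <- if (reversed) 0 else 1
      sucrose_prop[plan$odor == "A"] <- a_prop
      sucrose_prop[plan$odor == "B"] <- 1 - a_prop

      outcome <- rep("none", n)
      ab <- plan$odor %in% c("A", "B")
      outcome[ab] <- ifelse(sucrose_prop[ab] == 1, "sucrose", "denatonium")
      if (config$group == "air_puff") outcome[plan$odor == "D"] <- "air_puff"

      itis <- sample_iti(n, config$iti_rate, config$iti_max)
      # trial span: odor onset -> vacuum (vacuum_time after onset) ->
      # fixed post-vacuum delay -> variable ITI -> next odor onset
      span <- config$vacuum_time + config$post_vacuum_delay
      odor_on <- itis[1] + c(0, cumsum(rep(span, n - 1L) + itis[-1L]))
      odor_off <- odor_on + config$odor_duration
      outcome_time <- ifelse(outcome == "none", NA_real_,
                             odor_off + config$trace_delay)

      sessions[[s]] <- data.frame(
        session = s,
        phase = phase,
        odor = plan$odor,
        sucrose_prop = sucrose_prop,
        outcome = outcome,
        odor_on = odor_on,
        odor_off = odor_off,
        outcome_time = outcome_time,
        laser = FALSE,
        group = config$group,
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, sessions)
    out <- cbind(trial_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    attr(out, "config") <- config
    class(out) <- c("trial_table", "data.frame")
    out
  })
}

empty_trial_table <- function(config = NULL) {
  out <- data.frame(
    trial_id = integer(0), session = integer(0), phase = character(0),
    odor = character(0), sucrose_prop = numeric(0), outcome = character(0),
    odor_on = numeric(0), odor_off = numeric(0), outcome_time = numeric(0),
    laser = logical(0), group = character(0), stringsAsFactors = FALSE
  )
  attr(out, "config") <- config
  class(out) <- c("trial_table", "data.frame")
  out
}

# Session end time (per-session clock): last trial's onset plus the fixed
# vacuum + post-vacuum tail. Used as the recording duration for rate QC and
# as the anchor for the optotag identification epoch.
#' Duration of each session implied by a trial table
#'
#' @param trials a trial table.
#' @return Named numeric vector of session durations, s (last odor onset
#'   plus the fixed vacuum and post-vacuum tail).
#' @export
session_duration <- function(trials) {
  cfg <- attr(trials, "config")
  tail_s <- if (!is.null(cfg)) cfg$vacuum_time + cfg$post_vacuum_delay else 7.0
  if (nrow(trials) == 0L) return(stats::setNames(numeric(0), character(0)))
  vapply(split(trials$odor_on, trials$session), function(t) max(t) + tail_s,
         numeric(1))
}
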