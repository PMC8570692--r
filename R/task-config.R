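#' Configuration of the go/no-go odor discrimination task
#'
#' Describes one animal's full experimental timeline: conditioning sessions,
#' a probe (extinction) test with unreinforced odor mixtures, reversal
#' sessions in which the sucrose- and denatonium-predicting odors swap
#' contingencies, and a second probe test. Defaults reproduce the standard
#' protocol: 10 conditioning sessions of 50 trials per odor, probe sessions
#' with 53 trials per conditioning odor plus 8 presentations of each of three
#' mixtures, 1 s odors, a 1 s trace delay before the outcome, and
#' inter-trial intervals drawn from an exponential distribution (rate 0.3/s)
#' truncated at 30 s.
#'
#' @param n_conditioning number of conditioning sessions (default 10).
#' @param n_reversal number of reversal sessions (default 10).
#' @param trials_per_odor_conditioning presentations of each of the four
#'   odors per conditioning/reversal session (default 50).
#' @param trials_per_odor_probe presentations of each conditioning odor per
#'   probe session (default 53).
#' @param probe_mixture_repeats unreinforced presentations of each mixture
#'   per probe session (default 8).
#' @param mixtures sucrose-odor proportions of the probe mixtures, strictly
#'   inside (0, 1), sorted descending (default 0.85, 0.50, 0.15).
#' @param odor_duration odor (CS) duration, s.
#' @param trace_delay delay between odor offset and outcome, s.
#' @param vacuum_time time after odor onset at which residual solution is
#'   removed, s.
#' @param post_vacuum_delay fixed delay after the vacuum before the variable
#'   inter-trial interval starts, s.
#' @param iti_rate rate parameter of the exponential inter-trial-interval
#'   distribution, events/s.
#' @param iti_max upper truncation bound of the inter-trial interval, s.
#' @param group `"air_puff"` (odor D predicts an air puff) or
#'   `"no_air_puff"` (odor D unreinforced).
#' @param seed master integer seed for all randomness derived from this
#'   configuration.
#'
#' @return An object of class `task_config` (a named list, with a `phases`
#'   element giving the ordered session phases).
#' @examples
#' cfg <- task_config(group = "air_puff", seed = 1)
#' cfg$phases
#' @export
task_config <- function(n_conditioning = 10L,
                        n_reversal = 10L,
                        trials_per_odor_conditioning = 50L,
                        trials_per_odor_probe = 53L,
                        probe_mixture_repeats = 8L,
                        mixtures = c(0.85, 0.50, 0.15),
                        odor_duration = 1.0,
                        trace_delay = 1.0,
                        vacuum_time = 4.0,
                        post_vacuum_delay = 3.0,
                        iti_rate = 0.3,
                        iti_max = 30.0,
                        group = c("no_air_puff", "air_puff"),
                        seed = 1L) {
  group <- match.arg(group)
  for (nm in c("n_conditioning", "n_reversal")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v)) {
      stop_invalid("`%s` must be a non-negative integer", nm)
    }
  }
  for (nm in c("trials_per_odor_conditioning", "trials_per_odor_probe",
               "probe_mixture_repeats")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      stop_invalid("`%s` must be a positive integer", nm)
    }
  }
  for (nm in c("odor_duration", "trace_delay", "vacuum_time",
               "post_vacuum_delay", "iti_rate", "iti_max")) {
    check_number(get(nm), nm, positive = TRUE)
  }
  if (vacuum_time < odor_duration + trace_delay) {
    stop_invalid("`vacuum_time` must not precede outcome delivery")
  }
  if (!is.numeric(mixtures) || length(mixtures) < 1L ||
      any(mixtures <= 0) || any(mixtures >= 1)) {
    stop_invalid("`mixtures` must be proportions strictly inside (0, 1)")
  }
  if (is.unsorted(rev(mixtures), strictly = TRUE)) {
    stop_invalid("`mixtures` must be sorted strictly descending")
  }
  check_number(seed, "seed")

  phases <- character(0)
  if (n_conditioning > 0) {
    phases <- c(rep("conditioning", n_conditioning), "probe")
  }
  if (n_reversal > 0) {
    phases <- c(phases, rep("reversal", n_reversal), "probe")
  }

  structure(
    list(
      n_conditioning = as.integer(n_conditioning),
      n_reversal = as.integer(n_reversal),
      trials_per_odor_conditioning = as.integer(trials_per_odor_conditioning),
      trials_per_odor_probe = as.integer(trials_per_odor_probe),
      probe_mixture_repeats = as.integer(probe_mixture_repeats),
      mixtures = as.numeric(mixtures),
      odor_duration = odor_duration,
      trace_delay = trace_delay,
      vacuum_time = vacuum_time,
      post_vacuum_delay = post_vacuum_delay,
      iti_rate = iti_rate,
      iti_max = iti_max,
      group = group,
      seed = as.integer(seed),
      phases = phases
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("Go/no-go task configuration\n")
  cat(sprintf("  phases: %d conditioning + probe + %d reversal + probe\n",
              x$n_conditioning, x$n_reversal))
  cat(sprintf("  trials/odor: %d (conditioning), %d (probe) + %d x %d mixtures\n",
              x$trials_per_odor_conditioning, x$trials_per_odor_probe,
              x$probe_mixture_repeats, length(x$mixtures)))
  cat(sprintf("  odor %.1f s, trace %.1f s; ITI ~ Exp(%.2f) truncated at %.0f s\n",
              x$odor_duration, x$trace_delay, x$iti_rate, x$iti_max))
  cat(sprintf("  group: %s, seed: %d\n", x$group, x$seed))
  invisible(x)
}
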