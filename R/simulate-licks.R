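#' Parameters of the anticipatory-licking generator
#'
#' Licking within the odor + trace-delay window is modeled as a homogeneous
#' Poisson process whose rate depends on the trial's cue. The cue-evoked
#' rate interpolates linearly between `rate_denatonium` (sucrose proportion
#' 0) and `rate_sucrose` (proportion 1), reproducing lick rates that scale
#' smoothly with the sucrose-odor proportion of a mixture. Trials of the
#' neutral odors C/D lick at `rate_neutral`. In the air-puff group the
#' cue-evoked rate on sucrose and mixture cues is multiplied by
#' `group_multiplier` (< 1 reproduces the negative bias of an aversive
#' history). On unreinforced probe mixture trials the rate optionally
#' decays across the eight repeats as `exp(-extinction_decay * (k - 1))`
#' for repeat k. An optional logistic acquisition curve scales the
#' cue-dependent rate component across conditioning/reversal sessions.
#'
#' @param rate_sucrose lick rate on the pure sucrose cue, licks/s.
#' @param rate_denatonium lick rate on the pure denatonium cue, licks/s.
#' @param rate_neutral lick rate on odors C and D, licks/s.
#' @param group_multiplier multiplicative factor applied to the cue-evoked
#'   rate on sucrose and mixture cues in the air-puff group (1 = no group
#'   effect).
#' @param extinction_decay per-repeat exponential decay rate of the lick
#'   rate on probe mixture trials (0 = no extinction).
#' @param learning_k,learning_x0 optional logistic acquisition parameters
#'   (per-session rate `1/(1+exp(-k(s - x0)))` scaling the cue-dependent
#'   component within conditioning and, restarted, within reversal);
#'   `learning_k = NULL` means fully learned from session 1.
#' @param window observation window for licks relative to odor onset, s
#'   (default the odor + trace-delay period, `[0, 2]`).
#' @return A list of class `lick_params`.
#' @export
lick_params <- function(rate_sucrose = 8.0,
                        rate_denatonium = 0.3,
                        rate_neutral = 0.3,
                        group_multiplier = 0.8,
                        extinction_decay = 0.0,
                        learning_k = NULL,
                        learning_x0 = 3.0,
                        window = c(0, 2)) {
  for (nm in c("rate_sucrose", "rate_denatonium", "rate_neutral")) {
    v <- get(nm)
    check_number(v, nm)
    if (v < 0) stop_invalid("`%s` must be non-negative", nm)
  }
  check_number(group_multiplier, "group_multiplier", lower = 0)
  check_number(extinction_decay, "extinction_decay", lower = 0)
  if (!is.null(learning_k)) check_number(learning_k, "learning_k")
  check_number(learning_x0, "learning_x0")
  check_window(window)
  structure(
    list(rate_sucrose = rate_sucrose, rate_denatonium = rate_denatonium,
         rate_neutral = rate_neutral, group_multiplier = group_multiplier,
         extinction_decay = extinction_decay, learning_k = learning_k,
         learning_x0 = learning_x0, window = as.numeric(window)),
    class = "lick_params"
  )
}

# Expected lick rate for each trial row. Exposed internally so tests can
# compare empirical rates against the configured ground truth.
lick_rate_per_trial <- function(trials, params) {
  p <- trials$sucrose_prop
  cue <- params$rate_denatonium +
    (params$rate_sucrose - params$rate_denatonium) * ifelse(is.na(p), 0, p)
  rate <- ifelse(is.na(p), params$rate_neutral, cue)

  if (!is.null(params$learning_k)) {
    sess_in_phase <- stats::ave(trials$session, trials$phase,
                                FUN = function(s) match(s, sort(unique(s))))
    acq <- 1 / (1 + exp(-params$learning_k * (sess_in_phase - params$learning_x0)))
    learn <- trials$phase %in% c("conditioning", "reversal") & !is.na(p)
    rate[learn] <- params$rate_denatonium +
      (rate[learn] - params$rate_denatonium) * acq[learn]
  }

  grp_cue <- trials$group == "air_puff" & !is.na(p) & p > 0
  rate[grp_cue] <- rate[grp_cue] * params$group_multiplier

  if (params$extinction_decay > 0) {
    idx <- probe_trial_index(trials)
    mix <- !is.na(idx)
    rate[mix] <- rate[mix] * exp(-params$extinction_decay * (idx[mix] - 1))
  }
  rate
}

# 1..n presentation index of each probe mixture trial, per (session,
# mixture), in presentation order; NA elsewhere.
probe_trial_index <- function(trials) {
  idx <- rep(NA_integer_, nrow(trials))
  mix <- which(trials$phase == "probe" & trials$odor == "mix")
  if (length(mix) == 0L) return(idx)
  key <- paste(trials$session[mix], trials$sucrose_prop[mix])
  ord <- mix[order(trials$odor_on[mix])]
  key_ord <- paste(trials$session[ord], trials$sucrose_prop[ord])
  pos <- stats::ave(seq_along(ord), key_ord, FUN = seq_along)
  idx[ord] <- pos
  idx
}

#' Simulate anticipatory lick events for a trial table
#'
#' Draws a homogeneous Poisson lick train within each trial's observation
#' window at the rate implied by [lick_params()] and the trial's cue,
#' group, session, and probe-repeat index.
#'
#' @param trials a [generate_trial_table()] result (or compatible data
#'   frame).
#' @param params a [lick_params()] object.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return Data frame with columns `trial_id` and `lick_time` (seconds
#'   relative to odor onset, non-decreasing within trial).
#' @examples
#' trials <- generate_trial_table(task_config(n_conditioning = 1, n_reversal = 0))
#' licks <- simulate_licks(trials, lick_params(), seed = 1)
#' @export
simulate_licks <- function(trials, params = lick_params(), seed = NULL) {
  if (!inherits(params, "lick_params")) {
    stop_invalid("`params` must be a lick_params object")
  }
  if (nrow(trials) == 0L) {
    return(data.frame(trial_id = integer(0), lick_time = numeric(0)))
  }
  rates <- lick_rate_per_trial(trials, params)
  w <- params$window
  with_seed(seed, {
    counts <- stats::rpois(length(rates), rates * (w[2] - w[1]))
    times <- stats::runif(sum(counts), w[1], w[2])
    out <- data.frame(
      trial_id = rep(trials$trial_id, counts),
      lick_time = times
    )
    out <- out[order(out$trial_id, out$lick_time), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
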