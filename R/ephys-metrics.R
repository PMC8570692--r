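#' Align a spike train to odor onsets
#'
#' Maps session-clock spike times into trial-relative times within an
#' alignment window around each odor onset; spikes outside every window
#' are discarded. The result keeps the full trial structure (one entry per
#' trial, possibly empty) together with the trial labels needed by
#' downstream statistics.
#'
#' @param spike_times sorted spike timestamps, s (session clock).
#' @param trials trial table rows of the same session.
#' @param window alignment window relative to odor onset, s (default
#'   `c(-1, 2)`: 1 s pre-CS baseline plus the odor and trace-delay
#'   period).
#' @return An object of class `raster`: list with `trials` (the trial
#'   rows), `window`, and `aligned` (list of per-trial spike-time vectors
#'   relative to odor onset).
#' @examples
#' trials <- generate_trial_table(task_config(n_conditioning = 1, n_reversal = 0))
#' rec <- simulate_unit(trials, unit_spec(1, cue_gain = 2))
#' r <- align_spikes(rec$spikes, trials)
#' @export
align_spikes <- function(spike_times, trials, window = c(-1, 2)) {
  check_window(window)
  if (nrow(trials) == 0L) stop_invalid("`trials` must be non-empty")
  check_sorted_times(spike_times)
  lo <- findInterval(trials$odor_on + window[1], spike_times,
                     left.open = TRUE)
  hi <- findInterval(trials$odor_on + window[2], spike_times,
                     left.open = TRUE)
  aligned <- lapply(seq_len(nrow(trials)), function(i) {
    if (hi[i] <= lo[i]) return(numeric(0))
    spike_times[(lo[i] + 1L):hi[i]] - trials$odor_on[i]
  })
  structure(list(trials = trials, window = as.numeric(window),
                 aligned = aligned),
            class = "raster")
}

#' @export
print.raster <- function(x, ...) {
  cat(sprintf("Raster: %d trials, window [%g, %g] s, %d aligned spikes\n",
              nrow(x$trials), x$window[1], x$window[2],
              sum(lengths(x$aligned))))
  invisible(x)
}

# Per-trial spike counts in fixed bins across the raster window.
raster_bin_counts <- function(raster, bin_width) {
  edges <- seq(raster$window[1], raster$window[2], by = bin_width)
  if (abs(edges[length(edges)] - raster$window[2]) > 1e-9) {
    stop_invalid("`bin_width` must divide the window length")
  }
  nb <- length(edges) - 1L
  counts <- vapply(raster$aligned, function(s) {
    if (length(s) == 0L) return(integer(nb))
    tabulate(findInterval(s, edges, rightmost.closed = TRUE), nbins = nb)
  }, integer(nb))
  list(edges = edges, counts = matrix(counts, nrow = nb))  # bins x trials
}

#' Peri-stimulus time histogram
#'
#' Trial-averaged firing rate in fixed bins across the alignment window,
#' raw and with the mean pre-CS baseline rate subtracted.
#'
#' @param raster an [align_spikes()] result.
#' @param bin_width bin width, s (default 0.1; must divide the window).
#' @param baseline_window window used for the baseline rate, s relative to
#'   odor onset (default the 1 s immediately pre-odor).
#' @return Data frame with `bin_start`, `bin_end`, `rate` (spikes/s) and
#'   `rate_baseline_subtracted`.
#' @export
psth <- function(raster, bin_width = 0.1, baseline_window = c(-1, 0)) {
  if (!inherits(raster, "raster")) stop_invalid("`raster` must be a raster")
  check_number(bin_width, "bin_width", positive = TRUE)
  check_window(baseline_window, "baseline_window")
  n_trials <- nrow(raster$trials)
  if (n_trials == 0L) stop_invalid("PSTH undefined for zero trials")
  bc <- raster_bin_counts(raster, bin_width)
  rate <- rowSums(bc$counts) / (n_trials * bin_width)
  starts <- bc$edges[-length(bc$edges)]
  base <- starts >= baseline_window[1] & starts < baseline_window[2]
  base_rate <- if (any(base)) mean(rate[base]) else 0
  data.frame(bin_start = starts, bin_end = bc$edges[-1], rate = rate,
             rate_baseline_subtracted = rate - base_rate)
}

# auROC of counts `a` vs counts `b` with ties counted 0.5: the normalized
# Mann-Whitney statistic, computed from midranks. Values > 0.5 mean `a`
# tends to exceed `b`.
auroc_counts <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * nb)
}

#' Binned auROC discriminability between two trial classes
#'
#' For each time bin, computes the area under the ROC curve comparing the
#' per-trial spike counts of class A (conventionally sucrose trials)
#' against class B (denatonium trials): the probability that an ideal
#' observer, drawing one trial from each class, sees a higher count on the
#' class-A trial, with ties counted 0.5 (the Mann–Whitney convention).
#' 0.5 means no discriminability; 0 or 1 perfect discriminability; values
#' above 0.5 mean greater activity on class-A trials.
#'
#' @param raster an [align_spikes()] result.
#' @param class_a,class_b logical or integer selections of the raster's
#'   trials (>= 2 trials each).
#' @param bin_width bin width, s (default 0.1).
#' @return An object of class `auroc_profile`: data frame with
#'   `bin_start`, `bin_end`, `auroc`, plus attributes `n_a`, `n_b`,
#'   `window`.
#' @examples
#' # see binned_auroc tests for a worked 3x3-trial example (auROC 7/9)
#' @export
binned_auroc <- function(raster, class_a, class_b, bin_width = 0.1) {
  if (!inherits(raster, "raster")) stop_invalid("`raster` must be a raster")
  sel <- function(idx, nm) {
    i <- seq_len(nrow(raster$trials))
    i <- if (is.logical(idx)) i[idx] else intersect(i, idx)
    if (length(i) < 2L) {
      stop_invalid("`%s` must select at least 2 trials", nm)
    }
    i
  }
  ia <- sel(class_a, "class_a")
  ib <- sel(class_b, "class_b")
  bc <- raster_bin_counts(raster, bin_width)
  auroc <- apply(bc$counts, 1L, function(cnt) auroc_counts(cnt[ia], cnt[ib]))
  out <- data.frame(bin_start = bc$edges[-length(bc$edges)],
                    bin_end = bc$edges[-1], auroc = auroc)
  attr(out, "n_a") <- length(ia)
  attr(out, "n_b") <- length(ib)
  attr(out, "window") <- raster$window
  class(out) <- c("auroc_profile", "data.frame")
  out
}

#' Classify a neuron from its binned auROC profile
#'
#' A neuron is `excited` when at least one cue-period bin exceeds `hi`
#' (substantially greater activity on sucrose than denatonium trials),
#' `inhibited` when at least one falls below `lo`, and `none` otherwise.
#' If bins cross both thresholds the larger excursion from 0.5 decides.
#' The cue period defaults to odor onset through outcome delivery
#' (`[0, 2]` s: odor plus trace delay).
#'
#' @param profile a [binned_auroc()] result.
#' @param hi,lo classification thresholds (defaults 0.7 and 0.3).
#' @param cue_window cue period, s relative to odor onset.
#' @return `"excited"`, `"inhibited"`, or `"none"`.
#' @export
classify_discriminative <- function(profile, hi = 0.7, lo = 0.3,
                                    cue_window = c(0, 2)) {
  if (!inherits(profile, "auroc_profile")) {
    stop_invalid("`profile` must be an auroc_profile")
  }
  check_window(cue_window, "cue_window")
  w <- attr(profile, "window")
  if (!is.null(w) && (cue_window[1] < w[1] - 1e-9 || cue_window[2] > w[2] + 1e-9)) {
    stop_invalid("profile window does not cover `cue_window`")
  }
  in_cue <- profile$bin_start >= cue_window[1] - 1e-9 &
    profile$bin_start < cue_window[2] - 1e-9
  v <- profile$auroc[in_cue]
  exc <- any(v > hi)
  inh <- any(v < lo)
  if (exc && inh) {
    if (max(v - 0.5) >= max(0.5 - v)) "excited" else "inhibited"
  } else if (exc) {
    "excited"
  } else if (inh) {
    "inhibited"
  } else {
    "none"
  }
}

#' Cue-evoked firing-rate change versus baseline
#'
#' Paired comparison, across trials, of the firing rate during the cue
#' period against the rate during the pre-CS baseline (paired two-sided
#' t-test). Used to select neurons whose firing changes significantly
#' during the cue and to label the direction of the change.
#'
#' @param raster an [align_spikes()] result.
#' @param trial_sel logical or integer selection of trials (default all).
#' @param cue_window cue period, s relative to odor onset.
#' @param baseline_window baseline period, s relative to odor onset.
#' @return One-row data frame: `change` (cue minus baseline rate,
#'   spikes/s), `p_value` (NA with `degenerate = TRUE` when the paired
#'   differences have zero variance), `direction`
#'   (`"increase"`/`"decrease"`/`"none"`), `n_trials`.
#' @export
cue_response_change <- function(raster, trial_sel = NULL,
                                cue_window = c(0, 2),
                                baseline_window = c(-1, 0)) {
  if (!inherits(raster, "raster")) stop_invalid("`raster` must be a raster")
  check_window(cue_window, "cue_window")
  check_window(baseline_window, "baseline_window")
  idx <- seq_len(nrow(raster$trials))
  if (!is.null(trial_sel)) {
    idx <- if (is.logical(trial_sel)) idx[trial_sel] else
      intersect(idx, trial_sel)
  }
  if (length(idx) < 2L) stop_invalid("need at least 2 trials")
  rate_in <- function(s, w) sum(s >= w[1] & s < w[2]) / (w[2] - w[1])
  cue <- vapply(raster$aligned[idx], rate_in, numeric(1), w = cue_window)
  base <- vapply(raster$aligned[idx], rate_in, numeric(1), w = baseline_window)
  d <- cue - base
  change <- mean(d)
  degenerate <- stats::sd(d) < .Machine$double.eps^0.5
  p <- if (degenerate) NA_real_ else stats::t.test(cue, base, paired = TRUE)$p.value
  direction <- if (!degenerate && !is.na(p) && p < 0.05) {
    if (change > 0) "increase" else "decrease"
  } else {
    "none"
  }
  data.frame(change = change, p_value = p, degenerate = degenerate,
             direction = direction, n_trials = length(idx),
             stringsAsFactors = FALSE)
}
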