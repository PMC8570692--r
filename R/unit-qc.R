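#' Fraction of interspike-interval violations
#'
#' Fraction of consecutive interspike intervals shorter than the
#' refractory period (default 2 ms). High values indicate that the cluster
#' mixes spikes from more than one neuron, since a single neuron cannot
#' fire twice within its refractory period. For a Poisson train of rate r
#' the expected fraction is `1 - exp(-r * refractory)`.
#'
#' @param spike_times sorted spike timestamps, s.
#' @param refractory refractory period, s (default 0.002).
#' @return Fraction in [0, 1]; 0 by convention for fewer than 2 spikes.
#' @examples
#' isi_violation_fraction(c(0, 0.001, 1.0))  # 0.5
#' @export
isi_violation_fraction <- function(spike_times, refractory = 0.002) {
  check_number(refractory, "refractory", positive = TRUE)
  check_sorted_times(spike_times)
  if (length(spike_times) < 2L) return(0)
  mean(diff(spike_times) < refractory)
}

#' L-ratio cluster-isolation metric
#'
#' Sums, over all spikes *not* assigned to the cluster, the chi-square
#' upper-tail probability of their squared Mahalanobis distance to the
#' cluster (using the cluster's own mean and covariance, with degrees of
#' freedom equal to the feature dimension), and normalizes by the cluster
#' size. A non-member far from the cluster contributes ~0; one
#' indistinguishable from members contributes ~1. Well-isolated units have
#' values near 0; the conventional inclusion threshold is 0.05.
#'
#' The metric is invariant under affine maps of the feature space
#' (Mahalanobis invariance). Near-singular cluster covariances are
#' regularized by adding `ridge * trace/K` to the diagonal so that
#' degenerate fixtures do not abort quality control.
#'
#' @param features numeric matrix, one row per spike, one column per
#'   feature.
#' @param labels cluster assignment per spike.
#' @param cluster_id label of the cluster being scored.
#' @param ridge relative diagonal regularization applied when the
#'   covariance is near-singular (default 1e-8).
#' @return Non-negative scalar; smaller is better isolated.
#' @examples
#' fx <- simulate_cluster_features(300, n_dims = 4, separation = 10, seed = 1)
#' l_ratio(fx$features, fx$labels, 1)
#' @export
l_ratio <- function(features, labels, cluster_id, ridge = 1e-8) {
  features <- as.matrix(features)
  if (!is.numeric(features)) stop_invalid("`features` must be numeric")
  if (nrow(features) != length(labels)) {
    stop_invalid("`labels` must have one entry per feature row")
  }
  k <- ncol(features)
  member <- labels == cluster_id
  n_c <- sum(member)
  if (n_c <= k + 1L) {
    stop_invalid("cluster %s has %d members; needs more than K+1 = %d",
                 as.character(cluster_id), n_c, k + 1L)
  }
  if (n_c == nrow(features)) return(0)
  mu <- colMeans(features[member, , drop = FALSE])
  sigma <- stats::cov(features[member, , drop = FALSE])
  if (rcond(sigma) < 1e-12) {
    sigma <- sigma + diag(ridge * sum(diag(sigma)) / k, k)
  }
  d2 <- tryCatch(
    stats::mahalanobis(features[!member, , drop = FALSE], mu, sigma),
    error = function(e) NULL)
  if (is.null(d2) || any(!is.finite(d2))) {
    stop_invalid("cluster covariance singular even after regularization")
  }
  sum(stats::pchisq(d2, df = k, lower.tail = FALSE)) / n_c
}

#' Unit inclusion decision from quality metrics
#'
#' A unit enters the dataset only when all three criteria hold strictly:
#' L-ratio below `max_l_ratio` (default 0.05), interspike-interval
#' violation fraction below `max_isi_violation` (default 0.001, i.e.
#' 0.1%), and mean firing rate above `min_rate` (default 0.5 spikes/s over
#' the recording session).
#'
#' @param l_ratio L-ratio value.
#' @param isi_violation_fraction ISI violation fraction.
#' @param mean_rate mean firing rate over the session, spikes/s.
#' @param max_l_ratio,max_isi_violation,min_rate inclusion thresholds.
#' @return Logical: does the unit pass?
#' @examples
#' passes_qc(0.04, 0.0005, 1.0)   # TRUE
#' passes_qc(0.05, 0.0005, 1.0)   # FALSE: boundary is exclusive
#' @export
passes_qc <- function(l_ratio, isi_violation_fraction, mean_rate,
                      max_l_ratio = 0.05, max_isi_violation = 0.001,
                      min_rate = 0.5) {
  if (anyNA(c(l_ratio, isi_violation_fraction, mean_rate))) {
    stop_invalid("QC metrics must be complete (no NA)")
  }
  (l_ratio < max_l_ratio) &
    (isi_violation_fraction < max_isi_violation) &
    (mean_rate > min_rate)
}

#' Quality-control metrics for one unit
#'
#' Computes the three inclusion metrics — L-ratio (when features are
#' supplied), ISI-violation fraction, and mean rate over the session — and
#' the resulting pass/fail decision.
#'
#' @param spike_times sorted spike timestamps, s.
#' @param session_dur recording-session duration used as the rate
#'   denominator, s.
#' @param features,labels,cluster_id optional cluster-feature inputs for
#'   [l_ratio()]; when omitted the L-ratio is `NA` and the decision uses
#'   only the other two criteria.
#' @param ... thresholds passed to [passes_qc()].
#' @return One-row data frame: `l_ratio`, `isi_violation_fraction`,
#'   `mean_rate`, `passes`.
#' @export
qc_metrics <- function(spike_times, session_dur, features = NULL,
                       labels = NULL, cluster_id = NULL, ...) {
  check_number(session_dur, "session_dur", positive = TRUE)
  check_sorted_times(spike_times)
  lr <- if (!is.null(features)) l_ratio(features, labels, cluster_id) else
    NA_real_
  isi <- isi_violation_fraction(spike_times)
  rate <- length(spike_times) / session_dur
  pass <- if (is.na(lr)) {
    passes_qc(0, isi, rate, ...)
  } else {
    passes_qc(lr, isi, rate, ...)
  }
  data.frame(l_ratio = lr, isi_violation_fraction = isi, mean_rate = rate,
             passes = pass)
}
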