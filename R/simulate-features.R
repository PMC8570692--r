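#' Simulate spike-sorting cluster features
#'
#' Draws two multivariate-Gaussian clusters of waveform features with unit
#' covariance and centers `separation` apart (so `separation` is the
#' center distance in pooled-covariance units). With `separation = 0` the
#' clusters are statistically identical; as separation grows the expected
#' L-ratio of either cluster decreases toward 0. Labels are returned so
#' quality metrics can be checked against the generating truth.
#'
#' @param n_spikes spikes per cluster (a length-2 vector gives unequal
#'   cluster sizes).
#' @param n_dims feature-space dimension (>= 1).
#' @param separation distance between cluster centers, in pooled-covariance
#'   units (>= 0).
#' @param seed optional integer seed.
#' @return A list with `features` (numeric matrix, one row per spike) and
#'   `labels` (integer vector, 1 or 2).
#' @examples
#' fx <- simulate_cluster_features(500, n_dims = 4, separation = 8, seed = 1)
#' table(fx$labels)
#' @export
simulate_cluster_features <- function(n_spikes, n_dims = 8L, separation = 5.0,
                                      seed = NULL) {
  if (!is.numeric(n_dims) || length(n_dims) != 1L || n_dims < 1 ||
      n_dims != round(n_dims)) {
    stop_invalid("`n_dims` must be a positive integer")
  }
  check_number(separation, "separation", lower = 0)
  if (!is.numeric(n_spikes) || !length(n_spikes) %in% c(1L, 2L) ||
      any(n_spikes < 1) || any(n_spikes != round(n_spikes))) {
    stop_invalid("`n_spikes` must be one or two positive integers")
  }
  n <- if (length(n_spikes) == 1L) rep(as.integer(n_spikes), 2L) else
    as.integer(n_spikes)
  mu1 <- rep(0, n_dims)
  mu2 <- c(separation, rep(0, n_dims - 1L))
  with_seed(seed, {
    f1 <- MASS::mvrnorm(n[1], mu1, diag(n_dims))
    f2 <- MASS::mvrnorm(n[2], mu2, diag(n_dims))
    features <- rbind(matrix(f1, nrow = n[1]), matrix(f2, nrow = n[2]))
    colnames(features) <- paste0("f", seq_len(n_dims))
    list(features = features, labels = rep(1:2, n))
  })
}
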