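# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: the auROC oracle enumerates all cross-pairs, the L-ratio
# oracle loops over individual spikes solving one linear system each, and
# the Poisson oracle maximizes the log-likelihood directly with Newton
# steps.

# auROC as an explicit count over all (a, b) pairs, ties worth 0.5.
brute_auroc <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(a) * length(b))
}

# L-ratio by a per-spike loop: squared Mahalanobis distance computed one
# non-member at a time via solve().
brute_l_ratio <- function(features, labels, cluster_id) {
  member <- labels == cluster_id
  k <- ncol(features)
  mu <- colMeans(features[member, , drop = FALSE])
  sigma <- cov(features[member, , drop = FALSE])
  tot <- 0
  for (i in which(!member)) {
    d <- features[i, ] - mu
    d2 <- drop(t(d) %*% solve(sigma, d))
    tot <- tot + pchisq(d2, df = k, lower.tail = FALSE)
  }
  tot / sum(member)
}

# Poisson log-likelihood maximization by damped Newton iterations on the
# full design matrix (intercept, mixture, group, interaction).
brute_poisson_mle <- function(counts, design, tol = 1e-12, max_iter = 200) {
  X <- cbind(1, design$mixture, design$group, design$mixture * design$group)
  beta <- c(log(mean(counts) + 0.1), 0, 0, 0)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    grad <- drop(t(X) %*% (counts - mu))
    hess <- t(X) %*% (X * mu)
    step <- solve(hess, grad)
    # halve the step until the log-likelihood does not decrease
    ll <- sum(counts * eta - mu)
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      eta_new <- drop(X %*% beta_new)
      ll_new <- sum(counts * eta_new - exp(eta_new))
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    beta <- beta + lambda * step
    if (max(abs(lambda * step)) < tol) break
  }
  names(beta) <- c("intercept", "mixture", "group", "interaction")
  beta
}

# Minimal single-session trial table with the columns the analyses join on.
# `props` gives each trial's sucrose proportion (NA for neutral odors).
make_trials <- function(props, spacing = 5, group = "no_air_puff",
                        phase = "conditioning", session = 1L) {
  n <- length(props)
  odor <- ifelse(is.na(props), "C",
                 ifelse(props == 1, "A", ifelse(props == 0, "B", "mix")))
  outcome <- ifelse(is.na(props) | (props > 0 & props < 1), "none",
                    ifelse(props == 1, "sucrose", "denatonium"))
  odor_on <- spacing * seq_len(n)
  out <- data.frame(
    trial_id = seq_len(n), session = session, phase = phase, odor = odor,
    sucrose_prop = props, outcome = outcome, odor_on = odor_on,
    odor_off = odor_on + 1, outcome_time = ifelse(outcome == "none", NA_real_,
                                                  odor_on + 2),
    laser = FALSE, group = group, stringsAsFactors = FALSE
  )
  class(out) <- c("trial_table", "data.frame")
  out
}

# Expected per-trial lick rate of the generator (internal ground truth).
lick_rate_per_trial_public <- function(trials, par, all_trials = FALSE) {
  r <- gonogo:::lick_rate_per_trial(trials, par)
  if (all_trials) r else r[1]
}

# Raster built directly from per-trial aligned spike times, bypassing
# align_spikes(), for tests that control counts exactly.
make_raster <- function(aligned, window = c(-1, 2), props = NULL) {
  n <- length(aligned)
  trials <- make_trials(if (is.null(props)) rep(1, n) else props)
  structure(list(trials = trials, window = window, aligned = aligned),
            class = "raster")
}
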