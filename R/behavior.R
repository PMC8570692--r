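#' Anticipatory lick rate per trial
#'
#' Counts licks in a window relative to odor onset and converts to a rate.
#' The default window `[0, 2)` s covers the 1 s odor presentation plus the
#' 1 s trace delay before outcome delivery — the anticipatory period, the
#' primary behavioral readout of the task.
#'
#' @param licks data frame with `trial_id` and `lick_time` (s, relative to
#'   odor onset).
#' @param trials trial table; every `trial_id` in `licks` must appear here.
#' @param window half-open counting window `[start, end)` relative to odor
#'   onset, s.
#' @return Data frame with one row per trial: `trial_id`, `session`,
#'   `phase`, `odor`, `sucrose_prop`, `group`, `laser`, `n_licks`,
#'   `lick_rate` (licks/s), and `probe_trial_index` (1..n for probe
#'   mixture trials, `NA` elsewhere). Plus `mouse_id` when `trials` has
#'   one.
#' @examples
#' trials <- generate_trial_table(task_config(n_conditioning = 1, n_reversal = 0))
#' rates <- epoch_lick_rate(simulate_licks(trials, seed = 1), trials)
#' head(rates)
#' @export
epoch_lick_rate <- function(licks, trials, window = c(0, 2)) {
  check_window(window)
  if (!all(c("trial_id", "lick_time") %in% names(licks))) {
    stop_invalid("`licks` must have columns trial_id and lick_time")
  }
  orphan <- setdiff(unique(licks$trial_id), trials$trial_id)
  if (length(orphan) > 0L) {
    stop_invalid("licks reference unknown trial_id(s): %s",
                 paste(utils::head(sort(orphan), 10L), collapse = ", "))
  }
  keep <- licks$lick_time >= window[1] & licks$lick_time < window[2]
  counts <- table(factor(licks$trial_id[keep], levels = trials$trial_id))
  out <- data.frame(
    trial_id = trials$trial_id,
    session = trials$session,
    phase = trials$phase,
    odor = trials$odor,
    sucrose_prop = trials$sucrose_prop,
    group = trials$group,
    laser = trials$laser,
    n_licks = as.integer(counts),
    stringsAsFactors = FALSE
  )
  out$lick_rate <- out$n_licks / (window[2] - window[1])
  out$probe_trial_index <- probe_trial_index(trials)
  if ("mouse_id" %in% names(trials)) out$mouse_id <- trials$mouse_id
  out
}

# Human-readable cue label: odor letter, or the mixture's sucrose proportion.
cue_label <- function(odor, sucrose_prop) {
  ifelse(odor == "mix", sprintf("mix_%.2f", sucrose_prop), odor)
}

sem <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2L) return(NA_real_)
  stats::sd(x, na.rm = TRUE) / sqrt(n)
}

#' Session-wise learning curve of anticipatory licking
#'
#' Mean and SEM of the per-trial lick rate by session, cue, and group.
#' When a `mouse_id` column is present the SEM is computed across mouse
#' means (the usual plotting convention for multi-animal data); otherwise
#' across trials.
#'
#' @param rates output of [epoch_lick_rate()].
#' @return Data frame keyed by (`session`, `phase`, `cue`, `group`) with
#'   `mean_rate`, `sem`, and `n` (mice or trials).
#' @export
learning_curve <- function(rates) {
  if (nrow(rates) == 0L) stop_invalid("`rates` must contain at least one trial")
  rates$cue <- cue_label(rates$odor, rates$sucrose_prop)
  by_mouse <- "mouse_id" %in% names(rates)
  if (by_mouse) {
    mouse <- stats::aggregate(
      lick_rate ~ session + phase + cue + group + mouse_id, rates, mean)
    agg_from <- mouse
  } else {
    agg_from <- rates
  }
  out <- stats::aggregate(lick_rate ~ session + phase + cue + group, agg_from,
                          function(x) c(mean = mean(x), sem = sem(x),
                                        n = length(x)))
  out <- cbind(out[c("session", "phase", "cue", "group")],
               as.data.frame(out$lick_rate))
  names(out)[names(out) == "mean"] <- "mean_rate"
  out <- out[order(out$session, out$cue, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trial-by-trial extinction curve over probe mixture trials
#'
#' Mean lick rate at each of the (typically eight) successive unreinforced
#' presentations of every mixture, split by group — the trajectory that
#' distinguishes an extinction effect from a bias present from the first
#' probe trial.
#'
#' @param rates output of [epoch_lick_rate()].
#' @return Data frame keyed by (`sucrose_prop`, `probe_trial_index`,
#'   `group`) with `mean_rate`, `sem`, `n`. Empty (with a warning) when no
#'   probe mixture trials are present.
#' @export
extinction_curve <- function(rates) {
  mix <- rates[!is.na(rates$probe_trial_index), , drop = FALSE]
  if (nrow(mix) == 0L) {
    warning("no probe mixture trials present; returning empty curve")
    return(data.frame(sucrose_prop = numeric(0), probe_trial_index = integer(0),
                      group = character(0), mean_rate = numeric(0),
                      sem = numeric(0), n = integer(0)))
  }
  out <- stats::aggregate(lick_rate ~ sucrose_prop + probe_trial_index + group,
                          mix, function(x) c(mean = mean(x), sem = sem(x),
                                             n = length(x)))
  out <- cbind(out[c("sucrose_prop", "probe_trial_index", "group")],
               as.data.frame(out$lick_rate))
  names(out)[names(out) == "mean"] <- "mean_rate"
  out <- out[order(out$group, -out$sucrose_prop, out$probe_trial_index), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a logistic learning curve
#'
#' Least-squares fit of `f(x) = L / (1 + exp(-k (x - x0)))` to a response
#' measured across sessions; the learning rate is the `k` parameter.
#' Fitting uses Levenberg–Marquardt least squares with a multi-start grid
#' over sign and scale of `k` and over `x0` quantiles, keeping the best
#' residual sum of squares. A constant response cannot identify `k` or
#' `x0`; by convention the fit returns `L = const`, `k = 0`, flagged as a
#' boundary solution.
#'
#' @param x session indices (>= 4 points).
#' @param y response values (same length).
#' @return A list of class `logistic_fit`: `L`, `k`, `x0`, `rss`,
#'   `converged`, `boundary`, `fitted`.
#' @examples
#' x <- 1:10
#' y <- 10 / (1 + exp(-1.2 * (x - 5)))
#' fit_logistic(x, y)$k
#' @export
fit_logistic <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) {
    stop_invalid("logistic fit needs at least 4 points (3 parameters)")
  }
  if (stats::sd(y) < sqrt(.Machine$double.eps) * max(1, abs(mean(y)))) {
    return(structure(
      list(L = mean(y), k = 0, x0 = mean(x), rss = sum((y - mean(y))^2),
           converged = TRUE, boundary = TRUE, fitted = rep(mean(y), length(x))),
      class = "logistic_fit"))
  }

  dat <- data.frame(x = x, y = y)
  sgn <- if (stats::cor(x, y) >= 0) 1 else -1
  span <- max(diff(range(x)), 1)
  starts <- expand.grid(
    L = c(max(abs(y)) * sign(y[which.max(abs(y))]), 1.2 * max(y) + 1e-6),
    k = sgn * c(0.5, 2, 8) * 4 / span,  # shallow to steep on the x range
    x0 = stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ L / (1 + exp(-k * (x - x0))), data = dat,
        start = as.list(starts[i, ]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      cf <- stats::coef(fit)
      best <- list(L = unname(cf["L"]), k = unname(cf["k"]),
                   x0 = unname(cf["x0"]), rss = rss,
                   converged = isTRUE(fit$convInfo$isConv),
                   fitted = as.numeric(stats::fitted(fit)))
    }
  }
  if (is.null(best)) {
    return(structure(
      list(L = NA_real_, k = NA_real_, x0 = NA_real_, rss = NA_real_,
           converged = FALSE, boundary = FALSE, fitted = rep(NA_real_, length(x))),
      class = "logistic_fit"))
  }
  best$boundary <- FALSE
  structure(best, class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: L = %.4g, k = %.4g, x0 = %.4g (rss %.4g%s%s)\n",
              x$L, x$k, x$x0, x$rss,
              if (x$converged) "" else ", not converged",
              if (x$boundary) ", boundary solution" else ""))
  invisible(x)
}
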