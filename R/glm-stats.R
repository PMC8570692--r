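#' Design matrix for the spike-count regression
#'
#' Restricts a trial table to the sucrose-predicting odor, the
#' denatonium-predicting odor, and their mixtures (odors C and D are
#' excluded), and encodes the three regressors of the cue-evoked
#' spike-count model: `mixture` — the sucrose-odor proportion of the
#' stimulus on [0, 1] (1-df linear coding of the five stimuli 100%/0%,
#' 85%/15%, 50%/50%, 15%/85%, 0%/100%); `group` — indicator of the
#' air-puff group; and their `interaction`.
#'
#' @param trials trial table.
#' @param categorical also return `mixture_factor`, a factor coding of the
#'   stimulus, for users preferring a categorical model.
#' @return Data frame with `trial_id`, `mixture`, `group`, `interaction`
#'   (one row per included trial).
#' @examples
#' trials <- generate_trial_table(task_config(n_conditioning = 1, n_reversal = 0))
#' design <- encode_design(trials)
#' table(design$mixture)
#' @export
encode_design <- function(trials, categorical = FALSE) {
  known <- c("A", "B", "C", "D", "mix")
  bad <- setdiff(unique(trials$odor), known)
  if (length(bad) > 0L) {
    stop_invalid("unknown odor label(s): %s", paste(bad, collapse = ", "))
  }
  keep <- !is.na(trials$sucrose_prop)
  out <- data.frame(
    trial_id = trials$trial_id[keep],
    mixture = trials$sucrose_prop[keep],
    group = as.integer(trials$group[keep] == "air_puff")
  )
  out$interaction <- out$mixture * out$group
  if (categorical) {
    out$mixture_factor <- factor(out$mixture)
  }
  out
}

#' Poisson regression of cue-period spike counts
#'
#' Maximum-likelihood Poisson regression (log link, fitted by iteratively
#' reweighted least squares) of spike counts on mixture proportion,
#' air-puff group, and their interaction — the encoding model asking
#' whether cue-evoked firing scales with the sucrose proportion of the
#' stimulus and whether an aversive history shifts it. No exposure offset
#' is needed because all cue windows have equal length. Reported per
#' regressor: coefficient (log-rate units), standard error, and
#' z = coefficient / SE.
#'
#' @param counts non-negative integer spike counts, one per design row.
#' @param design data frame with columns `mixture` and `group`
#'   ([encode_design()] output, or any data frame with those columns).
#' @return An object of class `glm_result`: list with `coefficients`,
#'   `se`, `z`, `p_value` (named intercept/mixture/group/interaction,
#'   dropping aliased terms), `deviance`, `null_deviance`, `n`,
#'   `converged`, and the underlying `fit`.
#' @examples
#' d <- data.frame(mixture = rep(c(0, 1), 50), group = rep(0:1, each = 50))
#' y <- rpois(100, exp(1 + 0.5 * d$mixture))
#' fit_poisson_glm(y, d)
#' @export
fit_poisson_glm <- function(counts, design) {
  if (!all(c("mixture", "group") %in% names(design))) {
    stop_invalid("`design` must have columns mixture and group")
  }
  if (length(counts) != nrow(design)) {
    stop_invalid("`counts` must have one value per design row")
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    stop_invalid("`counts` must be non-negative integers")
  }
  dat <- data.frame(counts = as.numeric(counts),
                    mixture = design$mixture, group = design$group)
  # drop degenerate regressors (e.g. a single-group dataset) rather than
  # reporting aliased coefficients
  terms <- c("mixture", "group", "mixture:group")
  if (length(unique(dat$mixture)) < 2L) terms <- setdiff(terms, c("mixture", "mixture:group"))
  if (length(unique(dat$group)) < 2L) terms <- setdiff(terms, c("group", "mixture:group"))
  form <- stats::reformulate(if (length(terms)) terms else "1",
                             response = "counts")
  fit <- stats::glm(form, family = stats::poisson(), data = dat)
  if (!fit$converged) {
    stop_invalid("Poisson IRLS did not converge (deviance %.3g); check for separation",
                 fit$deviance)
  }
  sm <- summary(fit)$coefficients
  nm <- rownames(sm)
  nm[nm == "(Intercept)"] <- "intercept"
  nm[nm == "mixture:group"] <- "interaction"
  structure(
    list(coefficients = stats::setNames(sm[, 1], nm),
         se = stats::setNames(sm[, 2], nm),
         z = stats::setNames(sm[, 3], nm),
         p_value = stats::setNames(sm[, 4], nm),
         deviance = fit$deviance, null_deviance = fit$null.deviance,
         n = nrow(dat), converged = fit$converged, fit = fit),
    class = "glm_result"
  )
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("Poisson spike-count regression (n = %d, deviance %.1f)\n",
              x$n, x$deviance))
  print(round(data.frame(coef = x$coefficients, se = x$se, z = x$z,
                         p = x$p_value), 4))
  invisible(x)
}

#' Correlation between sucrose- and denatonium-evoked firing rates
#'
#' Pearson correlation, across units, of each unit's cue-evoked firing
#' rate on sucrose trials against its rate on denatonium trials, with a
#' percentile bootstrap 95% confidence interval over units. A positive
#' correlation indicates that neurons respond to both motivationally
#' significant cues with responses of similar sign.
#'
#' @param rate_sucrose,rate_denatonium paired per-unit firing rates
#'   (length >= 3).
#' @param n_boot bootstrap resamples (default 10000).
#' @param conf confidence level (default 0.95).
#' @param seed optional integer seed for the bootstrap.
#' @return List of class `correlation_result`: `r`, `ci_low`, `ci_high`,
#'   `n`, `n_boot`.
#' @export
cs_response_correlation <- function(rate_sucrose, rate_denatonium,
                                    n_boot = 10000L, conf = 0.95,
                                    seed = NULL) {
  x <- as.numeric(rate_sucrose); y <- as.numeric(rate_denatonium)
  if (length(x) != length(y)) stop_invalid("rate vectors must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_invalid("need at least 3 paired units")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_invalid("correlation undefined: zero variance in a rate vector")
  }
  r <- stats::cor(x, y)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) return(NA_real_)
      stats::cor(x[idx], y[idx])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2], n = n,
                 n_boot = as.integer(n_boot)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (95%% bootstrap CI %.3f to %.3f, n = %d units)\n",
              x$r, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Responsive-unit count summary
#'
#' Aggregates per-unit response classifications into the counts and the
#' responsive fraction reported for a population: units with firing-rate
#' increases, decreases, their sum as a percentage of all units, and the
#' percentage rounded to the nearest integer for reporting (the unrounded
#' value is retained).
#'
#' @param n_increase units with significant firing-rate increases.
#' @param n_decrease units with significant decreases.
#' @param n_total all units in the population.
#' @return One-row data frame: `n_increase`, `n_decrease`, `n_total`,
#'   `fraction_responsive_pct` (unrounded), `fraction_responsive_reported`
#'   (rounded to integer percent).
#' @examples
#' count_summary(5, 10, 35)  # 42.857%, reported 43%
#' @export
count_summary <- function(n_increase, n_decrease, n_total) {
  for (nm in c("n_increase", "n_decrease", "n_total")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v)) {
      stop_invalid("`%s` must be a non-negative integer", nm)
    }
  }
  if (n_increase + n_decrease > n_total) {
    stop_invalid("n_increase + n_decrease exceeds n_total")
  }
  frac <- if (n_total > 0) 100 * (n_increase + n_decrease) / n_total else 0
  data.frame(n_increase = n_increase, n_decrease = n_decrease,
             n_total = n_total, fraction_responsive_pct = frac,
             fraction_responsive_reported = round(frac))
}

#' Aggregate per-unit response directions by group
#'
#' Tabulates, for each experimental group, the number of units whose
#' cue-evoked firing significantly increased or decreased (from
#' [cue_response_change()] directions) and the responsive fraction.
#'
#' @param units data frame with one row per unit: columns `group` and
#'   `direction` (`"increase"`, `"decrease"`, or `"none"`).
#' @return Data frame with one row per group, as [count_summary()], plus
#'   the `group` column. Category counts always sum to the per-group
#'   total.
#' @export
aggregate_counts <- function(units) {
  if (!all(c("group", "direction") %in% names(units))) {
    stop_invalid("`units` must have columns group and direction")
  }
  groups <- sort(unique(units$group))
  out <- do.call(rbind, lapply(groups, function(g) {
    u <- units[units$group == g, , drop = FALSE]
    cbind(group = g,
          count_summary(sum(u$direction == "increase"),
                        sum(u$direction == "decrease"),
                        nrow(u)))
  }))
  rownames(out) <- NULL
  out
}
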