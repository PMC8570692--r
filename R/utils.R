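# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generator calls do
#' not perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-unit RNG stream: each unit's data depend only on the
# master seed and its own id, so the composition of a unit set does not
# change any single unit's spikes. Kept below 2^31 - 1.
derive_unit_seed <- function(master_seed, unit_id) {
  as.integer((as.numeric(master_seed) %% 2147483647 * 10007 +
                as.numeric(unit_id) * 9973) %% 2147483629) + 1L
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, positive = FALSE, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stop_invalid("`%s` must be strictly positive", name)
  if (x < lower || x > upper) {
    stop_invalid("`%s` must be in [%s, %s]", name, lower, upper)
  }
  invisible(x)
}

check_window <- function(window, name = "window") {
  if (!is.numeric(window) || length(window) != 2L || any(!is.finite(window))) {
    stop_invalid("`%s` must be two finite numbers", name)
  }
  if (window[2] <= window[1]) {
    stop_invalid("`%s` must satisfy start < end", name)
  }
  invisible(window)
}

check_sorted_times <- function(x, name = "spike_times") {
  if (length(x) == 0L) return(invisible(x))
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_invalid("`%s` must be finite numeric times", name)
  }
  if (is.unsorted(x)) {
    stop_invalid("`%s` must be sorted ascending", name)
  }
  invisible(x)
}

# Sequential refractory thinning: drop every spike closer than `tau` to the
# last retained spike. Equivalent to a left-to-right scan, implemented by
# repeatedly removing the first offender of each violating run.
enforce_refractory <- function(s, tau) {
  if (tau <= 0 || length(s) < 2L) return(s)
  repeat {
    bad <- which(diff(s) < tau) + 1L
    if (length(bad) == 0L) return(s)
    s <- s[-bad[c(TRUE, diff(bad) > 1L)]]
  }
}

# Uniformly scattered homogeneous Poisson events on [t0, t1) at `rate`.
poisson_events <- function(rate, t0, t1) {
  len <- t1 - t0
  if (len <= 0 || rate <= 0) return(numeric(0))
  n <- stats::rpois(1L, rate * len)
  if (n == 0L) return(numeric(0))
  sort(stats::runif(n, t0, t1))
}
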