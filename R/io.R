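# Delimited-text interfaces. Times are written with 6 decimal places;
# absent values (sucrose_prop on C/D trials, outcome_time on unreinforced
# trials) are empty fields.

fmt_time <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))

#' Write a trial table to CSV
#'
#' @param trials a trial table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- data.frame(
    trial_id = trials$trial_id, session = trials$session,
    phase = trials$phase, odor = trials$odor,
    sucrose_prop = ifelse(is.na(trials$sucrose_prop), "",
                          sprintf("%.2f", trials$sucrose_prop)),
    outcome = trials$outcome,
    odor_on = fmt_time(trials$odor_on), odor_off = fmt_time(trials$odor_off),
    outcome_time = fmt_time(trials$outcome_time),
    laser = trials$laser, group = trials$group,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' @param path file written by [write_trials()] (or following the same
#'   contract).
#' @return A `trial_table` data frame.
#' @export
read_trials <- function(path) {
  cols <- c(trial_id = "integer", session = "integer", phase = "character",
            odor = "character", sucrose_prop = "numeric",
            outcome = "character", odor_on = "numeric", odor_off = "numeric",
            outcome_time = "numeric", laser = "logical", group = "character")
  out <- utils::read.csv(path, colClasses = unname(cols),
                         stringsAsFactors = FALSE)
  missing <- setdiff(names(cols), names(out))
  if (length(missing) > 0L) {
    stop_invalid("trials file lacks column(s): %s",
                 paste(missing, collapse = ", "))
  }
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Write / read lick events
#'
#' `licks.csv` has columns `trial_id,lick_time`.
#' @param licks data frame with `trial_id`, `lick_time`.
#' @param path file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_licks <- function(licks, path) {
  out <- data.frame(trial_id = licks$trial_id,
                    lick_time = fmt_time(licks$lick_time))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_licks
#' @export
read_licks <- function(path) {
  utils::read.csv(path, colClasses = c("integer", "numeric"),
                  stringsAsFactors = FALSE)
}

#' Write / read spike trains
#'
#' `spikes.csv` has columns `unit_id,spike_time`, pooled across units.
#' @param units list of `unit_recording` objects.
#' @param path file path.
#' @return `path` (write); a named list of sorted spike-time vectors
#'   (read).
#' @export
write_spikes <- function(units, path) {
  out <- do.call(rbind, lapply(units, function(u) {
    data.frame(unit_id = u$unit_id, spike_time = fmt_time(u$spikes))
  }))
  if (is.null(out)) out <- data.frame(unit_id = integer(0), spike_time = character(0))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  df <- utils::read.csv(path, colClasses = c("integer", "numeric"),
                        stringsAsFactors = FALSE)
  lapply(split(df$spike_time, df$unit_id), sort)
}

#' Write / read light-pulse protocols
#'
#' `pulses.csv` has columns
#' `unit_id,pulse_time,triggered,trigger_spike_time`.
#' @param units list of `unit_recording` objects.
#' @param path file path.
#' @return `path` (write); a named list of pulse data frames (read).
#' @export
write_pulses <- function(units, path) {
  out <- do.call(rbind, lapply(units, function(u) {
    data.frame(unit_id = u$unit_id, pulse_time = fmt_time(u$pulses$pulse_time),
               triggered = u$pulses$triggered,
               trigger_spike_time = fmt_time(u$pulses$trigger_spike_time))
  }))
  if (is.null(out)) {
    out <- data.frame(unit_id = integer(0), pulse_time = character(0),
                      triggered = logical(0), trigger_spike_time = character(0))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pulses
#' @export
read_pulses <- function(path) {
  df <- utils::read.csv(path, colClasses = c("integer", "numeric", "logical",
                                             "numeric"),
                        stringsAsFactors = FALSE)
  lapply(split(df[c("pulse_time", "triggered", "trigger_spike_time")],
               df$unit_id),
         function(d) d[order(d$pulse_time), , drop = FALSE])
}

#' Write / read cluster features
#'
#' `features.csv` has columns `unit_id,label,f1..fK`; `label` is the
#' cluster assignment of each spike and `unit_id` the cluster under
#' scrutiny.
#' @param features numeric feature matrix.
#' @param labels cluster label per row.
#' @param unit_id cluster/unit identifier.
#' @param path file path.
#' @param append append to an existing file (for several units).
#' @return `path` (write); a list per unit with `features` and `labels`
#'   (read).
#' @export
write_features <- function(features, labels, unit_id, path, append = FALSE) {
  df <- cbind(data.frame(unit_id = unit_id, label = labels),
              as.data.frame(features))
  names(df)[-(1:2)] <- paste0("f", seq_len(ncol(features)))
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$unit_id), function(d) {
    list(features = as.matrix(d[, grep("^f[0-9]+$", names(d)), drop = FALSE]),
         labels = d$label)
  })
}
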