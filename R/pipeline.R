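#' Default synthetic population of unit specifications
#'
#' Builds a mixed population for demonstration and end-to-end runs: a
#' configurable fraction of cue-responsive units (positive cue gain, with
#' group hyperactivity in the air-puff group), a fraction of optotagged
#' antidromic projection units, one orthodromic-like unit (responds to
#' light but fails the collision test) and one poorly isolated unit per
#' dozen to exercise quality control.
#'
#' @param n_units population size.
#' @param frac_responsive fraction with positive cue gain.
#' @param frac_tagged fraction of antidromic optotagged units.
#' @param cue_gain cue-gain slope of responsive units.
#' @param group_gain air-puff-group cue-period gain of responsive units.
#' @param baseline_rate spontaneous rate, spikes/s.
#' @return List of [unit_spec()] objects.
#' @export
demo_unit_specs <- function(n_units = 12L, frac_responsive = 0.4,
                            frac_tagged = 0.25, cue_gain = 2.0,
                            group_gain = 1.4, baseline_rate = 5.0) {
  if (n_units == 0L) return(list())
  n_resp <- round(frac_responsive * n_units)
  n_tag <- round(frac_tagged * n_units)
  lapply(seq_len(n_units), function(i) {
    unit_spec(
      unit_id = i,
      baseline_rate = baseline_rate,
      cue_gain = if (i <= n_resp) cue_gain else 0,
      group_gain = if (i <= n_resp) group_gain else 1,
      tagged = i <= n_tag + 1L,
      antidromic = i <= n_tag,            # unit n_tag+1 is orthodromic-like
      tag_latency_ms = 3 + (i %% 5),
      tag_reliability = 0.9
    )
  })
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full simulation and analysis pipeline
#'
#' Orchestrates simulate -> QC -> behavior -> ephys -> optotag -> GLM into
#' one reproducible run: generates a session schedule, licks, spike
#' trains, light protocols and cluster features from `config`, analyzes
#' them with the package's modules, and writes every stage's table plus a
#' machine-readable `report.json` and a `manifest.json` (config hash,
#' seed, output checksums, per-stage status). Identical configuration and
#' seed give byte-identical outputs. A failing stage leaves completed
#' outputs in place and is recorded as failed in the manifest; stages that
#' need units report status `"no-units"` when the population is empty.
#'
#' Neural analyses run on the first probe session (which contains the
#' mixture stimuli the encoding model needs), or the last session when no
#' probe is configured.
#'
#' @param config a [task_config()].
#' @param out_dir output directory (created if needed).
#' @param unit_specs list of [unit_spec()] (default [demo_unit_specs()]).
#' @param lick_par a [lick_params()].
#' @param feature_separation cluster separation of each unit's simulated
#'   features (recycled; values below ~2 make the unit fail QC).
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly (list with `status` per stage).
#' @examples
#' \donttest{
#' cfg <- task_config(n_conditioning = 1, n_reversal = 0, seed = 7)
#' run_pipeline(cfg, tempfile("run"), unit_specs = demo_unit_specs(4))
#' }
#' @export
run_pipeline <- function(config, out_dir,
                         unit_specs = demo_unit_specs(),
                         lick_par = lick_params(),
                         feature_separation = 8,
                         quiet = FALSE) {
  if (!inherits(config, "task_config")) {
    stop_invalid("`config` must be a task_config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- if (quiet) function(...) invisible() else stage_log
  status <- list()
  outputs <- character(0)
  pth <- function(f) file.path(out_dir, f)

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      status[[name]] <<- paste("failed:", conditionMessage(res))
      log(name, status[[name]])
      NULL
    } else {
      if (is.null(status[[name]])) status[[name]] <<- "ok"
      log(name, status[[name]])
      res
    }
  }

  # --- simulate -------------------------------------------------------
  sim <- run_stage("simulate", function() {
    trials <- generate_trial_table(config)
    licks <- simulate_licks(trials, lick_par,
                            seed = derive_unit_seed(config$seed, 0L))
    probe_sessions <- unique(trials$session[trials$phase == "probe"])
    target <- if (length(probe_sessions) > 0L) probe_sessions[1] else
      max(trials$session)
    sess <- trials[trials$session == target, , drop = FALSE]
    attr(sess, "config") <- config
    sep <- rep_len(feature_separation, length(unit_specs))
    units <- lapply(seq_along(unit_specs), function(i) {
      u <- simulate_unit(sess, unit_specs[[i]])
      u$features <- simulate_cluster_features(
        c(400L, 400L), n_dims = 4L, separation = sep[i],
        seed = derive_unit_seed(config$seed, 100000L + unit_specs[[i]]$unit_id))
      u
    })
    write_trials(trials, pth("trials.csv"))
    write_licks(licks, pth("licks.csv"))
    write_spikes(units, pth("spikes.csv"))
    write_pulses(units, pth("pulses.csv"))
    for (i in seq_along(units)) {
      write_features(units[[i]]$features$features, units[[i]]$features$labels,
                     units[[i]]$unit_id, pth("features.csv"), append = i > 1)
    }
    outputs <<- c(outputs, "trials.csv", "licks.csv", "spikes.csv",
                  "pulses.csv", if (length(units) > 0) "features.csv")
    list(trials = trials, licks = licks, units = units, session = sess)
  })
  if (is.null(sim)) {
    return(invisible(write_manifest(config, out_dir, outputs, status)))
  }
  no_units <- length(sim$units) == 0L

  # --- behavior -------------------------------------------------------
  behavior <- run_stage("behavior", function() {
    rates <- epoch_lick_rate(sim$licks, sim$trials,
                             window = c(0, config$odor_duration +
                                          config$trace_delay))
    utils::write.csv(rates, pth("lick_rates.csv"), row.names = FALSE)
    curve <- learning_curve(rates)
    utils::write.csv(curve, pth("learning_curve.csv"), row.names = FALSE)
    ext <- suppressWarnings(extinction_curve(rates))
    utils::write.csv(ext, pth("extinction_curve.csv"), row.names = FALSE)
    outputs <<- c(outputs, "lick_rates.csv", "learning_curve.csv",
                  "extinction_curve.csv")
    list(rates = rates, curve = curve, extinction = ext)
  })

  # --- unit QC --------------------------------------------------------
  sess_dur <- unname(session_duration(sim$trials)[
    as.character(sim$session$session[1])])
  qc <- run_stage("qc", function() {
    if (no_units) {
      status[["qc"]] <<- "no-units"
      return(data.frame())
    }
    out <- do.call(rbind, lapply(sim$units, function(u) {
      in_session <- u$spikes[u$spikes <= sess_dur]
      cbind(unit_id = u$unit_id,
            qc_metrics(in_session, sess_dur,
                       features = u$features$features,
                       labels = u$features$labels, cluster_id = 1L))
    }))
    utils::write.csv(out, pth("qc.csv"), row.names = FALSE)
    outputs <<- c(outputs, "qc.csv")
    out
  })

  # --- ephys: auROC discriminability ----------------------------------
  cue_win <- c(0, config$odor_duration + config$trace_delay)
  ephys <- run_stage("ephys", function() {
    if (no_units) {
      status[["ephys"]] <<- "no-units"
      return(NULL)
    }
    keep <- qc$unit_id[qc$passes]
    suc <- sim$session$outcome == "sucrose"
    den <- sim$session$outcome == "denatonium"
    profiles <- list(); cats <- list()
    for (u in sim$units) {
      if (!u$unit_id %in% keep) next
      r <- align_spikes(u$spikes, sim$session, window = c(-1, cue_win[2]))
      prof <- binned_auroc(r, suc, den)
      chg <- cue_response_change(r, cue_window = cue_win)
      profiles[[length(profiles) + 1L]] <-
        cbind(unit_id = u$unit_id, prof[c("bin_start", "auroc")])
      cats[[length(cats) + 1L]] <- data.frame(
        unit_id = u$unit_id, group = config$group,
        category = classify_discriminative(prof, cue_window = cue_win),
        change = chg$change, p_value = chg$p_value,
        direction = chg$direction, stringsAsFactors = FALSE)
    }
    if (length(profiles) == 0L) {
      status[["ephys"]] <<- "no-passing-units"
      return(NULL)
    }
    profiles <- do.call(rbind, profiles)
    cats <- do.call(rbind, cats)
    utils::write.csv(profiles, pth("auroc_profiles.csv"), row.names = FALSE)
    utils::write.csv(cats, pth("unit_categories.csv"), row.names = FALSE)
    outputs <<- c(outputs, "auroc_profiles.csv", "unit_categories.csv")
    list(profiles = profiles, categories = cats)
  })

  # --- optotag --------------------------------------------------------
  opto <- run_stage("optotag", function() {
    if (no_units) {
      status[["optotag"]] <<- "no-units"
      return(NULL)
    }
    out <- do.call(rbind, lapply(sim$units, function(u) {
      cbind(unit_id = u$unit_id, optotag_unit(u$spikes, u$pulses))
    }))
    utils::write.csv(out, pth("optotag.csv"), row.names = FALSE)
    outputs <<- c(outputs, "optotag.csv")
    out
  })

  # --- GLM encoding ----------------------------------------------------
  glm_res <- run_stage("glm", function() {
    if (no_units || is.null(ephys)) {
      status[["glm"]] <<- "no-units"
      return(NULL)
    }
    design <- encode_design(sim$session)
    row_of <- match(design$trial_id, sim$session$trial_id)
    keep <- qc$unit_id[qc$passes]
    tabs <- list(); rate_s <- numeric(0); rate_d <- numeric(0)
    for (u in sim$units) {
      if (!u$unit_id %in% keep) next
      r <- align_spikes(u$spikes, sim$session, window = c(-1, cue_win[2]))
      counts <- vapply(r$aligned, function(s)
        sum(s >= cue_win[1] & s < cue_win[2]), numeric(1))
      tabs[[length(tabs) + 1L]] <- cbind(design, counts = counts[row_of],
                                         unit_id = u$unit_id)
      rate_s <- c(rate_s, mean(counts[sim$session$outcome == "sucrose"]) /
                    diff(cue_win))
      rate_d <- c(rate_d, mean(counts[sim$session$outcome == "denatonium"]) /
                    diff(cue_win))
    }
    if (length(tabs) == 0L) {
      status[["glm"]] <<- "no-units"
      return(NULL)
    }
    pooled <- do.call(rbind, tabs)
    utils::write.csv(pooled, pth("unit_trial_counts.csv"), row.names = FALSE)
    outputs <<- c(outputs, "unit_trial_counts.csv")
    fit <- fit_poisson_glm(pooled$counts, pooled)
    corr <- if (length(rate_s) >= 3 && stats::sd(rate_s) > 0 &&
                stats::sd(rate_d) > 0) {
      cs_response_correlation(rate_s, rate_d, n_boot = 2000L,
                              seed = derive_unit_seed(config$seed, 999983L))
    } else NULL
    counts_by_group <- if (!is.null(ephys$categories))
      aggregate_counts(ephys$categories) else NULL
    jsonlite::write_json(
      list(coefficients = as.list(fit$coefficients), se = as.list(fit$se),
           z = as.list(fit$z), p_value = as.list(fit$p_value),
           deviance = fit$deviance, n = fit$n,
           cs_correlation = if (!is.null(corr))
             corr[c("r", "ci_low", "ci_high", "n")] else NULL),
      pth("glm_results.json"), auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(counts_by_group, pth("counts_summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    outputs <<- c(outputs, "glm_results.json", "counts_summary.json")
    list(fit = fit, correlation = corr, counts = counts_by_group)
  })

  # --- report + manifest ----------------------------------------------
  run_stage("report", function() {
    report <- list(
      seed = config$seed,
      group = config$group,
      n_trials = nrow(sim$trials),
      n_units = length(sim$units),
      qc = if (!no_units && !is.null(qc)) qc else NULL,
      categories = if (!is.null(ephys)) ephys$categories else NULL,
      optotag = opto,
      glm = if (!is.null(glm_res)) list(
        coefficients = as.list(glm_res$fit$coefficients),
        z = as.list(glm_res$fit$z),
        n = glm_res$fit$n) else NULL,
      cs_correlation = if (!is.null(glm_res) && !is.null(glm_res$correlation))
        glm_res$correlation[c("r", "ci_low", "ci_high", "n")] else NULL,
      count_summary = if (!is.null(glm_res)) glm_res$counts else NULL
    )
    jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
    outputs <<- c(outputs, "report.json")
    NULL
  })

  invisible(write_manifest(config, out_dir, outputs, status))
}

# Manifest: config hash, seed, output checksums, per-stage status.
# Deliberately timestamp-free so identical runs are byte-identical.
write_manifest <- function(config, out_dir, outputs, status) {
  cfg_file <- file.path(out_dir, "config.json")
  cfg <- unclass(config)
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA)
  files <- unique(outputs)
  sums <- tools::md5sum(file.path(out_dir, files))
  names(sums) <- files
  manifest <- list(
    package = "gonogo",
    version = as.character(utils::packageVersion("gonogo")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    status = status,
    checksums = as.list(sums)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
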