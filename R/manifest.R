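# Seeded-run provenance. Every file-writing pipeline entry point records a
# manifest (JSON) alongside its outputs: the command, the full generating
# configuration (inline, so the manifest is self-contained), the seeds, the
# package version, and the md5 of each output. `replay_manifest()` re-runs
# the recorded command; because every source of randomness is seeded from
# the recorded configuration, replays reproduce the CSV outputs
# byte-for-byte.

.manifest_payload <- function(command, config_lists, outputs, seed) {
  list(command = command,
       package = "gonogo",
       package_version = as.character(utils::packageVersion("gonogo")),
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
       seed = seed,
       config = config_lists,
       outputs = data.frame(
         file = basename(outputs),
         md5 = unname(tools::md5sum(outputs)),
         stringsAsFactors = FALSE))
}

.write_manifest <- function(payload, outdir) {
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a cohort and write it to disk (with manifest)
#'
#' Writes one event-log CSV per subject-day (`<group>_s<subject>_d<day>.csv`),
#' a `truth.csv` of ground-truth policy parameters, a `metrics.csv` of
#' per-session behavioral metrics, and a self-contained `manifest.json`
#' from which [replay_manifest()] can reproduce every file byte-for-byte.
#'
#' @param spec a [cohort_spec()].
#' @param config a [task_config()].
#' @param outdir output directory (created if needed).
#' @return The cohort object, invisibly.
#' @export
simulate_cohort_files <- function(spec, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(spec, config)
  paths <- character(0)
  for (key in names(cohort$logs)) {
    p <- file.path(outdir, paste0(key, ".csv"))
    write_event_log(cohort$logs[[key]], p)
    paths <- c(paths, p)
  }
  truth_path <- file.path(outdir, "truth.csv")
  utils::write.csv(cohort$truth, truth_path, row.names = FALSE, quote = FALSE)
  metrics_path <- file.path(outdir, "metrics.csv")
  utils::write.csv(cohort_metrics(cohort), metrics_path, row.names = FALSE,
                   quote = FALSE)
  payload <- .manifest_payload(
    command = "simulate-cohort",
    config_lists = list(task = unclass(config),
                        cohort = list(n_per_group = spec$n_per_group,
                                      n_days = spec$n_days,
                                      base_seed = spec$base_seed,
                                      control = unclass(spec$control),
                                      defeated = unclass(spec$defeated))),
    outputs = c(paths, truth_path, metrics_path),
    seed = spec$base_seed)
  .write_manifest(payload, outdir)
  invisible(cohort)
}

#' Generate a synthetic calcium session and write it to disk (with manifest)
#'
#' Writes `traces.csv` (neurons x frames), `cues.csv` (cue events) and
#' `truth.csv` (per-neuron modulation ground truth), plus a `manifest.json`
#' for [replay_manifest()].
#'
#' @param spec a [calcium_sim_spec()].
#' @param outdir output directory (created if needed).
#' @return The simulation (list of `trace`, `truth`), invisibly.
#' @export
simulate_calcium_files <- function(spec, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_calcium(spec)
  trace_path <- file.path(outdir, "traces.csv")
  cue_path <- file.path(outdir, "cues.csv")
  write_trace_csv(sim$trace, trace_path, cue_path)
  truth_path <- file.path(outdir, "truth.csv")
  utils::write.csv(
    data.frame(neuron = rownames(sim$trace$values),
               modulated = seq_len(spec$n_neurons) %in%
                 sim$truth$modulated_ids,
               rate_gain = sim$truth$rate_gain),
    truth_path, row.names = FALSE, quote = FALSE)
  outputs <- c(trace_path, truth_path,
               if (!is.null(sim$trace$cue_events)) cue_path)
  sp <- unclass(spec)
  sp$cue_labels <- NULL
  payload <- .manifest_payload(
    command = "synth-calcium",
    config_lists = list(calcium = sp),
    outputs = outputs,
    seed = spec$seed)
  .write_manifest(payload, outdir)
  invisible(sim)
}

.policy_from_list <- function(lst) {
  do.call(agent_policy, lst)
}

#' Re-run a recorded pipeline from its manifest
#'
#' Reads a `manifest.json` written by [simulate_cohort_files()] or
#' [simulate_calcium_files()], reconstructs the generating configuration,
#' and re-executes the command into `outdir`. With the recorded seeds the
#' CSV outputs are byte-identical to the originals.
#'
#' @param manifest_path path to a `manifest.json`.
#' @param outdir directory to write the replayed outputs to.
#' @return `outdir`, invisibly.
#' @export
replay_manifest <- function(manifest_path, outdir) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(m$command)) {
    stop("manifest error: no `command` field in ", manifest_path,
         call. = FALSE)
  }
  if (m$command == "simulate-cohort") {
    cfg_args <- m$config$task
    config <- do.call(task_config, cfg_args)
    ch <- m$config$cohort
    spec <- cohort_spec(n_per_group = ch$n_per_group, n_days = ch$n_days,
                        control = .policy_from_list(ch$control),
                        defeated = .policy_from_list(ch$defeated),
                        base_seed = ch$base_seed)
    simulate_cohort_files(spec, config, outdir)
  } else if (m$command == "synth-calcium") {
    sp <- m$config$calcium
    if (is.null(sp$cue_frames)) sp$cue_frames <- integer(0)
    spec <- do.call(calcium_sim_spec, sp)
    simulate_calcium_files(spec, outdir)
  } else {
    stop("manifest error: unknown command `", m$command, "`", call. = FALSE)
  }
  invisible(outdir)
}
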