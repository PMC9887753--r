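#' Analysis parameter set
#'
#' One place for every tunable of the per-cell pipeline, so a run manifest
#' can record them all.
#'
#' @param f0_frames Baseline window length for F0 (10..40 frames).
#' @param rise_threshold Derivative-over-noise threshold for the first-rise
#'   locator.
#' @param min_prominence Spike detection prominence threshold in dF/F0
#'   units; `NULL` = 5x the robust noise scale of the trace.
#' @param onset_fraction Fraction of the local rise defining spike onset.
#' @param min_separation Minimum peak spacing in seconds; `NULL` = half the
#'   pacing interval.
#' @param latency_max Maximum stimulus-to-onset latency (s).
#' @param cv_threshold Maximum paced-amplitude CV for eligibility.
#' @param min_spikes Minimum paced spikes for eligibility.
#' @param rng_seed Seed for the random systolic-spike selection; mandatory,
#'   there is no default, so that every stochastic step is reproducible from
#'   the manifest.
#' @return An `analysis_params` list.
#' @export
analysis_params <- function(f0_frames = 30, rise_threshold = 5,
                            min_prominence = NULL, onset_fraction = 0.10,
                            min_separation = NULL, latency_max = 0.2,
                            cv_threshold = 0.25, min_spikes = 30L,
                            rng_seed = NULL) {
  if (is.null(rng_seed)) {
    stopf("rng_seed is mandatory: the systolic-spike selection is random")
  }
  structure(list(f0_frames = f0_frames, rise_threshold = rise_threshold,
                 min_prominence = min_prominence,
                 onset_fraction = onset_fraction,
                 min_separation = min_separation, latency_max = latency_max,
                 cv_threshold = cv_threshold, min_spikes = min_spikes,
                 rng_seed = as.integer(rng_seed)),
            class = "analysis_params")
}

#' Analyze one background-subtracted recording end to end
#'
#' Runs the full per-cell pipeline: locate the first rise, estimate F0,
#' normalize to dF/F0, detect and annotate spikes, apply eligibility QC,
#' segment the caffeine protocol, fit the final paced and caffeine decays,
#' fit one randomly chosen paced spike, and assemble the summary row.
#' Ineligible cells (and cells whose fits fail) keep their QC/diagnostic
#' fields but carry `NA` kinetics; they never abort a cohort run.
#'
#' @param trace A background-subtracted [fluor_trace()].
#' @param protocol A [protocol_descriptor()].
#' @param params An [analysis_params()].
#' @param cell_id,animal_id,group Identifiers for the summary row.
#' @return A `cell_analysis` list: `summary` (one-row data.frame), `spikes`,
#'   `qc`, `phases`, `fits` (list: `stim`, `caffeine`, `random`), `ntrace`.
#' @export
analyze_trace <- function(trace, protocol, params,
                          cell_id = trace$metadata$cell_id,
                          animal_id = NA_character_,
                          group = trace$metadata$group) {
  stopifnot(inherits(params, "analysis_params"))
  if (is.null(cell_id)) cell_id <- "cell"
  if (is.null(group)) group <- NA_character_

  ntrace <- normalize_trace(trace, f0_frames = params$f0_frames,
                            rise_threshold = params$rise_threshold)
  min_sep <- if (is.null(params$min_separation)) {
    0.5 / protocol$pacing_freq_hz
  } else {
    params$min_separation
  }
  spikes <- detect_spikes(ntrace, min_prominence = params$min_prominence,
                          min_separation = min_sep,
                          onset_fraction = params$onset_fraction)

  phases <- segment_protocol(ntrace, protocol, expect_caffeine = FALSE)
  proto2 <- protocol
  if (!is.null(phases$caffeine)) proto2$caffeine_s <- phases$caffeine[1]
  spikes <- assign_stimuli(spikes, proto2, latency_max = params$latency_max)
  qc <- qc_cell(spikes, cv_threshold = params$cv_threshold,
                min_spikes = params$min_spikes)

  caffeine <- NULL
  random_fit <- NULL
  random_row <- NA_integer_
  if (qc$eligible && !is.null(phases$caffeine)) {
    caffeine <- tryCatch(caffeine_analysis(ntrace, phases, spikes),
                         error = function(e) NULL)
    paced_rows <- which(!spikes$stimulus_label %in% c("ectopic", "caffeine"))
    if (length(paced_rows)) {
      sel <- select_systolic_spike(spikes[paced_rows, , drop = FALSE],
                                   seed = params$rng_seed)
      random_row <- paced_rows[sel]
      seg <- decay_segment_bounds(spikes, random_row, length(ntrace$value))
      if (seg[2] - seg[1] >= 4L) {
        random_fit <- fit_decay(ntrace$time[seg[1]:seg[2]],
                                ntrace$value[seg[1]:seg[2]])
      }
    }
  }

  summary <- summarize_cell(cell_id, animal_id, group, qc, spikes,
                            caffeine = caffeine, random_fit = random_fit,
                            random_spike_row = random_row)
  structure(list(summary = summary, spikes = spikes, qc = qc,
                 phases = phases,
                 fits = list(stim = caffeine$stim_fit,
                             caffeine = caffeine$caf_fit,
                             random = random_fit),
                 ntrace = ntrace),
            class = "cell_analysis")
}

#' Analyze a simulated cohort
#'
#' Applies [analyze_trace()] to every cell of a [simulate_cohort()] result,
#' deriving each cell's protocol descriptor from its simulation
#' configuration and subtracting the simulated camera background recorded in
#' the trace metadata. Per-cell failures are logged and skipped; the run
#' continues.
#'
#' @param cohort A `sim_cohort`.
#' @param params An [analysis_params()]; each cell's systolic-spike draw
#'   uses a child seed of `params$rng_seed`.
#' @param verbose Print per-cell QC/exclusion messages?
#' @return A `cohort_analysis` list: `summary` (one row per cell),
#'   `details` (per-cell `cell_analysis`), `excluded` (character log).
#' @export
analyze_cohort <- function(cohort, params, verbose = FALSE) {
  stopifnot(inherits(cohort, "sim_cohort"))
  rows <- vector("list", length(cohort))
  details <- vector("list", length(cohort))
  excluded <- character(0)
  for (i in seq_along(cohort)) {
    cell <- cohort[[i]]
    cfg <- cell$config
    protocol <- protocol_descriptor(pacing_freq_hz = cfg$pacing_freq,
                                    pacing_stop_s = cfg$paced_duration,
                                    stim_start_s = cfg$stim_start)
    p_i <- params
    p_i$rng_seed <- child_seed(params$rng_seed, i)
    res <- tryCatch({
      tr <- subtract_background(cell$trace)
      analyze_trace(tr, protocol, p_i, cell_id = cell$cell_id,
                    group = cell$group)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded <- c(excluded,
                    sprintf("%s: %s", cell$cell_id, conditionMessage(res)))
      if (verbose) message("excluded ", cell$cell_id, ": ",
                           conditionMessage(res))
      next
    }
    if (!res$qc$eligible) {
      excluded <- c(excluded, sprintf("%s: ineligible (%s)", cell$cell_id,
                                      paste(res$qc$reasons, collapse = ";")))
      if (verbose) message(cell$cell_id, " ineligible: ",
                           paste(res$qc$reasons, collapse = ";"))
    }
    rows[[i]] <- res$summary
    details[[i]] <- res
  }
  summary <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  structure(list(summary = summary, details = details, excluded = excluded),
            class = "cohort_analysis")
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the package version, every
#' analysis parameter, the simulation configuration or input paths, seeds,
#' and the exclusion log.
#'
#' @param path Output JSON path.
#' @param params An [analysis_params()].
#' @param config Optional [sim_config()] or list of input paths.
#' @param excluded Character vector of exclusion log lines.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(path, params, config = NULL,
                           excluded = character(0)) {
  manifest <- list(
    package = "catrace",
    version = as.character(utils::packageVersion("catrace")),
    params = unclass(params),
    config = if (is.null(config)) NULL else unclass(config),
    excluded = excluded
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Write a cohort summary as TSV
#'
#' @param summary `summary` data.frame from [analyze_cohort()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary_tsv <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
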