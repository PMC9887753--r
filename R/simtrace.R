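#' Simulation configuration for a paced Ca2+ recording
#'
#' Describes one synthetic Fluo-4 recording of a field-stimulated
#' cardiomyocyte: a paced phase of periodic transients, a stop-pacing pause,
#' and (optionally) a terminal caffeine transient that empties the SR. Each
#' transient rises linearly over `time_to_peak` and then decays as a single
#' exponential; paced (and ectopic) transients decay at the systolic rate
#' `k_serca + k_ncx` (SERCA2 reuptake plus NCX extrusion acting together)
#' while the caffeine transient decays at `k_ncx` alone, because caffeine
#' holds RyRs open and defeats net SR reuptake. Overlapping transients add
#' linearly.
#'
#' The recorded raw intensity is
#' `F(t) = background_level + f0_baseline * (1 + s(t)) + noise`,
#' with `s(t)` the summed transient signal on the dF/F0 scale, so the
#' signal-to-noise ratio on the dF/F0 scale is
#' `amplitude_mean * f0_baseline / noise_sd`. The defaults (amplitude 1.0,
#' baseline 500, noise sd 25) give SNR 20.
#'
#' @param frame_rate Acquisition rate, frames per second.
#' @param pacing_freq Field-stimulation frequency, Hz.
#' @param paced_duration Length of the paced phase, seconds.
#' @param pause_duration Stop-pacing pause before caffeine, seconds.
#' @param amplitude_mean Mean paced transient amplitude, dF/F0 units.
#' @param amplitude_cv Fractional spike-to-spike amplitude variability.
#' @param time_to_peak Rise time from onset to peak, seconds.
#' @param k_serca SERCA2 contribution to the decay rate constant, 1/s.
#' @param k_ncx NCX contribution to the decay rate constant, 1/s.
#' @param caffeine_amplitude Caffeine transient amplitude, dF/F0 units; must
#'   be at least `amplitude_mean` (caffeine releases the whole SR content).
#' @param f0_baseline Resting fluorescence F0, intensity units.
#' @param background_level Camera background, intensity units.
#' @param noise_sd Additive noise standard deviation, intensity units
#'   (Gaussian model; ignored under the Poisson model).
#' @param ectopic_rate Rate of spontaneous (unstimulated) transients, 1/s.
#' @param include_caffeine Append the caffeine transient and tail?
#' @param caffeine_tail Recording time after caffeine onset, seconds.
#' @param stim_start Time of the first stimulus, seconds; leaves a pre-rise
#'   baseline segment from which F0 is estimated.
#' @param caffeine_onset_jitter SD of Gaussian jitter on the caffeine onset,
#'   seconds (0 = onset exactly at the end of the pause).
#' @param noise_model `"gaussian"` (additive, camera-dominated regime) or
#'   `"poisson"` (photon-counting; the per-pixel mean is used as the rate).
#' @param seed Integer seed; identical configurations give identical output.
#'
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(frame_rate = 97,
                       pacing_freq = 0.5,
                       paced_duration = 180,
                       pause_duration = 60,
                       amplitude_mean = 1.0,
                       amplitude_cv = 0.1,
                       time_to_peak = 0.05,
                       k_serca = 3.5,
                       k_ncx = 1.5,
                       caffeine_amplitude = 1.4,
                       f0_baseline = 500,
                       background_level = 100,
                       noise_sd = 25,
                       ectopic_rate = 0,
                       include_caffeine = TRUE,
                       caffeine_tail = 30,
                       stim_start = 1.0,
                       caffeine_onset_jitter = 0,
                       noise_model = c("gaussian", "poisson"),
                       seed = 1L) {
  cfg <- list(frame_rate = frame_rate, pacing_freq = pacing_freq,
              paced_duration = paced_duration, pause_duration = pause_duration,
              amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
              time_to_peak = time_to_peak, k_serca = k_serca, k_ncx = k_ncx,
              caffeine_amplitude = caffeine_amplitude,
              f0_baseline = f0_baseline, background_level = background_level,
              noise_sd = noise_sd, ectopic_rate = ectopic_rate,
              include_caffeine = isTRUE(include_caffeine),
              caffeine_tail = caffeine_tail, stim_start = stim_start,
              caffeine_onset_jitter = caffeine_onset_jitter,
              noise_model = match.arg(noise_model), seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @noRd
validate_sim_config <- function(cfg) {
  pos <- c("frame_rate", "pacing_freq", "paced_duration", "pause_duration",
           "k_serca", "k_ncx", "f0_baseline", "time_to_peak",
           "amplitude_mean", "caffeine_amplitude")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stopf("invalid configuration: '%s' must be a positive finite number", f)
    }
  }
  nonneg <- c("amplitude_cv", "noise_sd", "ectopic_rate", "background_level",
              "caffeine_tail", "stim_start", "caffeine_onset_jitter")
  for (f in nonneg) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stopf("invalid configuration: '%s' must be a non-negative finite number", f)
    }
  }
  if (cfg$caffeine_amplitude < cfg$amplitude_mean) {
    stopf(paste("invalid configuration: 'caffeine_amplitude' must be >=",
                "'amplitude_mean' (caffeine releases the full SR content)"))
  }
  if (cfg$stim_start >= cfg$paced_duration) {
    stopf("invalid configuration: 'stim_start' must precede the end of pacing")
  }
  invisible(cfg)
}

# Add one transient (linear rise over ttp, then exponential decay at rate k)
# of amplitude amp starting at t0 into signal s defined on the uniform grid t.
#' @noRd
add_transient <- function(s, t, t0, amp, ttp, k) {
  dt <- t[2] - t[1]
  i0 <- max(1L, as.integer(ceiling((t0 - t[1]) / dt - 1e-9)) + 1L)
  if (i0 > length(t)) return(s)
  # truncate the tail where the contribution drops below 1e-12 of amplitude
  t_end <- t0 + ttp + log(1e12) / k
  i1 <- min(length(t), as.integer(floor((t_end - t[1]) / dt)) + 1L)
  if (i1 < i0) return(s)
  tt <- t[i0:i1] - t0
  contrib <- ifelse(tt <= ttp, amp * tt / ttp, amp * exp(-k * (tt - ttp)))
  s[i0:i1] <- s[i0:i1] + contrib
  s
}

# Deterministic event schedule + drawn amplitudes for a configuration.
# Called under the configuration seed.
#' @noRd
draw_events <- function(cfg) {
  stim_times <- seq(cfg$stim_start, cfg$paced_duration - 1e-9,
                    by = 1 / cfg$pacing_freq)
  n_stim <- length(stim_times)
  amps <- rnorm(n_stim, cfg$amplitude_mean,
                cfg$amplitude_cv * cfg$amplitude_mean)
  amps <- pmax(amps, 1e-6)

  span <- cfg$paced_duration + cfg$pause_duration
  ect_times <- numeric(0)
  if (cfg$ectopic_rate > 0) {
    n_ect <- rpois(1, cfg$ectopic_rate * span)
    if (n_ect > 0) ect_times <- sort(runif(n_ect, 0, span))
  }
  ect_amps <- if (length(ect_times)) {
    pmax(rnorm(length(ect_times), cfg$amplitude_mean,
               cfg$amplitude_cv * cfg$amplitude_mean), 1e-6)
  } else {
    numeric(0)
  }

  caffeine_onset <- NA_real_
  if (cfg$include_caffeine) {
    caffeine_onset <- span
    if (cfg$caffeine_onset_jitter > 0) {
      caffeine_onset <- span + rnorm(1, 0, cfg$caffeine_onset_jitter)
      caffeine_onset <- max(caffeine_onset, cfg$paced_duration + 1)
    }
  }
  list(stim_times = stim_times, stim_amps = amps,
       ect_times = ect_times, ect_amps = ect_amps,
       caffeine_onset = caffeine_onset)
}

# Noiseless summed transient signal s(t) on the dF/F0 scale.
#' @noRd
build_signal <- function(cfg, ev, t) {
  k_sys <- cfg$k_serca + cfg$k_ncx
  s <- numeric(length(t))
  for (i in seq_along(ev$stim_times)) {
    s <- add_transient(s, t, ev$stim_times[i], ev$stim_amps[i],
                       cfg$time_to_peak, k_sys)
  }
  for (i in seq_along(ev$ect_times)) {
    s <- add_transient(s, t, ev$ect_times[i], ev$ect_amps[i],
                       cfg$time_to_peak, k_sys)
  }
  if (cfg$include_caffeine) {
    s <- add_transient(s, t, ev$caffeine_onset, cfg$caffeine_amplitude,
                       cfg$time_to_peak, cfg$k_ncx)
  }
  s
}

#' @noRd
ground_truth <- function(cfg, ev) {
  structure(list(
    spike_times = c(ev$stim_times, ev$ect_times),
    spike_amplitudes = c(ev$stim_amps, ev$ect_amps),
    is_ectopic = c(rep(FALSE, length(ev$stim_times)),
                   rep(TRUE, length(ev$ect_times))),
    n_stimuli = length(ev$stim_times),
    k_sys_true = cfg$k_serca + cfg$k_ncx,
    k_caf_true = cfg$k_ncx,
    serca_function_true = cfg$k_serca,
    fractional_release_true = cfg$amplitude_mean / cfg$caffeine_amplitude,
    caffeine_onset = ev$caffeine_onset,
    caffeine_amplitude = if (cfg$include_caffeine) cfg$caffeine_amplitude else NA_real_
  ), class = "ground_truth")
}

#' Simulate one paced Ca2+ recording as a raw intensity trace
#'
#' Generates the raw fluorescence series
#' `F(t) = background_level + f0_baseline * (1 + s(t)) + noise`, where `s(t)`
#' sums a linear-rise/exponential-decay transient per stimulus (decay rate
#' `k_serca + k_ncx`), any spontaneous (ectopic) transients, and, after the
#' stop-pacing pause, a caffeine transient of amplitude `caffeine_amplitude`
#' decaying at `k_ncx` alone. The output is deterministic in `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `trace` (a raw-intensity [fluor_trace()];
#'   its metadata records `background_level` for [subtract_background()])
#'   and `truth` (a `ground_truth` list: spike times/amplitudes, `k_sys_true
#'   = k_serca + k_ncx`, `k_caf_true = k_ncx`, `serca_function_true =
#'   k_serca`, `fractional_release_true = amplitude_mean /
#'   caffeine_amplitude`, and the caffeine onset time).
#' @export
simulate_trace <- function(config) {
  validate_sim_config(config)
  cfg <- config
  duration <- cfg$paced_duration + cfg$pause_duration +
    if (cfg$include_caffeine) cfg$caffeine_tail else 0
  n <- as.integer(floor(duration * cfg$frame_rate))
  t <- (seq_len(n) - 1L) / cfg$frame_rate

  with_seed(cfg$seed, {
    ev <- draw_events(cfg)
    s <- build_signal(cfg, ev, t)
    mu <- cfg$background_level + cfg$f0_baseline * (1 + s)
    value <- switch(cfg$noise_model,
      gaussian = if (cfg$noise_sd > 0) mu + rnorm(n, 0, cfg$noise_sd) else mu,
      poisson  = rpois(n, pmax(mu, 0))
    )
    md <- list(background_level = cfg$background_level,
               frame_rate = cfg$frame_rate,
               pacing_freq = cfg$pacing_freq,
               stim_start = cfg$stim_start,
               pacing_stop = cfg$paced_duration,
               seed = cfg$seed)
    list(trace = fluor_trace(t, value, md), truth = ground_truth(cfg, ev))
  })
}

#' Simulate a time-lapse image stack of one cell
#'
#' Pixels inside the cell region follow the recording model of
#' [simulate_trace()] with independent per-pixel noise; all other pixels hold
#' `background_level` plus noise. Pixel values are quantized to unsigned
#' 16-bit integer counts (the camera's output format).
#'
#' @param config A [sim_config()].
#' @param geometry A list with `width`, `height` (pixels) and two disjoint
#'   rectangles `cell` and `background`, each `c(x0, y0, x1, y1)` in 0-based
#'   half-open coordinates (see [roi_rect()]).
#' @return A list with `stack` (an `image_stack`: array `frames` of dim
#'   `height x width x n`, `frame_interval`, `metadata`) and `truth` as in
#'   [simulate_trace()].
#' @export
simulate_stack <- function(config, geometry) {
  validate_sim_config(config)
  cfg <- config
  g <- geometry
  for (f in c("width", "height", "cell", "background")) {
    if (is.null(g[[f]])) stopf("geometry is missing '%s'", f)
  }
  check_rect(g$cell, g$width, g$height, "cell")
  check_rect(g$background, g$width, g$height, "background")
  if (rects_overlap(g$cell, g$background)) {
    stopf("geometry error: cell and background regions overlap")
  }

  duration <- cfg$paced_duration + cfg$pause_duration +
    if (cfg$include_caffeine) cfg$caffeine_tail else 0
  n <- as.integer(floor(duration * cfg$frame_rate))
  t <- (seq_len(n) - 1L) / cfg$frame_rate

  with_seed(cfg$seed, {
    ev <- draw_events(cfg)
    s <- build_signal(cfg, ev, t)
    cell_mu <- cfg$background_level + cfg$f0_baseline * (1 + s)

    frames <- array(0, dim = c(g$height, g$width, n))
    cell_rows <- (g$cell[2] + 1L):g$cell[4]
    cell_cols <- (g$cell[1] + 1L):g$cell[3]
    n_cell <- length(cell_rows) * length(cell_cols)
    npix <- g$height * g$width
    for (k in seq_len(n)) {
      fr <- matrix(cfg$background_level, g$height, g$width)
      fr[cell_rows, cell_cols] <- cell_mu[k]
      if (cfg$noise_model == "poisson") {
        fr[] <- rpois(npix, pmax(fr, 0))
      } else if (cfg$noise_sd > 0) {
        fr <- fr + rnorm(npix, 0, cfg$noise_sd)
      }
      frames[, , k] <- fr
    }
    frames <- round(pmin(pmax(frames, 0), 65535))
    stack <- image_stack(frames, 1 / cfg$frame_rate,
                         metadata = list(seed = cfg$seed,
                                         background_level = cfg$background_level))
    list(stack = stack, truth = ground_truth(cfg, ev))
  })
}

#' Simulate a two-group cohort of recordings
#'
#' Group 1 cells are drawn around the base configuration; group 2 cells have
#' selected parameters multiplied by `effect` (e.g. `list(k_serca = 1.5)` for
#' enhanced SERCA2 function). Per-cell biological variability is modeled as
#' lognormal jitter (sdlog `jitter_sdlog`) applied independently to `k_serca`
#' and `k_ncx`, and jointly (one shared multiplier per cell, emulating cell
#' size / dye loading) to `amplitude_mean` and `caffeine_amplitude` so that
#' the true fractional release is preserved. Deterministic in `seed`.
#'
#' @param base A [sim_config()]; its `seed` is ignored in favour of `seed`.
#' @param n_cells_per_group Cells per group (>= 1).
#' @param effect Named list of positive multipliers applied to group 2
#'   (allowed names: any positive numeric `sim_config` field).
#' @param jitter_sdlog Lognormal sdlog of per-cell parameter jitter.
#' @param seed Integer seed for the whole cohort.
#' @param group_labels Character vector of length 2.
#' @return A `sim_cohort`: list of cells, each
#'   `list(trace, truth, group, cell_id, config)`.
#' @export
simulate_cohort <- function(base, n_cells_per_group, effect = list(),
                            jitter_sdlog = 0.1, seed = 1L,
                            group_labels = c("group1", "group2")) {
  validate_sim_config(base)
  if (!is.numeric(n_cells_per_group) || n_cells_per_group < 1) {
    stopf("n_cells_per_group must be >= 1")
  }
  if (length(effect)) {
    if (is.null(names(effect)) || any(!nzchar(names(effect)))) {
      stopf("effect multipliers must be named")
    }
    bad <- names(effect)[!vapply(effect, function(x)
      is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
    if (length(bad)) stopf("effect multiplier '%s' must be > 0", bad[1])
  }
  if (jitter_sdlog < 0) stopf("jitter_sdlog must be >= 0")

  cells <- list()
  cell_no <- 0L
  for (gi in 1:2) {
    grp_base <- base
    if (gi == 2L) {
      for (nm in names(effect)) {
        if (is.null(grp_base[[nm]])) stopf("unknown effect parameter '%s'", nm)
        grp_base[[nm]] <- grp_base[[nm]] * effect[[nm]]
      }
    }
    for (ci in seq_len(n_cells_per_group)) {
      cell_no <- cell_no + 1L
      cfg <- grp_base
      cfg$seed <- child_seed(seed, cell_no)
      if (jitter_sdlog > 0) {
        mult <- with_seed(child_seed(seed, 100000L + cell_no),
                          exp(rnorm(3, 0, jitter_sdlog)))
        cfg$k_serca <- cfg$k_serca * mult[1]
        cfg$k_ncx <- cfg$k_ncx * mult[2]
        cfg$amplitude_mean <- cfg$amplitude_mean * mult[3]
        cfg$caffeine_amplitude <- cfg$caffeine_amplitude * mult[3]
      }
      class(cfg) <- "sim_config"
      sim <- simulate_trace(cfg)
      cell_id <- sprintf("%s_cell%02d", group_labels[gi], ci)
      sim$trace$metadata$cell_id <- cell_id
      sim$trace$metadata$group <- group_labels[gi]
      cells[[cell_no]] <- list(trace = sim$trace, truth = sim$truth,
                               group = group_labels[gi], cell_id = cell_id,
                               config = cfg)
    }
  }
  structure(cells, class = "sim_cohort")
}

#' Write a simulated trace and its ground truth to disk
#'
#' The trace goes to CSV (`time_s,intensity`, via [write_trace_csv()]) and
#' the ground truth to JSON alongside it.
#'
#' @param sim A `list(trace, truth)` as returned by [simulate_trace()].
#' @param trace_path Output CSV path.
#' @param truth_path Output JSON path; default replaces the extension.
#' @return Invisibly, the two paths.
#' @export
write_simulation <- function(sim, trace_path,
                             truth_path = sub("\\.csv$", "_truth.json",
                                              trace_path)) {
  write_trace_csv(sim$trace, trace_path)
  jsonlite::write_json(unclass(sim$truth), truth_path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(c(trace = trace_path, truth = truth_path))
}
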