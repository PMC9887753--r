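#' Detect Ca2+ transients by topographic prominence
#'
#' Local maxima of the dF/F0 trace are ranked by topographic prominence
#' (peak height above the highest of the two lowest points separating it
#' from higher terrain); peaks with prominence below `min_prominence` are
#' discarded and the survivors are thinned so that no two peaks lie closer
#' than `min_separation` (higher peak wins; ties break toward the earlier
#' sample). Prominence is unchanged by adding a constant to the trace, so
#' detection does not depend on the dF/F0 offset.
#'
#' For each retained peak the onset is found on the segment since the
#' previous retained peak (or the trace start): the last pre-peak sample
#' below `baseline + onset_fraction * (peak - baseline)`, where the local
#' baseline is the median of the 10 samples preceding the onset (solved by
#' fixed-point iteration from the segment minimum; deterministic).
#' Amplitude = peak value - local baseline, time to peak = peak time - onset
#' time, and rate of rise = amplitude / time to peak, by definition.
#'
#' @param ntrace A `norm_trace` (or anything with `time`, `value`,
#'   `frame_interval`).
#' @param min_prominence Minimum prominence in dF/F0 units; default 5x the
#'   robust noise scale of the trace (MAD of first differences / sqrt(2)).
#' @param min_separation Minimum peak spacing in seconds; default twice the
#'   frame interval (the smallest resolvable spacing). When pacing is known,
#'   half the pacing interval is the natural choice.
#' @param onset_fraction Fraction of the local rise defining the onset
#'   (default 0.10, the common 10% convention).
#' @return A data.frame with one row per spike: `peak_index`, `peak_time`,
#'   `onset_index`, `onset_time`, `amplitude`, `time_to_peak`,
#'   `rate_of_rise`, `prominence`, `local_baseline`. Zero rows if nothing is
#'   detected.
#' @export
detect_spikes <- function(ntrace, min_prominence = NULL,
                          min_separation = NULL, onset_fraction = 0.10) {
  y <- ntrace$value
  dt <- ntrace$frame_interval
  if (is.null(min_prominence)) min_prominence <- 5 * robust_noise_scale(y)
  if (is.null(min_separation)) min_separation <- 2 * dt
  if (min_prominence <= 0) stopf("min_prominence must be > 0")
  if (min_separation < 2 * dt) {
    stopf("min_separation must be at least 2 frame intervals")
  }
  if (onset_fraction <= 0 || onset_fraction >= 1) {
    stopf("onset_fraction must lie in (0, 1)")
  }

  pk <- find_peaks_cpp(as.numeric(y))
  keep <- pk$prominence >= min_prominence
  idx <- pk$index[keep]
  hgt <- pk$height[keep]
  prm <- pk$prominence[keep]
  empty <- data.frame(peak_index = integer(0), peak_time = numeric(0),
                      onset_index = integer(0), onset_time = numeric(0),
                      amplitude = numeric(0), time_to_peak = numeric(0),
                      rate_of_rise = numeric(0), prominence = numeric(0),
                      local_baseline = numeric(0))
  if (!length(idx)) return(empty)

  # Enforce separation: greedy by height (ties -> earlier sample).
  ord <- order(-hgt, idx)
  min_gap <- min_separation / dt - 1e-9  # tolerance for exact sample gaps
  kept <- integer(0)
  for (j in ord) {
    if (!length(kept) || all(abs(idx[kept] - idx[j]) >= min_gap)) {
      kept <- c(kept, j)
    }
  }
  kept <- kept[order(idx[kept])]
  idx <- idx[kept]; hgt <- hgt[kept]; prm <- prm[kept]

  m <- length(idx)
  onset <- integer(m); base <- numeric(m)
  seg_start <- c(1L, idx[-m] + 1L)
  for (i in seq_len(m)) {
    p <- idx[i]; s0 <- seg_start[i]
    b <- min(y[s0:p])
    o <- s0
    for (iter in 1:10) {
      thr <- b + onset_fraction * (hgt[i] - b)
      below <- which(y[s0:(p - 1L)] < thr)
      o_new <- if (length(below)) s0 + below[length(below)] - 1L else s0
      b_new <- median(y[max(1L, o_new - 10L):max(1L, o_new - 1L)])
      if (o_new == o && iter > 1L) { b <- b_new; break }
      o <- o_new; b <- b_new
    }
    if (b >= hgt[i]) {
      # descending terrain: the pre-onset median sits above the peak; fall
      # back to the segment minimum so the amplitude stays positive
      b <- min(y[s0:p])
      below <- which(y[s0:(p - 1L)] < b + onset_fraction * (hgt[i] - b))
      o <- if (length(below)) s0 + below[length(below)] - 1L else s0
    }
    onset[i] <- o; base[i] <- b
  }

  amp <- hgt - base
  ttp <- ntrace$time[idx] - ntrace$time[onset]
  data.frame(peak_index = idx, peak_time = ntrace$time[idx],
             onset_index = onset, onset_time = ntrace$time[onset],
             amplitude = amp, time_to_peak = ttp,
             rate_of_rise = amp / ttp, prominence = prm,
             local_baseline = base)
}

#' Assign detected spikes to pacing stimuli
#'
#' Each spike is mapped to the protocol phase containing it. Spikes whose
#' peak follows a stimulus within `latency_max` take that stimulus' index
#' (the peak is used rather than the onset because the detected onset
#' jitters by a sample or two under noise while the peak cannot precede its
#' stimulus); a second spike claiming an already-taken stimulus, a spike
#' peaking later than `latency_max` after its stimulus, a spike preceding
#' the first stimulus, and any spike in the stop-pacing pause are labeled
#' `"ectopic"` (spontaneous activity). In the caffeine phase, the
#' largest-amplitude spike is labeled `"caffeine"` and any others
#' `"ectopic"`.
#'
#' @param spikes Spike table from [detect_spikes()].
#' @param protocol A [protocol_descriptor()].
#' @param latency_max Maximum stimulus-to-peak latency in seconds; the
#'   default 0.2 s accommodates typical cardiomyocyte times-to-peak with
#'   room for frame quantization.
#' @return The spike table with an added character column `stimulus_label`
#'   (`"1"`, `"2"`, ... or `"ectopic"` / `"caffeine"`).
#' @export
assign_stimuli <- function(spikes, protocol, latency_max = 0.2) {
  p <- protocol
  n <- nrow(spikes)
  label <- rep("ectopic", n)
  if (n == 0L) {
    spikes$stimulus_label <- character(0)
    return(spikes)
  }
  stim_times <- seq(p$stim_start_s, p$pacing_stop_s - 1e-9,
                    by = 1 / p$pacing_freq_hz)
  caffeine_s <- p$caffeine_s

  in_caffeine <- if (!is.null(caffeine_s) && is.finite(caffeine_s)) {
    spikes$peak_time >= caffeine_s
  } else {
    rep(FALSE, n)
  }
  if (any(in_caffeine)) {
    caf_idx <- which(in_caffeine)
    main <- caf_idx[which.max(spikes$amplitude[caf_idx])]
    label[main] <- "caffeine"
  }

  taken <- logical(length(stim_times))
  paced <- which(!in_caffeine & spikes$peak_time < p$pacing_stop_s +
                   latency_max)
  for (i in paced) {
    s <- findInterval(spikes$peak_time[i] + 1e-9, stim_times)
    if (s >= 1L && !taken[s] &&
        spikes$peak_time[i] - stim_times[s] <= latency_max) {
      taken[s] <- TRUE
      label[i] <- as.character(s)
    }
  }
  spikes$stimulus_label <- label
  spikes
}

#' Cell-eligibility quality control
#'
#' A cell is eligible for kinetic analysis when it shows at least 30 paced
#' spikes, no automaticity (zero ectopic spikes of physiological size), and
#' regular amplitude clearance, operationalized as a paced-amplitude
#' coefficient of variation at or below `cv_threshold`.
#'
#' Automaticity counts only ectopic spikes whose amplitude reaches
#' `ectopic_min_frac` of the median paced amplitude: a genuine spontaneous
#' transient releases SR Ca2+ much like a paced one, whereas the rare noise
#' excursion that clears the prominence threshold in a long diastolic or
#' pause segment is far smaller. Sub-threshold ectopic labels are reported
#' (`n_ectopic_minor`) but do not disqualify the cell.
#'
#' @param spikes Annotated spike table from [assign_stimuli()].
#' @param cv_threshold Maximum allowed paced-amplitude CV (default 0.25).
#' @param min_spikes Minimum number of paced spikes (default 30).
#' @param ectopic_min_frac Fraction of the median paced amplitude an ectopic
#'   spike must reach to count as automaticity (default 0.5).
#' @return A `cell_qc` list: `n_spikes`, `amplitude_cv`, `n_ectopic`,
#'   `n_ectopic_minor`, `eligible`, `reasons`.
#' @export
qc_cell <- function(spikes, cv_threshold = 0.25, min_spikes = 30L,
                    ectopic_min_frac = 0.5) {
  if (is.null(spikes$stimulus_label)) {
    stopf("spikes must be annotated with assign_stimuli() before QC")
  }
  paced <- spikes[!spikes$stimulus_label %in% c("ectopic", "caffeine"), ,
                  drop = FALSE]
  n_spikes <- nrow(paced)
  ect <- spikes[spikes$stimulus_label == "ectopic", , drop = FALSE]
  n_ect_raw <- nrow(ect)
  n_ectopic <- if (n_spikes >= 1L && n_ect_raw) {
    sum(ect$amplitude >= ectopic_min_frac * median(paced$amplitude))
  } else {
    n_ect_raw
  }
  amplitude_cv <- if (n_spikes >= 2L) {
    sd(paced$amplitude) / mean(paced$amplitude)
  } else {
    NA_real_
  }
  reasons <- character(0)
  if (n_spikes < min_spikes) {
    reasons <- c(reasons, sprintf("n_spikes<%d", min_spikes))
  }
  if (n_ectopic > 0L) reasons <- c(reasons, "automaticity")
  if (!is.na(amplitude_cv) && amplitude_cv > cv_threshold) {
    reasons <- c(reasons, sprintf("amplitude_cv>%.2f", cv_threshold))
  }
  structure(list(n_spikes = n_spikes, amplitude_cv = amplitude_cv,
                 n_ectopic = n_ectopic,
                 n_ectopic_minor = n_ect_raw - n_ectopic,
                 eligible = length(reasons) == 0L, reasons = reasons),
            class = "cell_qc")
}

#' Write a spike table as TSV
#'
#' @param spikes Annotated spike table.
#' @param path Output path.
#' @param cell_id Cell identifier written in the first column.
#' @return Invisibly, `path`.
#' @export
write_spike_tsv <- function(spikes, path, cell_id = "cell") {
  out <- data.frame(cell_id = rep(cell_id, nrow(spikes)),
                    spike_idx = seq_len(nrow(spikes)),
                    peak_time_s = spikes$peak_time,
                    amplitude = spikes$amplitude,
                    time_to_peak_s = spikes$time_to_peak,
                    rate_of_rise_per_s = spikes$rate_of_rise,
                    stimulus_label = spikes$stimulus_label)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
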