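#' Fit a single-exponential decay
#'
#' Nonlinear least squares of `y(t) = A * exp(-k * (t - t0)) + C` on a decay
#' segment starting at a peak (`t0 = time[1]`), with `A, k >= 0` constrained
#' and the offset `C` free (diastolic dF/F0 need not return to the
#' pre-recording baseline). Initial values: `A = y[1] - min(y)`,
#' `C = min(y)`, and `k = ln(2) / t_half` from the first crossing of
#' `A/2 + C`. Levenberg-Marquardt via [minpack.lm::nlsLM()].
#'
#' The fit is flagged `converged` only when the optimizer converged, the
#' rate is away from its lower bound, and the residual RMSE is below
#' `0.2 * A`; a non-decaying segment therefore comes back with
#' `converged = FALSE` rather than an error.
#'
#' @param time,value Decay segment samples; `time[1]` is the peak time. At
#'   least 5 samples.
#' @return A `decay_fit`: list with `A`, `k` (1/s), `tau` (= 1/k, s), `C`,
#'   `rmse`, `n_points`, `converged`.
#' @export
fit_decay <- function(time, value) {
  if (length(time) != length(value)) stopf("time and value lengths differ")
  if (length(time) < 5L) {
    stopf("decay segment too short: need >= 5 samples, got %d", length(time))
  }
  tt <- time - time[1]
  y <- value
  C0 <- min(y)
  A0 <- y[1] - C0
  unconverged <- function() {
    structure(list(A = NA_real_, k = NA_real_, tau = NA_real_, C = NA_real_,
                   rmse = NA_real_, n_points = length(y), converged = FALSE),
              class = "decay_fit")
  }
  if (A0 <= 0) return(unconverged())
  half <- which(y <= A0 / 2 + C0)
  k0 <- if (length(half) && tt[half[1]] > 0) log(2) / tt[half[1]] else {
    1 / (max(tt) / 3)
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-k * tt) + C,
      start = list(A = A0, k = k0, C = C0),
      lower = c(A = 0, k = 0, C = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(unconverged())
  cf <- coef(fit)
  rmse <- sqrt(mean(resid(fit)^2))
  converged <- is.finite(cf[["k"]]) && cf[["k"]] > 1e-8 && cf[["A"]] > 0 &&
    rmse < 0.2 * cf[["A"]]
  structure(list(A = unname(cf[["A"]]), k = unname(cf[["k"]]),
                 tau = 1 / unname(cf[["k"]]), C = unname(cf[["C"]]),
                 rmse = rmse, n_points = length(y), converged = converged),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> k = %.4g 1/s (tau = %.4g s), A = %.4g, C = %.4g, rmse = %.3g, %s\n",
    x$k, x$tau, x$A, x$C, x$rmse,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Decay segment of spike i: from its peak to the onset of the next spike,
# or to end_index when it is the last one.
#' @noRd
decay_segment_bounds <- function(spikes, i, end_index) {
  from <- spikes$peak_index[i]
  to <- if (i < nrow(spikes)) spikes$onset_index[i + 1L] else end_index
  c(from, min(to, end_index))
}

#' Randomly select one paced spike for the systolic decay fit
#'
#' Uniform choice among the eligible paced spikes, reproducible under
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param spikes Spike table (paced spikes only).
#' @param seed Integer seed.
#' @return The 1-based row index of the chosen spike.
#' @export
select_systolic_spike <- function(spikes, seed) {
  n <- nrow(spikes)
  if (is.null(n) || n < 1L) stopf("no eligible paced spikes to select from")
  if (n == 1L) return(1L)
  with_seed(seed, sample.int(n, 1L))
}

#' Protocol descriptor
#'
#' @param pacing_freq_hz Field-stimulation frequency, Hz.
#' @param pacing_stop_s Time pacing stops (end of the paced phase), s.
#' @param caffeine_s Caffeine onset time, s; `NA` to detect it from the
#'   trace (largest-prominence peak after the pause).
#' @param stim_start_s Time of the first stimulus, s.
#' @param iso_condition Recording under isoproterenol? (annotation only).
#' @return A `protocol` list.
#' @export
protocol_descriptor <- function(pacing_freq_hz = 0.5, pacing_stop_s = 180,
                                caffeine_s = NA_real_, stim_start_s = 1,
                                iso_condition = FALSE) {
  if (pacing_freq_hz <= 0) stopf("pacing_freq_hz must be > 0")
  if (pacing_stop_s <= stim_start_s) {
    stopf("pacing_stop_s must follow stim_start_s")
  }
  structure(list(pacing_freq_hz = pacing_freq_hz,
                 pacing_stop_s = pacing_stop_s,
                 caffeine_s = caffeine_s, stim_start_s = stim_start_s,
                 iso_condition = isTRUE(iso_condition)),
            class = "protocol")
}

#' Read a protocol descriptor from YAML or JSON
#'
#' Keys: `pacing_freq_hz`, `pacing_stop_s`, optional `caffeine_s`,
#' `stim_start_s`, `iso_condition`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `protocol` list.
#' @export
read_protocol <- function(path) {
  j <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  protocol_descriptor(
    pacing_freq_hz = j$pacing_freq_hz,
    pacing_stop_s = j$pacing_stop_s,
    caffeine_s = if (is.null(j$caffeine_s)) NA_real_ else j$caffeine_s,
    stim_start_s = if (is.null(j$stim_start_s)) 1 else j$stim_start_s,
    iso_condition = isTRUE(j$iso_condition)
  )
}

#' Segment a recording into paced / pause / caffeine phases
#'
#' Phases echo the protocol descriptor when it carries a caffeine time;
#' otherwise the caffeine onset is detected as the onset of the
#' largest-prominence peak after pacing stops.
#'
#' @param ntrace A `norm_trace`.
#' @param protocol A [protocol_descriptor()].
#' @param expect_caffeine Error if no caffeine transient can be located?
#' @param min_prominence Detection threshold for the caffeine peak; default
#'   as in [detect_spikes()].
#' @return A `protocol_phases` list: `paced = c(t0, t1)`,
#'   `pause = c(t1, t2)`, `caffeine = c(t2, t_end)` (all half-open, s), or
#'   `caffeine = NULL` when `expect_caffeine = FALSE` and none is found.
#' @export
segment_protocol <- function(ntrace, protocol, expect_caffeine = TRUE,
                             min_prominence = NULL) {
  t_end <- ntrace$time[length(ntrace$time)] + ntrace$frame_interval
  t1 <- protocol$pacing_stop_s
  if (t1 >= t_end) stopf("pacing stop lies beyond the end of the trace")
  t2 <- protocol$caffeine_s

  if (is.null(t2) || !is.finite(t2)) {
    post <- which(ntrace$time >= t1)
    t2 <- NA_real_
    if (length(post) > 10L) {
      seg <- list(time = ntrace$time[post], value = ntrace$value[post],
                  frame_interval = ntrace$frame_interval)
      sp <- detect_spikes(seg, min_prominence = min_prominence,
                          min_separation = 2 * ntrace$frame_interval)
      if (nrow(sp)) t2 <- sp$onset_time[which.max(sp$prominence)]
    }
    if (!is.finite(t2)) {
      if (expect_caffeine) stopf("caffeine transient not found")
      return(structure(list(paced = c(0, t1), pause = c(t1, t_end),
                            caffeine = NULL),
                       class = "protocol_phases"))
    }
  } else if (t2 >= t_end) {
    stopf("caffeine time lies beyond the end of the trace")
  }
  structure(list(paced = c(0, t1), pause = c(t1, t2),
                 caffeine = c(t2, t_end)),
            class = "protocol_phases")
}

#' Caffeine-protocol decomposition: final paced and caffeine decay fits
#'
#' Fits a single exponential to the decay of the final electrically
#' stimulated transient (peak to the caffeine onset) and to the
#' caffeine-induced transient (peak to the end of the trace). The systolic
#' decay reflects SERCA2 + NCX removal; the caffeine decay reflects NCX
#' alone, and the caffeine amplitude proxies the SR Ca2+ content.
#'
#' @param ntrace A `norm_trace`.
#' @param phases A `protocol_phases` with a caffeine phase.
#' @param spikes Annotated spike table ([assign_stimuli()]).
#' @return List with `stim_fit`, `caf_fit` (both `decay_fit`),
#'   `amplitude_stim`, `amplitude_caffeine`.
#' @export
caffeine_analysis <- function(ntrace, phases, spikes) {
  if (is.null(phases$caffeine)) stopf("caffeine phase missing from protocol")
  paced <- which(!spikes$stimulus_label %in% c("ectopic", "caffeine") &
                   spikes$peak_time < phases$paced[2])
  if (!length(paced)) stopf("no paced spike available for caffeine analysis")
  caf <- which(spikes$stimulus_label == "caffeine")
  if (!length(caf)) stopf("caffeine transient not present in spike table")
  caf <- caf[1]

  last <- paced[length(paced)]
  stim_end <- spikes$onset_index[caf] - 1L
  stim_seg <- spikes$peak_index[last]:stim_end
  stim_fit <- fit_decay(ntrace$time[stim_seg], ntrace$value[stim_seg])

  caf_seg <- spikes$peak_index[caf]:length(ntrace$value)
  caf_fit <- fit_decay(ntrace$time[caf_seg], ntrace$value[caf_seg])

  list(stim_fit = stim_fit, caf_fit = caf_fit,
       amplitude_stim = spikes$amplitude[last],
       amplitude_caffeine = spikes$amplitude[caf])
}

#' SERCA2 function from the two decay rates
#'
#' The systolic transient decays through SERCA2 reuptake plus NCX extrusion;
#' the caffeine transient decays through NCX (and other minor pathways)
#' alone. Their difference estimates the SERCA2 contribution to cytosolic
#' Ca2+ removal. A negative value is returned as-is (it flags a cell where
#' the caffeine decay outpaced the systolic decay) rather than censored.
#'
#' @param k_sys Systolic decay rate constant, 1/s (converged fit).
#' @param k_caf Caffeine-induced decay rate constant, 1/s (converged fit).
#' @return `k_sys - k_caf`, 1/s.
#' @export
serca_function <- function(k_sys, k_caf) {
  if (!is.finite(k_sys) || !is.finite(k_caf)) {
    stopf("serca_function requires two converged decay rates")
  }
  k_sys - k_caf
}

#' Fractional SR Ca2+ release
#'
#' Ratio of the Ca2+ released by the final electrical stimulus to the Ca2+
#' released by caffeine (which empties the SR), using dF/F0 amplitudes as
#' the proxy for released Ca2+.
#'
#' @param amplitude_stim,amplitude_caffeine Positive dF/F0 amplitudes.
#' @return `amplitude_stim / amplitude_caffeine`.
#' @export
fractional_release <- function(amplitude_stim, amplitude_caffeine) {
  if (!is.finite(amplitude_stim) || amplitude_stim <= 0) {
    stopf("amplitude_stim must be positive")
  }
  if (!is.finite(amplitude_caffeine) || amplitude_caffeine <= 0) {
    stopf("amplitude_caffeine must be positive")
  }
  amplitude_stim / amplitude_caffeine
}

#' Assemble the per-cell summary row
#'
#' @param cell_id,animal_id,group Identifiers.
#' @param qc A `cell_qc` from [qc_cell()].
#' @param spikes Annotated spike table.
#' @param caffeine Result of [caffeine_analysis()], or `NULL`.
#' @param random_fit `decay_fit` of the randomly selected systolic spike, or
#'   `NULL`.
#' @param random_spike_row Row index of that spike, or `NA`.
#' @return One-row data.frame (`cell_summary`); ineligible cells carry their
#'   QC reasons and `NA` kinetic fields. `k_sys` is the final-paced-spike
#'   decay rate, `k_sys_random` the randomly-selected-spike decay rate; time
#'   constants `tau_* = 1/k_*` are reported alongside.
#' @export
summarize_cell <- function(cell_id, animal_id = NA_character_,
                           group = NA_character_, qc, spikes,
                           caffeine = NULL, random_fit = NULL,
                           random_spike_row = NA_integer_) {
  paced <- spikes[!spikes$stimulus_label %in% c("ectopic", "caffeine"), ,
                  drop = FALSE]
  has_caf <- !is.null(caffeine) &&
    caffeine$stim_fit$converged && caffeine$caf_fit$converged
  k_sys <- if (has_caf) caffeine$stim_fit$k else NA_real_
  k_caf <- if (has_caf) caffeine$caf_fit$k else NA_real_
  out <- data.frame(
    cell_id = cell_id, animal_id = animal_id, group = group,
    n_spikes = qc$n_spikes,
    n_ectopic = qc$n_ectopic,
    eligible = qc$eligible,
    qc_reasons = paste(qc$reasons, collapse = ";"),
    mean_amplitude = if (nrow(paced)) mean(paced$amplitude) else NA_real_,
    mean_rate_of_rise = if (nrow(paced)) mean(paced$rate_of_rise) else NA_real_,
    amplitude_cv = qc$amplitude_cv,
    amplitude_stim = if (has_caf) caffeine$amplitude_stim else NA_real_,
    amplitude_caffeine = if (has_caf) caffeine$amplitude_caffeine else NA_real_,
    k_sys = k_sys,
    k_sys_random = if (!is.null(random_fit) && random_fit$converged) {
      random_fit$k
    } else {
      NA_real_
    },
    random_spike_row = random_spike_row,
    k_caf = k_caf,
    tau_sys = 1 / k_sys,
    tau_caf = 1 / k_caf,
    serca_function = if (has_caf) serca_function(k_sys, k_caf) else NA_real_,
    fractional_release = if (has_caf) {
      fractional_release(caffeine$amplitude_stim, caffeine$amplitude_caffeine)
    } else {
      NA_real_
    },
    stringsAsFactors = FALSE
  )
  class(out) <- c("cell_summary", class(out))
  out
}
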