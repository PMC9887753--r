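ntrace_from <- function(value, dt = 0.01) {
  list(time = (seq_along(value) - 1) * dt, value = value, frame_interval = dt)
}

test_that("flat traces yield no spikes", {
  nt <- ntrace_from(rep(0.2, 300))
  expect_identical(nrow(detect_spikes(nt, min_prominence = 0.1)), 0L)
})

test_that("noiseless paced trace yields one spike per stimulus with true amplitudes", {
  cfg <- quiet_cfg(paced_duration = 180, pause_duration = 5,
                   include_caffeine = FALSE, amplitude_cv = 0.1, seed = 11L)
  sn <- sim_ntrace(cfg)
  expect_identical(sn$truth$n_stimuli, 90L)
  sp <- detect_spikes(sn$ntrace, min_prominence = 0.2,
                      min_separation = 0.5 / cfg$pacing_freq)
  expect_identical(nrow(sp), 90L)
  rel <- abs(sp$amplitude - sn$truth$spike_amplitudes) /
    sn$truth$spike_amplitudes
  expect_lt(max(rel), 0.01)
  # peaks land at stimulus + time_to_peak on the sample grid
  expect_lt(max(abs(sp$peak_time - (sn$truth$spike_times + cfg$time_to_peak))),
            1.5 / cfg$frame_rate)
})

test_that("rate of rise is amplitude over time-to-peak, bit for bit", {
  sn <- sim_ntrace(noisy_cfg(seed = 21))
  sp <- detect_spikes(sn$ntrace)
  expect_gt(nrow(sp), 5L)
  expect_identical(sp$rate_of_rise, sp$amplitude / sp$time_to_peak)
  # worked example: amplitude 1.2 over 0.05 s
  expect_equal(1.2 / 0.05, 24)
})

test_that("detector matches the brute-force prominence scan on random traces", {
  set.seed(77)
  for (rep in 1:30) {
    y <- cumsum(rnorm(200)) + rnorm(200, sd = 0.3)
    minp <- runif(1, 0.5, 3)
    msep <- sample(2:15, 1)
    sp <- detect_spikes(ntrace_from(y), min_prominence = minp,
                        min_separation = msep * 0.01)
    expect_identical(sp$peak_index, bf_detect_peaks(y, minp, msep))
  }
})

test_that("detection commutes with time shifts and dF/F0 offsets", {
  sn <- sim_ntrace(noisy_cfg(seed = 8))
  nt <- sn$ntrace
  base <- detect_spikes(nt, min_prominence = 0.3, min_separation = 1)
  shifted <- list(time = nt$time + 12.5, value = nt$value + 3.7,
                  frame_interval = nt$frame_interval)
  moved <- detect_spikes(shifted, min_prominence = 0.3, min_separation = 1)
  expect_identical(moved$peak_index, base$peak_index)
  expect_equal(moved$amplitude, base$amplitude)
  expect_equal(moved$peak_time, base$peak_time + 12.5)
})

test_that("spike count matches ground truth across seeded noisy runs", {
  # SNR 10, short paced-only recordings
  miss <- 0L
  for (s in 1:25) {
    cfg <- noisy_cfg(snr = 10, paced_duration = 21, pause_duration = 2,
                     include_caffeine = FALSE, seed = 100 + s)
    sn <- sim_ntrace(cfg)
    proto <- protocol_descriptor(pacing_freq_hz = cfg$pacing_freq,
                                 pacing_stop_s = cfg$paced_duration,
                                 stim_start_s = cfg$stim_start)
    sp <- assign_stimuli(detect_spikes(sn$ntrace,
                                       min_separation = 0.5 / cfg$pacing_freq),
                         proto)
    n_paced <- sum(!sp$stimulus_label %in% c("ectopic", "caffeine"))
    if (n_paced != sn$truth$n_stimuli) miss <- miss + 1L
  }
  expect_identical(miss, 0L)
})

test_that("stimulus assignment separates paced, ectopic and caffeine spikes", {
  cfg <- quiet_cfg(seed = 2)
  sn <- sim_ntrace(cfg)
  proto <- protocol_descriptor(pacing_freq_hz = 0.5,
                               pacing_stop_s = cfg$paced_duration,
                               caffeine_s = sn$truth$caffeine_onset,
                               stim_start_s = cfg$stim_start)
  sp <- assign_stimuli(detect_spikes(sn$ntrace, min_prominence = 0.2,
                                     min_separation = 1), proto)
  expect_identical(sum(sp$stimulus_label == "ectopic"), 0L)
  expect_identical(sum(sp$stimulus_label == "caffeine"), 1L)
  expect_identical(sum(!sp$stimulus_label %in% c("ectopic", "caffeine")),
                   sn$truth$n_stimuli)

  # spike in the pause phase (pre-caffeine) is ectopic by definition
  t <- sn$ntrace$time
  v <- sn$ntrace$value
  pause_mid <- cfg$paced_duration + 3
  rise <- pmax(0, pmin((t - pause_mid) / 0.05, 1)) *
    exp(-pmax(0, t - pause_mid - 0.05) * 5)
  sp2 <- assign_stimuli(detect_spikes(list(time = t, value = v + rise,
                                           frame_interval = sn$ntrace$frame_interval),
                                      min_prominence = 0.2,
                                      min_separation = 1), proto)
  expect_identical(sum(sp2$stimulus_label == "ectopic"), 1L)
  ect <- sp2[sp2$stimulus_label == "ectopic", ]
  expect_lt(abs(ect$onset_time - pause_mid), 0.1)
})

test_that("an injected mid-diastole spike is labeled ectopic", {
  cfg <- quiet_cfg(include_caffeine = FALSE, pause_duration = 2, seed = 6)
  sn <- sim_ntrace(cfg)
  t <- sn$ntrace$time
  inj <- 8.0  # 1 s after the stimulus at 7 s, mid-diastole
  rise <- pmax(0, pmin((t - inj) / 0.05, 1)) *
    exp(-pmax(0, t - inj - 0.05) * 5)
  nt <- list(time = t, value = sn$ntrace$value + rise,
             frame_interval = sn$ntrace$frame_interval)
  proto <- protocol_descriptor(pacing_freq_hz = 0.5,
                               pacing_stop_s = cfg$paced_duration,
                               stim_start_s = cfg$stim_start)
  sp <- assign_stimuli(detect_spikes(nt, min_prominence = 0.2,
                                     min_separation = 0.5), proto)
  expect_identical(sum(sp$stimulus_label == "ectopic"), 1L)
  qc <- qc_cell(sp, min_spikes = 5L)
  expect_false(qc$eligible)
  expect_true("automaticity" %in% qc$reasons)
})

test_that("cell QC applies the 30-spike, automaticity and CV rules", {
  mk <- function(n, labels = as.character(seq_len(n)), amp = 1) {
    data.frame(peak_index = seq_len(n) * 100, peak_time = seq_len(n) * 2,
               onset_index = seq_len(n) * 100 - 5,
               onset_time = seq_len(n) * 2 - 0.05,
               amplitude = rep(amp, n), time_to_peak = 0.05,
               rate_of_rise = amp / 0.05, prominence = amp,
               local_baseline = 0, stimulus_label = labels)
  }
  qc29 <- qc_cell(mk(29))
  expect_false(qc29$eligible)
  expect_true("n_spikes<30" %in% qc29$reasons)

  qc40 <- qc_cell(mk(40))
  expect_true(qc40$eligible)
  expect_identical(qc40$n_spikes, 40L)
  expect_equal(qc40$amplitude_cv, 0)

  with_ect <- rbind(mk(40), mk(1, labels = "ectopic"))
  qce <- qc_cell(with_ect)
  expect_false(qce$eligible)
  expect_identical(qce$reasons, "automaticity")

  # low-amplitude ectopic labels (noise excursions) do not disqualify
  minor <- rbind(mk(40), mk(1, labels = "ectopic", amp = 0.2))
  qcm <- qc_cell(minor)
  expect_true(qcm$eligible)
  expect_identical(qcm$n_ectopic_minor, 1L)

  irregular <- mk(40)
  irregular$amplitude <- rep(c(0.4, 1.6), 20)
  qcv <- qc_cell(irregular)
  expect_false(qcv$eligible)
  expect_match(qcv$reasons, "amplitude_cv", all = FALSE)
})
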