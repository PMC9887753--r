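test_that("fit_decay recovers a clean exponential to 1e-6", {
  t <- seq(0, 1, by = 1 / 97)
  y <- 2 * exp(-3 * t)
  fit <- fit_decay(t, y)
  expect_true(fit$converged)
  expect_equal(fit$k, 3.0, tolerance = 1e-6)
  expect_equal(fit$A, 2.0, tolerance = 1e-6)
  expect_equal(abs(fit$C), 0, tolerance = 1e-6)
  expect_equal(fit$tau, 1 / fit$k)
})

test_that("fit_decay flags constant and too-short segments", {
  t <- seq(0, 1, by = 0.01)
  expect_false(fit_decay(t, rep(1, length(t)))$converged)
  expect_error(fit_decay(t[1:4], c(4, 3, 2, 1)), "5 samples")
  # rising segment: no decay to fit
  expect_false(fit_decay(t, exp(t))$converged)
})

test_that("fit_decay is calibrated under noise (Monte Carlo)", {
  t <- seq(0, 1.9, by = 1 / 97)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    y <- exp(-5 * t) + rnorm(length(t), 0, 0.02)
    abs(fit_decay(t, y)$k - 5) / 5
  }, numeric(1))
  expect_lt(median(errs), 0.02)
  expect_lt(quantile(errs, 0.95), 0.10)
})

test_that("fit_decay agrees with the grid-search + golden-section oracle", {
  t <- seq(0, 1.5, by = 1 / 97)
  for (k_true in c(1, 2.5, 5, 10)) {
    y <- 1.3 * exp(-k_true * t) + 0.05
    fit <- fit_decay(t, y)
    oracle <- grid_fit_decay(t, y)
    expect_lt(abs(fit$k - oracle$k) / oracle$k, 0.01)
  }
})

test_that("random systolic spike selection is reproducible and uniform", {
  sp <- data.frame(peak_index = c(10, 110, 210, 310))
  expect_identical(select_systolic_spike(sp[1, , drop = FALSE], seed = 99), 1L)
  draws <- vapply(1:50, function(i) select_systolic_spike(sp, seed = 123),
                  integer(1))
  expect_identical(length(unique(draws)), 1L)

  freq <- tabulate(vapply(1:10000,
                          function(s) select_systolic_spike(sp, seed = s),
                          integer(1)), 4) / 10000
  expect_true(all(abs(freq - 0.25) <= 0.02))
})

test_that("RNG state of the caller is not disturbed by spike selection", {
  sp <- data.frame(peak_index = c(10, 110, 210))
  set.seed(1); a <- rnorm(1)
  set.seed(1); invisible(select_systolic_spike(sp, seed = 42)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("protocol segmentation echoes descriptors and detects caffeine onset", {
  cfg <- quiet_cfg(seed = 2)
  sn <- sim_ntrace(cfg)
  proto_known <- protocol_descriptor(0.5, cfg$paced_duration,
                                     caffeine_s = 26.5)
  ph <- segment_protocol(sn$ntrace, proto_known)
  expect_equal(ph$paced, c(0, 20))
  expect_equal(ph$pause, c(20, 26.5))
  expect_equal(ph$caffeine[1], 26.5)

  # detection path: onset within 3 samples of the true caffeine onset
  proto_nd <- protocol_descriptor(0.5, cfg$paced_duration)
  ph2 <- segment_protocol(sn$ntrace, proto_nd)
  expect_lt(abs(ph2$caffeine[1] - sn$truth$caffeine_onset),
            3 / cfg$frame_rate)

  # trace ending at pacing stop: caffeine expected but absent
  cut <- which(sn$ntrace$time < cfg$paced_duration)
  short_nt <- list(time = sn$ntrace$time[cut], value = sn$ntrace$value[cut],
                   frame_interval = sn$ntrace$frame_interval)
  expect_error(segment_protocol(short_nt,
                                protocol_descriptor(0.5, cfg$paced_duration - 0.01)),
               "caffeine transient not found")
})

test_that("caffeine analysis recovers both decay rates on noiseless input", {
  cfg <- quiet_cfg(k_serca = 3.5, k_ncx = 1.5, seed = 4)
  sn <- sim_ntrace(cfg)
  proto <- protocol_descriptor(0.5, cfg$paced_duration)
  ph <- segment_protocol(sn$ntrace, proto)
  proto$caffeine_s <- ph$caffeine[1]
  sp <- assign_stimuli(detect_spikes(sn$ntrace, min_prominence = 0.2,
                                     min_separation = 1), proto)
  res <- caffeine_analysis(sn$ntrace, ph, sp)
  expect_true(res$stim_fit$converged && res$caf_fit$converged)
  expect_equal(res$stim_fit$k, 5.0, tolerance = 0.01)
  expect_equal(res$caf_fit$k, 1.5, tolerance = 0.01)
  expect_equal(res$amplitude_caffeine, cfg$caffeine_amplitude,
               tolerance = 0.01)

  # equal paced and caffeine amplitudes give a ratio of 1
  cfg_eq <- quiet_cfg(caffeine_amplitude = 1.0, amplitude_cv = 0, seed = 5)
  sn_eq <- sim_ntrace(cfg_eq)
  ph_eq <- segment_protocol(sn_eq$ntrace, proto <- protocol_descriptor(0.5, 20))
  proto$caffeine_s <- ph_eq$caffeine[1]
  sp_eq <- assign_stimuli(detect_spikes(sn_eq$ntrace, min_prominence = 0.2,
                                        min_separation = 1), proto)
  res_eq <- caffeine_analysis(sn_eq$ntrace, ph_eq, sp_eq)
  expect_equal(fractional_release(res_eq$amplitude_stim,
                                  res_eq$amplitude_caffeine),
               1.0, tolerance = 0.01)

  ph_none <- structure(list(paced = c(0, 20), pause = c(20, 36),
                            caffeine = NULL), class = "protocol_phases")
  expect_error(caffeine_analysis(sn$ntrace, ph_none, sp), "caffeine phase")
})

test_that("serca_function and fractional_release identities hold", {
  expect_identical(serca_function(5.0, 2.0), 3.0)
  expect_identical(serca_function(4.2, 4.2), 0.0)
  expect_lt(serca_function(1.0, 2.5), 0)  # reported, not censored
  expect_error(serca_function(NA_real_, 1), "converged")

  expect_identical(fractional_release(0.6, 1.2), 0.5)
  expect_identical(fractional_release(0.9, 0.9), 1.0)
  expect_error(fractional_release(-1, 2), "positive")
  expect_error(fractional_release(1, 0), "positive")
})

test_that("cell summaries carry identities, QC reasons and group labels", {
  base <- quiet_cfg(paced_duration = 70, pause_duration = 8,
                    caffeine_tail = 8, amplitude_cv = 0.05)
  coh <- simulate_cohort(base, n_cells_per_group = 2, jitter_sdlog = 0.05,
                         seed = 31L)
  res <- analyze_cohort(coh, analysis_params(rng_seed = 5L))
  expect_identical(nrow(res$summary), 4L)
  expect_identical(res$summary$group, c("group1", "group1", "group2", "group2"))
  ok <- res$summary$eligible
  expect_true(all(ok))
  expect_identical(res$summary$serca_function[ok],
                   res$summary$k_sys[ok] - res$summary$k_caf[ok])
  expect_true(all(is.finite(res$summary$k_sys_random[ok])))

  # ineligible cell: null kinetic fields, reasons recorded
  short <- simulate_cohort(quiet_cfg(paced_duration = 10, pause_duration = 4,
                                     caffeine_tail = 5),
                           n_cells_per_group = 1, jitter_sdlog = 0, seed = 3L)
  res2 <- analyze_cohort(short, analysis_params(rng_seed = 5L))
  expect_false(any(res2$summary$eligible))
  expect_match(res2$summary$qc_reasons, "n_spikes<30")
  expect_true(all(is.na(res2$summary$k_sys)))
  expect_true(all(is.na(res2$summary$serca_function)))
  expect_identical(length(res2$excluded), 2L)
})
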