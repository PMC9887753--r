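test_that("configuration validation names the offending field", {
  expect_error(sim_config(frame_rate = 0), "frame_rate")
  expect_error(sim_config(k_serca = -1), "k_serca")
  expect_error(sim_config(ectopic_rate = -0.1), "ectopic_rate")
  expect_error(sim_config(amplitude_mean = 1.2, caffeine_amplitude = 1.0),
               "caffeine_amplitude")
})

test_that("noiseless construction reaches the configured peak amplitude", {
  # isolated transient (grid-aligned rise): apex carries the full amplitude
  cfg <- quiet_cfg(amplitude_mean = 1.0, amplitude_cv = 0,
                   paced_duration = 2, pause_duration = 4,
                   include_caffeine = FALSE)
  sim <- simulate_trace(cfg)
  s <- (sim$trace$value - cfg$background_level - cfg$f0_baseline) /
    cfg$f0_baseline
  expect_equal(max(s), 1.0, tolerance = 1e-12)

  # with 0.5 Hz pacing, apexes additionally carry the linear-superposition
  # tail of the preceding transient, exp(-k_sys * 1.95 s) ~ 6e-5
  cfg2 <- quiet_cfg(amplitude_mean = 1.0, amplitude_cv = 0)
  sim2 <- simulate_trace(cfg2)
  paced <- sim2$trace$time < cfg2$paced_duration
  s2 <- (sim2$trace$value[paced] - cfg2$background_level - cfg2$f0_baseline) /
    cfg2$f0_baseline
  expect_equal(max(s2), 1.0, tolerance = 1e-4)
  expect_gte(max(s2), 1.0)
})

test_that("noiseless decay segments follow the closed-form exponential", {
  # single isolated transient, so no tail from a neighbouring spike
  cfg <- quiet_cfg(paced_duration = 2, pause_duration = 8,
                   include_caffeine = FALSE)
  sim <- simulate_trace(cfg)
  k <- sim$truth$k_sys_true
  t <- sim$trace$time
  s <- (sim$trace$value - cfg$background_level - cfg$f0_baseline) /
    cfg$f0_baseline
  peak <- which.max(s)
  seg <- peak:(peak + 300)
  expected <- s[peak] * exp(-k * (t[seg] - t[peak]))
  expect_lt(max(abs(s[seg] - expected)), 1e-9)
})

test_that("identical seeds give identical traces; arithmetic of truth holds", {
  cfg <- noisy_cfg(seed = 1L)
  a <- simulate_trace(cfg)
  b <- simulate_trace(cfg)
  expect_identical(a$trace$value, b$trace$value)
  expect_identical(a$truth, b$truth)

  cfg2 <- quiet_cfg(k_serca = 3.5, k_ncx = 1.5)
  tr <- simulate_trace(cfg2)$truth
  expect_identical(tr$k_sys_true, 5.0)
  expect_identical(tr$serca_function_true, 3.5)
  expect_identical(tr$k_sys_true - tr$k_caf_true, tr$serca_function_true)
  expect_true(tr$fractional_release_true > 0 &&
                tr$fractional_release_true <= 1)
})

test_that("the simulator records every drawn spike in the ground truth", {
  cfg <- noisy_cfg(ectopic_rate = 0.05, seed = 9L)
  sim <- simulate_trace(cfg)
  expect_length(sim$truth$spike_amplitudes, length(sim$truth$spike_times))
  expect_identical(sum(!sim$truth$is_ectopic), sim$truth$n_stimuli)
  expect_true(all(sim$truth$spike_amplitudes > 0))
})

test_that("increasing k_serca speeds systolic decay, leaves caffeine decay alone", {
  base <- quiet_cfg()
  fast <- quiet_cfg(k_serca = base$k_serca * 2)
  sim_b <- simulate_trace(base)
  sim_f <- simulate_trace(fast)
  t <- sim_b$trace$time
  # compare dF/F0 one diastolic interval after the same paced peak
  s_b <- (sim_b$trace$value - 600) / 500
  s_f <- (sim_f$trace$value - 600) / 500
  peak <- which.max(s_b[t < base$paced_duration])
  later <- peak + 50
  expect_lt(s_f[later], s_b[later])
  expect_gt(sim_f$truth$k_sys_true, sim_b$truth$k_sys_true)
  expect_identical(sim_f$truth$k_caf_true, sim_b$truth$k_caf_true)
  # caffeine decay samples are identical by construction
  caf <- t >= sim_b$truth$caffeine_onset + 1
  expect_equal(s_f[caf], s_b[caf], tolerance = 1e-6)
})

test_that("cohorts with unit effect are identical in law; multipliers scale truth", {
  base <- quiet_cfg(paced_duration = 4, pause_duration = 3, caffeine_tail = 3)
  coh <- simulate_cohort(base, n_cells_per_group = 150,
                         effect = list(k_serca = 1, k_ncx = 1),
                         jitter_sdlog = 0.15, seed = 5L)
  serca <- vapply(coh, function(c) c$truth$serca_function_true, numeric(1))
  grp <- vapply(coh, function(c) c$group, character(1))
  m1 <- mean(serca[grp == "group1"]); m2 <- mean(serca[grp == "group2"])
  # equal means within 3 sd of the Monte-Carlo error of the difference
  se <- sqrt(var(serca[grp == "group1"]) / 150 +
               var(serca[grp == "group2"]) / 150)
  expect_lt(abs(m1 - m2), 3 * se)

  # jitter-free: exactly the configured parameters, scaled in group 2
  coh0 <- simulate_cohort(base, n_cells_per_group = 1,
                          effect = list(k_serca = 1.5), jitter_sdlog = 0,
                          seed = 1L)
  expect_length(coh0, 2L)
  expect_identical(coh0[[1]]$truth$serca_function_true, base$k_serca)
  expect_equal(coh0[[2]]$truth$serca_function_true, 1.5 * base$k_serca)
  expect_identical(coh0[[1]]$truth$k_caf_true, coh0[[2]]$truth$k_caf_true)
})

test_that("simulated stacks agree with simulated traces after extraction", {
  cfg <- quiet_cfg(paced_duration = 6, pause_duration = 3, caffeine_tail = 4,
                   noise_sd = 10, f0_baseline = 2000, background_level = 400)
  geom <- list(width = 24, height = 16, cell = c(2, 2, 14, 14),
               background = c(17, 2, 23, 14))
  sim <- simulate_stack(cfg, geom)
  cell <- roi_rect(2, 2, 14, 14, "cell")
  bg <- roi_rect(17, 2, 23, 14, "bg")
  tr <- extract_trace(sim$stack, cell, bg)
  expect_length(tr$value, dim(sim$stack$frames)[3])

  ref <- simulate_trace(quiet_cfg(paced_duration = 6, pause_duration = 3,
                                  caffeine_tail = 4, noise_sd = 0,
                                  f0_baseline = 2000, background_level = 400))
  noiseless <- ref$trace$value - cfg$background_level
  # ROI mean of n_pix independent pixels has sd noise_sd/sqrt(n_pix); allow
  # half a count of 16-bit quantization on top. The 3 sd band must hold for
  # nearly all frames and a 6 sd band for every frame.
  # combined sd of (cell ROI mean - background ROI mean): 144 + 72 pixels
  se <- cfg$noise_sd * sqrt(1 / (12 * 12) + 1 / (6 * 12))
  dev <- abs(tr$value - noiseless)
  expect_gte(mean(dev <= 3 * se + 1), 0.99)
  expect_lt(max(dev), 6 * se + 1)
})

test_that("noiseless stack background region is exact; bad geometry errors", {
  cfg <- quiet_cfg(paced_duration = 3, pause_duration = 2, caffeine_tail = 2)
  geom <- list(width = 12, height = 8, cell = c(1, 1, 5, 5),
               background = c(7, 1, 11, 7))
  sim <- simulate_stack(cfg, geom)
  bgvals <- sim$stack$frames[2:7, 8:11, ]
  expect_true(all(bgvals == cfg$background_level))

  expect_error(simulate_stack(cfg, utils::modifyList(geom, list(cell = c(3, 3, 3, 5)))),
               "empty")
  expect_error(simulate_stack(cfg, utils::modifyList(geom, list(cell = c(1, 1, 13, 5)))),
               "exceeds")
  expect_error(simulate_stack(cfg, utils::modifyList(geom, list(background = c(4, 1, 8, 5)))),
               "overlap")
})
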