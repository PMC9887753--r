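#!/usr/bin/env Rscript
# Step 1 — simulate the study's recordings.
#
# Generates a two-group cohort of paced Fluo-4 recordings under the caffeine
# protocol (0.5 Hz field stimulation, stop-pacing pause, 10 mM caffeine):
# a control group and a group with SERCA2 pumping enhanced 1.5-fold, the
# contrast whose direction the downstream analysis should recover. Also
# writes one example trace + ground truth and a small image stack, so steps
# 2-3 can demonstrate the file-based entry points.
#
# Outputs under results/: cohort.rds is deliberately avoided — the cohort is
# regenerated from the seed in later steps; traces/ holds CSV + JSON truth
# for the example cell; stack.tif (+ sidecar) holds the example stack.

suppressPackageStartupMessages(library(catrace))

seed <- 20260930L
dir.create("results/traces", recursive = TRUE, showWarnings = FALSE)

base <- sim_config()  # 97 fps, 0.5 Hz, 180 s paced + 60 s pause + caffeine
cat("base configuration: k_serca =", base$k_serca, "1/s, k_ncx =",
    base$k_ncx, "1/s, SNR =", base$amplitude_mean * base$f0_baseline /
      base$noise_sd, "\n")

# one example recording written to disk in the exchange formats
sim <- simulate_trace(sim_config(seed = seed))
write_simulation(sim, "results/traces/example_cell.csv")
cat("example trace:", length(sim$trace), "samples,",
    sim$truth$n_stimuli, "stimuli, caffeine at",
    sim$truth$caffeine_onset, "s\n")

# a small synthetic image stack around the same model
geom <- list(width = 32, height = 24, cell = c(4, 4, 20, 20),
             background = c(24, 4, 31, 20))
stk <- simulate_stack(sim_config(paced_duration = 20, pause_duration = 6,
                                 caffeine_tail = 8, seed = seed),
                      geom)
write_stack_tiff(stk$stack, "results/traces/example_stack.tif")
jsonlite::write_json(list(label = "cell", type = "rect",
                          coords = c(4, 4, 20, 20)),
                     "results/traces/example_cell_roi.json",
                     auto_unbox = TRUE)
jsonlite::write_json(list(label = "background", type = "rect",
                          coords = c(24, 4, 31, 20)),
                     "results/traces/example_background_roi.json",
                     auto_unbox = TRUE)
cat("example stack:", paste(dim(stk$stack$frames), collapse = " x "),
    "written with ROI definitions\n")

# the cohort itself is defined by (base config, effect, seed); record that
manifest <- list(seed = seed, n_cells_per_group = 12,
                 effect = list(k_serca = 1.5), base = unclass(base))
jsonlite::write_json(manifest, "results/cohort_manifest.json",
                     auto_unbox = TRUE, digits = NA)
cat("cohort manifest written: 2 x 12 cells, k_serca x1.5 in group 2\n")
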