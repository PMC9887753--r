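#!/usr/bin/env Rscript
# Step 2 — read the example stack back and extract its ROI trace.
#
# Demonstrates the image-stack entry point of the pipeline: multi-page TIFF
# in, per-frame background-subtracted ROI mean out, and checks the
# round-trip against the trace-level simulation. Requires step 1.

suppressPackageStartupMessages(library(catrace))

stack <- read_stack("results/traces/example_stack.tif")
cell <- read_roi_json("results/traces/example_cell_roi.json")
bg <- read_roi_json("results/traces/example_background_roi.json")
cat("stack:", paste(dim(stack$frames), collapse = " x "),
    "@", signif(1 / stack$frame_interval, 4), "frames/s\n")

trace <- extract_trace(stack, cell, bg)
write_trace_csv(trace, "results/traces/example_stack_trace.csv")
cat("extracted", length(trace), "samples; baseline (first 50 frames) =",
    signif(mean(trace$value[1:50]), 5), "intensity units\n")

# the extracted trace runs through the same normalization as CSV traces
nt <- normalize_trace(trace)
cat("F0 =", signif(nt$f0_estimate$f0, 5), "from window [",
    nt$f0_estimate$window_start, ",", nt$f0_estimate$window_end, ")\n")
sp <- detect_spikes(nt, min_separation = 1)
cat("detected", nrow(sp), "transients in the stack trace\n")
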