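#!/usr/bin/env Rscript
# Step 4 - visualization.
# Renders short vector-projectile cineloop excerpts (dense style for the
# overview, sparse-large for the early-diastole vortices) and composes the
# synchronized three-panel frame sequence with the pressure trace.

suppressPackageStartupMessages(library(vfimix))

run_file <- "scratch/high_ecmo_run.rds"
run <- if (file.exists(run_file)) readRDS(run_file) else
  run_pipeline(default_run_config("high_ecmo", seed = 1))
fps <- 1 / diff(run$fields[[1]]$frame_times[1:2])

# early-diastole excerpt around t = 0.5 s (vortex window), 40 frames
window <- which(run$fields[[1]]$frame_times >= 0.48 &
                  run$fields[[1]]$frame_times < 0.48 + 40 / fps)
crop <- function(f) {
  f$vx <- f$vx[, , window, drop = FALSE]
  f$vz <- f$vz[, , window, drop = FALSE]
  f$valid <- f$valid[, , window, drop = FALSE]
  f$frame_times <- f$frame_times[window]
  f
}
loops <- lapply(run$fields, function(f)
  render_cineloop(crop(f), render_style("sparse-large"), seed = 1))
compose_video(loops, run$offsets_s, run$waveforms[[1]], fps = fps,
              slowdown = 10, out_dir = "results/cineloop_high_ecmo")
cat("wrote", length(window), "composed frames (1/10 speed replay)\n")
cat("to results/cineloop_high_ecmo (PNG sequence + manifest.json)\n")
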