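# Shared fixtures: small geometries and scenes, a brute-force
# categorization oracle, and cached demo pipeline runs.

tiny_geometry <- function(position = "distal_arch", spacing = 2, ...) {
  geometry_config(position, grid_spacing_mm = spacing, ...)
}

quick_scene <- function(position = "distal_arch", ecmo = 0.35,
                        duration = 0.7, spacing = 2, vortices = list(),
                        seed = 1, ...) {
  generate_flow_scene(
    geometry_config(position, grid_spacing_mm = spacing),
    pump_settings(ecmo_flow_lpm = ecmo),
    vortex_spec = vortices, seed = seed, duration_s = duration, ...)
}

# uniform-velocity vector field on a small open geometry (lumen = full fov)
uniform_field <- function(vx0, vz0, nf = 3, spacing = 2) {
  g <- geometry_config("distal_arch", fov_width_mm = 10, fov_depth_mm = 10,
                       grid_spacing_mm = spacing, vessel_diameter_mm = 100)
  dims <- c(g$nz, g$nx, nf)
  vector_field(seq(0, by = 8e-4, length.out = nf),
               array(vx0, dims), array(vz0, dims),
               valid = array(TRUE, dims), geometry = g)
}

# element-wise categorization oracle using explicit acos angle arithmetic
# (independent of the vectorized atan2 implementation)
oracle_categorize_one <- function(vx, vz, valid, axis_deg, cone_deg,
                                  speed_threshold, min_speed) {
  if (!valid) return(0L)
  speed <- sqrt(vx^2 + vz^2)
  if (speed < min_speed || speed == 0) return(0L)
  ax <- c(cos(axis_deg * pi / 180), sin(axis_deg * pi / 180))
  cosd <- (vx * ax[1] + vz * ax[2]) / speed
  cosd <- max(-1, min(1, cosd))
  ang_ant <- acos(cosd) * 180 / pi
  ang_ret <- 180 - ang_ant
  fast <- speed > speed_threshold
  if (ang_ant <= cone_deg) return(if (fast) 1L else 2L)
  if (ang_ret <= cone_deg) return(if (fast) 3L else 4L)
  5L
}

# cached demo pipeline runs shared across test files
.run_cache <- new.env(parent = emptyenv())
demo_run <- function(condition, seed = 1) {
  key <- paste(condition, seed, sep = "_")
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- run_pipeline(default_run_config(condition,
                                                         seed = seed))
  .run_cache[[key]]
}

# count strict local maxima per cycle of a periodic sampled series
count_cycle_peaks <- function(x) {
  n <- length(x)
  prev <- x[c(n, seq_len(n - 1))]
  nxt <- x[c(seq_len(n - 1) + 1, 1)]
  sum(x > prev & x > nxt)
}
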