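# End-to-end pipeline: generate -> acquire -> solve -> segment ->
# categorize -> summarize (-> render), fully determined by one global seed,
# and the two-condition comparison.

#' Default run configuration
#'
#' The bench study conditions: three probe positions along the thoracic
#' aorta, 1.5 s loops at 1250 fps, the pulsatile pump at 30 mL / 90 bpm
#' (2.7 L/min, 40/60 systole/diastole), ECMO at 0.35 (low) or 1.0 (high)
#' L/min, dual +/-10 degree plane-wave Doppler at 10 kHz PRF, the +/-30
#' degree / 0.25 m/s five-group categorization, and 0.3 s systole windows.
#'
#' @param condition `"low_ecmo"` or `"high_ecmo"`.
#' @param seed Global integer seed; every stochastic stage derives its seed
#'   from it.
#' @param grid_spacing_mm Simulation pixel pitch (default 2 mm, a coarse
#'   analysis grid).
#' @param duration_s Loop duration (default 1.5 s).
#' @param noise_std_hz Doppler frequency noise SD (default 5 Hz; the
#'   phantom's strong scatterers give high Doppler SNR).
#' @return A `run_config` nested list (scene / pump / acquisition /
#'   analysis / render blocks).
#' @export
default_run_config <- function(condition = c("low_ecmo", "high_ecmo"),
                               seed = 1, grid_spacing_mm = 2,
                               duration_s = 1.5, noise_std_hz = 5) {
  condition <- match.arg(condition)
  ecmo <- if (condition == "low_ecmo") 0.35 else 1.0
  structure(list(
    condition = condition,
    seed = as.integer(seed),
    scene = list(
      positions = c("ascending", "distal_arch", "mid_descending"),
      grid_spacing_mm = grid_spacing_mm,
      duration_s = duration_s,
      dt_s = 8e-4,
      start_offsets_s = c(0, 0.21, 0.37),
      onset_s = 0.1,
      gate_width_s = 0.3,
      interface_halfwidth_mm = 4,
      total_path_mm = 230,
      flux_smooth_tau_s = 0.15,
      vortices = "default"
    ),
    pump = list(
      stroke_volume_ml = 30, heart_rate_bpm = 90,
      systole_fraction = 0.4, ecmo_flow_lpm = ecmo
    ),
    pressure = list(
      systolic_mmhg = 81, diastolic_mmhg = 57, bimodal = TRUE,
      sample_rate_hz = 500
    ),
    acquisition = list(
      center_frequency_hz = 5e6, sound_speed_mps = 1540,
      prf_hz = 10000, tx_angles_deg = c(-10, 10), pairs_per_frame = 4,
      noise_std_hz = noise_std_hz, iq_mode = FALSE
    ),
    analysis = list(
      cone_deg = 30, speed_threshold_mps = 0.25, min_speed_mps = 0.02,
      systole_duration_s = 0.3, onset_min_area_frac = 0.05,
      mixing_bin_mm = 4
    ),
    render = list(enabled = FALSE, style = "dense-small")
  ), class = "run_config")
}

#' Run the full single-condition pipeline
#'
#' Generates the three positions' flow scenes and pressure waveforms (each
#' loop starting at its own point of the pump cycle), simulates the
#' dual-angle Doppler acquisitions, solves the vector fields, synchronizes
#' the loops on their pressure waveforms, detects the systole onset in the
#' proximal ascending aorta, segments the cardiac phases, categorizes the
#' vectors, computes per-frame group ratios and per-phase summaries, and
#' localizes the mixing zone. Identical configurations produce identical
#' artifacts.
#'
#' @param config A `run_config`.
#' @param out_dir Optional output directory; when given, writes
#'   `ratios.csv`, `phase_summary.csv`, `phases.csv`, `manifest.json`, and
#'   (if rendering is enabled) PNG cineloop frames.
#' @return A `pipeline_run` list: `config`, per-position `fields` and
#'   `labels`, `ratios` (long data frame with `position`), `summary`,
#'   `phases`, `offsets_s`, `onset_s`, `mixing_zone_mm`, `waveforms`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  sc <- config$scene; an <- config$analysis
  pump <- pump_settings(config$pump$stroke_volume_ml,
                        config$pump$heart_rate_bpm,
                        config$pump$systole_fraction,
                        config$pump$ecmo_flow_lpm)
  n_pos <- length(sc$positions)
  fields <- list(); labels <- list(); waveforms <- list()
  ratios_all <- list()

  pr_n <- round(config$pressure$sample_rate_hz * sc$duration_s)
  for (i in seq_len(n_pos)) {
    pos <- sc$positions[i]
    g <- geometry_config(pos, grid_spacing_mm = sc$grid_spacing_mm)
    scene <- generate_flow_scene(
      g, pump, vortex_spec = if (identical(sc$vortices, "default")) NULL
      else list(),
      seed = config$seed + i,
      duration_s = sc$duration_s, dt_s = sc$dt_s,
      onset_s = sc$onset_s, gate_width_s = sc$gate_width_s,
      interface_halfwidth_mm = sc$interface_halfwidth_mm,
      total_path_mm = sc$total_path_mm,
      flux_smooth_tau_s = sc$flux_smooth_tau_s,
      t0_s = sc$start_offsets_s[i])
    waveforms[[pos]] <- generate_pressure_waveform(
      pump, config$pressure$systolic_mmhg, config$pressure$diastolic_mmhg,
      config$pressure$bimodal, n_samples = pr_n,
      duration_s = sc$duration_s, t0_s = sc$start_offsets_s[i])
    acq <- acquisition_config(
      center_frequency_hz = config$acquisition$center_frequency_hz,
      sound_speed_mps = config$acquisition$sound_speed_mps,
      prf_hz = config$acquisition$prf_hz,
      tx_angles_deg = config$acquisition$tx_angles_deg,
      pairs_per_frame = config$acquisition$pairs_per_frame,
      noise_std_hz = config$acquisition$noise_std_hz,
      iq_mode = isTRUE(config$acquisition$iq_mode),
      seed = config$seed + 100 + i)
    frames <- acquire(scene, acq)
    fields[[pos]] <- solve_vectors(frames)
  }

  offsets <- synchronize_cineloops(waveforms)

  # systole onset from the ascending-aorta loop (the reference clock)
  onset_raw <- detect_systole_onset(
    fields[["ascending"]], min_area_frac = an$onset_min_area_frac,
    min_speed = an$min_speed_mps)
  onset_s <- onset_raw %% pump$cycle_period_s
  phases <- segment_phases(onset_s, pump$cycle_period_s,
                           an$systole_duration_s)

  for (i in seq_len(n_pos)) {
    pos <- sc$positions[i]
    lm <- categorize_vectors(fields[[pos]], cone_deg = an$cone_deg,
                             speed_threshold = an$speed_threshold_mps,
                             min_speed = an$min_speed_mps)
    labels[[pos]] <- lm
    rt <- group_ratios(lm)
    # place this loop's frames on the reference cycle clock
    rt$time_aligned <- (rt$time - (offsets[i] - offsets[1])) %%
      pump$cycle_period_s
    rt$position <- pos
    ratios_all[[pos]] <- rt
  }
  ratios <- do.call(rbind, ratios_all)
  rownames(ratios) <- NULL

  summaries <- lapply(sc$positions, function(pos) {
    rt <- ratios_all[[pos]]
    rt2 <- rt; rt2$time <- rt2$time_aligned
    s <- phase_summary(rt2, phases)
    s$position <- pos
    s
  })
  summary_df <- do.call(rbind, summaries)

  mixing_mm <- localize_mixing_zone(labels, bin_mm = an$mixing_bin_mm)

  run <- structure(list(
    config = config, fields = fields, labels = labels,
    ratios = ratios, summary = summary_df, phases = phases,
    offsets_s = offsets, onset_s = onset_s,
    mixing_zone_mm = as.numeric(mixing_mm),
    waveforms = waveforms
  ), class = "pipeline_run")

  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$ratios, file.path(out_dir, "ratios.csv"),
                   row.names = FALSE)
  utils::write.csv(run$summary, file.path(out_dir, "phase_summary.csv"),
                   row.names = FALSE)
  w <- run$phases$windows
  utils::write.csv(data.frame(phase = rownames(w), start_s = w[, 1],
                              end_s = w[, 2]),
                   file.path(out_dir, "phases.csv"), row.names = FALSE)
  cfg_yaml <- yaml::as.yaml(unclass(run$config), precision = 15)
  tmp <- tempfile(); writeLines(cfg_yaml, tmp)
  manifest <- list(
    package = "vfimix",
    version = as.character(utils::packageVersion("vfimix")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = run$config$seed,
    condition = run$config$condition,
    config_md5 = unname(tools::md5sum(tmp)),
    config = unclass(run$config),
    onset_s = run$onset_s,
    offsets_s = as.numeric(run$offsets_s),
    mixing_zone_mm = run$mixing_zone_mm
  )
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (isTRUE(run$config$render$enabled)) {
    style <- render_style(run$config$render$style)
    loops <- lapply(run$fields, render_cineloop, style = style,
                    seed = run$config$seed)
    compose_video(loops, run$offsets_s, run$waveforms[[1]],
                  fps = 1 / diff(run$fields[[1]]$frame_times[1:2]),
                  out_dir = file.path(out_dir, "cineloop"))
  }
  invisible(out_dir)
}

#' Compare two ECMO-condition runs
#'
#' Welch comparison of the per-frame group ratios between two runs, per
#' (position, phase, group), plus both runs' mixing-zone estimates. The two
#' runs must share their analysis settings. When both samples are constant
#' and equal (e.g. a group absent from both runs) the comparison is reported
#' as no difference (`t = 0`, `p = 1`, `df = NA`).
#'
#' @param run_a,run_b `pipeline_run` objects.
#' @return List with `table` (position, phase, group, means, t, df, p) and
#'   `mixing_zone_mm` (named c(a, b)).
#' @export
compare_conditions <- function(run_a, run_b) {
  if (!identical(run_a$config$analysis, run_b$config$analysis))
    stop_vfimix("runs use different analysis settings",
                "vfimix_incompatible_runs")
  pick <- function(run, pos, ph, gr) {
    rt <- run$ratios
    ph_f <- assign_phase(rt$time_aligned, run$phases)
    r <- rt$ratio[rt$position == pos & rt$group == gr & ph_f == ph]
    r[!is.na(r)]
  }
  positions <- unique(run_a$ratios$position)
  phases <- rownames(run_a$phases$windows)
  groups <- levels(run_a$ratios$group)
  grid <- expand.grid(position = positions, phase = phases, group = groups,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    a <- pick(run_a, grid$position[i], grid$phase[i], grid$group[i])
    b <- pick(run_b, grid$position[i], grid$phase[i], grid$group[i])
    res <- tryCatch(welch_t_test(a, b), vfimix_degenerate_test = function(e) {
      if (mean(a) == mean(b)) list(t = 0, df = NA_real_, p = 1)
      else list(t = NA_real_, df = NA_real_, p = NA_real_)
    })
    data.frame(position = grid$position[i], phase = grid$phase[i],
               group = grid$group[i],
               mean_a = mean(a), mean_b = mean(b),
               n_a = length(a), n_b = length(b),
               t = res$t, df = res$df, p = res$p)
  })
  list(table = do.call(rbind, rows),
       mixing_zone_mm = c(a = run_a$mixing_zone_mm,
                          b = run_b$mixing_zone_mm))
}
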