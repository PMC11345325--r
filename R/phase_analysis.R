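# Cardiac-phase segmentation: systole onset is the first appearance of
# anterograde vectors at the proximal end of the ascending-aorta image;
# the cycle is partitioned into late diastole / systole / early diastole.

#' Detect the systole onset from the vector field
#'
#' Returns the earliest frame time at which the fraction of region-of-
#' interest pixels carrying valid anterograde vectors (within the +/- 30
#' degree cone around the anterograde axis) exceeds `min_area_frac`. The
#' default ROI is the 20% of lumen pixels nearest the anterograde inflow
#' edge (smallest path coordinate) of the image.
#'
#' @param field A `vector_field` with geometry.
#' @param roi Optional logical nz x nx mask overriding the default ROI.
#' @param axis_deg Anterograde axis angle; defaults to the geometry's.
#' @param cone_deg Half-angle of the anterograde cone (default 30).
#' @param min_area_frac Minimum ROI fraction (default 0.05).
#' @param min_speed Speed floor (m/s); default 0 counts any nonzero valid
#'   vector (raise above the noise floor for noisy acquisitions).
#' @return Onset time in seconds.
#' @export
detect_systole_onset <- function(field, roi = NULL, axis_deg = NULL,
                                 cone_deg = 30, min_area_frac = 0.05,
                                 min_speed = 0) {
  g <- field$geometry
  axis_deg <- axis_deg %||% g$anterograde_axis_deg
  if (is.null(roi)) {
    if (is.null(g))
      stop_vfimix("need geometry or an explicit ROI", "vfimix_invalid_input")
    s <- g$path_mm[g$lumen_mask]
    cut <- stats::quantile(s, 0.2)
    roi <- g$lumen_mask & g$path_mm <= cut
  }
  if (!any(roi))
    stop_vfimix("empty ROI", "vfimix_invalid_input")
  n_roi <- sum(roi)
  for (k in seq_along(field$frame_times)) {
    vx <- field$vx[, , k][roi]; vz <- field$vz[, , k][roi]
    ok <- field$valid[, , k][roi]
    sp <- sqrt(vx^2 + vz^2)
    ang <- atan2(vz, vx) * 180 / pi
    antero <- ok & sp > min_speed &
      abs(angle_diff_deg(ang, axis_deg)) <= cone_deg
    if (sum(antero) / n_roi > min_area_frac)
      return(field$frame_times[k])
  }
  stop_vfimix("no frame with sufficient anterograde flow in the ROI",
              "vfimix_onset_not_found")
}

#' Segment the cardiac cycle into three phases
#'
#' Half-open windows partitioning `[0, cycle)`: late diastole `[0, onset)`,
#' systole `[onset, onset + systole_duration)`, early diastole
#' `[onset + systole_duration, cycle)`.
#'
#' @param onset_s Systole onset within the cycle, `0 <= onset < cycle`.
#' @param cycle_period_s Cycle period (s).
#' @param systole_duration_s Systole duration (default 0.3 s, read off the
#'   pressure curve).
#' @return A `phase_windows` object with a 3 x 2 window matrix.
#' @export
segment_phases <- function(onset_s, cycle_period_s,
                           systole_duration_s = 0.3) {
  if (onset_s < 0 || onset_s >= cycle_period_s)
    stop_vfimix("onset must lie within the cycle", "vfimix_invalid_config")
  if (systole_duration_s <= 0 || onset_s + systole_duration_s >= cycle_period_s)
    stop_vfimix("systole window must end before the cycle does",
                "vfimix_invalid_config")
  w <- rbind(
    late_diastole = c(0, onset_s),
    systole = c(onset_s, onset_s + systole_duration_s),
    early_diastole = c(onset_s + systole_duration_s, cycle_period_s)
  )
  colnames(w) <- c("start", "end")
  structure(list(
    cycle_period_s = cycle_period_s,
    systole_onset_s = onset_s,
    systole_duration_s = systole_duration_s,
    windows = w
  ), class = "phase_windows")
}

#' Assign times to cardiac phases
#'
#' @param times Times in seconds (any range; reduced modulo the cycle).
#' @param phases A [segment_phases()] result.
#' @return Factor with levels late_diastole / systole / early_diastole.
#' @export
assign_phase <- function(times, phases) {
  u <- times %% phases$cycle_period_s
  w <- phases$windows
  lab <- character(length(u))
  for (ph in rownames(w))
    lab[u >= w[ph, "start"] & u < w[ph, "end"]] <- ph
  factor(lab, levels = rownames(w))
}

#' Synchronize cineloops on their pressure waveforms
#'
#' Folds each loop's pressure waveform onto the cardiac cycle (averaging
#' over the recorded cycles), then finds the circular shift maximizing its
#' cross-correlation with the first loop's folded waveform. Folding keeps
#' the circular correlation unbiased when the recording does not span an
#' integer number of cycles.
#'
#' @param waveforms List of `pressure_waveform`s (same pump cycle).
#' @param n_bins Cycle bins for the folded profiles (default: one per
#'   waveform sample within a cycle).
#' @return Numeric vector of offsets in seconds (first entry 0) in
#'   `[0, cycle)`; `offset[k]` is the delay of loop k relative to loop 1,
#'   i.e. loop k's waveform equals loop 1's evaluated `offset[k]` earlier.
#' @export
synchronize_cineloops <- function(waveforms, n_bins = NULL) {
  if (length(waveforms) < 2)
    stop_vfimix("need at least two loops", "vfimix_invalid_input")
  period <- waveforms[[1]]$cycle_period_s
  dt <- diff(waveforms[[1]]$times[1:2])
  n_bins <- n_bins %||% max(64L, round(period / dt))
  prof <- lapply(waveforms, function(w) {
    if (stats::sd(w$pressure_mmhg) == 0)
      stop_vfimix("constant waveform: alignment undefined",
                  "vfimix_alignment_undefined")
    fold_cycle(w, n_bins)
  })
  fr <- stats::fft(prof[[1]] - mean(prof[[1]]))
  vapply(prof, function(x) {
    fx <- stats::fft(x - mean(x))
    # peak of the circular cross-correlation with the reference profile
    cc <- Re(stats::fft(fx * Conj(fr), inverse = TRUE))
    lag <- which.max(cc) - 1
    (lag * period / n_bins) %% period
  }, numeric(1))
}

# cycle-folded waveform profile (bin means, gaps filled by interpolation)
fold_cycle <- function(w, n_bins) {
  u <- (w$times %% w$cycle_period_s) / w$cycle_period_s
  bin <- floor(u * n_bins) + 1
  prof <- vapply(seq_len(n_bins), function(b) {
    v <- w$pressure_mmhg[bin == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  if (anyNA(prof)) {
    idx <- seq_len(n_bins)
    ok <- !is.na(prof)
    prof <- stats::approx(idx[ok], prof[ok], idx, rule = 2)$y
  }
  prof
}
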