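# Dual-angle plane-wave Doppler acquisition: project the true field onto
# each steered transmit, wrap at the per-angle Nyquist, add measurement
# noise; optionally synthesize slow-time IQ ensembles and estimate the
# Doppler frequency with the lag-one autocorrelation (Kasai) estimator.

#' Acquisition configuration
#'
#' @param center_frequency_hz Transmit center frequency (default 5 MHz,
#'   linear array).
#' @param sound_speed_mps Speed of sound (default 1540 m/s).
#' @param prf_hz Overall pulse repetition frequency (default 10 kHz);
#'   interleaving over the transmit angles divides it per angle.
#' @param tx_angles_deg Steering angles (default `c(-10, 10)` degrees),
#'   at least two distinct values.
#' @param pairs_per_frame Transmit pairs accumulated per displayed vector
#'   frame (default 4; with two angles this gives 8 events per frame,
#'   i.e. 800 microseconds at 10 kHz - the displayed 1250 fps).
#' @param noise_std_hz SD of the zero-mean Doppler-frequency noise
#'   (frequency mode) in Hz.
#' @param iq_mode If TRUE, synthesize complex slow-time ensembles and
#'   estimate frequencies with [kasai_estimate()] instead of reading them
#'   off directly.
#' @param iq_noise_std Additive complex white-noise SD relative to unit
#'   signal amplitude (iq mode only).
#' @param seed Integer seed for the acquisition noise stream.
#' @return An `acquisition_config`.
#' @export
acquisition_config <- function(center_frequency_hz = 5e6,
                               sound_speed_mps = 1540,
                               prf_hz = 10000,
                               tx_angles_deg = c(-10, 10),
                               pairs_per_frame = 4,
                               noise_std_hz = 0,
                               iq_mode = FALSE,
                               iq_noise_std = 0,
                               seed = 1) {
  if (prf_hz <= 0)
    stop_vfimix("prf_hz must be positive", "vfimix_invalid_config")
  if (length(unique(tx_angles_deg)) < 2)
    stop_vfimix("need at least two distinct transmit angles",
                "vfimix_invalid_config")
  if (pairs_per_frame < 1)
    stop_vfimix("pairs_per_frame must be at least 1", "vfimix_invalid_config")
  n_angles <- length(tx_angles_deg)
  structure(list(
    center_frequency_hz = center_frequency_hz,
    sound_speed_mps = sound_speed_mps,
    prf_hz = prf_hz,
    tx_angles_deg = tx_angles_deg,
    n_angles = n_angles,
    per_angle_prf_hz = prf_hz / n_angles,
    pairs_per_frame = pairs_per_frame,
    frame_interval_s = pairs_per_frame * n_angles / prf_hz,
    noise_std_hz = noise_std_hz,
    iq_mode = iq_mode,
    iq_noise_std = iq_noise_std,
    seed = seed
  ), class = "acquisition_config")
}

#' Doppler frequency of a velocity under a steered plane wave
#'
#' Round-trip Doppler shift for plane-wave transmit at angle `alpha`
#' (counterclockwise from +x) with receive along depth:
#' `f_d = (f0 / c) * (v_x * sin(alpha) + v_z * (1 + cos(alpha)))`.
#' Vectorized over `vx` / `vz`.
#'
#' @param vx,vz Velocity components (m/s).
#' @param tx_angle_deg Steering angle (degrees).
#' @param f0 Center frequency (Hz).
#' @param c Sound speed (m/s).
#' @return Doppler frequency in Hz (same shape as `vx`).
#' @export
project_velocity_to_doppler <- function(vx, vz, tx_angle_deg,
                                        f0 = 5e6, c = 1540) {
  a <- tx_angle_deg * pi / 180
  (f0 / c) * (vx * sin(a) + vz * (1 + cos(a)))
}

#' Wrap a Doppler frequency at the per-angle Nyquist limit
#'
#' Modular wrapping into `(-prf/2, +prf/2]`, flagging inputs that fell
#' outside that interval (aliased). Vectorized.
#'
#' @param f Doppler frequency (Hz).
#' @param per_angle_prf Per-angle PRF (Hz), positive.
#' @return List with `f` (wrapped) and `aliased` (logical).
#' @export
wrap_alias <- function(f, per_angle_prf) {
  if (per_angle_prf <= 0)
    stop_vfimix("per_angle_prf must be positive", "vfimix_invalid_config")
  w <- f - per_angle_prf * ceiling(f / per_angle_prf - 0.5)
  # put the boundary on +prf/2, not -prf/2
  at_neg <- w <= -per_angle_prf / 2
  w[at_neg] <- w[at_neg] + per_angle_prf
  list(f = w, aliased = abs(f - w) > per_angle_prf / 4)
}

#' Kasai lag-one autocorrelation Doppler estimator
#'
#' Mean Doppler frequency from the phase of the lag-one autocorrelation of a
#' complex slow-time ensemble: `prf / (2 * pi) * Arg(sum conj(x_n) x_{n+1})`.
#' A pure complex exponential below Nyquist is recovered exactly; above it
#' the estimate wraps like [wrap_alias()].
#'
#' @param iq Complex slow-time vector, length at least 2.
#' @param per_angle_prf Sampling (per-angle) PRF in Hz.
#' @return Frequency in Hz, or `NA_real_` for an all-zero ensemble
#'   (undefined frequency).
#' @export
kasai_estimate <- function(iq, per_angle_prf) {
  if (length(iq) < 2)
    stop_vfimix("ensemble length must be at least 2", "vfimix_invalid_input")
  if (all(iq == 0)) return(NA_real_)
  r1 <- sum(Conj(iq[-length(iq)]) * iq[-1])
  per_angle_prf / (2 * pi) * Arg(r1)
}

#' Simulate a dual-angle Doppler acquisition of a flow scene
#'
#' For each displayed frame and each transmit angle, interpolates the true
#' velocity to the frame time, projects it onto the steered-plane-wave
#' Doppler axis, wraps at the per-angle Nyquist and adds zero-mean Gaussian
#' frequency noise (frequency mode). In IQ mode a slow-time complex
#' exponential ensemble of length `pairs_per_frame` is synthesized per pixel
#' (plus complex white noise) and the map is read back through
#' [kasai_estimate()].
#'
#' @param scene A `flow_scene`.
#' @param cfg An [acquisition_config()].
#' @return A `doppler_frame_set`: `frame_times`, per-angle `doppler_hz` and
#'   `aliased` arrays (nz x nx x n_frames), geometry and config.
#' @export
acquire <- function(scene, cfg = acquisition_config()) {
  stopifnot(inherits(scene, "flow_scene"),
            inherits(cfg, "acquisition_config"))
  if (length(scene$times) == 0 || all(scene$lumen_mask == FALSE))
    stop_vfimix("empty scene", "vfimix_invalid_input")
  g <- scene$geometry
  frame_times <- seq(scene$times[1], scene$times[length(scene$times)],
                     by = cfg$frame_interval_s)
  nf <- length(frame_times)
  nz <- g$nz; nx <- g$nx
  doppler <- lapply(cfg$tx_angles_deg, function(a) array(0, c(nz, nx, nf)))
  aliased <- lapply(cfg$tx_angles_deg, function(a)
    array(FALSE, c(nz, nx, nf)))

  with_seed(cfg$seed, {
    for (k in seq_len(nf)) {
      vx <- interp_time_slice(scene$vx, scene$times, frame_times[k])
      vz <- interp_time_slice(scene$vz, scene$times, frame_times[k])
      for (i in seq_along(cfg$tx_angles_deg)) {
        f_true <- project_velocity_to_doppler(
          vx, vz, cfg$tx_angles_deg[i],
          cfg$center_frequency_hz, cfg$sound_speed_mps)
        wr <- wrap_alias(f_true, cfg$per_angle_prf_hz)
        if (cfg$iq_mode) {
          f_meas <- iq_measure_map(wr$f, cfg)
        } else {
          f_meas <- wr$f
          if (cfg$noise_std_hz > 0)
            f_meas <- f_meas + rnorm(length(f_meas), 0, cfg$noise_std_hz)
        }
        doppler[[i]][, , k] <- f_meas
        aliased[[i]][, , k] <- wr$aliased
      }
    }
  })

  structure(list(
    frame_times = frame_times,
    doppler_hz = doppler,
    aliased = aliased,
    geometry = g,
    lumen_mask = scene$lumen_mask,
    config = cfg
  ), class = "doppler_frame_set")
}

# synthesize per-pixel IQ ensembles at the given frequencies and read the
# map back through the Kasai estimator
iq_measure_map <- function(f_map, cfg) {
  n <- cfg$pairs_per_frame
  if (n < 2) n <- 2
  npx <- length(f_map)
  tn <- (seq_len(n) - 1) / cfg$per_angle_prf_hz
  # npx x n matrix of complex exponentials
  ph <- outer(as.vector(f_map), tn, function(f, t) 2 * pi * f * t)
  iq <- exp(1i * ph)
  if (cfg$iq_noise_std > 0) {
    iq <- iq + matrix(complex(real = rnorm(npx * n, 0, cfg$iq_noise_std),
                              imaginary = rnorm(npx * n, 0,
                                                cfg$iq_noise_std)),
                      npx, n)
  }
  r1 <- rowSums(Conj(iq[, -n, drop = FALSE]) * iq[, -1, drop = FALSE])
  out <- cfg$per_angle_prf_hz / (2 * pi) * Arg(r1)
  out[rowSums(abs(iq)) == 0] <- NA_real_
  matrix(out, nrow(f_map), ncol(f_map))
}
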