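# Ground-truth flow scenes for a thoracic aorta under VA-ECMO:
# a pulsatile anterograde cardiac stream meets a steady retrograde ECMO
# return jet; the interface ("mixing zone") position follows the flux ratio.

#' Cardiac pump settings
#'
#' Pulsatile-pump operating point. Cardiac output is derived as
#' `stroke_volume_ml * heart_rate_bpm / 1000` (L/min).
#'
#' @param stroke_volume_ml Stroke volume in mL (default 30, a low-output
#'   heart supported by ECMO).
#' @param heart_rate_bpm Heart rate in beats per minute (default 90).
#' @param systole_fraction Fraction of the cycle spent in systole, in (0, 1)
#'   (default 0.40).
#' @param ecmo_flow_lpm Steady retrograde ECMO flow rate in L/min
#'   (study settings: 0.35 low, 1.0 high).
#' @return A `pump_settings` list with the derived `cardiac_output_lpm` and
#'   `cycle_period_s`.
#' @export
pump_settings <- function(stroke_volume_ml = 30, heart_rate_bpm = 90,
                          systole_fraction = 0.40, ecmo_flow_lpm = 0.35) {
  if (!is.finite(heart_rate_bpm) || heart_rate_bpm <= 0)
    stop_vfimix("heart_rate_bpm must be positive", "vfimix_invalid_config")
  if (stroke_volume_ml < 0 || ecmo_flow_lpm < 0)
    stop_vfimix("volumes and flow rates must be nonnegative",
                "vfimix_invalid_config")
  if (systole_fraction <= 0 || systole_fraction >= 1)
    stop_vfimix("systole_fraction must be in (0, 1)", "vfimix_invalid_config")
  structure(list(
    stroke_volume_ml = stroke_volume_ml,
    heart_rate_bpm = heart_rate_bpm,
    systole_fraction = systole_fraction,
    ecmo_flow_lpm = ecmo_flow_lpm,
    cardiac_output_lpm = stroke_volume_ml * heart_rate_bpm / 1000,
    cycle_period_s = 60 / heart_rate_bpm
  ), class = "pump_settings")
}

#' Imaging-plane geometry at one probe position
#'
#' Describes one 38 mm (width) x 40 mm (depth) imaging plane on the aorta.
#' The vessel is modeled as a straight segment crossing the image center at
#' the anterograde axis angle; the lumen mask keeps pixels within half a
#' vessel diameter of the centerline. The per-pixel path coordinate is the
#' distance from the aortic root measured along the centerline.
#'
#' @param position_id One of `"ascending"`, `"distal_arch"`,
#'   `"mid_descending"`.
#' @param fov_width_mm,fov_depth_mm Field of view (defaults 38 x 40 mm).
#' @param grid_spacing_mm Pixel pitch in mm.
#' @param vessel_diameter_mm Lumen diameter; defaults per position
#'   (ascending 26.9, distal arch 24, mid descending 23.7 mm).
#' @param anterograde_axis_deg Angle of the local "from the cardiac pump"
#'   flow direction, counterclockwise from +x, in [0, 360). Defaults per
#'   position (15, 0, 345 degrees).
#' @param path_length_mm Centerline distance from the aortic root to the
#'   image center; defaults 50 / 110 / 180 mm per position.
#' @return A `geometry_config` with grid axes, `lumen_mask` (nz x nx),
#'   per-pixel `path_mm` and `perp_mm` coordinate maps.
#' @export
geometry_config <- function(position_id = c("ascending", "distal_arch",
                                            "mid_descending"),
                            fov_width_mm = 38, fov_depth_mm = 40,
                            grid_spacing_mm = 1,
                            vessel_diameter_mm = NULL,
                            anterograde_axis_deg = NULL,
                            path_length_mm = NULL) {
  position_id <- match.arg(position_id)
  if (fov_width_mm <= 0 || fov_depth_mm <= 0 || grid_spacing_mm <= 0)
    stop_vfimix("field of view and grid spacing must be positive",
                "vfimix_invalid_config")
  defaults <- list(
    ascending      = list(d = 26.9, axis = 15,  path = 50),
    distal_arch    = list(d = 24.0, axis = 0,   path = 110),
    mid_descending = list(d = 23.7, axis = 345, path = 180)
  )[[position_id]]
  vessel_diameter_mm <- vessel_diameter_mm %||% defaults$d
  anterograde_axis_deg <- (anterograde_axis_deg %||% defaults$axis) %% 360
  path_length_mm <- path_length_mm %||% defaults$path

  x_mm <- seq(0, fov_width_mm, by = grid_spacing_mm)
  z_mm <- seq(0, fov_depth_mm, by = grid_spacing_mm)
  nx <- length(x_mm); nz <- length(z_mm)
  cx <- fov_width_mm / 2; cz <- fov_depth_mm / 2
  a <- anterograde_axis_deg * pi / 180
  dx <- matrix(rep(x_mm - cx, each = nz), nz, nx)
  dz <- matrix(rep(z_mm - cz, times = nx), nz, nx)
  along <- dx * cos(a) + dz * sin(a)
  perp <- -dx * sin(a) + dz * cos(a)
  lumen <- abs(perp) <= vessel_diameter_mm / 2
  if (!any(lumen))
    stop_vfimix("lumen mask is empty", "vfimix_invalid_config")

  structure(list(
    position_id = position_id,
    fov_width_mm = fov_width_mm, fov_depth_mm = fov_depth_mm,
    grid_spacing_mm = grid_spacing_mm,
    vessel_diameter_mm = vessel_diameter_mm,
    anterograde_axis_deg = anterograde_axis_deg,
    path_length_mm = path_length_mm,
    x_mm = x_mm, z_mm = z_mm, nx = nx, nz = nz,
    lumen_mask = lumen,
    path_mm = path_length_mm + along,
    perp_mm = perp
  ), class = "geometry_config")
}

#' Arterial pressure waveform of the pulsatile pump
#'
#' Periodic pressure trace spanning at least `duration_s`. The systolic
#' upstroke is a smooth bump in mid systole; with `bimodal = TRUE` a second,
#' smaller bump follows it, emulating the re-bouncing ball valve of the pump
#' that gives the measured trace its bi-modal shape. The series is scaled so
#' its maximum equals `systolic_mmhg` and its minimum `diastolic_mmhg`.
#'
#' @param pump A [pump_settings()].
#' @param systolic_mmhg,diastolic_mmhg Peak and trough pressures
#'   (defaults 81 / 57 mmHg, the bench measurement without ECMO flow).
#' @param bimodal Add the secondary valve-bounce peak (default TRUE).
#' @param n_samples Total number of samples over `duration_s`
#'   (at least 16 per cardiac cycle).
#' @param duration_s Length of the trace in seconds (default 1.5).
#' @param t0_s Phase offset: the recording starts `t0_s` into the pump
#'   cycle (default 0), as when loops are acquired at different times.
#' @return A `pressure_waveform` with `times` and `pressure_mmhg`.
#' @export
generate_pressure_waveform <- function(pump, systolic_mmhg = 81,
                                       diastolic_mmhg = 57, bimodal = TRUE,
                                       n_samples = 1500, duration_s = 1.5,
                                       t0_s = 0) {
  stopifnot(inherits(pump, "pump_settings"))
  period <- pump$cycle_period_s
  n_cycles <- duration_s / period
  if (n_samples / n_cycles < 16)
    stop_vfimix("need at least 16 samples per cardiac cycle",
                "vfimix_invalid_config")
  if (systolic_mmhg < diastolic_mmhg)
    stop_vfimix("systolic pressure below diastolic", "vfimix_invalid_config")
  times <- seq(0, duration_s, length.out = n_samples)
  if (systolic_mmhg == diastolic_mmhg) {
    p <- rep(systolic_mmhg, n_samples)
  } else {
    u <- ((times + t0_s) / period) %% 1
    s <- pressure_shape(u, bimodal)
    ref <- pressure_shape(seq(0, 1, length.out = 4096), bimodal)
    s <- (s - min(ref)) / (max(ref) - min(ref))
    p <- diastolic_mmhg + (systolic_mmhg - diastolic_mmhg) * s
  }
  structure(list(
    times = times, pressure_mmhg = p,
    systolic_mmhg = systolic_mmhg, diastolic_mmhg = diastolic_mmhg,
    cycle_period_s = period, bimodal = bimodal
  ), class = "pressure_waveform")
}

# circular-gaussian bump shape on cycle fraction u in [0, 1)
pressure_shape <- function(u, bimodal) {
  cdist <- function(u, c0) pmin(abs(u - c0), 1 - abs(u - c0))
  s <- exp(-(cdist(u, 0.35) / 0.12)^2 / 2)
  if (bimodal) s <- s + 0.45 * exp(-(cdist(u, 0.62) / 0.05)^2 / 2)
  s
}

#' Smoothed systolic gating window
#'
#' Dimensionless gate in [0, 1]: `sin^2(pi * (t - onset) / width)` inside the
#' ejection window each cycle, zero elsewhere. Its cycle mean is
#' `width / (2 * period)`, used to calibrate peak flux.
#' @keywords internal
cardiac_gate <- function(t, period, onset_s = 0.1, gate_width_s = 0.3) {
  u <- t %% period
  g <- numeric(length(t))
  inside <- u >= onset_s & u < onset_s + gate_width_s
  g[inside] <- sin(pi * (u[inside] - onset_s) / gate_width_s)^2
  g
}

#' Mixing-zone interface position from the stream momentum balance
#'
#' Places the anterograde/retrograde interface along the aortic path at the
#' cardiac share of the stream momentum flux,
#' `L * Qc^p / (Qc^p + Qe^p)` with `p = 2` by default (dynamic pressure
#' scales with the square of the volumetric flux for a fixed cross-section):
#' at the distal end of the modeled path when there is no ECMO flow, at the
#' root when there is no cardiac flux, and monotonically moving rootward as
#' the ECMO flow rate rises.
#'
#' @param cardiac_flux_lpm Cardiac flux series (L/min, nonnegative).
#' @param ecmo_flux_lpm Steady ECMO flux (L/min, nonnegative scalar).
#' @param total_path_mm Length of the modeled root-to-distal path
#'   (default 230 mm).
#' @param sharpness Exponent `p` of the balance (default 2, a momentum
#'   balance; 1 gives a plain flux share).
#' @return Interface path position series in mm, clamped to
#'   `[0, total_path_mm]`.
#' @export
compute_mixing_interface <- function(cardiac_flux_lpm, ecmo_flux_lpm,
                                     total_path_mm = 230, sharpness = 2) {
  if (any(cardiac_flux_lpm < 0) || ecmo_flux_lpm < 0)
    stop_vfimix("fluxes must be nonnegative", "vfimix_invalid_config")
  qc <- cardiac_flux_lpm^sharpness
  qe <- ecmo_flux_lpm^sharpness
  pos <- ifelse(cardiac_flux_lpm == 0, 0,
                ifelse(qc + qe == 0, 0, total_path_mm * qc / (qc + qe)))
  pmin(pmax(pos, 0), total_path_mm)
}

#' A Lamb-Oseen vortex specification
#'
#' @param center_mm `c(x, z)` image coordinates of the core center (mm).
#' @param circulation_m2s Circulation (m^2/s); sign sets the rotation sense
#'   (positive = counterclockwise in the x-z plane).
#' @param core_radius_mm Gaussian core radius (mm).
#' @param window_s `c(start, end)` activity window in cycle time (s); the
#'   strength ramps smoothly over `ramp_s` at both ends.
#' @param ramp_s On/off ramp duration (s).
#' @return A `vortex_spec` list.
#' @export
vortex <- function(center_mm, circulation_m2s, core_radius_mm = 5,
                   window_s = c(0.4, 0.65), ramp_s = 0.05) {
  stopifnot(length(center_mm) == 2, length(window_s) == 2,
            window_s[2] > window_s[1], core_radius_mm > 0)
  structure(list(center_mm = center_mm, circulation_m2s = circulation_m2s,
                 core_radius_mm = core_radius_mm, window_s = window_s,
                 ramp_s = ramp_s), class = "vortex_spec")
}

#' Default diastolic vortices per position and ECMO condition
#'
#' In the ascending aorta the colliding streams shed vortices in early
#' diastole: one under low ECMO flow, a counter-rotating pair under high
#' ECMO flow. Other positions carry none by default.
#'
#' @param geometry A [geometry_config()].
#' @param ecmo_flow_lpm ECMO flow rate (L/min); above 0.5 L/min a second
#'   vortex is added.
#' @return List of [vortex()] specs (possibly empty).
#' @export
default_vortex_spec <- function(geometry, ecmo_flow_lpm) {
  if (geometry$position_id != "ascending") return(list())
  cx <- geometry$fov_width_mm / 2; cz <- geometry$fov_depth_mm / 2
  a <- geometry$anterograde_axis_deg * pi / 180
  axis <- c(cos(a), sin(a)); perp <- c(-sin(a), cos(a))
  v1 <- vortex(c(cx, cz) - 6 * axis + 4 * perp, circulation_m2s = 0.010,
               core_radius_mm = 5, window_s = c(0.40, 0.65))
  if (ecmo_flow_lpm <= 0.5) return(list(v1))
  v2 <- vortex(c(cx, cz) + 6 * axis - 4 * perp, circulation_m2s = -0.010,
               core_radius_mm = 5, window_s = c(0.40, 0.65))
  list(v1, v2)
}

#' Generate a ground-truth flow scene
#'
#' Builds the time-resolved 2D velocity field on one imaging plane. The
#' anterograde cardiac stream is a parabolic (Poiseuille-like) jet across the
#' vessel diameter, gated each cycle by a smoothed systolic window and scaled
#' so the cycle-mean volumetric flux through the root cross-section equals
#' the pump's cardiac output. The retrograde ECMO stream is a steady
#' parabolic jet of 12 mm width (the ECMO return tube bore), flux-matched to
#' the set ECMO rate. The two streams are blended logistically along the
#' path coordinate around the interface position, which follows the
#' flux-share model of [compute_mixing_interface()] driven by an
#' exponentially smoothed cardiac flux (stream inertia), so the mixing zone
#' sweeps rootward through diastole and distally through systole. Vortices
#' are added as Lamb-Oseen fields inside the lumen during their time
#' windows, with a small seeded jitter of their centers.
#'
#' @param geometry A [geometry_config()].
#' @param pump A [pump_settings()].
#' @param vortex_spec List of [vortex()] specs; `NULL` (default) uses
#'   [default_vortex_spec()]; `list()` disables vortices.
#' @param seed Integer seed for the scene's single pseudo-random stream.
#' @param duration_s Scene duration (default 1.5 s).
#' @param dt_s Time step (default 800 microseconds, one display frame).
#' @param onset_s Systolic gate onset within the cycle (default 0.1 s).
#' @param gate_width_s Systolic gate width (default 0.3 s).
#' @param interface_halfwidth_mm Logistic blending half-width (default 4 mm).
#' @param interface_mm Optional fixed interface position (mm) overriding the
#'   flux-share model (used for controlled recovery experiments).
#' @param total_path_mm Modeled root-to-distal path length (default 230 mm).
#' @param flux_smooth_tau_s Time constant of the inertial smoothing of the
#'   cardiac flux driving the interface (default 0.15 s).
#' @param ecmo_jet_width_mm Width of the retrograde jet (default 12 mm,
#'   clamped to the vessel diameter).
#' @param center_jitter_mm SD of the seeded vortex-center jitter
#'   (default 0.5 mm).
#' @param t0_s Phase offset: the scene starts `t0_s` into the pump cycle
#'   (default 0).
#' @return A `flow_scene` with `times`, velocity arrays `vx`, `vz`
#'   (nz x nx x nt, m/s; zero outside the lumen), the geometry, pump,
#'   and the ground-truth `interface_mm` series.
#' @export
generate_flow_scene <- function(geometry, pump, vortex_spec = NULL, seed = 1,
                                duration_s = 1.5, dt_s = 8e-4,
                                onset_s = 0.1, gate_width_s = 0.3,
                                interface_halfwidth_mm = 4,
                                interface_mm = NULL, total_path_mm = 230,
                                flux_smooth_tau_s = 0.15,
                                ecmo_jet_width_mm = 12,
                                center_jitter_mm = 0.5, t0_s = 0) {
  stopifnot(inherits(geometry, "geometry_config"),
            inherits(pump, "pump_settings"))
  period <- pump$cycle_period_s
  if (gate_width_s >= period || onset_s + gate_width_s > period)
    stop_vfimix("systolic gate does not fit in the cycle",
                "vfimix_invalid_config")
  vortex_spec <- vortex_spec %||%
    default_vortex_spec(geometry, pump$ecmo_flow_lpm)
  for (vs in vortex_spec) {
    ij <- nearest_pixel(geometry, vs$center_mm)
    if (!geometry$lumen_mask[ij[1], ij[2]])
      stop_vfimix("vortex center outside lumen", "vfimix_invalid_config")
  }

  times <- seq(0, duration_s, by = dt_s)
  nt <- length(times)
  nz <- geometry$nz; nx <- geometry$nx

  # peak cardiac flux so that the cycle-mean equals cardiac output;
  # the sin^2 gate has cycle mean gate_width / (2 * period)
  gate <- cardiac_gate(times + t0_s, period, onset_s, gate_width_s)
  gate_mean <- gate_width_s / (2 * period)
  q_peak_lpm <- if (gate_mean > 0) pump$cardiac_output_lpm / gate_mean else 0
  qc_lpm <- q_peak_lpm * gate

  # inertial smoothing of the flux that drives the interface position:
  # first-order low-pass run over three warm-up cycles for periodic state
  qc_smooth <- lowpass_periodic(qc_lpm, times, period, flux_smooth_tau_s)

  if (is.null(interface_mm)) {
    m_mm <- compute_mixing_interface(qc_smooth, pump$ecmo_flow_lpm,
                                     total_path_mm)
  } else {
    m_mm <- rep(interface_mm, nt)
  }

  d_m <- geometry$vessel_diameter_mm / 1000
  area_vessel <- pi * d_m^2 / 4                      # m^2
  vmax_c <- 2 * (qc_lpm / 60000) / area_vessel       # centerline m/s series
  jet_w_mm <- min(ecmo_jet_width_mm, geometry$vessel_diameter_mm)
  area_jet <- pi * (jet_w_mm / 1000)^2 / 4
  vmax_e <- 2 * (pump$ecmo_flow_lpm / 60000) / area_jet

  r <- geometry$perp_mm
  prof_c <- pmax(1 - (2 * r / geometry$vessel_diameter_mm)^2, 0)
  prof_e <- pmax(1 - (2 * r / jet_w_mm)^2, 0)
  a <- geometry$anterograde_axis_deg * pi / 180
  dir <- c(cos(a), sin(a))
  lum <- geometry$lumen_mask

  vtx <- with_seed(seed, lapply(vortex_spec, function(vs) {
    vs$center_mm <- vs$center_mm + rnorm(2, 0, center_jitter_mm)
    vs
  }))
  vtx_fields <- lapply(vtx, function(vs) vortex_field(geometry, vs))

  vx <- array(0, c(nz, nx, nt)); vz <- array(0, c(nz, nx, nt))
  u_cycle <- (times + t0_s) %% period
  for (k in seq_len(nt)) {
    w <- stats::plogis((m_mm[k] - geometry$path_mm) / interface_halfwidth_mm)
    vel <- w * vmax_c[k] * prof_c - (1 - w) * vmax_e * prof_e
    fx <- dir[1] * vel; fz <- dir[2] * vel
    for (i in seq_along(vtx)) {
      amp <- vortex_ramp(u_cycle[k], vtx[[i]])
      if (amp > 0) {
        fx <- fx + amp * vtx_fields[[i]]$vx
        fz <- fz + amp * vtx_fields[[i]]$vz
      }
    }
    fx[!lum] <- 0; fz[!lum] <- 0
    vx[, , k] <- fx; vz[, , k] <- fz
  }

  structure(list(
    geometry = geometry, pump = pump, times = times,
    vx = vx, vz = vz, lumen_mask = lum,
    cycle_period_s = period, onset_s = onset_s, gate_width_s = gate_width_s,
    interface_mm = m_mm, interface_halfwidth_mm = interface_halfwidth_mm,
    total_path_mm = total_path_mm, vortex_spec = vtx, seed = seed,
    t0_s = t0_s
  ), class = "flow_scene")
}

nearest_pixel <- function(geometry, xy_mm) {
  c(which.min(abs(geometry$z_mm - xy_mm[2])),
    which.min(abs(geometry$x_mm - xy_mm[1])))
}

# Lamb-Oseen tangential field evaluated on the grid (unit amplitude)
vortex_field <- function(geometry, vs) {
  dx <- outer(rep(1, geometry$nz), geometry$x_mm - vs$center_mm[1])
  dz <- outer(geometry$z_mm - vs$center_mm[2], rep(1, geometry$nx))
  r_mm <- sqrt(dx^2 + dz^2)
  r_m <- r_mm / 1000
  rc_m <- vs$core_radius_mm / 1000
  vt <- ifelse(r_m > 0,
               vs$circulation_m2s / (2 * pi * r_m) *
                 (1 - exp(-(r_m / rc_m)^2)), 0)
  ux <- ifelse(r_mm > 0, -dz / r_mm, 0)
  uz <- ifelse(r_mm > 0, dx / r_mm, 0)
  list(vx = vt * ux, vz = vt * uz)
}

vortex_ramp <- function(u, vs) {
  w <- vs$window_s; rp <- vs$ramp_s
  if (u < w[1] || u > w[2]) return(0)
  amp_in <- min(1, (u - w[1]) / rp)
  amp_out <- min(1, (w[2] - u) / rp)
  min(amp_in, amp_out)
}

# first-order low-pass with periodic steady state (3 warm-up cycles)
lowpass_periodic <- function(x, times, period, tau) {
  if (tau <= 0) return(x)
  dt <- diff(times[1:2])
  alpha <- dt / (tau + dt)
  n_cycle <- max(2L, round(period / dt))
  idx <- rep(seq_len(min(n_cycle, length(x))), length.out = 3 * n_cycle)
  y <- mean(x)
  for (i in idx) y <- y + alpha * (x[i] - y)   # warm-up on repeated cycles
  out <- numeric(length(x))
  for (k in seq_along(x)) {
    y <- y + alpha * (x[k] - y)
    out[k] <- y
  }
  out
}

#' Volumetric flux through a cross-section of the scene
#'
#' Numerically integrates the axial velocity over the circular cross-section
#' at path position `s_mm`, assuming axisymmetry about the centerline:
#' `Q(t) = integral of v_par(r) * 2 * pi * r dr`, with `v_par` the
#' velocity component along the anterograde axis sampled by bilinear
#' interpolation along the perpendicular chord (both halves averaged).
#'
#' @param scene A `flow_scene`.
#' @param s_mm Path position of the section (mm); default the image-center
#'   path length.
#' @param n_r Number of radial samples.
#' @return Flux series in L/min (positive = anterograde), one per scene time.
#' @export
compute_section_flux <- function(scene, s_mm = NULL, n_r = 64) {
  g <- scene$geometry
  s_mm <- s_mm %||% g$path_length_mm
  a <- g$anterograde_axis_deg * pi / 180
  dir <- c(cos(a), sin(a)); perp <- c(-sin(a), cos(a))
  cx <- g$fov_width_mm / 2; cz <- g$fov_depth_mm / 2
  R <- g$vessel_diameter_mm / 2
  r_mm <- seq(0, R, length.out = n_r)
  base <- c(cx, cz) + (s_mm - g$path_length_mm) * dir
  p_pos <- cbind(base[1] + r_mm * perp[1], base[2] + r_mm * perp[2])
  p_neg <- cbind(base[1] - r_mm * perp[1], base[2] - r_mm * perp[2])
  nt <- length(scene$times)
  q <- numeric(nt)
  for (k in seq_len(nt)) {
    vpar_p <- bilinear_sample(scene$vx[, , k], g, p_pos) * dir[1] +
      bilinear_sample(scene$vz[, , k], g, p_pos) * dir[2]
    vpar_n <- bilinear_sample(scene$vx[, , k], g, p_neg) * dir[1] +
      bilinear_sample(scene$vz[, , k], g, p_neg) * dir[2]
    vbar <- (vpar_p + vpar_n) / 2
    integrand <- vbar * 2 * pi * (r_mm / 1000)        # m/s * m
    q[k] <- sum((integrand[-1] + integrand[-n_r]) / 2 * diff(r_mm / 1000))
  }
  q * 60000   # m^3/s -> L/min
}

# bilinear sampling of a (nz, nx) map at mm coordinates; zero outside grid
bilinear_sample <- function(map, geometry, xy_mm) {
  h <- geometry$grid_spacing_mm
  fx <- xy_mm[, 1] / h; fz <- xy_mm[, 2] / h
  i0 <- floor(fz); j0 <- floor(fx)
  wz <- fz - i0; wx <- fx - j0
  nz <- geometry$nz; nx <- geometry$nx
  val <- function(i, j) {
    ok <- i >= 0 & i <= nz - 1 & j >= 0 & j <= nx - 1
    out <- numeric(length(i))
    out[ok] <- map[cbind(i[ok] + 1, j[ok] + 1)]
    out
  }
  (1 - wz) * (1 - wx) * val(i0, j0) + (1 - wz) * wx * val(i0, j0 + 1) +
    wz * (1 - wx) * val(i0 + 1, j0) + wz * wx * val(i0 + 1, j0 + 1)
}
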