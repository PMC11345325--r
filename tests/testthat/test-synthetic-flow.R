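test_that("pump settings derive cardiac output and validate inputs", {
  p <- pump_settings(stroke_volume_ml = 30, heart_rate_bpm = 90)
  expect_equal(p$cardiac_output_lpm, 2.7)
  expect_equal(p$cycle_period_s, 60 / 90)
  expect_error(pump_settings(heart_rate_bpm = 0), class = "vfimix_invalid_config")
  expect_error(pump_settings(heart_rate_bpm = -10), class = "vfimix_invalid_config")
  expect_error(pump_settings(systole_fraction = 1.2), class = "vfimix_invalid_config")
})

test_that("pressure waveform hits the configured pressures and is periodic", {
  p <- pump_settings(heart_rate_bpm = 90)
  w <- generate_pressure_waveform(p, 81, 57, bimodal = TRUE,
                                  n_samples = 1500, duration_s = 1.5)
  expect_equal(w$cycle_period_s, 60 / 90)
  expect_lt(abs(max(w$pressure_mmhg) - 81), 2)
  expect_lt(abs(min(w$pressure_mmhg) - 57), 2)
  expect_gte(w$times[length(w$times)] - w$times[1], 1.5 - 1e-9)
  # periodicity: samples one cycle apart agree
  keep <- w$times + w$cycle_period_s <= max(w$times) + 1e-12
  shifted <- stats::approx(w$times, w$pressure_mmhg,
                           w$times[keep] + w$cycle_period_s)$y
  expect_equal(shifted, w$pressure_mmhg[keep], tolerance = 1e-4)
})

test_that("bimodal waveform has two local maxima per cycle, unimodal one", {
  p90 <- pump_settings(heart_rate_bpm = 90)
  one_cycle <- function(pump, bimodal) {
    w <- generate_pressure_waveform(pump, 81, 57, bimodal = bimodal,
                                    n_samples = 128,
                                    duration_s = pump$cycle_period_s)
    # drop the duplicated endpoint before circular peak counting
    w$pressure_mmhg[-length(w$pressure_mmhg)]
  }
  expect_equal(count_cycle_peaks(one_cycle(p90, TRUE)), 2)
  p60 <- pump_settings(heart_rate_bpm = 60)
  expect_equal(count_cycle_peaks(one_cycle(p60, FALSE)), 1)
})

test_that("degenerate pressure amplitude gives a constant trace", {
  p <- pump_settings()
  w <- generate_pressure_waveform(p, 70, 70)
  expect_true(all(w$pressure_mmhg == 70))
})

test_that("pressure waveform rejects bad configs", {
  p <- pump_settings()
  expect_error(generate_pressure_waveform(p, n_samples = 10),
               class = "vfimix_invalid_config")
  expect_error(generate_pressure_waveform(p, systolic_mmhg = 50,
                                          diastolic_mmhg = 60),
               class = "vfimix_invalid_config")
})

test_that("mixing interface follows the flux balance and its bounds", {
  expect_equal(compute_mixing_interface(2.7, 0), 230)
  expect_equal(compute_mixing_interface(0, 1.0), 0)
  expect_equal(compute_mixing_interface(0, 0), 0)
  # monotone nonincreasing in ecmo flux at every time point
  set.seed(42)
  qc <- runif(50, 0, 12)
  ecmo_grid <- seq(0, 3, by = 0.25)
  pos <- vapply(ecmo_grid, compute_mixing_interface,
                numeric(length(qc)), cardiac_flux_lpm = qc)
  expect_true(all(diff(t(pos)) <= 1e-12))
  # high vs low at equal cardiac flux
  expect_true(all(compute_mixing_interface(qc, 1.0) <=
                    compute_mixing_interface(qc, 0.35)))
  expect_true(all(pos >= 0 & pos <= 230))
  expect_error(compute_mixing_interface(-1, 0.5),
               class = "vfimix_invalid_config")
})

test_that("identical config and seed give a bit-identical scene", {
  s1 <- quick_scene(duration = 0.2, vortices = NULL, position = "ascending",
                    ecmo = 1.0, seed = 7)
  s2 <- quick_scene(duration = 0.2, vortices = NULL, position = "ascending",
                    ecmo = 1.0, seed = 7)
  expect_identical(s1$vx, s2$vx)
  expect_identical(s1$vz, s2$vz)
  expect_identical(s1$interface_mm, s2$interface_mm)
})

test_that("velocity is zero outside the lumen and times increase", {
  s <- quick_scene(duration = 0.2)
  out <- !s$lumen_mask
  for (k in seq_along(s$times)) {
    expect_true(all(s$vx[, , k][out] == 0))
    expect_true(all(s$vz[, , k][out] == 0))
  }
  expect_true(all(diff(s$times) > 0))
})

test_that("without ECMO flow all systolic in-lumen vectors are anterograde", {
  s <- quick_scene(ecmo = 0, duration = 0.7)
  g <- s$geometry
  a <- g$anterograde_axis_deg * pi / 180
  u <- s$times %% s$cycle_period_s
  sys_frames <- which(u >= 0.1 & u < 0.4)
  for (k in sys_frames) {
    proj <- s$vx[, , k] * cos(a) + s$vz[, , k] * sin(a)
    expect_true(all(proj[g$lumen_mask] >= -1e-12))
  }
})

test_that("with zero cardiac output all flow is retrograde, interface at root", {
  p <- pump_settings(stroke_volume_ml = 0, ecmo_flow_lpm = 1.0)
  g <- tiny_geometry("mid_descending")
  s <- generate_flow_scene(g, p, vortex_spec = list(), seed = 1,
                           duration_s = 0.2)
  expect_true(all(s$interface_mm == 0))
  a <- g$anterograde_axis_deg * pi / 180
  proj <- s$vx * cos(a) + s$vz * sin(a)
  nz_speed <- sqrt(s$vx^2 + s$vz^2) > 0
  expect_true(all(proj[nz_speed] < 0))
})

test_that("cycle-mean root flux matches cardiac output within 5%", {
  p <- pump_settings(ecmo_flow_lpm = 0)
  g <- geometry_config("ascending", grid_spacing_mm = 1)
  s <- generate_flow_scene(g, p, vortex_spec = list(), seed = 1,
                           duration_s = p$cycle_period_s)
  q <- compute_section_flux(s)
  in_cycle <- s$times < p$cycle_period_s
  expect_lt(abs(mean(q[in_cycle]) - 2.7) / 2.7, 0.05)
})

test_that("the field is near-divergence-free away from the blending band", {
  s <- quick_scene(position = "distal_arch", ecmo = 1.0, duration = 0.7,
                   spacing = 2)
  g <- s$geometry
  h_m <- g$grid_spacing_mm / 1000
  interior <- g$lumen_mask
  interior[] <- FALSE
  interior[2:(g$nz - 1), 2:(g$nx - 1)] <-
    g$lumen_mask[2:(g$nz - 1), 2:(g$nx - 1)] &
    g$lumen_mask[1:(g$nz - 2), 2:(g$nx - 1)] &
    g$lumen_mask[3:g$nz, 2:(g$nx - 1)] &
    g$lumen_mask[2:(g$nz - 1), 1:(g$nx - 2)] &
    g$lumen_mask[2:(g$nz - 1), 3:g$nx]
  for (k in seq(1, length(s$times), by = 100)) {
    vx <- s$vx[, , k]; vz <- s$vz[, , k]
    div <- matrix(0, g$nz, g$nx)
    div[2:(g$nz - 1), 2:(g$nx - 1)] <-
      (vx[2:(g$nz - 1), 3:g$nx] - vx[2:(g$nz - 1), 1:(g$nx - 2)]) / (2 * h_m) +
      (vz[3:g$nz, 2:(g$nx - 1)] - vz[1:(g$nz - 2), 2:(g$nx - 1)]) / (2 * h_m)
    far <- interior & abs(g$path_mm - s$interface_mm[k]) >
      8 * s$interface_halfwidth_mm
    if (any(far)) expect_lt(max(abs(div[far])), 0.1)
  }
})

test_that("default high-ECMO ascending scene shows two vortex cores at 0.5 s", {
  p <- pump_settings(ecmo_flow_lpm = 1.0)
  g <- geometry_config("ascending", grid_spacing_mm = 1)
  s <- generate_flow_scene(g, p, seed = 1)
  expect_length(s$vortex_spec, 2)
  k <- which.min(abs(s$times - 0.5))
  h_m <- g$grid_spacing_mm / 1000
  vx <- s$vx[, , k]; vz <- s$vz[, , k]
  curl <- matrix(0, g$nz, g$nx)
  curl[2:(g$nz - 1), 2:(g$nx - 1)] <-
    (vz[2:(g$nz - 1), 3:g$nx] - vz[2:(g$nz - 1), 1:(g$nx - 2)]) / (2 * h_m) -
    (vx[3:g$nz, 2:(g$nx - 1)] - vx[1:(g$nz - 2), 2:(g$nx - 1)]) / (2 * h_m)
  # per configured (jittered) core: |curl| peak of the right sign nearby
  found <- vapply(s$vortex_spec, function(vs) {
    dx2 <- outer(rep(1, g$nz), (g$x_mm - vs$center_mm[1])^2)
    dz2 <- outer((g$z_mm - vs$center_mm[2])^2, rep(1, g$nx))
    near <- sqrt(dx2 + dz2) <= vs$core_radius_mm
    peak <- max(abs(curl[near]))
    sign_ok <- sign(curl[near][which.max(abs(curl[near]))]) ==
      sign(vs$circulation_m2s)
    peak > 0.5 * max(abs(curl)) && sign_ok
  }, logical(1))
  expect_true(all(found))
  # the two cores are distinct locations
  c1 <- s$vortex_spec[[1]]$center_mm
  c2 <- s$vortex_spec[[2]]$center_mm
  expect_gt(sqrt(sum((c1 - c2)^2)), s$vortex_spec[[1]]$core_radius_mm)
})

test_that("a vortex centered outside the lumen is rejected", {
  g <- tiny_geometry("distal_arch")
  # the arch vessel is a horizontal band: the image corner is outside
  bad <- vortex(c(1, 1), 0.01)
  expect_error(
    generate_flow_scene(g, pump_settings(), vortex_spec = list(bad),
                        seed = 1, duration_s = 0.1),
    class = "vfimix_invalid_config")
})
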