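# Vector-projectile style rendering: arrow "projectiles" advected by the
# estimated field, drawn speed-coded on the lumen silhouette, and composed
# into synchronized multi-panel frame sequences with the pressure trace.

#' Spawn a projectile set inside the lumen
#'
#' @param geometry A [geometry_config()].
#' @param density_per_cm2 Projectiles per square centimeter of lumen
#'   (default 30).
#' @param lifetime_frames Mean projectile lifetime; individual lifetimes are
#'   drawn uniformly in `[0.5, 1.5] * lifetime_frames`.
#' @param seed Integer seed.
#' @return A `projectile_set` data frame with `x_mm`, `z_mm`, `age`,
#'   `lifetime`.
#' @export
spawn_projectiles <- function(geometry, density_per_cm2 = 30,
                              lifetime_frames = 40, seed = 1) {
  lumen_area_cm2 <- sum(geometry$lumen_mask) * (geometry$grid_spacing_mm / 10)^2
  n <- max(1L, round(density_per_cm2 * lumen_area_cm2))
  ps <- with_seed(seed, random_lumen_points(geometry, n, lifetime_frames))
  structure(ps, class = c("projectile_set", "data.frame"),
            geometry = geometry, seed = seed, step = 0L)
}

random_lumen_points <- function(geometry, n, lifetime_frames) {
  out <- data.frame(x_mm = numeric(0), z_mm = numeric(0),
                    age = integer(0), lifetime = integer(0))
  while (nrow(out) < n) {
    m <- (n - nrow(out)) * 3 + 8
    x <- runif(m, 0, geometry$fov_width_mm)
    z <- runif(m, 0, geometry$fov_depth_mm)
    keep <- point_in_lumen(geometry, x, z)
    if (!any(keep)) next
    add <- data.frame(
      x_mm = x[keep], z_mm = z[keep], age = 0L,
      lifetime = as.integer(round(runif(sum(keep), 0.5 * lifetime_frames,
                                        1.5 * lifetime_frames))))
    out <- rbind(out, add)
  }
  out[seq_len(n), , drop = FALSE]
}

point_in_lumen <- function(geometry, x_mm, z_mm) {
  i <- round(z_mm / geometry$grid_spacing_mm) + 1
  j <- round(x_mm / geometry$grid_spacing_mm) + 1
  ok <- i >= 1 & i <= geometry$nz & j >= 1 & j <= geometry$nx
  ok[ok] <- geometry$lumen_mask[cbind(i[ok], j[ok])]
  ok
}

#' Advect projectiles through one frame
#'
#' Explicit Euler step `x <- x + v(x) * dt` with bilinear velocity
#' interpolation. Projectiles that leave the lumen or exceed their lifetime
#' respawn at seeded random lumen positions; the projectile count is
#' conserved.
#'
#' @param projectiles A `projectile_set`.
#' @param vx,vz Velocity maps for the frame (nz x nx, m/s).
#' @param dt Frame interval (s).
#' @return The advected `projectile_set`.
#' @export
advect <- function(projectiles, vx, vz, dt) {
  g <- attr(projectiles, "geometry")
  seed <- attr(projectiles, "seed")
  step <- attr(projectiles, "step") + 1L
  p <- as.data.frame(projectiles)
  xy <- cbind(p$x_mm, p$z_mm)
  ux <- bilinear_sample(vx, g, xy)
  uz <- bilinear_sample(vz, g, xy)
  p$x_mm <- p$x_mm + ux * dt * 1000    # m/s * s -> mm
  p$z_mm <- p$z_mm + uz * dt * 1000
  p$age <- p$age + 1L
  dead <- !point_in_lumen(g, p$x_mm, p$z_mm) | p$age > p$lifetime
  if (any(dead)) {
    fresh <- with_seed(seed + step,
                       random_lumen_points(g, sum(dead),
                                           mean(p$lifetime)))
    p[dead, ] <- fresh
  }
  structure(p, class = c("projectile_set", "data.frame"),
            geometry = g, seed = seed, step = step)
}

#' Render style presets
#'
#' `"dense-small"` is the standard cineloop look; `"sparse-large"` draws
#' fewer, larger arrows to bring out vortex features.
#'
#' @param name Style name.
#' @return A style list: `density_per_cm2`, `arrow_scale`, `upscale`,
#'   `speed_range` (m/s) and the marked fast/slow threshold.
#' @export
render_style <- function(name = c("dense-small", "sparse-large")) {
  name <- match.arg(name)
  if (name == "dense-small") {
    list(name = name, density_per_cm2 = 30, arrow_scale = 1, upscale = 4,
         speed_range = c(0, 0.6), speed_threshold = 0.25)
  } else {
    list(name = name, density_per_cm2 = 8, arrow_scale = 2.5, upscale = 4,
         speed_range = c(0, 0.6), speed_threshold = 0.25)
  }
}

speed_colormap <- function(speed, style) {
  lim <- style$speed_range
  u <- pmin(pmax((speed - lim[1]) / (lim[2] - lim[1]), 0), 1)
  ramp <- grDevices::colorRamp(c("#7f0000", "#f46d43", "#fee090",
                                 "#74add1", "#313695"))
  # threshold marked: slow speeds stay in the warm half of the ramp,
  # fast speeds in the cool half
  thr <- (style$speed_threshold - lim[1]) / (lim[2] - lim[1])
  u2 <- ifelse(u <= thr, 0.5 * u / thr, 0.5 + 0.5 * (u - thr) / (1 - thr))
  ramp(u2) / 255
}

#' Render one VPI-style frame
#'
#' Draws the lumen silhouette and one arrow per projectile, oriented by the
#' local vector and colored by speed, into an RGB raster. Pure function of
#' its inputs; identical inputs give identical pixel buffers.
#'
#' @param vx,vz Velocity maps for the frame (nz x nx, m/s).
#' @param projectiles A `projectile_set`.
#' @param style A [render_style()].
#' @return RGB array `(nz*upscale) x (nx*upscale) x 3` in [0, 1], with an
#'   `"arrows"` attribute (data frame of drawn positions, angles, speeds)
#'   for metadata read-back.
#' @export
render_frame <- function(vx, vz, projectiles, style = render_style()) {
  g <- attr(projectiles, "geometry")
  up <- style$upscale
  H <- g$nz * up; W <- g$nx * up
  px_mm <- g$grid_spacing_mm / up
  img <- array(0.05, c(H, W, 3))
  sil <- matrix(0.18, g$nz, g$nx)[rep(seq_len(g$nz), each = up),
                                  rep(seq_len(g$nx), each = up)]
  lum_up <- g$lumen_mask[rep(seq_len(g$nz), each = up),
                         rep(seq_len(g$nx), each = up)]
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[lum_up] <- sil[lum_up]
    img[, , ch] <- plane
  }
  p <- as.data.frame(projectiles)
  if (nrow(p) == 0)
    return(structure(img, arrows = data.frame(x_mm = numeric(0),
                                              z_mm = numeric(0),
                                              angle_deg = numeric(0),
                                              speed = numeric(0))))
  xy <- cbind(p$x_mm, p$z_mm)
  ux <- bilinear_sample(vx, g, xy)
  uz <- bilinear_sample(vz, g, xy)
  speed <- sqrt(ux^2 + uz^2)
  ang <- atan2(uz, ux)
  cols <- speed_colormap(speed, style)
  len_mm <- style$arrow_scale * (1 + 6 * pmin(speed / style$speed_range[2], 1))
  for (i in seq_len(nrow(p))) {
    if (speed[i] == 0) next
    img <- draw_arrow(img, p$x_mm[i], p$z_mm[i], ang[i], len_mm[i],
                      cols[i, ], px_mm)
  }
  structure(img, arrows = data.frame(x_mm = p$x_mm, z_mm = p$z_mm,
                                     angle_deg = ang * 180 / pi,
                                     speed = speed))
}

# draw a line with a simple two-barb head into the raster (no antialiasing)
draw_arrow <- function(img, x0, z0, ang, len_mm, rgb, px_mm) {
  tip <- c(x0 + cos(ang) * len_mm, z0 + sin(ang) * len_mm)
  img <- draw_segment(img, c(x0, z0), tip, rgb, px_mm)
  for (s in c(1, -1)) {
    barb <- ang + pi + s * pi / 6
    bend <- tip + 0.35 * len_mm * c(cos(barb), sin(barb))
    img <- draw_segment(img, tip, bend, rgb, px_mm)
  }
  img
}

draw_segment <- function(img, a, b, rgb, px_mm) {
  H <- dim(img)[1]; W <- dim(img)[2]
  n <- max(2L, ceiling(sqrt(sum((b - a)^2)) / px_mm) * 2L)
  t <- seq(0, 1, length.out = n)
  xs <- a[1] + t * (b[1] - a[1]); zs <- a[2] + t * (b[2] - a[2])
  j <- round(xs / px_mm) + 1; i <- round(zs / px_mm) + 1
  ok <- i >= 1 & i <= H & j >= 1 & j <= W
  idx <- unique(cbind(i[ok], j[ok]))
  if (nrow(idx)) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- rgb[ch]
      img[, , ch] <- plane
    }
  }
  img
}

#' Render a whole vector field as a projectile cineloop
#'
#' Advects a projectile set through the field and renders every frame.
#'
#' @param field A `vector_field` with geometry.
#' @param style A [render_style()].
#' @param seed Seed for projectile spawning/respawn.
#' @return List of RGB frames (with arrow metadata attributes).
#' @export
render_cineloop <- function(field, style = render_style(), seed = 1) {
  g <- field$geometry
  ps <- spawn_projectiles(g, style$density_per_cm2, seed = seed)
  dt <- diff(field$frame_times[1:2])
  nf <- length(field$frame_times)
  frames <- vector("list", nf)
  for (k in seq_len(nf)) {
    frames[[k]] <- render_frame(field$vx[, , k], field$vz[, , k], ps, style)
    ps <- advect(ps, field$vx[, , k], field$vz[, , k], dt)
  }
  frames
}

#' Compose synchronized multi-position cineloops into a frame sequence
#'
#' Aligns the loops by the given offsets (circular frame shift), stacks the
#' panels side by side above a shared pressure-trace strip with a moving
#' time cursor, and writes numbered PNG frames plus a JSON manifest
#' (fps, slowdown, per-frame cursor time and per-panel source frames). The
#' manifest's `fps_out = fps / slowdown`, so a slowdown of 10 plays 10x
#' longer.
#'
#' @param loops List of rendered frame stacks (lists of RGB arrays) with
#'   equal frame counts and sizes after alignment.
#' @param offsets Offsets in seconds from [synchronize_cineloops()].
#' @param waveform A `pressure_waveform` shared by the composition.
#' @param fps Acquisition frame rate of the loops (frames per second).
#' @param slowdown Replay slowdown factor (default 1; 10 gives the
#'   1/10-speed replay).
#' @param out_dir Output directory for `frame_%04d.png` and
#'   `manifest.json`; created if missing.
#' @return Invisibly, the manifest list.
#' @export
compose_video <- function(loops, offsets, waveform, fps, slowdown = 1,
                          out_dir) {
  if (length(offsets) != length(loops))
    stop_vfimix("one offset per loop required", "vfimix_composition_error")
  nfs <- vapply(loops, length, integer(1))
  if (length(unique(nfs)) != 1)
    stop_vfimix("mismatched frame counts after alignment",
                "vfimix_composition_error")
  nf <- nfs[1]
  shift <- as.integer(round(offsets * fps)) %% nf
  aligned <- lapply(seq_along(loops), function(i) {
    idx <- ((seq_len(nf) - 1 + shift[i]) %% nf) + 1
    loops[[i]][idx]
  })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dt <- 1 / fps
  cursor_times <- ((seq_len(nf) - 1) * dt) %% waveform$cycle_period_s
  panel_src <- vapply(seq_along(loops), function(i)
    ((seq_len(nf) - 1L + shift[i]) %% nf) + 1L, integer(nf))
  strip_h <- 40L
  for (k in seq_len(nf)) {
    row <- do.call(abind3, lapply(aligned, `[[`, k))
    frame <- add_pressure_strip(row, waveform, cursor_times[k], strip_h)
    png::writePNG(frame, file.path(out_dir, sprintf("frame_%04d.png", k)))
  }
  manifest <- list(
    n_frames = nf, fps_in = fps, slowdown = slowdown,
    fps_out = fps / slowdown,
    duration_s = nf / (fps / slowdown),
    offsets_s = as.numeric(offsets),
    cursor_time_s = cursor_times,
    panel_source_frame = panel_src
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# horizontal concatenation of RGB arrays (equal heights)
abind3 <- function(...) {
  parts <- list(...)
  H <- dim(parts[[1]])[1]
  W <- sum(vapply(parts, function(p) dim(p)[2], integer(1)))
  out <- array(0, c(H, W, 3))
  at <- 0L
  for (p in parts) {
    w <- dim(p)[2]
    out[, at + seq_len(w), ] <- p
    at <- at + w
  }
  out
}

add_pressure_strip <- function(row, waveform, cursor_t, strip_h) {
  H <- dim(row)[1]; W <- dim(row)[2]
  strip <- array(0.1, c(strip_h, W, 3))
  u <- (waveform$times %% waveform$cycle_period_s) / waveform$cycle_period_s
  ord <- order(u)
  p <- waveform$pressure_mmhg[ord]; u <- u[ord]
  rng <- range(waveform$pressure_mmhg)
  span <- if (diff(rng) > 0) diff(rng) else 1
  j <- pmax(1L, pmin(W, round(u * (W - 1)) + 1L))
  i <- pmax(1L, pmin(strip_h,
                     strip_h - round((p - rng[1]) / span * (strip_h - 3)) - 1L))
  for (ch in 1:3) {
    plane <- strip[, , ch]
    plane[cbind(i, j)] <- 0.8
    strip[, , ch] <- plane
  }
  jc <- pmax(1L, pmin(W, round(cursor_t / waveform$cycle_period_s *
                                 (W - 1)) + 1L))
  strip[, jc, 1] <- 1; strip[, jc, 2] <- 0.3; strip[, jc, 3] <- 0.3
  out <- array(0, c(H + strip_h, W, 3))
  out[seq_len(H), , ] <- row
  out[H + seq_len(strip_h), , ] <- strip
  out
}
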