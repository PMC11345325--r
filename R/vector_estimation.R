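# Least-squares recovery of 2D velocity vectors from multi-angle Doppler
# maps: one linear Doppler equation per transmit angle, solved per pixel.

#' Build the multi-angle Doppler system matrix
#'
#' Row i is `(f0 / c) * c(sin(a_i), 1 + cos(a_i))` for steering angle `a_i`,
#' so that `A %*% c(vx, vz)` gives the per-angle Doppler frequencies.
#'
#' @param tx_angles_deg Steering angles (degrees), at least two distinct.
#' @param f0 Center frequency (Hz).
#' @param c Sound speed (m/s).
#' @return An `n_angles x 2` matrix of full column rank.
#' @export
build_system <- function(tx_angles_deg, f0 = 5e6, c = 1540) {
  if (length(tx_angles_deg) < 2 || length(unique(tx_angles_deg)) < 2)
    stop_vfimix("need at least two distinct angles (rank-deficient system)",
                "vfimix_rank_deficient")
  a <- tx_angles_deg * pi / 180
  A <- (f0 / c) * cbind(sin(a), 1 + cos(a))
  if (qr(A)$rank < 2)
    stop_vfimix("Doppler system matrix is rank deficient",
                "vfimix_rank_deficient")
  A
}

#' Solve per-pixel flow vectors from a Doppler frame set
#'
#' For every pixel and frame solves `argmin_v || A v - f ||_2` over the
#' per-angle Doppler frequencies `f` (normal equations; with two angles this
#' is an exact 2x2 solve). Pixels flagged aliased at any angle, outside the
#' lumen, or (with more than two angles) with a residual above the threshold
#' are marked invalid.
#'
#' @param frames A `doppler_frame_set` from [acquire()], or a compatible
#'   list with `doppler_hz`, `aliased`, `frame_times`, `config`, and
#'   optionally `geometry` / `lumen_mask`.
#' @param residual_threshold_hz Validity cut on the per-pixel residual norm;
#'   default `3 * noise_std_hz` (only applied with > 2 angles, where the
#'   residual is informative).
#' @return A `vector_field`: `frame_times`, `vx`, `vz` (m/s), `valid`
#'   (logical), `residual` (Hz), all `nz x nx x n_frames`, plus geometry.
#' @export
solve_vectors <- function(frames, residual_threshold_hz = NULL) {
  cfg <- frames$config
  maps <- frames$doppler_hz
  n_ang <- length(maps)
  if (n_ang < 2)
    stop_vfimix("need Doppler maps for at least two angles",
                "vfimix_invalid_input")
  dims <- dim(maps[[1]])
  for (m in maps) {
    if (!identical(dim(m), dims))
      stop_vfimix("Doppler map shapes differ across angles",
                  "vfimix_invalid_input")
  }
  A <- build_system(cfg$tx_angles_deg, cfg$center_frequency_hz,
                    cfg$sound_speed_mps)
  pinv <- solve(crossprod(A), t(A))          # 2 x n_angles
  nz <- dims[1]; nx <- dims[2]; nf <- dims[3]
  npx <- nz * nx

  vx <- array(NA_real_, dims); vz <- array(NA_real_, dims)
  residual <- array(0, dims)
  aliased_any <- array(FALSE, dims)
  for (i in seq_len(n_ang))
    aliased_any <- aliased_any | frames$aliased[[i]]

  for (k in seq_len(nf)) {
    Fm <- vapply(seq_len(n_ang), function(i) as.vector(maps[[i]][, , k]),
                 numeric(npx))                      # npx x n_angles
    V <- Fm %*% t(pinv)                             # npx x 2
    vx[, , k] <- V[, 1]
    vz[, , k] <- V[, 2]
    R <- Fm - V %*% t(A)
    residual[, , k] <- sqrt(rowSums(R^2))
  }

  valid <- !aliased_any & is.finite(vx) & is.finite(vz)
  lum <- frames$lumen_mask
  if (!is.null(lum))
    valid <- valid & array(rep(lum, nf), dims)
  if (n_ang > 2) {
    thr <- residual_threshold_hz %||% (3 * max(cfg$noise_std_hz, 1e-9))
    valid <- valid & residual <= thr
  }
  vx[!valid & !is.finite(vx)] <- 0
  vz[!valid & !is.finite(vz)] <- 0

  structure(list(
    frame_times = frames$frame_times,
    vx = vx, vz = vz, valid = valid, residual = residual,
    geometry = frames$geometry,
    config = cfg
  ), class = "vector_field")
}

#' Assemble a vector field directly from arrays
#'
#' Entry point for externally supplied per-frame 2D vector fields (e.g. read
#' from CSV) so they can feed the categorization stages without a Doppler
#' acquisition.
#'
#' @param frame_times Frame times (s).
#' @param vx,vz Velocity arrays, `nz x nx x n_frames` (m/s).
#' @param valid Optional logical validity array (default: finite entries).
#' @param geometry Optional [geometry_config()] for path coordinates.
#' @return A `vector_field`.
#' @export
vector_field <- function(frame_times, vx, vz, valid = NULL, geometry = NULL) {
  stopifnot(identical(dim(vx), dim(vz)),
            length(frame_times) == dim(vx)[3])
  valid <- valid %||% (is.finite(vx) & is.finite(vz))
  structure(list(
    frame_times = frame_times, vx = vx, vz = vz, valid = valid,
    residual = array(0, dim(vx)), geometry = geometry, config = NULL
  ), class = "vector_field")
}
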