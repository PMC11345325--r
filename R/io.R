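# Plain-text serialization: vector fields as long-form CSV plus a JSON
# metadata sidecar, run configurations as YAML. External per-frame vector
# fields in the same CSV layout can enter the pipeline mid-stream.

#' Write a vector field to CSV + JSON
#'
#' Writes `<prefix>.csv` (long form: `frame`, `row`, `col`, `vx`, `vz`,
#' `valid`; only pixels that are valid or nonzero) and `<prefix>.json`
#' (dimensions, frame times, units, geometry summary).
#'
#' @param field A `vector_field`.
#' @param prefix Output path prefix (without extension).
#' @return Invisibly, the two file paths.
#' @export
write_vector_field <- function(field, prefix) {
  dims <- dim(field$vx)
  keep <- field$valid | field$vx != 0 | field$vz != 0
  idx <- which(keep, arr.ind = TRUE)
  df <- data.frame(frame = idx[, 3], row = idx[, 1], col = idx[, 2],
                   vx = field$vx[keep], vz = field$vz[keep],
                   valid = as.integer(field$valid[keep]))
  df <- df[order(df$frame, df$row, df$col), ]
  csv <- paste0(prefix, ".csv"); meta <- paste0(prefix, ".json")
  utils::write.csv(df, csv, row.names = FALSE)
  g <- field$geometry
  jsonlite::write_json(list(
    dims = dims, frame_times = field$frame_times,
    units = list(velocity = "m/s", time = "s", length = "mm"),
    geometry = if (!is.null(g)) list(
      position_id = g$position_id,
      fov_width_mm = g$fov_width_mm, fov_depth_mm = g$fov_depth_mm,
      grid_spacing_mm = g$grid_spacing_mm,
      vessel_diameter_mm = g$vessel_diameter_mm,
      anterograde_axis_deg = g$anterograde_axis_deg,
      path_length_mm = g$path_length_mm)
  ), meta, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, meta))
}

#' Read a vector field from CSV + JSON
#'
#' Inverse of [write_vector_field()]; omitted pixels are zero and invalid.
#'
#' @param prefix Path prefix used when writing.
#' @return A `vector_field`.
#' @export
read_vector_field <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(prefix, ".csv"))
  dims <- as.integer(meta$dims)
  vx <- array(0, dims); vz <- array(0, dims)
  valid <- array(FALSE, dims)
  at <- cbind(df$row, df$col, df$frame)
  vx[at] <- df$vx; vz[at] <- df$vz; valid[at] <- df$valid > 0
  geometry <- NULL
  if (!is.null(meta$geometry) && length(meta$geometry)) {
    geometry <- geometry_config(
      position_id = meta$geometry$position_id,
      fov_width_mm = meta$geometry$fov_width_mm,
      fov_depth_mm = meta$geometry$fov_depth_mm,
      grid_spacing_mm = meta$geometry$grid_spacing_mm,
      vessel_diameter_mm = meta$geometry$vessel_diameter_mm,
      anterograde_axis_deg = meta$geometry$anterograde_axis_deg,
      path_length_mm = meta$geometry$path_length_mm)
  }
  vector_field(meta$frame_times, vx, vz, valid, geometry)
}

#' Write / read a run configuration as YAML
#'
#' Configurations round-trip unchanged through serialization.
#'
#' @param config A `run_config` list from [default_run_config()].
#' @param path YAML file path.
#' @return `write_run_config`: invisibly, `path`. `read_run_config`: the
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}
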