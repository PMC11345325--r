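# Five-group flow-vector categorization (fast/slow anterograde, fast/slow
# retrograde, other), per-frame area ratios, per-phase summaries with Welch
# comparisons, and mixing-zone localization along the aortic path.

#' Flow group labels
#'
#' Integer codes used in label maps: 0 background, 1 fast_antero,
#' 2 slow_antero, 3 fast_retro, 4 slow_retro, 5 other.
#' @export
flow_groups <- function() {
  c(fast_antero = 1L, slow_antero = 2L, fast_retro = 3L,
    slow_retro = 4L, other = 5L)
}

#' Categorize flow vectors into the five groups
#'
#' A valid vector with speed at or above `min_speed` is anterograde if its
#' direction lies within `cone_deg` of the anterograde axis, retrograde if
#' within `cone_deg` of the opposite axis, and "other" otherwise; the
#' anterograde and retrograde groups are split into fast (speed strictly
#' above `speed_threshold`) and slow (at or below; a speed of exactly
#' 0.25 m/s is slow). The cone boundary is inclusive. Pixels that are
#' invalid, below `min_speed`, or of zero magnitude (undefined direction)
#' are background.
#'
#' @param field A `vector_field`.
#' @param axis_deg Anterograde axis angle (degrees); defaults to the
#'   geometry's.
#' @param cone_deg Half-angle of the direction cones (default 30; must be
#'   below 90 so the cones are disjoint).
#' @param speed_threshold Fast/slow split (default 0.25 m/s).
#' @param min_speed Flow-area floor (default 0.02 m/s): slower pixels do not
#'   count as flow area.
#' @return A `group_label_map`: integer array `nz x nx x n_frames` plus
#'   `frame_times` and the level codes.
#' @export
categorize_vectors <- function(field, axis_deg = NULL, cone_deg = 30,
                               speed_threshold = 0.25, min_speed = 0.02) {
  if (cone_deg >= 90 || cone_deg <= 0)
    stop_vfimix("cone half-angle must be in (0, 90) so cones are disjoint",
                "vfimix_invalid_config")
  axis_deg <- axis_deg %||% field$geometry$anterograde_axis_deg
  if (is.null(axis_deg))
    stop_vfimix("no anterograde axis available", "vfimix_invalid_input")
  sp <- sqrt(field$vx^2 + field$vz^2)
  ang <- atan2(field$vz, field$vx) * 180 / pi
  d_ant <- abs(angle_diff_deg(ang, axis_deg))
  d_ret <- abs(angle_diff_deg(ang, axis_deg + 180))
  flow <- field$valid & sp >= min_speed & sp > 0
  lab <- array(0L, dim(sp))
  fast <- sp > speed_threshold
  lab[flow & d_ant <= cone_deg & fast] <- 1L
  lab[flow & d_ant <= cone_deg & !fast] <- 2L
  lab[flow & d_ret <= cone_deg & fast] <- 3L
  lab[flow & d_ret <= cone_deg & !fast] <- 4L
  lab[flow & d_ant > cone_deg & d_ret > cone_deg] <- 5L
  structure(list(
    labels = lab, frame_times = field$frame_times,
    groups = flow_groups(), geometry = field$geometry,
    settings = list(axis_deg = axis_deg, cone_deg = cone_deg,
                    speed_threshold = speed_threshold, min_speed = min_speed)
  ), class = "group_label_map")
}

#' Per-frame area ratios of the flow groups
#'
#' The flow area of a frame is its count of non-background pixels; each
#' group's ratio is its pixel count over the flow area. Frames with zero
#' flow area carry `NA` ratios (undefined).
#'
#' @param label_map A [categorize_vectors()] result.
#' @return A `group_ratio_series` data frame in long form: `frame`, `time`,
#'   `group`, `ratio`, `flow_area_px`.
#' @export
group_ratios <- function(label_map) {
  lab <- label_map$labels
  nf <- dim(lab)[3]
  groups <- label_map$groups
  out <- vector("list", nf)
  for (k in seq_len(nf)) {
    counts <- tabulate(lab[, , k], nbins = 5L)
    area <- sum(counts)
    ratio <- if (area > 0) counts / area else rep(NA_real_, 5)
    out[[k]] <- data.frame(
      frame = k, time = label_map$frame_times[k],
      group = names(groups), ratio = ratio, flow_area_px = area,
      row.names = NULL
    )
  }
  res <- do.call(rbind, out)
  res$group <- factor(res$group, levels = names(groups))
  class(res) <- c("group_ratio_series", "data.frame")
  res
}

#' Per-phase summary of group ratios
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of each group's
#' per-frame ratio over the frames falling in each cardiac-phase window.
#' Phases with no frames are flagged missing (`n_frames = 0`, `NA` moments),
#' never fabricated.
#'
#' @param ratios A [group_ratios()] result.
#' @param phases A [segment_phases()] result.
#' @return Data frame: `phase`, `group`, `mean`, `sd`, `n_frames`.
#' @export
phase_summary <- function(ratios, phases) {
  ratios$phase <- assign_phase(ratios$time, phases)
  grid <- expand.grid(phase = rownames(phases$windows),
                      group = levels(ratios$group),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    r <- ratios$ratio[ratios$phase == grid$phase[i] &
                        ratios$group == grid$group[i]]
    r <- r[!is.na(r)]
    data.frame(phase = grid$phase[i], group = grid$group[i],
               mean = if (length(r)) mean(r) else NA_real_,
               sd = if (length(r) > 1) stats::sd(r) else
                 if (length(r) == 1) 0 else NA_real_,
               n_frames = length(r))
  })
  out <- do.call(rbind, res)
  out$phase <- factor(out$phase, levels = rownames(phases$windows))
  out$group <- factor(out$group, levels = levels(ratios$group))
  out
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic
#' `t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' t distribution.
#'
#' @param a,b Numeric samples, each of length at least 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop_vfimix("each sample needs at least 2 observations",
                "vfimix_invalid_input")
  va <- stats::var(a); vb <- stats::var(b)
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (mean(a) == mean(b))
      stop_vfimix("zero variance in both samples with equal means",
                  "vfimix_degenerate_test")
    stop_vfimix("zero pooled variance", "vfimix_degenerate_test")
  }
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Localize the mixing zone along the aortic path
#'
#' Pools the label maps of all imaged positions onto the centerline path
#' coordinate (per-pixel, binned). For every path bin and frame with flow in
#' that bin, the anterograde and retrograde area ratios within the bin are
#' computed; the per-bin time averages of those frame ratios give
#' anterograde and retrograde profiles along the path, and the estimate is
#' the path position where they cross (linear interpolation at the sign
#' change of their difference). Averaging frame ratios rather than raw
#' pixel counts keeps the narrow retrograde jet, present in many diastolic
#' frames, from being outvoted by the full-width systolic stream. Data
#' containing only one stream are not localizable and yield `NA` with a
#' reason attribute. Path bins with very little pixel support (image-corner
#' slivers) are discarded. If the profiles have not crossed by the most
#' distal sampled bin but their difference is still declining there, the
#' crossing is linearly extrapolated from the last two bins (clamped to
#' `total_path_mm`): the mixing zone lies distal of the imaged field.
#'
#' @param label_maps List of [categorize_vectors()] results, one per imaged
#'   position (each needs geometry with `path_mm`).
#' @param bin_mm Path bin width in mm (default 4).
#' @param min_support_frac Bins whose total pixel support is below this
#'   fraction of the median bin support are dropped (default 0.25).
#' @param total_path_mm Clamp for the extrapolated estimate (default 230).
#' @return Estimated interface path position (mm), or `NA_real_` when not
#'   localizable.
#' @export
localize_mixing_zone <- function(label_maps, bin_mm = 4,
                                 min_support_frac = 0.25,
                                 total_path_mm = 230) {
  acc <- list()
  for (lm in label_maps) {
    g <- lm$geometry
    if (is.null(g))
      stop_vfimix("label map lacks geometry/path coordinates",
                  "vfimix_invalid_input")
    nf <- dim(lm$labels)[3]
    s <- as.vector(g$path_mm)
    bin_all <- round(s / bin_mm) * bin_mm
    for (k in seq_len(nf)) {
      lab <- as.vector(lm$labels[, , k])
      keep <- lab > 0L
      if (!any(keep)) next
      b <- bin_all[keep]
      n <- tapply(rep(1L, sum(keep)), b, sum)
      ant <- tapply(lab[keep] %in% c(1L, 2L), b, sum)
      ret <- tapply(lab[keep] %in% c(3L, 4L), b, sum)
      acc[[length(acc) + 1L]] <- data.frame(
        bin = as.numeric(names(n)),
        n_px = as.numeric(n),
        antero_ratio = as.numeric(ant) / as.numeric(n),
        retro_ratio = as.numeric(ret) / as.numeric(n)
      )
    }
  }
  if (!length(acc))
    return(structure(NA_real_, reason = "no flow pixels"))
  d <- do.call(rbind, acc)
  if (sum(d$antero_ratio) == 0 || sum(d$retro_ratio) == 0)
    return(structure(NA_real_, reason = "single-stream data"))
  support <- stats::aggregate(n_px ~ bin, d, sum)
  keep_bins <- support$bin[support$n_px >=
                             min_support_frac * stats::median(support$n_px)]
  d <- d[d$bin %in% keep_bins, ]
  prof <- stats::aggregate(cbind(antero_ratio, retro_ratio) ~ bin, d, mean)
  prof <- prof[order(prof$bin), ]
  diff_ratio <- prof$antero_ratio - prof$retro_ratio
  nb <- length(diff_ratio)
  sgn <- sign(diff_ratio)
  cross <- which(sgn[-nb] > 0 & sgn[-1] <= 0)
  if (length(cross)) {
    i <- cross[1]
    x0 <- prof$bin[i]; x1 <- prof$bin[i + 1]
    y0 <- diff_ratio[i]; y1 <- diff_ratio[i + 1]
    if (y0 == y1) return((x0 + x1) / 2)
    return(x0 + y0 * (x1 - x0) / (y0 - y1))
  }
  if (nb >= 2 && diff_ratio[nb] < diff_ratio[nb - 1] && diff_ratio[nb] > 0) {
    # declining but uncrossed: the interface lies distal of the field
    slope <- (diff_ratio[nb] - diff_ratio[nb - 1]) /
      (prof$bin[nb] - prof$bin[nb - 1])
    est <- prof$bin[nb] - diff_ratio[nb] / slope
    return(min(est, total_path_mm))
  }
  structure(NA_real_, reason = "no crossing along path")
}
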