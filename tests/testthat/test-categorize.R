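make_field <- function(vx, vz, valid = NULL) {
  dims <- c(dim(vx), 1)
  vector_field(0, array(vx, dims), array(vz, dims),
               valid = if (!is.null(valid)) array(valid, dims))
}

test_that("single vectors land in the documented groups", {
  # along the axis at 0.5 m/s -> fast anterograde
  f <- make_field(matrix(0.5), matrix(0))
  lm <- categorize_vectors(f, axis_deg = 0)
  expect_equal(as.vector(lm$labels), 1L)
  # opposite the axis at 0.20 m/s -> slow retrograde
  f <- make_field(matrix(-0.2), matrix(0))
  expect_equal(as.vector(categorize_vectors(f, axis_deg = 0)$labels), 4L)
  # perpendicular to the axis -> other
  f <- make_field(matrix(0), matrix(0.3))
  expect_equal(as.vector(categorize_vectors(f, axis_deg = 0)$labels), 5L)
  # below the flow-area floor -> background
  f <- make_field(matrix(0.01), matrix(0))
  expect_equal(as.vector(categorize_vectors(f, axis_deg = 0)$labels), 0L)
  # invalid pixel -> background
  f <- make_field(matrix(0.5), matrix(0), valid = FALSE)
  expect_equal(as.vector(categorize_vectors(f, axis_deg = 0)$labels), 0L)
})

test_that("boundary conventions: 0.25 m/s is slow, the cone edge is inside", {
  f <- make_field(matrix(0.25), matrix(0))
  expect_equal(as.vector(categorize_vectors(f, axis_deg = 0)$labels), 2L)
  # a vector along +x with the axis at exactly 30 degrees: angular
  # distance is exactly the cone half-angle -> still anterograde
  f <- make_field(matrix(0.2), matrix(0))
  expect_equal(as.vector(categorize_vectors(f, axis_deg = 30)$labels), 2L)
  expect_equal(as.vector(categorize_vectors(f, axis_deg = 150)$labels), 4L)
  # zero-magnitude vectors have no direction -> background
  f <- make_field(matrix(0), matrix(0))
  expect_equal(as.vector(categorize_vectors(f, axis_deg = 0)$labels), 0L)
})

test_that("overlapping cones are rejected", {
  f <- make_field(matrix(0.5), matrix(0))
  expect_error(categorize_vectors(f, axis_deg = 0, cone_deg = 95),
               class = "vfimix_invalid_config")
})

test_that("categorization matches a brute-force oracle on random vectors", {
  set.seed(31)
  n <- 10000
  vx <- matrix(runif(n, -0.6, 0.6), 100, 100)
  vz <- matrix(runif(n, -0.6, 0.6), 100, 100)
  # sprinkle exact zeros and tiny speeds
  vx[1:50] <- 0; vz[1:50] <- 0
  vx[51:100] <- 0.001; vz[51:100] <- 0
  valid <- matrix(runif(n) > 0.05, 100, 100)
  f <- make_field(vx, vz, valid)
  axis <- 37
  lm <- categorize_vectors(f, axis_deg = axis)
  oracle <- mapply(oracle_categorize_one, vx, vz, valid,
                   MoreArgs = list(axis_deg = axis, cone_deg = 30,
                                   speed_threshold = 0.25, min_speed = 0.02))
  expect_equal(as.vector(lm$labels), as.vector(oracle))
})

test_that("negating every vector swaps anterograde and retrograde exactly", {
  set.seed(32)
  vx <- matrix(runif(400, -0.6, 0.6), 20, 20)
  vz <- matrix(runif(400, -0.6, 0.6), 20, 20)
  l1 <- categorize_vectors(make_field(vx, vz), axis_deg = 10)$labels
  l2 <- categorize_vectors(make_field(-vx, -vz), axis_deg = 10)$labels
  expect_equal(sum(l1 == 1L), sum(l2 == 3L))
  expect_equal(sum(l1 == 2L), sum(l2 == 4L))
  expect_equal(sum(l1 == 3L), sum(l2 == 1L))
  expect_equal(sum(l1 == 4L), sum(l2 == 2L))
  expect_equal(which(l1 == 5L), which(l2 == 5L))
  expect_equal(which(l1 == 0L), which(l2 == 0L))
})

test_that("group ratios count areas and always sum to one", {
  f <- make_field(matrix(0.5, 4, 4), matrix(0, 4, 4))
  r <- group_ratios(categorize_vectors(f, axis_deg = 0))
  expect_equal(r$ratio[r$group == "fast_antero"], 1)
  expect_equal(sum(r$ratio), 1)
  # empty frame carries the undefined-ratio sentinel
  f0 <- make_field(matrix(0, 4, 4), matrix(0, 4, 4))
  r0 <- group_ratios(categorize_vectors(f0, axis_deg = 0))
  expect_true(all(is.na(r0$ratio)))
  expect_equal(unique(r0$flow_area_px), 0)
})

test_that("random label maps match a counting oracle", {
  set.seed(33)
  lm <- list(labels = array(sample(0:5, 600, replace = TRUE), c(10, 6, 10)),
             frame_times = seq(0, by = 0.01, length.out = 10),
             groups = flow_groups(), geometry = NULL, settings = list())
  class(lm) <- "group_label_map"
  r <- group_ratios(lm)
  for (k in 1:10) {
    lab <- lm$labels[, , k]
    area <- sum(lab > 0)
    for (gname in names(flow_groups())) {
      got <- r$ratio[r$frame == k & r$group == gname]
      expect_equal(got, sum(lab == flow_groups()[[gname]]) / area)
    }
    expect_equal(sum(r$ratio[r$frame == k]), 1)
  }
})

test_that("phase summaries use frame-ratio means and sample SDs", {
  ph <- segment_phases(0.1, 2 / 3, 0.3)
  # constant series: SD zero everywhere observed
  lm <- list(labels = array(1L, c(2, 2, 20)),
             frame_times = seq(0, 0.63, length.out = 20),
             groups = flow_groups(), geometry = NULL, settings = list())
  class(lm) <- "group_label_map"
  s <- phase_summary(group_ratios(lm), ph)
  expect_true(all(s$sd[s$n_frames > 1] == 0))
  # two frames at 0.2 and 0.4 ratio in one phase: closed-form moments
  labs <- array(1L, c(10, 1, 2)); labs[3:10, 1, 1] <- 5L; labs[7:10, 1, 2] <- 5L
  lm2 <- list(labels = labs, frame_times = c(0.15, 0.2),
              groups = flow_groups(), geometry = NULL, settings = list())
  class(lm2) <- "group_label_map"
  s2 <- phase_summary(group_ratios(lm2), ph)
  row <- s2[s2$phase == "systole" & s2$group == "fast_antero", ]
  expect_equal(row$mean, mean(c(0.2, 0.6)))
  expect_equal(row$sd, sqrt(((0.2 - 0.4)^2 + (0.6 - 0.4)^2) / 1))
  expect_equal(row$n_frames, 2)
  # empty phases are flagged, not fabricated
  row_ld <- s2[s2$phase == "late_diastole" & s2$group == "fast_antero", ]
  expect_equal(row_ld$n_frames, 0)
  expect_true(is.na(row_ld$mean))
})

test_that("Welch test matches the closed form and stats::t.test", {
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  res <- welch_t_test(a, b)
  # hand evaluation of the Welch formulas
  se2 <- var(a) / 3 + var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$t, t_hand)
  expect_equal(res$df, df_hand)
  ref <- stats::t.test(a, b, var.equal = FALSE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$df, unname(ref$parameter))
  expect_equal(res$p, ref$p.value)
})

test_that("Welch test handles identical and degenerate samples", {
  a <- c(0.1, 0.2, 0.3)
  res <- welch_t_test(a, a)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_error(welch_t_test(c(1, 1), c(1, 1)),
               class = "vfimix_degenerate_test")
  expect_error(welch_t_test(1, c(1, 2)), class = "vfimix_invalid_input")
})

test_that("single-stream data yield the not-localizable sentinel", {
  g <- tiny_geometry()
  dims <- c(g$nz, g$nx, 2)
  f <- vector_field(c(0, 8e-4), array(0.5, dims), array(0, dims),
                    geometry = g)
  lm <- categorize_vectors(f, axis_deg = 0)
  est <- localize_mixing_zone(list(lm))
  expect_true(is.na(est))
  expect_equal(attr(est, "reason"), "single-stream data")
})

test_that("higher ECMO flow shifts retrograde dominance into late diastole", {
  mk <- function(ecmo) {
    s <- quick_scene(position = "distal_arch", ecmo = ecmo, duration = 0.7,
                     seed = 2)
    vf <- solve_vectors(acquire(s, acquisition_config(noise_std_hz = 5,
                                                      seed = 6)))
    ph <- segment_phases(0.1, s$cycle_period_s, 0.3)
    phase_summary(group_ratios(categorize_vectors(vf)), ph)
  }
  s_low <- mk(0.35); s_high <- mk(1.0)
  retro <- function(s, ph) sum(s$mean[s$phase == ph &
                                        s$group %in% c("fast_retro",
                                                       "slow_retro")])
  expect_gt(retro(s_high, "late_diastole"), retro(s_low, "late_diastole"))
})
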