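#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_vfimix <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "vfimix_error")))
}

#' Signed angular difference in degrees
#'
#' Smallest-magnitude difference `a - b`, wrapped into (-180, 180].
#' @keywords internal
angle_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

#' Linear time interpolation of a (nz, nx, nt) array stack
#'
#' Returns the slice at time `t` by linear interpolation between bracketing
#' frames; clamps outside the stored range.
#' @keywords internal
interp_time_slice <- function(arr, times, t) {
  nt <- length(times)
  if (t <= times[1]) return(arr[, , 1])
  if (t >= times[nt]) return(arr[, , nt])
  i <- findInterval(t, times)
  t0 <- times[i]; t1 <- times[i + 1]
  w <- (t - t0) / (t1 - t0)
  (1 - w) * arr[, , i] + w * arr[, , i + 1]
}
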