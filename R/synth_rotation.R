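#' Configuration for the rotation-trace simulator
#'
#' Describes a synthetic open-field heading trace that completes a known
#' number of clockwise (CW) then counterclockwise (CCW) full turns, with
#' Gaussian heading jitter. CW is the direction of decreasing heading
#' angle (image coordinates), matching the analysis default.
#'
#' The planned path overshoots each block of turns by 135 degrees and the
#' jitter is clamped to +/- 89 degrees, which together guarantee that the
#' accumulator counter recovers the requested counts exactly: the
#' overshoot ensures every completed turn is crossed even at the jitter
#' extreme, while overshoot + jitter stays short of a spurious extra turn.
#'
#' @param cw_turns,ccw_turns non-negative integer full-turn counts.
#' @param duration session duration in seconds; default 2400 (40 min).
#' @param fs trace sampling rate in Hz; default 5.
#' @param jitter_sd heading jitter SD in degrees; must be `< 22.5` so the
#'   +/- 89 degree clamp is essentially never active.
#' @param seed integer random seed.
#' @return list of class `rotation_sim_config`.
#' @export
rotation_sim_config <- function(cw_turns = 5L, ccw_turns = 2L,
                                duration = 2400, fs = 5,
                                jitter_sd = 5, seed = 1L) {
  if (cw_turns < 0 || ccw_turns < 0 ||
      cw_turns != round(cw_turns) || ccw_turns != round(ccw_turns)) {
    stop("turn counts must be non-negative integers")
  }
  if (duration <= 0 || fs <= 0) stop("duration and fs must be positive")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (jitter_sd >= 22.5) {
    stop("jitter_sd >= 22.5 degrees would risk spurious turn crossings")
  }
  cfg <- list(cw_turns = as.integer(cw_turns), ccw_turns = as.integer(ccw_turns),
              duration = duration, fs = fs, jitter_sd = jitter_sd,
              seed = as.integer(seed))
  class(cfg) <- "rotation_sim_config"
  cfg
}

#' Simulate a heading trace with known rotation counts
#'
#' Builds a piecewise-linear cumulative-angle path completing the
#' requested CW turns (heading decreasing) followed by the CCW turns,
#' each block overshooting by 135 degrees, adds clamped Gaussian jitter,
#' and wraps to `[0, 360)` degrees.
#'
#' @param config a [rotation_sim_config()].
#' @param mouse,session identifiers carried into the output.
#' @return list of class `rotation_trace` with `time` (s), `heading`
#'   (degrees in `[0, 360)`), `mouse`, `session`, and `truth`
#'   (list `cw`, `ccw`, `net = cw - ccw`).
#' @export
gen_rotation <- function(config, mouse = "m1", session = "post") {
  stopifnot(inherits(config, "rotation_sim_config"))
  n <- max(2L, round(config$duration * config$fs) + 1L)
  time <- seq(0, config$duration, length.out = n)
  over <- 135
  # piecewise-linear cumulative angle: down for CW block, up for CCW block
  knots_y <- c(0)
  if (config$cw_turns > 0) knots_y <- c(knots_y, -360 * config$cw_turns - over)
  if (config$ccw_turns > 0) {
    # end `over` degrees beyond the last CCW threshold, which sits at
    # 360 * (ccw - cw) on the cumulative scale
    knots_y <- c(knots_y, 360 * (config$ccw_turns - config$cw_turns) + over)
  }
  if (length(knots_y) == 1) knots_y <- c(0, 0)
  knots_x <- seq(0, config$duration, length.out = length(knots_y))
  planned <- stats::approx(knots_x, knots_y, xout = time)$y
  # jitter is clamped at 4.5 SD (capped below 90 degrees); the planned
  # per-sample step plus the worst-case jitter swing must then stay below
  # the 180-degree unwrap limit, or crossings could be missed
  clamp <- min(89, 4.5 * config$jitter_sd)
  if (max(abs(diff(planned))) + 2 * clamp >= 180) {
    stop("sampling rate too low for the requested turn rate and jitter; ",
         "increase fs or duration")
  }
  jitter <- withr::with_seed(config$seed, {
    pmin(pmax(stats::rnorm(n, sd = config$jitter_sd), -clamp), clamp)
  })
  heading <- (planned + jitter) %% 360
  structure(list(time = time, heading = heading, mouse = mouse,
                 session = session,
                 truth = list(cw = config$cw_turns, ccw = config$ccw_turns,
                              net = config$cw_turns - config$ccw_turns)),
            class = "rotation_trace")
}
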