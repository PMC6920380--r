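#' Unwrap a wrapped heading series to a continuous cumulative angle
#'
#' Maps successive heading differences into `(-180, 180]` degrees and
#' accumulates them from the first heading, so full turns appear as
#' +/- 360 degree excursions of the cumulative series. Re-wrapping the
#' result modulo 360 recovers the input exactly.
#'
#' @param heading heading series in degrees (any real values; typically
#'   wrapped to `[0, 360)`).
#' @param time optional time stamps; validated to be strictly increasing.
#' @return cumulative continuous angle series (degrees).
#' @export
unwrap_heading <- function(heading, time = NULL) {
  if (length(heading) < 2) stop("trace needs at least 2 samples")
  if (!is.null(time)) {
    if (length(time) != length(heading)) stop("time and heading lengths differ")
    if (any(diff(time) <= 0)) stop("time stamps must be strictly increasing")
  }
  d <- diff(heading)
  dm <- ((d + 180) %% 360) - 180  # [-180, 180)
  dm[dm == -180] <- 180           # convention: half-turn counts as +180
  cumsum(c(heading[1], dm))
}

#' Count full clockwise / counterclockwise rotations
#'
#' Accumulator method emulating commercial tracking software: a CW turn
#' is registered each time the cumulative unwrapped angle moves a
#' further 360 degrees below its running reference, and the reference
#' steps by 360 whenever a full turn completes in either direction.
#' Partial turns never count: an animal oscillating within less than a
#' full turn registers nothing. CCW turns are counted by running the
#' same clockwise accumulator on the time-reversed trace, which makes
#' the two directions exactly symmetric: reversing a trace always swaps
#' the CW and CCW counts.
#'
#' @param trace a `rotation_trace` (from [gen_rotation()] or
#'   [read_rotation_trace()]), or a numeric heading vector.
#' @param time time stamps when `trace` is a bare vector.
#' @param cw_sign which heading direction is clockwise: `"neg"` (default;
#'   heading decreases during a CW turn, image coordinates) or `"pos"`.
#'   Camera mounting flips chirality, hence the flag.
#' @param window optional `c(start, end)` time window (seconds, half-open
#'   `[start, end)`) to which the trace is trimmed before counting, e.g.
#'   to drop an acclimation period.
#' @return list of class `rotation_counts`: `cw`, `ccw`, `net = cw - ccw`.
#' @export
count_rotations <- function(trace, time = NULL, cw_sign = c("neg", "pos"),
                            window = NULL) {
  cw_sign <- match.arg(cw_sign)
  if (inherits(trace, "rotation_trace")) {
    time <- trace$time
    heading <- trace$heading
  } else {
    heading <- trace
  }
  if (!is.null(window)) {
    if (is.null(time)) stop("a time vector is required to apply a window")
    keep <- time >= window[1] & time < window[2]
    if (sum(keep) < 2) stop("analysis window contains fewer than 2 samples")
    heading <- heading[keep]
    time <- time[keep]
  }
  theta <- unwrap_heading(heading, time)
  if (cw_sign == "pos") theta <- -theta  # internally, CW = decreasing angle
  cw <- accumulate_cw(theta)
  ccw <- accumulate_cw(rev(theta))
  structure(list(cw = cw, ccw = ccw, net = cw - ccw),
            class = "rotation_counts")
}

# Clockwise turns of an unwrapped angle series: shared-reference
# accumulator whose reference steps by 360 on every completed turn.
accumulate_cw <- function(theta) {
  ref <- theta[1]
  cw <- 0L
  for (th in theta[-1]) {
    while (th <= ref - 360) { cw <- cw + 1L; ref <- ref - 360 }
    while (th >= ref + 360) { ref <- ref + 360 }
  }
  cw
}

#' Grubbs test for a single outlier
#'
#' Two-sided Grubbs test: `G = max |x_i - mean| / SD` (sample SD) compared
#' against the critical value
#' `G_crit = ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with `t` the
#' upper `alpha / (2n)` quantile of Student's t on `n - 2` degrees of
#' freedom. At most one outlier is flagged per call (single-pass, no
#' iterative removal).
#'
#' @param values numeric vector, `n >= 3`, non-constant.
#' @param alpha significance level in `(0, 0.5)`; default 0.05.
#' @return list of class `grubbs_result`: `statistic` (G), `critical`
#'   (G_crit), `p_value` (approximate two-sided p, capped at 1),
#'   `outlier_index` (index of the most extreme value, or `NA` when not
#'   significant), `outlier` (logical decision).
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3) stop("Grubbs test needs n >= 3")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must be in (0, 0.5)")
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation: Grubbs statistic undefined")
  dev <- abs(values - mean(values))
  i_max <- which.max(dev)
  G <- dev[i_max] / s
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  G_crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  # invert G -> t to get an approximate p-value on the same scale
  denom <- (n - 1)^2 - n * G^2
  p <- if (denom <= 0) 0 else {
    ts <- sqrt((n - 2) * n * G^2 / denom)
    min(1, 2 * n * stats::pt(ts, df = n - 2, lower.tail = FALSE))
  }
  outlier <- G > G_crit
  structure(list(statistic = G, critical = G_crit, p_value = p,
                 outlier_index = if (outlier) i_max else NA_integer_,
                 outlier = outlier),
            class = "grubbs_result")
}
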