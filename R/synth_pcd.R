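#' Configuration for the cavitation-pulse simulator
#'
#' Describes synthetic passive-cavitation-detection (PCD) pulses: a sum of
#' harmonic tones at `n * f0`, ultraharmonic tones at `(n + 1/2) * f0`,
#' a broadband (inertial) component simulated as Gaussian white noise
#' band-limited to the analysis band, and unfiltered sensor noise.
#'
#' @param f0 fundamental frequency in Hz; default 1.5 MHz.
#' @param fs sampling rate in Hz; default 50 MHz. Must exceed twice the
#'   highest generated frequency.
#' @param duration pulse duration in seconds; default 0.2 ms (10,000
#'   samples at the default rate).
#' @param harmonics named numeric vector of tone amplitudes; names are
#'   multiples of `f0` (e.g. `c("2" = 1)` is a tone at `2 * f0`).
#' @param ultraharmonics named numeric vector; names are half-integer
#'   multiples of `f0` (e.g. `c("2.5" = 0.3)`).
#' @param broadband_sd SD of the white noise that is band-limited to
#'   `broadband_band` to form the inertial component; 0 disables it.
#' @param broadband_band length-2 band (Hz) of the inertial component;
#'   default 3-9 MHz.
#' @param sensor_sd SD of unfiltered wideband sensor noise; 0 disables it.
#' @param n_pulses number of pulses to generate.
#' @param microbubbles logical flag carried into the metadata (with- vs
#'   without-microbubble recordings share the same model here; the flag
#'   labels the recording).
#' @param seed integer random seed.
#' @return list of class `pcd_sim_config`.
#' @export
pcd_sim_config <- function(f0 = 1.5e6, fs = 5e7, duration = 2e-4,
                           harmonics = c("2" = 1.0, "3" = 0.6, "4" = 0.4,
                                         "5" = 0.25, "6" = 0.15),
                           ultraharmonics = c("2.5" = 0.3, "3.5" = 0.2,
                                              "4.5" = 0.12, "5.5" = 0.08),
                           broadband_sd = 0.05,
                           broadband_band = c(3e6, 9e6),
                           sensor_sd = 0.01,
                           n_pulses = 5L, microbubbles = TRUE, seed = 1L) {
  stopifnot(f0 > 0, fs > 0, duration > 0, n_pulses >= 1)
  if (any(harmonics < 0) || any(ultraharmonics < 0)) {
    stop("tone amplitudes must be >= 0")
  }
  if (broadband_sd < 0 || sensor_sd < 0) stop("noise SDs must be >= 0")
  mults <- c(as.numeric(names(harmonics)), as.numeric(names(ultraharmonics)))
  if (length(mults) && any(is.na(mults))) {
    stop("tone names must be numeric multiples of f0")
  }
  fmax <- max(c(mults * f0, broadband_band[2]))
  if (fmax >= fs / 2) {
    stop("aliasing: highest generated frequency ", fmax, " Hz >= fs/2")
  }
  cfg <- list(f0 = f0, fs = fs, duration = duration,
              harmonics = harmonics, ultraharmonics = ultraharmonics,
              broadband_sd = broadband_sd, broadband_band = broadband_band,
              sensor_sd = sensor_sd, n_pulses = as.integer(n_pulses),
              microbubbles = isTRUE(microbubbles), seed = as.integer(seed))
  class(cfg) <- "pcd_sim_config"
  cfg
}

#' Analytic in-band RMS of band-limited white noise
#'
#' White Gaussian noise of standard deviation `sd` sampled at `fs` has a
#' flat one-sided spectral density `sd^2 / (fs / 2)` per Hz, so its RMS
#' restricted to a set of frequency intervals of total width W is
#' `sd * sqrt(W / (fs / 2))`.
#'
#' @param sd time-domain SD of the white noise before band-limiting.
#' @param fs sampling rate in Hz.
#' @param intervals two-column matrix of `(lo, hi)` frequencies in Hz.
#' @return the analytic RMS over the intervals.
#' @export
noise_band_rms <- function(sd, fs, intervals) {
  intervals <- matrix(intervals, ncol = 2)
  w <- sum(pmax(intervals[, 2] - intervals[, 1], 0))
  sd * sqrt(w / (fs / 2))
}

# Ideal band-pass by zeroing FFT bins outside the band (half-open upper
# edge, matching band_rms bin selection).
band_limit <- function(x, fs, band) {
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  f_alias <- pmin(f, fs - f)  # frequency of each bin's content
  keep <- f_alias >= band[1] & f_alias < band[2]
  X <- stats::fft(x)
  X[!keep] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Simulate PCD pulses with analytic ground truth
#'
#' Each pulse is the sum of the configured harmonic and ultraharmonic
#' tones (phase 0), a band-limited Gaussian broadband component, and
#' wideband sensor noise. The ground truth stores each component's
#' analytic RMS: `A / sqrt(2)` per tone (combined in quadrature across
#' tones of a kind) and the analytic in-band RMS for the broadband
#' component via [noise_band_rms()].
#'
#' @param config a [pcd_sim_config()].
#' @return list of class `pulse_set` with `pulses` (list of numeric
#'   vectors), `fs`, `f0`, `microbubbles`, `seed`, and `truth` (list with
#'   `harmonic_rms`, `ultraharmonic_rms`, `broadband_sd`,
#'   `broadband_band`, `broadband_inband_rms`, `sensor_sd`).
#' @export
gen_pcd <- function(config) {
  stopifnot(inherits(config, "pcd_sim_config"))
  n <- round(config$fs * config$duration)
  if (n < 64) stop("pulse duration too short: fewer than 64 samples")
  t <- (0:(n - 1)) / config$fs

  tone_sum <- function(amps) {
    s <- numeric(n)
    for (nm in names(amps)) {
      f <- as.numeric(nm) * config$f0
      s <- s + amps[[nm]] * sin(2 * pi * f * t)
    }
    s
  }
  clean <- tone_sum(config$harmonics) + tone_sum(config$ultraharmonics)

  pulses <- withr::with_seed(config$seed, {
    lapply(seq_len(config$n_pulses), function(i) {
      x <- clean
      if (config$broadband_sd > 0) {
        x <- x + band_limit(stats::rnorm(n, sd = config$broadband_sd),
                            config$fs, config$broadband_band)
      }
      if (config$sensor_sd > 0) x <- x + stats::rnorm(n, sd = config$sensor_sd)
      x
    })
  })

  quad <- function(amps) if (length(amps)) sqrt(sum((amps / sqrt(2))^2)) else 0
  truth <- list(
    harmonic_rms = quad(config$harmonics),
    ultraharmonic_rms = quad(config$ultraharmonics),
    broadband_sd = config$broadband_sd,
    broadband_band = config$broadband_band,
    broadband_inband_rms = noise_band_rms(config$broadband_sd, config$fs,
                                          matrix(config$broadband_band, ncol = 2)),
    sensor_sd = config$sensor_sd
  )
  structure(list(pulses = pulses, fs = config$fs, f0 = config$f0,
                 microbubbles = config$microbubbles, seed = config$seed,
                 truth = truth),
            class = "pulse_set")
}
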