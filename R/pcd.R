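#' One-sided amplitude spectrum of a PCD pulse
#'
#' FFT-based one-sided spectrum with Parseval normalisation: the squared
#' magnitudes sum to the mean-square of the signal, so the
#' root-sum-of-squares of magnitudes over any set of bins is the RMS
#' contribution of that band to the signal. A sinusoid of amplitude A at a
#' bin frequency yields magnitude A / sqrt(2) at its bin.
#'
#' @param samples numeric vector, at least 64 finite samples.
#' @param fs sampling rate in Hz.
#' @param window `"rect"` (default) or `"hann"`. The Hann window is
#'   normalised by its RMS so that broadband (noise) levels are preserved;
#'   narrowband tone amplitudes are smeared across neighbouring bins.
#' @return list of class `pulse_spectrum` with `freq` (Hz), `mag`
#'   (amplitude units), `fs`, `n`.
#' @export
pulse_spectrum <- function(samples, fs, window = c("rect", "hann")) {
  window <- match.arg(window)
  n <- length(samples)
  if (n < 64) stop("pulse must have at least 64 samples")
  if (!all(is.finite(samples))) stop("pulse contains non-finite samples")
  if (fs <= 0) stop("sampling rate must be positive")
  fs <- as.numeric(fs)
  x <- samples
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
    x <- x * w / sqrt(mean(w^2))
  }
  X <- stats::fft(x)
  half <- floor(n / 2)
  k <- 0:half
  mag <- Mod(X[k + 1]) / n
  # interior bins carry the conjugate half's energy too
  interior <- k > 0 & !(n %% 2 == 0 & k == half)
  mag[interior] <- mag[interior] * sqrt(2)
  structure(list(freq = k * fs / n, mag = mag, fs = fs, n = n),
            class = "pulse_spectrum")
}

#' Band RMS of a spectrum over a set of frequency intervals
#'
#' Root-sum-of-squares of the Parseval-normalised magnitudes whose bin
#' centres fall in any interval, half-open on the upper edge
#' (`lo <= f < hi`). With the [pulse_spectrum()] scaling this equals the
#' time-domain RMS of the signal content in those intervals.
#'
#' @param spectrum a [pulse_spectrum()].
#' @param intervals two-column matrix of `(lo, hi)` frequencies in Hz.
#' @return the band RMS.
#' @export
band_rms <- function(spectrum, intervals) {
  stopifnot(inherits(spectrum, "pulse_spectrum"))
  intervals <- matrix(intervals, ncol = 2)
  sel <- rep(FALSE, length(spectrum$freq))
  for (i in seq_len(nrow(intervals))) {
    sel <- sel | (spectrum$freq >= intervals[i, 1] & spectrum$freq < intervals[i, 2])
  }
  if (!any(sel)) stop("no spectral bins fall in the requested intervals")
  sqrt(sum(spectrum$mag[sel]^2))
}

#' Harmonic / ultraharmonic band plan for cavitation-dose analysis
#'
#' Enumerates the harmonic (`n * f0`) and ultraharmonic (`(n + 1/2) * f0`)
#' peak windows that intersect the analysis band, each window extending
#' `half_width` either side of its centre and clipped to the band edges.
#' With the defaults (f0 = 1.5 MHz, band 3-9 MHz) the harmonics are
#' {3, 4.5, 6, 7.5, 9} MHz and the ultraharmonics {3.75, 5.25, 6.75,
#' 8.25} MHz.
#'
#' @param f0 fundamental (transmit) frequency in Hz; default 1.5 MHz.
#' @param f_lo,f_hi analysis band in Hz; default 3-9 MHz.
#' @param half_width peak window half-width in Hz; must be `< f0 / 4` so
#'   harmonic and ultraharmonic windows stay disjoint. Default 150 kHz.
#' @return list of class `band_plan` with `f0`, `band`, `half_width`,
#'   `harmonic_centers`, `ultraharmonic_centers`, `harmonic_windows`,
#'   `ultraharmonic_windows` (two-column matrices).
#' @export
band_plan <- function(f0 = 1.5e6, f_lo = 3e6, f_hi = 9e6, half_width = 1.5e5) {
  if (f_lo >= f_hi) stop("f_lo must be < f_hi")
  if (half_width <= 0 || half_width >= f0 / 4) {
    stop("half_width must be in (0, f0/4) so peak windows stay disjoint")
  }
  centers <- function(mult0) {
    n_max <- ceiling((f_hi + half_width) / f0)
    cand <- (seq(0, n_max) + mult0) * f0
    cand[cand - half_width < f_hi & cand + half_width > f_lo]
  }
  windows <- function(cc) {
    if (!length(cc)) return(matrix(numeric(0), ncol = 2))
    cbind(pmax(cc - half_width, f_lo), pmin(cc + half_width, f_hi))
  }
  hc <- centers(0); hc <- hc[hc > 0]
  uc <- centers(0.5)
  structure(list(
    f0 = f0, band = c(f_lo, f_hi), half_width = half_width,
    harmonic_centers = hc, ultraharmonic_centers = uc,
    harmonic_windows = windows(hc), ultraharmonic_windows = windows(uc)
  ), class = "band_plan")
}

#' Stable cavitation dose (harmonic or ultraharmonic)
#'
#' Spectral RMS over the union of the plan's harmonic (SCDh) or
#' ultraharmonic (SCDu) peak windows.
#'
#' @param spectrum a [pulse_spectrum()].
#' @param plan a [band_plan()].
#' @param kind `"harmonic"` or `"ultraharmonic"`.
#' @return the dose (amplitude units).
#' @export
scd <- function(spectrum, plan, kind = c("harmonic", "ultraharmonic")) {
  kind <- match.arg(kind)
  win <- if (kind == "harmonic") plan$harmonic_windows else plan$ultraharmonic_windows
  if (!nrow(win)) stop("band plan has no ", kind, " windows")
  band_rms(spectrum, win)
}

#' Inertial cavitation dose
#'
#' Spectral RMS of the broadband content of the analysis band, i.e. over
#' the band minus every harmonic and ultraharmonic window.
#'
#' @param spectrum a [pulse_spectrum()].
#' @param plan a [band_plan()].
#' @return the dose (amplitude units).
#' @export
icd <- function(spectrum, plan) {
  gaps <- band_complement(plan)
  if (!nrow(gaps)) stop("harmonic/ultraharmonic windows cover the whole band")
  band_rms(spectrum, gaps)
}

#' Intervals of the analysis band between the peak windows
#'
#' @param plan a [band_plan()].
#' @return two-column matrix of `(lo, hi)` intervals (the ICD support).
#' @export
band_complement <- function(plan) {
  win <- rbind(plan$harmonic_windows, plan$ultraharmonic_windows)
  win <- win[order(win[, 1]), , drop = FALSE]
  lo <- plan$band[1]
  gaps <- NULL
  for (i in seq_len(nrow(win))) {
    if (win[i, 1] > lo) gaps <- rbind(gaps, c(lo, win[i, 1]))
    lo <- max(lo, win[i, 2])
  }
  if (lo < plan$band[2]) gaps <- rbind(gaps, c(lo, plan$band[2]))
  if (is.null(gaps)) matrix(numeric(0), ncol = 2) else gaps
}

#' Per-pulse cavitation doses for a set of pulses
#'
#' @param pulses a `pulse_set` (see [gen_pcd()] / [read_pulse_set()]) or a
#'   list of numeric vectors.
#' @param plan a [band_plan()].
#' @param fs sampling rate, required when `pulses` is a bare list.
#' @param window spectral window, see [pulse_spectrum()].
#' @return data frame `pulse`, `scdh`, `scdu`, `icd`.
#' @export
cavitation_doses <- function(pulses, plan = band_plan(), fs = NULL,
                             window = "rect") {
  if (inherits(pulses, "pulse_set")) {
    fs <- pulses$fs
    pulses <- pulses$pulses
  }
  if (is.null(fs)) stop("fs is required when pulses is a plain list")
  rows <- lapply(seq_along(pulses), function(i) {
    sp <- pulse_spectrum(pulses[[i]], fs, window = window)
    data.frame(pulse = i,
               scdh = scd(sp, plan, "harmonic"),
               scdu = scd(sp, plan, "ultraharmonic"),
               icd = icd(sp, plan))
  })
  do.call(rbind, rows)
}

#' Normalise cavitation doses against a microbubble-free baseline
#'
#' Per metric, the per-sonication aggregate (mean over pulses) with
#' microbubbles is divided by the aggregate without microbubbles, giving
#' the unitless normalised doses reported per animal.
#'
#' @param with_mb,baseline data frames from [cavitation_doses()].
#' @return named numeric vector `scdh`, `scdu`, `icd`.
#' @export
normalize_doses <- function(with_mb, baseline) {
  metrics <- c("scdh", "scdu", "icd")
  stopifnot(all(metrics %in% names(with_mb)), all(metrics %in% names(baseline)))
  if (!nrow(with_mb) || !nrow(baseline)) stop("empty pulse list")
  vapply(metrics, function(m) {
    b <- mean(baseline[[m]])
    if (b <= 0) stop("baseline aggregate for ", m, " is zero; cannot normalise")
    mean(with_mb[[m]]) / b
  }, numeric(1))
}
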