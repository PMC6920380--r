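# fs and duration chosen so every harmonic/ultraharmonic of f0 = 1.5 MHz
# falls on an exact FFT bin (bin width 5 kHz)
fs0 <- 5e7
n0 <- 10000
tone <- function(f, a = 1, n = n0) a * sin(2 * pi * f * (0:(n - 1)) / fs0)

test_that("pulse spectrum is Parseval-normalised and linear", {
  sp0 <- pulse_spectrum(rep(0, 128), fs0)
  expect_true(all(sp0$mag == 0))

  x <- tone(3e6)
  sp <- pulse_spectrum(x, fs0)
  expect_equal(band_rms(sp, cbind(2.9e6, 3.1e6)), 1 / sqrt(2),
               tolerance = 1e-6)
  # full-band spectral RMS = time-domain RMS (Parseval)
  expect_equal(sqrt(sum(sp$mag^2)), sqrt(mean(x^2)), tolerance = 1e-9)

  # additivity of spectra for tones on distinct bins
  y <- tone(4.5e6, 0.5)
  sp_sum <- pulse_spectrum(x + y, fs0)
  expect_equal(sp_sum$mag, pulse_spectrum(x, fs0)$mag + pulse_spectrum(y, fs0)$mag,
               tolerance = 1e-9)

  expect_error(pulse_spectrum(c(x[1:100], NA), fs0), "finite")
  expect_error(pulse_spectrum(x[1:10], fs0), "64")
})

test_that("band plan enumerates harmonic and ultraharmonic windows", {
  pl <- band_plan()
  expect_equal(pl$harmonic_centers / 1e6, c(3.0, 4.5, 6.0, 7.5, 9.0))
  expect_equal(pl$ultraharmonic_centers / 1e6, c(3.75, 5.25, 6.75, 8.25))

  pl2 <- band_plan(f0 = 2e6)
  expect_equal(pl2$harmonic_centers / 1e6, c(4, 6, 8))

  expect_error(band_plan(half_width = 1.5e6 / 4), "half_width")
  expect_error(band_plan(f_lo = 9e6, f_hi = 3e6), "f_lo")

  # windows clipped to the band and disjoint between kinds
  expect_true(all(pl$harmonic_windows >= 3e6 & pl$harmonic_windows <= 9e6))
  win <- rbind(pl$harmonic_windows, pl$ultraharmonic_windows)
  win <- win[order(win[, 1]), ]
  expect_true(all(diff(as.vector(t(win))) >= 0))
})

test_that("stable cavitation doses isolate their windows", {
  pl <- band_plan()
  sp <- pulse_spectrum(tone(3e6, 2), fs0)
  expect_equal(scd(sp, pl, "harmonic"), 2 / sqrt(2), tolerance = 1e-6)
  # leakage into the other windows stays below 1% of the harmonic value
  expect_lt(scd(sp, pl, "ultraharmonic"), 0.01 * scd(sp, pl, "harmonic"))
  expect_lt(icd(sp, pl), 0.01 * scd(sp, pl, "harmonic"))

  expect_equal(scd(pulse_spectrum(rep(0, n0), fs0), pl, "harmonic"), 0)

  # homogeneity: doubling the amplitude doubles every dose
  ps <- gen_pcd(pcd_sim_config(seed = 6, n_pulses = 1))
  sp1 <- pulse_spectrum(ps$pulses[[1]], ps$fs)
  sp2 <- pulse_spectrum(2 * ps$pulses[[1]], ps$fs)
  expect_equal(scd(sp2, pl, "harmonic"), 2 * scd(sp1, pl, "harmonic"))
  expect_equal(scd(sp2, pl, "ultraharmonic"), 2 * scd(sp1, pl, "ultraharmonic"))
  expect_equal(icd(sp2, pl), 2 * icd(sp1, pl))
})

test_that("inertial cavitation dose recovers band-limited noise", {
  pl <- band_plan()
  cfg <- pcd_sim_config(harmonics = numeric(0), ultraharmonics = numeric(0),
                        broadband_sd = 0.3, sensor_sd = 0, n_pulses = 1,
                        duration = 4e-4, seed = 21)
  ps <- gen_pcd(cfg)
  sp <- pulse_spectrum(ps$pulses[[1]], ps$fs)
  analytic <- noise_band_rms(0.3, ps$fs, band_complement(pl))
  expect_equal(icd(sp, pl), analytic, tolerance = 0.05)
  expect_equal(icd(pulse_spectrum(rep(0, n0), fs0), pl), 0)
})

test_that("component doses add up for a composite signal", {
  pl <- band_plan()
  withr::with_seed(31, {
    noise <- stats::rnorm(n0, sd = 0.25)
  })
  bl_noise <- {
    X <- stats::fft(noise)
    f <- (0:(n0 - 1)) * fs0 / n0
    fa <- pmin(f, fs0 - f)
    X[!(fa >= 3e6 & fa < 9e6)] <- 0
    Re(stats::fft(X, inverse = TRUE)) / n0
  }
  x <- tone(4.5e6, 1.2) + tone(5.25e6, 0.4) + bl_noise
  sp <- pulse_spectrum(x, fs0)
  noise_h <- noise_band_rms(0.25, fs0, band_plan()$harmonic_windows)
  expect_equal(scd(sp, pl, "harmonic"),
               sqrt((1.2 / sqrt(2))^2 + noise_h^2), tolerance = 0.05)
  expect_equal(scd(sp, pl, "ultraharmonic"),
               sqrt((0.4 / sqrt(2))^2 +
                      noise_band_rms(0.25, fs0, pl$ultraharmonic_windows)^2),
               tolerance = 0.05)
  expect_equal(icd(sp, pl), noise_band_rms(0.25, fs0, band_complement(pl)),
               tolerance = 0.05)
})

test_that("doses match generator ground truth over a seeded sweep", {
  pl <- band_plan()
  for (seed in 1:10) {
    amp_h <- 0.5 + 0.1 * seed
    amp_u <- 0.2 + 0.02 * seed
    cfg <- pcd_sim_config(harmonics = c("2" = amp_h, "4" = amp_h / 2),
                          ultraharmonics = c("2.5" = amp_u),
                          broadband_sd = 0.02, sensor_sd = 0.005,
                          n_pulses = 1, seed = seed)
    ps <- gen_pcd(cfg)
    dd <- cavitation_doses(ps, pl)
    expect_equal(dd$scdh, ps$truth$harmonic_rms, tolerance = 0.05)
    expect_equal(dd$scdu, ps$truth$ultraharmonic_rms, tolerance = 0.05)
    expect_equal(dd$icd,
                 noise_band_rms(cfg$broadband_sd, cfg$fs, band_complement(pl)),
                 tolerance = 0.25)
  }
})

test_that("dose normalisation divides by the baseline aggregate", {
  ps <- gen_pcd(pcd_sim_config(seed = 2, n_pulses = 3))
  dd <- cavitation_doses(ps)
  expect_equal(unname(normalize_doses(dd, dd)), c(1, 1, 1))

  ps2 <- ps
  ps2$pulses <- lapply(ps$pulses, function(p) 2 * p)
  dd2 <- cavitation_doses(ps2)
  expect_equal(unname(normalize_doses(dd2, dd)), c(2, 2, 2), tolerance = 1e-9)

  expect_error(normalize_doses(dd[0, ], dd), "empty")
  zero <- dd; zero$scdu <- 0
  expect_error(normalize_doses(dd, zero), "scdu")

  # invariance to pulse ordering
  expect_equal(unname(normalize_doses(dd2[c(3, 1, 2), ], dd)),
               unname(normalize_doses(dd2, dd)))
})
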