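test_that("histology simulator stores exact ground truth and is seed-reproducible", {
  cfg <- histology_sim_config(
    rois = default_striatum_rois(frac_ipsi = 0.30, frac_contra = 0.25),
    seed = 7
  )
  sec <- gen_histology(cfg)
  fr <- sec$truth$fraction
  expect_equal(fr[sec$truth$hemisphere == "ipsi"], 0.30)
  expect_equal(fr[sec$truth$hemisphere == "contra"], 0.25)
  expect_equal(fr[1] / fr[2], 1.2)
  expect_equal(sec$truth$n_positive, as.integer(round(fr * sec$truth$n_pixels)))

  sec2 <- gen_histology(cfg)
  expect_identical(sec$image, sec2$image)
  expect_identical(sec$mask, sec2$mask)

  sec3 <- gen_histology(histology_sim_config(
    rois = default_striatum_rois(frac_ipsi = 0.30, frac_contra = 0.25),
    seed = 8
  ))
  expect_false(identical(sec$image, sec3$image))
})

test_that("histology forward model round-trips through OD deconvolution", {
  # zero noise, float mode: deconvolving the image must recover the
  # simulated per-stain concentration maps to 1e-6
  cfg <- histology_sim_config(noise_sd = 0, quantize = FALSE, seed = 3)
  sec <- gen_histology(cfg)
  od <- rgb_to_od(sec$image, white_point = cfg$white_point)
  conc <- deconvolve(od, hdab_stain_matrix(), clip = FALSE)
  expect_lt(max(abs(conc[, , "dab"] - sec$concentrations$dab)), 1e-6)
  expect_lt(max(abs(conc[, , "hematoxylin"] - sec$concentrations$hematoxylin)),
            1e-6)
  expect_lt(max(abs(conc[, , "residual"])), 1e-6)

  # 8-bit mode: recovery within one OD quantization step at the darkest
  # simulated intensity
  cfg8 <- histology_sim_config(noise_sd = 0, quantize = TRUE, seed = 3)
  sec8 <- gen_histology(cfg8)
  darkest <- min(sec8$image[sec8$image > 0])
  quant_step <- -log10((darkest - 0.5) / 255) + log10((darkest + 0.5) / 255)
  od8 <- rgb_to_od(sec8$image, white_point = cfg8$white_point)
  conc8 <- deconvolve(od8, clip = FALSE)
  expect_lt(max(abs(conc8[, , "dab"] - sec8$concentrations$dab)),
            3 * quant_step)
})

test_that("histology simulator rejects invalid configurations", {
  rois <- default_striatum_rois()
  rois$fraction[1] <- 1.5
  expect_error(histology_sim_config(rois = rois), "fraction")
  rois <- default_striatum_rois()
  rois$col1[1] <- 10000
  expect_error(histology_sim_config(rois = rois), "bounds")
  overlapping <- default_striatum_rois()
  overlapping$col0[2] <- overlapping$col0[1]
  overlapping$col1[2] <- overlapping$col1[1]
  expect_error(gen_histology(histology_sim_config(rois = overlapping)),
               "overlap")
})

test_that("pcd simulator matches analytic component RMS values", {
  # single tone at 2*f0, amplitude A, no noise -> harmonic RMS A/sqrt(2)
  cfg <- pcd_sim_config(harmonics = c("2" = 0.8), ultraharmonics = numeric(0),
                        broadband_sd = 0, sensor_sd = 0, n_pulses = 1)
  ps <- gen_pcd(cfg)
  expect_equal(ps$truth$harmonic_rms, 0.8 / sqrt(2))
  expect_equal(sqrt(mean(ps$pulses[[1]]^2)), 0.8 / sqrt(2), tolerance = 1e-6)

  # all amplitudes zero, no noise -> all-zero pulse
  cfg0 <- pcd_sim_config(harmonics = numeric(0), ultraharmonics = numeric(0),
                         broadband_sd = 0, sensor_sd = 0, n_pulses = 1)
  ps0 <- gen_pcd(cfg0)
  expect_true(all(ps0$pulses[[1]] == 0))
  expect_equal(ps0$truth$harmonic_rms, 0)
  expect_equal(ps0$truth$broadband_inband_rms, 0)

  # broadband only: time-domain RMS of the band-limited realization is
  # within 1% of the analytic in-band RMS
  cfgb <- pcd_sim_config(harmonics = numeric(0), ultraharmonics = numeric(0),
                         broadband_sd = 0.2, sensor_sd = 0, n_pulses = 1,
                         duration = 1e-3, seed = 11)
  psb <- gen_pcd(cfgb)
  expect_equal(sqrt(mean(psb$pulses[[1]]^2)), psb$truth$broadband_inband_rms,
               tolerance = 0.01)
})

test_that("pcd simulator rejects aliasing and is seed-reproducible", {
  expect_error(pcd_sim_config(harmonics = c("40" = 1)), "liasing")
  cfg <- pcd_sim_config(seed = 5, n_pulses = 2)
  expect_identical(gen_pcd(cfg)$pulses, gen_pcd(cfg)$pulses)
})

test_that("rotation simulator constructs the requested turns", {
  # 3 CW, 0 CCW, zero jitter: monotone decreasing heading sweep
  tr <- gen_rotation(rotation_sim_config(3, 0, jitter_sd = 0, duration = 600))
  theta <- unwrap_heading(tr$heading, tr$time)
  expect_true(all(diff(theta) <= 0))
  expect_lt(min(theta) - theta[1], -1080)
  expect_identical(tr$truth, list(cw = 3L, ccw = 0L, net = 3L))

  tr2 <- gen_rotation(rotation_sim_config(2, 1, jitter_sd = 0, duration = 600))
  expect_identical(tr2$truth$net, 1L)

  cfg <- rotation_sim_config(4, 2, seed = 9, duration = 600)
  expect_identical(gen_rotation(cfg)$heading, gen_rotation(cfg)$heading)
  expect_error(rotation_sim_config(3, 1, jitter_sd = 30), "jitter")
})

test_that("dose arithmetic reproduces the session and study masses", {
  d <- session_dose(dose_spec())
  expect_equal(d$session_mass_mg, 0.40008)
  expect_equal(d$session_mass_mg, 0.4, tolerance = 0.001)
  expect_equal(d$study_mass_mg, d$session_mass_mg * 3)
  expect_equal(d$study_mass_mg, 1.2, tolerance = 0.001)
  expect_equal(d$droplets, 8)
  expect_equal(session_dose(dose_spec(session_volume_ul = 0))$session_mass_mg, 0)
  expect_error(dose_spec(concentration_mg_ml = 0))
})

test_that("generated pulses satisfy Parseval to 0.5%", {
  ps <- gen_pcd(pcd_sim_config(seed = 2, n_pulses = 3))
  for (p in ps$pulses) {
    sp <- pulse_spectrum(p, ps$fs)
    spectral <- sqrt(sum(sp$mag^2))
    expect_equal(spectral, sqrt(mean(p^2)), tolerance = 0.005)
  }
})
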