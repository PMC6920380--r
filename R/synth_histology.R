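#' Configuration for the brightfield histology simulator
#'
#' Describes a synthetic DAB/hematoxylin-stained coronal section: image
#' geometry, rectangular regions of interest (ROIs) per hemisphere, the
#' ground-truth TH+ pixel fraction per ROI, and the optical model.
#'
#' The forward model is Beer-Lambert: each pixel's OD vector is
#' `c_hema * H + c_dab * D` (+ optional Gaussian OD noise) and the emitted
#' intensity is `I_c = I0_c * 10^(-OD_c)`. TH+ pixels are a spatially random
#' subset of each ROI at the requested fraction, so the area-fraction ground
#' truth is exact by construction. Pixels outside every ROI are bare glass
#' (zero stain), which is what the white-balance step keys on.
#'
#' @param width,height image size in pixels.
#' @param rois data frame with columns `region`, `hemisphere`
#'   (`"ipsi"`/`"contra"`), `row0`, `row1`, `col0`, `col1` (inclusive pixel
#'   bounds) and `fraction` (TH+ pixel fraction in `[0, 1]`).
#' @param dab_od OD amplitude of the DAB stain on TH+ pixels.
#' @param hema_od hematoxylin background OD inside tissue (all ROI pixels).
#' @param noise_sd SD of additive Gaussian noise applied per pixel per OD
#'   channel; `0` for noise-free sections.
#' @param white_point length-3 incident white intensity `I0` per channel,
#'   each in `(0, 255]`.
#' @param quantize logical; `TRUE` rounds intensities to 8-bit integers
#'   (the realistic camera model), `FALSE` keeps doubles for exact
#'   round-trip tests.
#' @param seed integer random seed; identical seeds give bit-identical
#'   sections.
#' @return A list of class `histology_sim_config`.
#' @export
histology_sim_config <- function(width = 160, height = 120,
                                 rois = default_striatum_rois(width, height),
                                 dab_od = 1.0, hema_od = 0.3,
                                 noise_sd = 0,
                                 white_point = c(255, 255, 255),
                                 quantize = TRUE, seed = 1L) {
  need <- c("region", "hemisphere", "row0", "row1", "col0", "col1", "fraction")
  if (!is.data.frame(rois) || !all(need %in% names(rois))) {
    stop("rois must be a data frame with columns ", paste(need, collapse = ", "))
  }
  if (any(rois$fraction < 0 | rois$fraction > 1)) {
    stop("TH+ fractions must lie in [0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(white_point) != 3 || any(white_point <= 0) || any(white_point > 255)) {
    stop("white_point must be three values in (0, 255]")
  }
  if (any(rois$row0 < 1 | rois$col0 < 1 | rois$row1 > height | rois$col1 > width |
            rois$row0 > rois$row1 | rois$col0 > rois$col1)) {
    stop("ROI rectangles must be non-empty and inside the image bounds")
  }
  cfg <- list(
    width = as.integer(width), height = as.integer(height), rois = rois,
    dab_od = dab_od, hema_od = hema_od, noise_sd = noise_sd,
    white_point = white_point, quantize = isTRUE(quantize),
    seed = as.integer(seed)
  )
  class(cfg) <- "histology_sim_config"
  cfg
}

#' Default two-hemisphere striatum ROI layout
#'
#' Places one rectangular striatal ROI per hemisphere with a glass margin
#' around the tissue (ipsilateral on the left half of the image, following
#' the convention that the treated hemisphere is the left one).
#'
#' @param width,height image size in pixels.
#' @param frac_ipsi,frac_contra ground-truth TH+ fractions for the two ROIs.
#' @return ROI data frame suitable for [histology_sim_config()].
#' @export
default_striatum_rois <- function(width = 160, height = 120,
                                  frac_ipsi = 0.30, frac_contra = 0.25) {
  half <- width %/% 2
  rh <- round(height * 5 / 12)            # 50 rows at the default height
  rw <- round(half * 0.5)                 # 40 cols at the default width
  r0 <- round(height * 0.2)
  c0 <- round(half * 0.2)
  data.frame(
    region = "striatum",
    hemisphere = c("ipsi", "contra"),
    row0 = r0, row1 = r0 + rh - 1,
    col0 = c(c0, half + c0),
    col1 = c(c0, half + c0) + rw - 1,
    fraction = c(frac_ipsi, frac_contra),
    stringsAsFactors = FALSE
  )
}

#' ROI layout for the substantia nigra (SNc + SNr)
#'
#' Four rectangles: pars compacta and pars reticulata in each hemisphere.
#'
#' @param width,height image size in pixels.
#' @param fractions named vector with entries `snc_ipsi`, `snc_contra`,
#'   `snr_ipsi`, `snr_contra`.
#' @return ROI data frame suitable for [histology_sim_config()].
#' @export
default_sn_rois <- function(width = 160, height = 120,
                            fractions = c(snc_ipsi = 0.30, snc_contra = 0.30,
                                          snr_ipsi = 0.25, snr_contra = 0.25)) {
  half <- width %/% 2
  r0 <- round(height * 0.15)
  mk <- function(region, hemi, rowoff, frac) {
    c0 <- if (hemi == "ipsi") round(half * 0.2) else half + round(half * 0.2)
    data.frame(region = region, hemisphere = hemi,
               row0 = r0 + rowoff, row1 = r0 + rowoff + 29,
               col0 = c0, col1 = c0 + 39, fraction = frac,
               stringsAsFactors = FALSE)
  }
  rbind(
    mk("SNc", "ipsi", 0, fractions[["snc_ipsi"]]),
    mk("SNc", "contra", 0, fractions[["snc_contra"]]),
    mk("SNr", "ipsi", 40, fractions[["snr_ipsi"]]),
    mk("SNr", "contra", 40, fractions[["snr_contra"]])
  )
}

#' Simulate a stained brightfield section with known ground truth
#'
#' Runs the Beer-Lambert forward model described in
#' [histology_sim_config()] and returns the RGB image, an integer ROI label
#' mask, the label legend, the exact per-ROI TH+ ground truth, and the
#' simulated per-stain concentration maps (kept for round-trip tests).
#'
#' @param config a [histology_sim_config()].
#' @param stains a [stain_matrix()].
#' @param mouse,section identifiers carried into the output metadata.
#' @return A list of class `section_image` with elements `image`
#'   (height x width x 3 array on the 0-255 scale), `mask` (integer matrix,
#'   0 = background), `legend` (data frame `label`, `region`, `hemisphere`),
#'   `truth` (data frame with the realised TH+ fraction per ROI),
#'   `concentrations` (list of hematoxylin/dab matrices), `white_point`,
#'   `mouse`, `section`.
#' @export
gen_histology <- function(config, stains = hdab_stain_matrix(),
                          mouse = "m1", section = 1L) {
  stopifnot(inherits(config, "histology_sim_config"))
  rois <- config$rois
  h <- config$height; w <- config$width
  mask <- matrix(0L, h, w)
  for (i in seq_len(nrow(rois))) {
    blk <- mask[rois$row0[i]:rois$row1[i], rois$col0[i]:rois$col1[i]]
    if (any(blk != 0L)) stop("ROIs overlap: ", rois$region[i], "/", rois$hemisphere[i])
    mask[rois$row0[i]:rois$row1[i], rois$col0[i]:rois$col1[i]] <- i
  }

  c_hema <- matrix(0, h, w)
  c_dab <- matrix(0, h, w)
  truth <- rois[, c("region", "hemisphere")]
  truth$n_pixels <- 0L; truth$n_positive <- 0L; truth$fraction <- NA_real_

  withr::with_seed(config$seed, {
    for (i in seq_len(nrow(rois))) {
      idx <- which(mask == i)
      n <- length(idx)
      npos <- round(rois$fraction[i] * n)
      pos <- if (npos > 0) sample(idx, npos) else integer(0)
      c_hema[idx] <- config$hema_od
      c_dab[pos] <- config$dab_od
      truth$n_pixels[i] <- n
      truth$n_positive[i] <- as.integer(npos)
      truth$fraction[i] <- npos / n
    }
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      od <- c_hema * stains["hematoxylin", ch] + c_dab * stains["dab", ch]
      if (config$noise_sd > 0) {
        od <- od + matrix(stats::rnorm(h * w, sd = config$noise_sd), h, w)
      }
      img[, , ch] <- config$white_point[ch] * 10^(-od)
    }
    if (config$quantize) {
      img <- round(pmin(pmax(img, 0), 255))
    }
    out <- list(
      image = img, mask = mask,
      legend = data.frame(label = seq_len(nrow(rois)),
                          region = rois$region, hemisphere = rois$hemisphere,
                          stringsAsFactors = FALSE),
      truth = truth,
      concentrations = list(hematoxylin = c_hema, dab = c_dab),
      white_point = config$white_point,
      mouse = mouse, section = section
    )
  })
  class(out) <- "section_image"
  out
}
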