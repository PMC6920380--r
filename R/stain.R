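#' White balance a brightfield image
#'
#' Estimates the incident white point `I0` per channel as an upper
#' percentile of that channel's intensities (robust to specular or
#' saturated pixels) and rescales so that the estimated white point maps
#' to 255. Brightfield sections include bare glass around the tissue, so
#' the upper tail of each channel is a direct estimate of `I0`.
#'
#' @param image height x width x 3 numeric array on the 0-255 scale.
#' @param percentile percentile (in `(50, 100]`) used to estimate the
#'   white point; default 99.
#' @return list with `image` (rescaled, clipped to `[0, 255]`, not
#'   re-quantized) and `white_point` (the pre-scaling estimate of `I0`).
#' @export
white_balance <- function(image, percentile = 99) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  if (percentile <= 50 || percentile > 100) {
    stop("percentile must be in (50, 100]")
  }
  wp <- vapply(1:3, function(ch) {
    stats::quantile(image[, , ch], percentile / 100, names = FALSE)
  }, numeric(1))
  if (any(wp <= 0)) stop("white point undefined: a channel is uniformly zero")
  out <- image
  for (ch in 1:3) out[, , ch] <- pmin(pmax(image[, , ch] * 255 / wp[ch], 0), 255)
  list(image = out, white_point = wp)
}

#' Convert intensities to optical density
#'
#' Beer-Lambert transform `OD_c = -log10(max(I_c, eps) / I0_c)`. The
#' `eps` floor (one intensity unit) keeps the transform finite at I = 0.
#'
#' @param image height x width x 3 array of intensities.
#' @param white_point length-3 incident intensity `I0` per channel
#'   (after [white_balance()] this is `c(255, 255, 255)`).
#' @param eps intensity floor guarding the logarithm.
#' @return height x width x 3 OD array.
#' @export
rgb_to_od <- function(image, white_point = c(255, 255, 255), eps = 1) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3,
            length(white_point) == 3, all(white_point > 0))
  od <- array(0, dim = dim(image))
  for (ch in 1:3) {
    od[, , ch] <- -log10(pmax(image[, , ch], eps) / white_point[ch])
  }
  od
}

#' Colour deconvolution in OD space
#'
#' Inverts the stain matrix per pixel: `concentrations = OD %*% M^-1`.
#' Small negative concentrations (noise outside the stain simplex) are
#' clipped to zero by default.
#'
#' @param od height x width x 3 OD array.
#' @param stains a [stain_matrix()].
#' @param clip clip negative concentrations to 0 (default `TRUE`).
#' @return height x width x 3 array; the third dimension is named
#'   `hematoxylin`, `dab`, `residual`.
#' @export
deconvolve <- function(od, stains = hdab_stain_matrix(), clip = TRUE) {
  stopifnot(length(dim(od)) == 3, dim(od)[3] == 3)
  Minv <- solve(unclass(stains))
  d <- dim(od)
  flat <- matrix(od, ncol = 3) %*% Minv
  if (clip) flat[flat < 0] <- 0
  out <- array(flat, dim = d)
  dimnames(out) <- list(NULL, NULL, rownames(stains))
  out
}

#' DAB concentration to analysis grayscale
#'
#' Affine, order-reversing map `gray = g_max - (g_max / od_max) * dab`, so
#' that strongly stained (high-DAB) pixels are dark, matching the
#' "dark DAB pixels below the threshold" convention. The map is not
#' clipped, so it is exactly invertible.
#'
#' @param dab matrix of DAB concentrations (OD units).
#' @param od_max DAB concentration mapped to gray 0; default 2.
#' @param g_max gray value of a DAB-free pixel; default 255.
#' @return matrix of gray values.
#' @export
dab_gray <- function(dab, od_max = 2, g_max = 255) {
  stopifnot(od_max > 0, all(is.finite(dab)))
  g_max - (g_max / od_max) * dab
}

#' Pooled-statistics threshold for one ROI region on one section
#'
#' The ipsilateral and contralateral pixels of a region are pooled and the
#' threshold set half a standard deviation below the pooled mean:
#' `T = mean - 0.5 * SD` with the sample (n-1) SD. Each region on each
#' section gets its own threshold, absorbing section-to-section variation
#' in DAB colour development.
#'
#' @param ipsi_pixels,contra_pixels gray values from the two hemispheres.
#' @return the threshold (gray units).
#' @export
pooled_threshold <- function(ipsi_pixels, contra_pixels) {
  pooled <- c(ipsi_pixels, contra_pixels)
  if (length(pooled) < 2) stop("need at least 2 pooled pixels")
  mean(pooled) - 0.5 * stats::sd(pooled)
}

#' TH+ area fraction of one ROI
#'
#' Counts pixels strictly below the threshold and normalises by the ROI
#' area.
#'
#' @param roi_pixels gray values of the ROI.
#' @param threshold threshold from [pooled_threshold()].
#' @return list with `threshold`, `th_pixels`, `roi_pixels`, `fraction`.
#' @export
th_area <- function(roi_pixels, threshold) {
  n <- length(roi_pixels)
  if (n == 0) stop("empty ROI")
  k <- sum(roi_pixels < threshold)
  list(threshold = threshold, th_pixels = as.integer(k),
       roi_pixels = as.integer(n), fraction = k / n)
}

#' Ipsilateral / contralateral area ratio
#'
#' @param ipsi_fraction,contra_fraction TH+ area fractions.
#' @return `ipsi_fraction / contra_fraction`.
#' @export
area_ratio <- function(ipsi_fraction, contra_fraction) {
  if (any(contra_fraction <= 0)) {
    stop("contralateral fraction is zero: ratio undefined")
  }
  ipsi_fraction / contra_fraction
}

#' Quantify TH+ staining on one section
#'
#' Full per-section pipeline: white balance, OD transform, colour
#' deconvolution, DAB grayscale, then one pooled threshold per region
#' (ipsi + contra pixels combined) and per-hemisphere TH+ area fractions.
#'
#' @param section a `section_image` (from [gen_histology()] or
#'   [read_section()]): list with `image`, `mask`, `legend`, `mouse`,
#'   `section`.
#' @param stains a [stain_matrix()].
#' @param percentile white-balance percentile, see [white_balance()].
#' @param od_max grayscale mapping limit, see [dab_gray()].
#' @return data frame with one row per (region, hemisphere):
#'   `mouse`, `region`, `hemisphere`, `section`, `threshold`, `th_pixels`,
#'   `roi_pixels`, `fraction`.
#' @export
quantify_section <- function(section, stains = hdab_stain_matrix(),
                             percentile = 99, od_max = 2) {
  wb <- white_balance(section$image, percentile)
  od <- rgb_to_od(wb$image, white_point = c(255, 255, 255))
  conc <- deconvolve(od, stains)
  gray <- dab_gray(conc[, , "dab"], od_max = od_max)

  legend <- section$legend
  rows <- list()
  for (region in unique(legend$region)) {
    lab_i <- legend$label[legend$region == region & legend$hemisphere == "ipsi"]
    lab_c <- legend$label[legend$region == region & legend$hemisphere == "contra"]
    if (length(lab_i) != 1 || length(lab_c) != 1) {
      stop("region ", region, " must have exactly one ipsi and one contra ROI")
    }
    px_i <- gray[section$mask == lab_i]
    px_c <- gray[section$mask == lab_c]
    if (!length(px_i) || !length(px_c)) stop("empty ROI for region ", region)
    thr <- pooled_threshold(px_i, px_c)
    for (hemi in c("ipsi", "contra")) {
      q <- th_area(if (hemi == "ipsi") px_i else px_c, thr)
      rows[[length(rows) + 1L]] <- data.frame(
        mouse = section$mouse, region = region, hemisphere = hemi,
        section = section$section, threshold = q$threshold,
        th_pixels = q$th_pixels, roi_pixels = q$roi_pixels,
        fraction = q$fraction, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Per-mouse summary of section-level quantifications
#'
#' For each region, averages the per-section TH+ fractions within each
#' hemisphere (unweighted mean over sections) and takes the ratio of the
#' two hemisphere means (ratio of means, not mean of per-section ratios;
#' more stable when the contralateral fraction is small).
#'
#' @param quants data frame from [quantify_section()], possibly rbind-ed
#'   over sections, for a single mouse.
#' @return data frame with one row per region: `mouse`, `region`,
#'   `ipsi_mean`, `contra_mean`, `ratio`.
#' @export
mouse_summary <- function(quants) {
  stopifnot(is.data.frame(quants))
  if (length(unique(quants$mouse)) != 1) stop("mouse_summary expects a single mouse")
  rows <- lapply(unique(quants$region), function(region) {
    sub <- quants[quants$region == region, ]
    mi <- sub$fraction[sub$hemisphere == "ipsi"]
    mc <- sub$fraction[sub$hemisphere == "contra"]
    if (!length(mi) || !length(mc)) {
      stop("region ", region, " has sections on one hemisphere only")
    }
    ipsi_mean <- mean(mi)
    contra_mean <- mean(mc)
    data.frame(mouse = sub$mouse[1], region = region,
               ipsi_mean = ipsi_mean, contra_mean = contra_mean,
               ratio = area_ratio(ipsi_mean, contra_mean),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
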