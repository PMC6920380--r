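#' Write a section image, label mask and legend to disk
#'
#' The image goes to an 8-bit RGB TIFF, the mask to a 16-bit
#' single-channel TIFF, and the legend (plus ground truth, when the
#' section came from the simulator) to a JSON sidecar.
#'
#' @param section a `section_image`.
#' @param dir output directory (created if missing).
#' @param stem file stem; defaults to `<mouse>_s<section>`.
#' @return invisibly, the paths written (`image`, `mask`, `legend`).
#' @export
write_section <- function(section, dir, stem = NULL) {
  if (is.null(stem)) stem <- sprintf("%s_s%s", section$mouse, section$section)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(image = file.path(dir, paste0(stem, ".tif")),
                mask = file.path(dir, paste0(stem, "_mask.tif")),
                legend = file.path(dir, paste0(stem, "_legend.json")))
  img <- round(pmin(pmax(section$image, 0), 255))
  tiff::writeTIFF(img / 255, paths$image, bits.per.sample = 8L)
  tiff::writeTIFF(section$mask / 65535, paths$mask, bits.per.sample = 16L)
  meta <- list(mouse = section$mouse, section = section$section,
               legend = section$legend)
  if (!is.null(section$truth)) meta$truth <- section$truth
  jsonlite::write_json(meta, paths$legend, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a section image written by [write_section()]
#'
#' @param image_path 8-bit RGB TIFF path.
#' @param mask_path 16-bit label-mask TIFF path.
#' @param legend_path JSON legend path.
#' @return a `section_image` list (`image` on the 0-255 scale, integer
#'   `mask`, `legend`, `mouse`, `section`, and `truth` when present).
#' @export
read_section <- function(image_path, mask_path, legend_path) {
  img <- tiff::readTIFF(image_path) * 255
  msk <- round(tiff::readTIFF(mask_path) * 65535)
  if (length(dim(msk)) == 3) msk <- msk[, , 1]
  storage.mode(msk) <- "integer"
  meta <- jsonlite::read_json(legend_path, simplifyVector = TRUE)
  out <- list(image = img, mask = msk, legend = meta$legend,
              mouse = meta$mouse, section = meta$section,
              truth = meta$truth)
  class(out) <- "section_image"
  out
}

#' Write a pulse set as float32 binary plus JSON sidecar
#'
#' Samples are concatenated pulse-by-pulse as 32-bit little-endian
#' floats; the sidecar records the sampling rate, pulse layout,
#' microbubble flag and seed.
#'
#' @param pulse_set a `pulse_set` from [gen_pcd()].
#' @param path output `.bin` path; the sidecar is `<path>.json`.
#' @return invisibly, list of the two paths.
#' @export
write_pulse_set <- function(pulse_set, path) {
  stopifnot(inherits(pulse_set, "pulse_set"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  for (p in pulse_set$pulses) {
    writeBin(as.numeric(p), con, size = 4L, endian = "little")
  }
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(
    fs_hz = pulse_set$fs, f0_hz = pulse_set$f0,
    n_pulses = length(pulse_set$pulses),
    samples_per_pulse = length(pulse_set$pulses[[1]]),
    microbubbles = pulse_set$microbubbles, seed = pulse_set$seed
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(list(signal = path, sidecar = sidecar))
}

#' Read a pulse set written by [write_pulse_set()]
#'
#' @param path `.bin` path; the sidecar is read from `<path>.json`.
#' @return a `pulse_set` (without simulator ground truth).
#' @export
read_pulse_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n_total <- meta$n_pulses * meta$samples_per_pulse
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = n_total, size = 4L, endian = "little")
  if (length(x) != n_total) stop("pulse binary shorter than sidecar declares")
  pulses <- split(x, rep(seq_len(meta$n_pulses), each = meta$samples_per_pulse))
  names(pulses) <- NULL
  structure(list(pulses = pulses, fs = meta$fs_hz, f0 = meta$f0_hz,
                 microbubbles = isTRUE(meta$microbubbles), seed = meta$seed,
                 truth = NULL),
            class = "pulse_set")
}

#' Write / read a rotation trace as CSV
#'
#' CSV dialect: comma-separated, header `time_s,heading_deg`, UTF-8,
#' '.' decimal separator.
#'
#' @param trace a `rotation_trace`.
#' @param path CSV path.
#' @return `write_rotation_trace`: invisibly, the path.
#' @export
write_rotation_trace <- function(trace, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(time_s = trace$time,
                              heading_deg = trace$heading),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rotation_trace
#' @param mouse,session identifiers attached to the read trace.
#' @return `read_rotation_trace`: a `rotation_trace`.
#' @export
read_rotation_trace <- function(path, mouse = NA_character_,
                                session = NA_character_) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "heading_deg") %in% names(df))) {
    stop("trace CSV must have columns time_s, heading_deg")
  }
  structure(list(time = df$time_s, heading = df$heading_deg,
                 mouse = mouse, session = session, truth = NULL),
            class = "rotation_trace")
}

#' Write an analysis table as CSV
#'
#' @param df data frame (e.g. from [quantify_section()],
#'   [mouse_summary()] or [cavitation_doses()]).
#' @param path CSV path.
#' @return invisibly, the path.
#' @export
write_table_csv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @return `read_table_csv`: the data frame.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
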