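# Known manifest keys and their defaults. `simulate` holds the
# synthetic-study parameters; `analysis` the pipeline parameters.
manifest_defaults <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "quantify", "stats"),
    simulate = list(
      groups = c("MPTP", "FUS", "IN+FUS"),
      effects = c(1, 1, 1.2),
      n_per_group = 7L,
      n_sections = 6L,
      image_width = 160L,
      image_height = 120L,
      frac_contra = 0.25,
      between_sd = 0.03,
      within_sd = 0.01,
      noise_sd = 0.03,
      dab_od = 1.0,
      hema_od = 0.3
    ),
    analysis = list(
      percentile = 99,
      od_max = 2,
      alpha = 0.05,
      grubbs_screen = FALSE,
      cw_sign = "neg",
      f0 = 1.5e6,
      band = c(3e6, 9e6),
      half_width = 1.5e5
    )
  )
}

#' Load and validate a study manifest
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON manifest, rejects unknown keys
#' at the top and section level, and fills documented defaults
#' (analysis percentile 99, alpha 0.05, etc.). The manifest round-trips
#' losslessly through [write_manifest()].
#'
#' @param path manifest file path.
#' @return list of class `study_manifest`.
#' @export
load_manifest <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- manifest_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown manifest key(s): ", paste(unknown, collapse = ", "))
  }
  man <- defaults
  for (k in names(raw)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      bad <- setdiff(names(raw[[k]]), names(defaults[[k]]))
      if (length(bad)) {
        stop("unknown key(s) in manifest section '", k, "': ",
             paste(bad, collapse = ", "))
      }
      man[[k]] <- utils::modifyList(defaults[[k]], raw[[k]])
    } else {
      man[[k]] <- raw[[k]]
    }
  }
  a <- man$analysis
  if (a$percentile <= 50 || a$percentile > 100) {
    stop("manifest analysis.percentile must be in (50, 100]")
  }
  if (a$alpha <= 0 || a$alpha >= 1) stop("manifest analysis.alpha must be in (0, 1)")
  if (!a$cw_sign %in% c("neg", "pos")) {
    stop("manifest analysis.cw_sign must be 'neg' or 'pos'")
  }
  s <- man$simulate
  if (length(s$effects) != length(s$groups)) {
    stop("manifest simulate.effects must match simulate.groups in length")
  }
  man$seed <- as.integer(man$seed)
  class(man) <- "study_manifest"
  man
}

#' @rdname load_manifest
#' @param manifest a `study_manifest`.
#' @return `write_manifest`: invisibly, the path.
#' @export
write_manifest <- function(manifest, path) {
  m <- unclass(manifest)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(m, path)
  } else {
    jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# Provenance sidecar: package version, parameters, input hashes, seed.
write_provenance <- function(path, params, inputs = character(0), seed = NA) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(list(
    tool = "neuroquant",
    version = as.character(utils::packageVersion("neuroquant")),
    parameters = params, input_md5 = hashes, seed = seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the synthetic-study pipeline described by a manifest
#'
#' Executes the requested stages in dependency order:
#' \describe{
#'   \item{simulate}{generates one synthetic stained section per mouse
#'     and section (TH+ fractions drawn as in [gen_group_study()], with
#'     the group's effect ratio applied to the ipsilateral hemisphere)
#'     and writes TIFF images, masks and legends.}
#'   \item{quantify}{reads the written sections back and runs
#'     [quantify_section()] and [mouse_summary()], writing the
#'     per-section and per-mouse CSV tables.}
#'   \item{stats}{runs [group_analysis()] on the per-mouse table and
#'     writes a results JSON.}
#' }
#' Every stage writes a provenance JSON (package version, parameters,
#' input hashes, seed). Reruns with identical inputs are bit-identical.
#'
#' @param manifest a `study_manifest` from [load_manifest()], or a path
#'   to one.
#' @param out_dir output directory.
#' @return invisibly, a list with the per-mouse table and (when the
#'   stats stage ran) the `group_analysis` results.
#' @export
run_pipeline <- function(manifest, out_dir) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  stopifnot(inherits(manifest, "study_manifest"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- manifest$simulate
  a <- manifest$analysis
  stages <- manifest$stages

  img_dir <- file.path(out_dir, "sections")
  section_index <- NULL

  if ("simulate" %in% stages) {
    withr::with_seed(manifest$seed, {
      midx <- 0L
      for (gi in seq_along(s$groups)) {
        for (m in seq_len(s$n_per_group)) {
          midx <- midx + 1L
          id <- sprintf("m%02d", midx)
          mu <- max(0.05, stats::rnorm(1, s$frac_contra, s$between_sd))
          for (sec in seq_len(s$n_sections)) {
            # per-section variation on top of the mouse-level fraction
            fi <- min(max(s$effects[gi] * mu +
                            stats::rnorm(1, sd = s$within_sd), 0), 1)
            fc <- min(max(mu + stats::rnorm(1, sd = s$within_sd), 0), 1)
            cfg <- histology_sim_config(
              width = s$image_width, height = s$image_height,
              rois = default_striatum_rois(s$image_width, s$image_height,
                                           frac_ipsi = fi, frac_contra = fc),
              dab_od = s$dab_od, hema_od = s$hema_od,
              noise_sd = s$noise_sd,
              seed = sample.int(.Machine$integer.max, 1)
            )
            section <- gen_histology(cfg, mouse = id, section = sec)
            paths <- write_section(section, img_dir)
            section_index <- rbind(section_index, data.frame(
              mouse = id, group = s$groups[gi], section = sec,
              image = paths$image, mask = paths$mask, legend = paths$legend,
              stringsAsFactors = FALSE
            ))
          }
        }
      }
    })
    write_table_csv(section_index, file.path(out_dir, "section_index.csv"))
    write_provenance(file.path(out_dir, "simulate_provenance.json"),
                     params = s, seed = manifest$seed)
  }

  results <- list()
  if ("quantify" %in% stages) {
    idx_path <- file.path(out_dir, "section_index.csv")
    if (!file.exists(idx_path)) {
      stop("stage 'quantify' failed: section_index.csv missing; ",
           "run the simulate stage or provide an index")
    }
    section_index <- read_table_csv(idx_path)
    missing <- !file.exists(section_index$image) |
      !file.exists(section_index$mask) | !file.exists(section_index$legend)
    if (any(missing)) {
      stop("stage 'quantify' failed: missing input file(s): ",
           paste(section_index$image[missing], collapse = ", "))
    }
    quants <- do.call(rbind, lapply(seq_len(nrow(section_index)), function(i) {
      sec <- read_section(section_index$image[i], section_index$mask[i],
                          section_index$legend[i])
      quantify_section(sec, percentile = a$percentile, od_max = a$od_max)
    }))
    per_mouse <- do.call(rbind, lapply(unique(quants$mouse), function(id) {
      ms <- mouse_summary(quants[quants$mouse == id, ])
      ms$group <- section_index$group[match(id, section_index$mouse)]
      ms
    }))
    write_table_csv(quants, file.path(out_dir, "roi_quants.csv"))
    write_table_csv(per_mouse, file.path(out_dir, "mouse_summary.csv"))
    write_provenance(file.path(out_dir, "quantify_provenance.json"),
                     params = a,
                     inputs = c(section_index$image, section_index$mask),
                     seed = manifest$seed)
    results$per_mouse <- per_mouse
  }

  if ("stats" %in% stages) {
    pm_path <- file.path(out_dir, "mouse_summary.csv")
    if (!file.exists(pm_path)) {
      stop("stage 'stats' failed: mouse_summary.csv missing; ",
           "run the quantify stage first")
    }
    per_mouse <- read_table_csv(pm_path)
    tab <- data.frame(mouse = per_mouse$mouse, group = per_mouse$group,
                      region = per_mouse$region,
                      ipsi = per_mouse$ipsi_mean,
                      contra = per_mouse$contra_mean,
                      ratio = per_mouse$ratio, stringsAsFactors = FALSE)
    ga <- group_analysis(tab, alpha = a$alpha,
                         grubbs_screen = isTRUE(a$grubbs_screen))
    res <- lapply(ga, function(r) list(
      group_means = as.list(r$group_means),
      group_sem = as.list(r$group_sem),
      paired_p = lapply(r$paired, function(x) x$p_value),
      anova = list(F = r$anova$statistic, df = r$anova$df,
                   p = r$anova$p_value),
      pairwise = r$pairwise,
      removed = r$removed$mouse
    ))
    jsonlite::write_json(res, file.path(out_dir, "group_stats.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    write_provenance(file.path(out_dir, "stats_provenance.json"),
                     params = list(alpha = a$alpha,
                                   grubbs_screen = a$grubbs_screen),
                     inputs = pm_path, seed = manifest$seed)
    results$group_analysis <- ga
  }

  invisible(results)
}
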