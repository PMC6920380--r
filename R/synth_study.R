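#' Simulate a three-group unilateral-treatment study table
#'
#' Forward-simulates per-mouse, per-section TH+ area fractions for a
#' study design with bilateral lesioning and unilateral treatment: each
#' mouse has a latent contralateral fraction drawn from a between-mouse
#' distribution, the ipsilateral fraction is the contralateral one
#' multiplied by the group's effect ratio, and every section adds
#' independent within-mouse measurement noise. Mouse-level values are
#' the section means per hemisphere and their ratio, exactly as
#' [mouse_summary()] computes them from real sections.
#'
#' Defaults mirror the study design this package targets: three groups
#' (lesion-only control, sonication-only control, treated) of 7 mice
#' with 6 sections each, a 1.2x ipsilateral effect in the treated group
#' only, contralateral fractions around 0.25, between-mouse SD 0.03 and
#' within-mouse (section) SD 0.01.
#'
#' @param effects named numeric vector of ipsi/contra effect ratios, one
#'   per group; names are the group labels.
#' @param n_per_group mice per group (recycled over groups).
#' @param n_sections sections per mouse.
#' @param contra_mean,between_sd mean and SD of the latent contralateral
#'   fraction across mice.
#' @param within_sd SD of the per-section measurement noise.
#' @param region region label carried into the table.
#' @param seed integer random seed.
#' @return list with `mice` (data frame `mouse`, `group`, `region`,
#'   `ipsi`, `contra`, `ratio`), `sections` (per-section data frame) and
#'   `truth` (the effect ratios).
#' @export
gen_group_study <- function(effects = c(MPTP = 1, FUS = 1, `IN+FUS` = 1.2),
                            n_per_group = 7L, n_sections = 6L,
                            contra_mean = 0.25, between_sd = 0.03,
                            within_sd = 0.01, region = "striatum",
                            seed = 1L) {
  stopifnot(length(effects) >= 2, !is.null(names(effects)),
            all(effects > 0), n_per_group >= 2, n_sections >= 1,
            contra_mean > 0, between_sd >= 0, within_sd >= 0)
  n_per_group <- rep_len(as.integer(n_per_group), length(effects))

  withr::with_seed(seed, {
    mice <- NULL
    sections <- NULL
    midx <- 0L
    for (gi in seq_along(effects)) {
      g <- names(effects)[gi]
      for (m in seq_len(n_per_group[gi])) {
        midx <- midx + 1L
        id <- sprintf("m%02d", midx)
        mu <- max(0.05, stats::rnorm(1, contra_mean, between_sd))
        contra_s <- mu + stats::rnorm(n_sections, sd = within_sd)
        ipsi_s <- effects[gi] * mu + stats::rnorm(n_sections, sd = within_sd)
        contra_s <- pmin(pmax(contra_s, 0), 1)
        ipsi_s <- pmin(pmax(ipsi_s, 0), 1)
        sections <- rbind(sections, data.frame(
          mouse = id, group = g, region = region,
          section = seq_len(n_sections),
          ipsi = ipsi_s, contra = contra_s, stringsAsFactors = FALSE
        ))
        mice <- rbind(mice, data.frame(
          mouse = id, group = g, region = region,
          ipsi = mean(ipsi_s), contra = mean(contra_s),
          ratio = area_ratio(mean(ipsi_s), mean(contra_s)),
          stringsAsFactors = FALSE
        ))
      }
    }
    list(mice = mice, sections = sections, truth = effects)
  })
}
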