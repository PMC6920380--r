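#' Two-tailed paired Student's t-test
#'
#' Thin, validated wrapper around [stats::t.test()] returning the uniform
#' result structure used throughout the package.
#'
#' @param a,b paired measurement vectors of equal length, `n >= 2`.
#' @param alpha significance level; default 0.05.
#' @return list of class `nq_test`: `statistic` (t), `df`, `p_value`,
#'   `p_adjusted` (`NA` here), `significant`, `degenerate` (`FALSE`),
#'   `method`.
#' @export
paired_t <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2) stop("paired t-test needs n >= 2")
  d <- a - b
  if (stats::sd(d) == 0) {
    stop("zero standard deviation of differences: paired t undefined")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  nq_test(statistic = unname(tt$statistic), df = unname(tt$parameter),
          p_value = tt$p.value, alpha = alpha, method = "paired t")
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA via [stats::aov()]; also returns
#' the within-group mean square, which the Holm-Sidak pairwise follow-up
#' uses for pooled-variance comparisons.
#'
#' @param groups list of numeric vectors, one per group; at least two
#'   groups of `n >= 2` each.
#' @param alpha significance level; default 0.05.
#' @return `nq_test` with `statistic` (F), `df` (numerator, denominator),
#'   `p_value`, plus `ms_within` and the group `means` and sizes `n`.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("ANOVA needs at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("every group needs n >= 2")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1))))
  )
  if (stats::var(df$value) == 0) {
    stop("all values identical: ANOVA undefined")
  }
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  res <- nq_test(statistic = tab["group", "F value"],
                 df = c(tab["group", "Df"], tab["Residuals", "Df"]),
                 p_value = tab["group", "Pr(>F)"], alpha = alpha,
                 method = "one-way ANOVA")
  res$ms_within <- tab["Residuals", "Mean Sq"]
  res$means <- vapply(groups, mean, numeric(1))
  res$n <- vapply(groups, length, integer(1))
  res
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sorts the raw p-values ascending, applies the Sidak adjustment
#' `1 - (1 - p_(i))^(m - i + 1)` at each step, enforces monotone
#' non-decreasing adjusted values down the sorted list, and maps back to
#' the input order. Rejection follows the step-down rule, which with the
#' monotone adjusted values reduces to `adjusted < alpha`.
#'
#' @param p raw p-values in `[0, 1]`.
#' @param alpha significance level; default 0.05.
#' @return list with `adjusted` (same order as input) and `reject`
#'   (logical).
#' @export
holm_sidak <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must be in [0, 1]")
  m <- length(p)
  ord <- order(p)
  adj_sorted <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj_sorted <- cummax(adj_sorted)
  adjusted <- numeric(m)
  adjusted[ord] <- adj_sorted
  list(adjusted = adjusted, reject = adjusted < alpha)
}

#' Percent of injected dose per gram of tissue
#'
#' `100 * tissue_conc / injected`, truncated (not rounded) to the
#' requested number of decimals, matching the reporting convention of
#' biodistribution tables (e.g. 29.05 ug/g of a 400 ug dose -> 7.2625 ->
#' 7.2 %/g).
#'
#' @param tissue_conc_ug_g tissue concentration in ug per gram.
#' @param injected_ug injected dose in ug; must be positive.
#' @param decimals decimals kept after truncation; default 1. Use
#'   `decimals = Inf` to disable truncation.
#' @return percent injected dose per gram.
#' @export
pct_injected_per_gram <- function(tissue_conc_ug_g, injected_ug, decimals = 1) {
  if (injected_ug <= 0) stop("injected dose must be positive")
  x <- 100 * tissue_conc_ug_g / injected_ug
  if (is.infinite(decimals)) return(x)
  trunc(x * 10^decimals) / 10^decimals
}

#' Protein concentration normalised to total protein
#'
#' @param bdnf_ng_ml measured concentration in ng/mL.
#' @param total_protein_mg_ml total protein in mg/mL; must be positive.
#' @return concentration in ng per mg of total protein.
#' @export
bdnf_per_total_protein <- function(bdnf_ng_ml, total_protein_mg_ml) {
  if (any(total_protein_mg_ml <= 0)) stop("total protein must be positive")
  bdnf_ng_ml / total_protein_mg_ml
}

# Uniform result container for the statistical tests.
nq_test <- function(statistic, df, p_value, alpha, method,
                    degenerate = FALSE) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 p_adjusted = NA_real_,
                 significant = !degenerate && p_value < alpha,
                 degenerate = degenerate, method = method),
            class = "nq_test")
}

# Degenerate-result wrapper so batch analyses complete instead of failing.
flagged_test <- function(method, reason) {
  res <- nq_test(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                 alpha = 0.05, method = method, degenerate = TRUE)
  res$reason <- reason
  res
}

#' Full group-level analysis of a study table
#'
#' Reproduces the study's statistical workflow per region: an optional
#' Grubbs screen of each group's ipsi/contra ratios (at most one value
#' removed per group, logged), a two-tailed paired t-test of ipsilateral
#' vs contralateral means within each group, a one-way ANOVA of the
#' ratios across groups, and Holm-Sidak-corrected pairwise comparisons
#' of group mean ratios using the ANOVA's pooled within-group variance.
#' Degenerate tests (zero variance) are returned flagged rather than
#' raising, so batch runs complete.
#'
#' @param table data frame with columns `mouse`, `group`, `region`,
#'   `ipsi`, `contra` and optionally `ratio` (computed as `ipsi / contra`
#'   when absent); one row per mouse per region.
#' @param alpha significance level; default 0.05.
#' @param pairs `"all"` (default: every group pair) or a list of
#'   length-2 character vectors naming the comparisons to correct over.
#' @param grubbs_screen logical; screen each group's ratios for a single
#'   outlier before testing (default `FALSE`).
#' @param grubbs_alpha significance level of the screen; default 0.05.
#' @return list of class `group_analysis` keyed by region; each entry has
#'   `paired` (named list of `nq_test` per group), `anova`, `pairwise`
#'   (data frame `group_a`, `group_b`, `statistic`, `df`, `p_value`,
#'   `p_adjusted`, `significant`), `removed` (data frame of
#'   Grubbs-removed mice), `group_means`, `group_sem`.
#' @export
group_analysis <- function(table, alpha = 0.05, pairs = "all",
                           grubbs_screen = FALSE, grubbs_alpha = 0.05) {
  need <- c("mouse", "group", "region", "ipsi", "contra")
  if (!all(need %in% names(table))) {
    stop("table must have columns ", paste(need, collapse = ", "))
  }
  by_mouse <- unique(table[, c("mouse", "group")])
  if (anyDuplicated(by_mouse$mouse)) stop("each mouse must be in exactly one group")
  if (is.null(table$ratio)) table$ratio <- area_ratio(table$ipsi, table$contra)

  out <- list()
  for (region in unique(table$region)) {
    sub <- table[table$region == region, ]
    groups <- unique(sub$group)
    removed <- sub[0, ]

    if (grubbs_screen) {
      for (g in groups) {
        rows <- which(sub$group == g)
        if (length(rows) >= 3 && stats::sd(sub$ratio[rows]) > 0) {
          gr <- grubbs_test(sub$ratio[rows], alpha = grubbs_alpha)
          if (gr$outlier) {
            removed <- rbind(removed, sub[rows[gr$outlier_index], ])
            sub <- sub[-rows[gr$outlier_index], ]
          }
        }
      }
    }

    paired <- lapply(stats::setNames(groups, groups), function(g) {
      gi <- sub$ipsi[sub$group == g]
      gc <- sub$contra[sub$group == g]
      tryCatch(paired_t(gi, gc, alpha = alpha),
               error = function(e) flagged_test("paired t", conditionMessage(e)))
    })

    ratio_groups <- lapply(stats::setNames(groups, groups),
                           function(g) sub$ratio[sub$group == g])
    an <- tryCatch(one_way_anova(ratio_groups, alpha = alpha),
                   error = function(e) flagged_test("one-way ANOVA",
                                                    conditionMessage(e)))

    pairwise <- NULL
    if (!an$degenerate && length(groups) >= 2) {
      cmp <- if (identical(pairs, "all")) {
        utils::combn(groups, 2, simplify = FALSE)
      } else pairs
      rows <- lapply(cmp, function(pr) {
        na <- an$n[[pr[1]]]; nb <- an$n[[pr[2]]]
        se <- sqrt(an$ms_within * (1 / na + 1 / nb))
        tstat <- (an$means[[pr[1]]] - an$means[[pr[2]]]) / se
        dfree <- an$df[2]
        data.frame(group_a = pr[1], group_b = pr[2], statistic = tstat,
                   df = dfree,
                   p_value = 2 * stats::pt(abs(tstat), dfree, lower.tail = FALSE),
                   stringsAsFactors = FALSE)
      })
      pairwise <- do.call(rbind, rows)
      hs <- holm_sidak(pairwise$p_value, alpha = alpha)
      pairwise$p_adjusted <- hs$adjusted
      pairwise$significant <- hs$reject
    }

    sem <- function(x) stats::sd(x) / sqrt(length(x))
    out[[region]] <- list(
      paired = paired, anova = an, pairwise = pairwise, removed = removed,
      group_means = vapply(ratio_groups, mean, numeric(1)),
      group_sem = vapply(ratio_groups, sem, numeric(1))
    )
  }
  class(out) <- "group_analysis"
  out
}
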