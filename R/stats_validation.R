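# Count-validation metrics and the group-comparison statistics used across
# the analyses: relative percent difference, one-way ANOVA and Tukey's
# multiple-comparison test.

#' Relative percent difference between two counts
#'
#' `100 * |a - b| / ((a + b) / 2)`; symmetric and scale-invariant. Used to
#' validate automated against human cell counts.
#'
#' @param a,b nonnegative counts, not both zero.
#' @return RPD in percent.
#' @export
rpd <- function(a, b) {
  if (a + b <= 0) stop("RPD undefined for two zero counts")
  100 * abs(a - b) / ((a + b) / 2)
}

#' RPD validation panel: three human counts vs an automated count
#'
#' Computes the three pairwise RPDs among the human counts and the RPD of
#' the human mean against the automated count.
#'
#' @param humans numeric length-3 vector of human counts.
#' @param automated automated count.
#' @return list with `pairwise` (named length-3), `human_vs_auto`,
#'   `summary` (min/max over all four values).
#' @export
rpd_panel <- function(humans, automated) {
  stopifnot(length(humans) == 3, all(humans > 0), automated > 0)
  pairs <- utils::combn(3, 2)
  pw <- apply(pairs, 2, function(p) rpd(humans[p[1]], humans[p[2]]))
  names(pw) <- apply(pairs, 2, paste, collapse = "v")
  hva <- rpd(mean(humans), automated)
  all_v <- c(pw, human_vs_auto = hva)
  list(pairwise = pw, human_vs_auto = hva,
       summary = c(min = min(all_v), max = max(all_v)))
}

#' One-way ANOVA across groups
#'
#' Classical fixed-effects one-way analysis of variance:
#' `F = MS_between / MS_within` with `k - 1` and `N - k` degrees of
#' freedom.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   of size >= 2).
#' @return an `anova_result`: list with `F`, `df_between`, `df_within`,
#'   `p`, plus group means.
#' @export
oneway_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 2))
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (all(vapply(groups, stats::var, numeric(1)) == 0) &&
      length(unique(vapply(groups, mean, numeric(1)))) == 1L) {
    # all groups constant and equal: F is 0/0; report the degenerate case
    res <- list(F = 0, df_between = nlevels(g) - 1L,
                df_within = length(y) - nlevels(g), p = 1,
                group_means = vapply(groups, mean, numeric(1)),
                degenerate = TRUE)
    class(res) <- "anova_result"
    return(res)
  }
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  res <- list(F = unname(ft$statistic),
              df_between = as.integer(ft$parameter[["num df"]]),
              df_within = as.integer(ft$parameter[["denom df"]]),
              p = unname(ft$p.value),
              group_means = vapply(groups, mean, numeric(1)),
              degenerate = FALSE)
  class(res) <- "anova_result"
  res
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d,%d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Tukey's multiple-comparison test
#'
#' Studentized-range-based adjusted p-values for all pairwise group
#' contrasts, with the Tukey-Kramer correction for unequal group sizes
#' (via [stats::TukeyHSD()] on the pooled-variance fit).
#'
#' @param groups list of numeric vectors, one per group; names are used as
#'   group labels.
#' @return data.frame with `pair`, `mean_diff`, `p_adj` and significance
#'   stars at 0.05/0.01/0.001.
#' @export
tukey_hsd <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 2))
  labs <- names(groups) %||% paste0("g", seq_along(groups))
  y <- unlist(groups)
  g <- factor(rep(labs, vapply(groups, length, integer(1))), levels = labs)
  if (stats::var(y) == 0 ||
      sum((y - stats::ave(y, g))^2) == 0 &&
      length(unique(tapply(y, g, mean))) == 1L) {
    pairs <- utils::combn(labs, 2)
    return(data.frame(pair = apply(pairs, 2, paste, collapse = "-"),
                      mean_diff = 0, p_adj = 1, stars = "",
                      stringsAsFactors = FALSE))
  }
  fit <- stats::aov(y ~ g)
  tk <- stats::TukeyHSD(fit)$g
  data.frame(pair = rownames(tk), mean_diff = tk[, "diff"],
             p_adj = tk[, "p adj"],
             stars = ifelse(tk[, "p adj"] < 0.001, "***",
                     ifelse(tk[, "p adj"] < 0.01, "**",
                     ifelse(tk[, "p adj"] < 0.05, "*", ""))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-region group comparison across targets
#'
#' Runs the one-way ANOVA and Tukey HSD per region on percent-of-total
#' values grouped by target, mirroring the per-subregion group statistics
#' of the study.
#'
#' @param ctable a `connectivity_table` for one condition.
#' @param value column to compare (default `percent_total`).
#' @return data.frame with one row per (region, Tukey pair) carrying the
#'   region-level F, dfs and p alongside the pair-adjusted p.
#' @export
region_group_stats <- function(ctable, value = "percent_total") {
  out <- list()
  for (r in sort(unique(ctable$region_code[!ctable$excluded]))) {
    sel <- ctable$region_code == r & !ctable$excluded
    sub <- ctable[sel, , drop = FALSE]
    per_mouse <- tapply(sub[[value]], sub$mouse_id, sum)
    tg <- tapply(sub$target, sub$mouse_id, function(x) x[1])
    groups <- split(as.numeric(per_mouse), unname(tg))
    if (length(groups) < 2 ||
        any(vapply(groups, length, integer(1)) < 2)) next
    an <- oneway_anova(groups)
    tk <- tukey_hsd(groups)
    out[[r]] <- cbind(region_code = r,
                      F = an$F, df_between = an$df_between,
                      df_within = an$df_within, p = an$p, tk,
                      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
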