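#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences `x_high - x_low`, the
#' workhorse comparison for per-unit parameter changes between contrast
#' conditions. Uses the exact null distribution for n <= 25 (when ties and
#' zeros permit) and the normal approximation with continuity correction
#' otherwise. If every difference is zero the test is degenerate and p = 1
#' is returned with a warning.
#'
#' @param x_low,x_high Paired finite vectors, length >= 6.
#' @return List with `statistic` (V), `p_value` and `n` (non-zero pairs).
#' @export
paired_signed_rank <- function(x_low, x_high) {
  stopifnot(length(x_low) == length(x_high), length(x_low) >= 6,
            all(is.finite(x_low)), all(is.finite(x_high)))
  d <- x_high - x_low
  if (all(d == 0)) {
    warning("all paired differences are zero; signed-rank test degenerate")
    return(list(statistic = NA_real_, p_value = 1, n = 0L))
  }
  n_nz <- sum(d != 0)
  wt <- suppressWarnings(
    stats::wilcox.test(x_high, x_low, paired = TRUE,
                       exact = n_nz <= 25, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n = n_nz)
}

#' Flag outliers by distance from the mean
#'
#' Flags values lying more than `k` SDs from the sample mean. Changes in
#' STRF tuning parameters are screened at k = 1.96 (flagged but retained in
#' the paired tests); the laminar ANOVA and the gain-threshold correlation
#' exclude gain changes beyond k = 3. A zero-variance vector yields no
#' flags.
#'
#' @param values Numeric vector, length >= 3.
#' @param k SD multiplier.
#' @return Logical vector of flags.
#' @export
detect_outliers <- function(values, k = 1.96) {
  stopifnot(length(values) >= 3, is.finite(k), k > 0)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    return(rep(FALSE, length(values)))
  }
  abs(values - mean(values)) > k * s
}

#' Two-factor laminar ANOVA on gain-control strength
#'
#' Tests whether the strength of contrast gain control differs between
#' cortical layers: an additive fixed-effects ANOVA (no interaction) with
#' the per-unit gain change as the response, layer as one factor and
#' penetration as a blocking factor. Units whose gain change lies more than
#' `outlier_k` SD from the population mean are excluded first; layers with
#' fewer than 2 units are dropped with a warning. Pairwise layer contrasts
#' are Tukey-Kramer corrected (on the model-adjusted layer means).
#'
#' The sum-of-squares type for the unbalanced design is configurable;
#' Type III with sum-to-zero contrasts is the default, matching the default
#' of the commercial stats toolchain most electrophysiology labs use.
#'
#' @param table Data frame with columns `gain_change_pct` (or `response`),
#'   `layer` and `penetration_id`.
#' @param response Name of the response column.
#' @param outlier_k SD multiplier for the exclusion rule (default 3).
#' @param ss_type Sum-of-squares type: `"III"` (default), `"II"` or `"I"`.
#' @return List with `anova_table` (data frame: term, df, sum_sq, F, p),
#'   `pairwise` (Tukey-Kramer layer contrasts, data frame), `n_excluded`,
#'   `layer_means` and the fitted `model`.
#' @export
laminar_anova <- function(table, response = "gain_change_pct",
                          outlier_k = 3, ss_type = c("III", "II", "I")) {
  ss_type <- match.arg(ss_type)
  stopifnot(all(c(response, "layer", "penetration_id") %in% names(table)))
  y <- table[[response]]
  out <- detect_outliers(y, outlier_k)
  tab <- table[!out, , drop = FALSE]
  tab$layer <- droplevels(factor(tab$layer))
  counts <- base::table(tab$layer)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning(sprintf("dropping layer(s) with < 2 units: %s",
                    paste(small, collapse = ", ")))
    tab <- tab[!tab$layer %in% small, , drop = FALSE]
    tab$layer <- droplevels(tab$layer)
  }
  if (nlevels(tab$layer) < 2) stop("need >= 2 layers with >= 2 units each")
  tab$penetration_id <- droplevels(factor(tab$penetration_id))
  single_pen <- nlevels(tab$penetration_id) < 2
  form <- if (single_pen) {
    stats::reformulate("layer", response = response)
  } else {
    stats::reformulate(c("layer", "penetration_id"), response = response)
  }
  old_con <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old_con))
  fit <- stats::aov(form, data = tab)
  at <- if (ss_type == "I") {
    s <- summary(fit)[[1]]
    data.frame(
      term = trimws(rownames(s)), df = s$Df, sum_sq = s$`Sum Sq`,
      f_value = s$`F value`, p_value = s$`Pr(>F)`,
      stringsAsFactors = FALSE
    )
  } else {
    a <- car::Anova(fit, type = ss_type)
    data.frame(
      term = trimws(rownames(a)), df = a$Df, sum_sq = a$`Sum Sq`,
      f_value = a$`F value`, p_value = a$`Pr(>F)`,
      stringsAsFactors = FALSE
    )
  }
  emm <- emmeans::emmeans(fit, "layer")
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  lm_means <- tapply(tab[[response]], tab$layer, mean)
  list(
    anova_table = at,
    pairwise = prs,
    n_excluded = sum(out),
    layer_means = lm_means,
    n_per_layer = as.integer(base::table(tab$layer)),
    model = fit
  )
}

#' Correlation between gain and threshold changes
#'
#' Pearson correlation between per-unit gain changes and threshold changes,
#' after removing units more than `outlier_k` SD from the mean of either
#' distribution. A weak correlation indicates that contrast-dependent gain
#' and threshold shifts are dissociable effects.
#'
#' @param table Data frame with columns `gain_change_pct` and
#'   `threshold_change_pct`.
#' @param outlier_k SD multiplier for outlier removal (default 3).
#' @return List with `r`, `p_value` and `n` (units retained).
#' @export
gain_threshold_correlation <- function(table, outlier_k = 3) {
  stopifnot(all(c("gain_change_pct", "threshold_change_pct") %in%
                  names(table)))
  g <- table$gain_change_pct
  th <- table$threshold_change_pct
  keep <- !(detect_outliers(g, outlier_k) | detect_outliers(th, outlier_k))
  g <- g[keep]
  th <- th[keep]
  if (length(g) < 3) stop("fewer than 3 units after outlier removal")
  ct <- stats::cor.test(g, th, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(g))
}

#' Plain-text population report
#'
#' Formats the population-level results (medians, signed-rank tests, laminar
#' ANOVA, pairwise comparisons, gain-threshold correlation) as a readable
#' text report.
#'
#' @param table Per-unit population table (see [laminar_anova()]).
#' @param path Optional file to write to.
#' @return The report lines, invisibly if written to `path`.
#' @export
population_report <- function(table, path = NULL) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  n <- nrow(table)
  add("Contrast gain control population report (n = %d units)", n)
  add("------------------------------------------------------")
  med_g <- stats::median(table$gain_change_pct)
  sr_g <- paired_signed_rank(rep(0, n), table$gain_change_pct)
  add("Median gain change: %.1f%% (signed-rank vs 0: p = %.3g)",
      med_g, sr_g$p_value)
  if ("threshold_change_pct" %in% names(table)) {
    sr_t <- paired_signed_rank(rep(0, n), table$threshold_change_pct)
    add("Median threshold change: %.2f%% (signed-rank vs 0: p = %.3g)",
        stats::median(table$threshold_change_pct), sr_t$p_value)
  }
  if ("baseline_change_pct" %in% names(table)) {
    add("Median baseline change: %.2f%%",
        stats::median(table$baseline_change_pct))
  }
  if (all(c("layer", "penetration_id") %in% names(table)) &&
      nlevels(droplevels(factor(table$layer))) >= 2) {
    la <- tryCatch(laminar_anova(table), error = function(e) NULL,
                   warning = function(w) suppressWarnings(laminar_anova(table)))
    if (!is.null(la)) {
      add("")
      add("Laminar ANOVA (%d outliers excluded at 3 SD):", la$n_excluded)
      for (i in seq_len(nrow(la$anova_table))) {
        r <- la$anova_table[i, ]
        if (!is.na(r$f_value)) {
          add("  %-16s df = %d, F = %.2f, p = %.3g", r$term, r$df,
              r$f_value, r$p_value)
        }
      }
      add("  Layer means (%%): %s",
          paste(sprintf("%s: %.1f", names(la$layer_means), la$layer_means),
                collapse = "; "))
      add("  Tukey-Kramer pairwise layer contrasts:")
      for (i in seq_len(nrow(la$pairwise))) {
        r <- la$pairwise[i, ]
        add("    %-14s estimate = %.1f, p = %.3g", r$contrast, r$estimate,
            r$p.value)
      }
    }
  }
  if (all(c("gain_change_pct", "threshold_change_pct") %in% names(table)) &&
      n >= 4) {
    gt <- tryCatch(gain_threshold_correlation(table),
                   error = function(e) NULL)
    if (!is.null(gt)) {
      add("")
      add("Gain vs threshold change: R = %.2f, p = %.3g (n = %d)",
          gt$r, gt$p_value, gt$n)
    }
  }
  if (!is.null(path)) {
    writeLines(ln, path)
    return(invisible(ln))
  }
  ln
}
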