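# Interpretability: between-system Gait Profile Score comparison, group
# contrasts, minimal-detectable-change reading, outlier attenuation.

shapiro_ok <- function(x, alpha) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || sd(x) < 1e-12) return(FALSE)
  tryCatch(shapiro.test(x)$p.value >= alpha, error = function(e) FALSE)
}

paired_p <- function(x, y, parametric) {
  d <- y - x
  if (all(abs(d) < 1e-12)) return(1)
  if (parametric) {
    t.test(x, y, paired = TRUE)$p.value
  } else {
    suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE)$p.value)
  }
}

#' Compare Gait Profile Scores between measuring systems
#'
#' Runs the interpretability analysis on paired side-averaged GPS values:
#' \itemize{
#' \item a normality check per distribution (Shapiro-Wilk at `config$alpha`;
#'   `config$nonparametric = TRUE` forces the nonparametric branch);
#' \item an overall paired between-system test (paired t-test or paired
#'   Wilcoxon) and between-system correlation (Pearson or Spearman);
#' \item per-group paired Wilcoxon tests, Bonferroni-corrected across groups;
#' \item per-system group comparisons: Kruskal-Wallis ANOVA with pairwise
#'   unpaired Wilcoxon tests (Bonferroni adjusted);
#' \item the group mean GPS difference read against the group's minimal
#'   detectable change;
#' \item Tukey-rule outliers per system, to check whether extreme reference
#'   deviations are attenuated by the inertial system.
#' }
#'
#' @param table A paired [cohort_table()].
#' @param bank_opto,bank_imu Optional [build_normative_bank()] results; built
#'   from `table` when omitted.
#' @param config An [analysis_config()].
#' @return A list of class `interpret_report`.
#' @export
compare_gps_systems <- function(table, bank_opto = NULL, bank_imu = NULL,
                                config = analysis_config()) {
  tab <- cohort_table(table)
  if (is.null(bank_opto)) bank_opto <- build_normative_bank(tab, "OPTO")
  if (is.null(bank_imu)) bank_imu <- build_normative_bank(tab, "IMU")
  g_o <- gps_table(tab, bank_opto)[, .(subject_id, group, gps_opto = gps)]
  g_i <- gps_table(tab, bank_imu)[, .(subject_id, group, gps_imu = gps)]
  g <- merge(g_o, g_i, by = c("subject_id", "group"))
  if (!nrow(g)) abort_pairing("no subjects with paired GPS values")

  alpha <- config$alpha
  d <- g$gps_imu - g$gps_opto
  normal <- !config$nonparametric &&
    shapiro_ok(d, alpha)
  p_overall <- paired_p(g$gps_opto, g$gps_imu, parametric = normal)

  corr_normal <- !config$nonparametric &&
    shapiro_ok(g$gps_opto, alpha) && shapiro_ok(g$gps_imu, alpha)
  corr <- if (all(abs(d) < 1e-12)) {
    list(estimate = 1, p.value = 0, method = "identical scores")
  } else if (corr_normal) {
    ct <- cor.test(g$gps_opto, g$gps_imu, method = "pearson")
    list(estimate = unname(ct$estimate), p.value = ct$p.value,
         method = "pearson")
  } else {
    ct <- suppressWarnings(
      cor.test(g$gps_opto, g$gps_imu, method = "spearman", exact = FALSE))
    list(estimate = unname(ct$estimate), p.value = ct$p.value,
         method = "spearman")
  }

  sizes <- g[, .N, by = group]
  small <- sizes[N < 2L, group]
  if (length(small)) {
    warning(sprintf("group(s) with a single subject excluded from group tests: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
  }
  gt <- g[!group %in% small]
  by_group <- gt[, .(
    n = .N,
    gps_opto_mean = mean(gps_opto), gps_opto_sd = sd(gps_opto),
    gps_imu_mean = mean(gps_imu), gps_imu_sd = sd(gps_imu),
    p_paired = paired_p(gps_opto, gps_imu, parametric = FALSE)
  ), by = group]
  by_group[, p_paired := pmin(1, p_paired * .N)]  # Bonferroni across groups
  by_group[, delta_gps := gps_imu_mean - gps_opto_mean]
  by_group[, mdc := ifelse(group == "AS", config$mdc_as, config$mdc_patho)]
  by_group[, exceeds_mdc := mdc_flag(delta_gps, group, config)]
  setorderv(by_group, "group")

  group_comparison <- NULL
  if (length(unique(gt$group)) >= 2L) {
    pw <- function(values) {
      kw <- kruskal.test(values, factor(gt$group))$p.value
      pmat <- suppressWarnings(
        stats::pairwise.wilcox.test(values, factor(gt$group),
                                    p.adjust.method = "bonferroni",
                                    exact = FALSE)$p.value)
      list(kruskal_p = kw, pairwise_p = pmat)
    }
    group_comparison <- list(OPTO = pw(gt$gps_opto), IMU = pw(gt$gps_imu))
  }

  out_o <- find_outliers(setNames(g$gps_opto, g$subject_id))
  out_i <- find_outliers(setNames(g$gps_imu, g$subject_id))

  structure(list(
    gps_by_subject = g[],
    by_group = by_group[],
    paired = list(p_value = p_overall,
                  test = if (normal) "paired t-test" else "paired Wilcoxon",
                  normal_differences = normal),
    correlation = corr,
    group_comparison = group_comparison,
    outliers = list(OPTO = out_o, IMU = out_i),
    alpha = alpha
  ), class = "interpret_report")
}

#' @export
print.interpret_report <- function(x, ...) {
  cat("<interpret_report>\n")
  cat(sprintf("  overall between-system: %s p = %.3g | %s correlation = %.2f (p = %.3g)\n",
              x$paired$test, x$paired$p_value, x$correlation$method,
              x$correlation$estimate, x$correlation$p.value))
  print(x$by_group[, .(group, n, gps_opto_mean, gps_opto_sd, gps_imu_mean,
                       gps_imu_sd, p_paired, exceeds_mdc)], digits = 3)
  cat(sprintf("  outliers: OPTO {%s} | IMU {%s}\n",
              paste(x$outliers$OPTO, collapse = ", "),
              paste(x$outliers$IMU, collapse = ", ")))
  invisible(x)
}
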