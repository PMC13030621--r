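# Analysis configuration: defaults, validation, JSON loading.

#' Build an analysis configuration
#'
#' Central knobs of the agreement/interpretability analysis:
#' \describe{
#'   \item{mdc_patho}{Minimal detectable change of the Gait Profile Score for
#'     the pathological groups (CP, OMD), degrees. Default 1.7.}
#'   \item{mdc_as}{Minimal detectable change for the asymptomatic group,
#'     degrees. Default 0.7.}
#'   \item{clinical_threshold}{RMSE level (degrees) below which a
#'     between-system error is read as clinically acceptable. Default 5.}
#'   \item{gps_outcomes}{The nine angles entering the Gait Profile Score.}
#'   \item{alpha}{Two-sided significance level. Default 0.05.}
#'   \item{seed}{Integer seed for seeded pipeline stages.}
#'   \item{nonparametric}{Force the nonparametric branch (paired Wilcoxon /
#'     Spearman) regardless of the normality check. Default `FALSE`.}
#' }
#'
#' @param mdc_patho,mdc_as Positive MDC thresholds in degrees.
#' @param clinical_threshold Positive RMSE acceptability threshold in degrees.
#' @param gps_outcomes Character vector; must equal the canonical 9-outcome set.
#' @param alpha Significance level in (0, 1).
#' @param seed Integer seed.
#' @param nonparametric Logical flag.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(mdc_patho = 1.7, mdc_as = 0.7,
                            clinical_threshold = 5.0,
                            gps_outcomes = GPS_OUTCOMES,
                            alpha = 0.05, seed = 1L,
                            nonparametric = FALSE) {
  for (nm in c("mdc_patho", "mdc_as", "clinical_threshold")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v <= 0) {
      abort_validation(sprintf("'%s' must be a positive number, got %s",
                               nm, format(v)))
    }
  }
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    abort_validation("'alpha' must lie in (0, 1)")
  }
  if (!is_scalar_number(seed) || seed != round(seed)) {
    abort_validation("'seed' must be a single integer")
  }
  if (!is.character(gps_outcomes) ||
      !setequal(gps_outcomes, GPS_OUTCOMES)) {
    bad <- setdiff(gps_outcomes, GPS_OUTCOMES)
    abort_validation(sprintf(
      "'gps_outcomes' must be exactly the 9 GPS angles%s",
      if (length(bad)) paste0("; unknown: ", paste(bad, collapse = ", ")) else ""))
  }
  if (!is.logical(nonparametric) || length(nonparametric) != 1L ||
      is.na(nonparametric)) {
    abort_validation("'nonparametric' must be TRUE or FALSE")
  }
  structure(list(
    mdc_patho = mdc_patho, mdc_as = mdc_as,
    clinical_threshold = clinical_threshold,
    gps_outcomes = GPS_OUTCOMES[GPS_OUTCOMES %in% gps_outcomes],
    alpha = alpha, seed = as.integer(seed),
    nonparametric = nonparametric
  ), class = "analysis_config")
}

#' Load an analysis configuration from JSON
#'
#' Absent keys take their documented defaults; unknown keys are rejected so
#' typos do not silently fall back to defaults.
#'
#' @param path Path to a JSON file holding a single object.
#' @return An [analysis_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("config file not found: %s", path))
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort_parse(sprintf("cannot parse config JSON: %s",
                                        conditionMessage(e)))
                  })
  if (!is.list(raw)) abort_parse("config JSON must be an object")
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort_validation(sprintf("unknown config key(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  do.call(analysis_config, raw)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat(sprintf("  MDC: %.1f deg (CP/OMD), %.1f deg (AS) | acceptable RMSE < %.1f deg\n",
              x$mdc_patho, x$mdc_as, x$clinical_threshold))
  cat(sprintf("  alpha = %.3g | seed = %d | nonparametric = %s\n",
              x$alpha, x$seed, x$nonparametric))
  invisible(x)
}
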