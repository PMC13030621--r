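# Test-retest reliability: discrete curve parameters, intra-/inter-operator
# measurement tables, variance-component ICC from a two-way mixed model.

#' Discrete parameters of an angle cycle
#'
#' The clinically read summary values of a kinematic curve: maximum, minimum,
#' range of motion and mean over the 101 samples.
#'
#' @param cycle An [angle_cycle()] or bare 101-sample numeric.
#' @return Named numeric: `max`, `min`, `rom`, `mean` (degrees).
#' @export
discrete_params <- function(cycle) {
  x <- as_samples(cycle, "cycle")
  c(max = max(x), min = min(x), rom = max(x) - min(x), mean = mean(x))
}

DISCRETE_PARAMETERS <- c("max", "min", "rom", "mean")

#' Build the subject-by-condition reliability measurement table
#'
#' Reduces a cohort to one value per subject and condition for every
#' outcome, discrete parameter and system, averaging the per-cycle discrete
#' parameters over cycles and sides:
#' \describe{
#'   \item{intra}{operator A's sessions 1 and 2 (test-retest one week apart);
#'     conditions are the sessions.}
#'   \item{inter}{session 2 led by operators A and B; conditions are the
#'     operators.}
#' }
#' Subjects missing either condition are dropped and logged.
#'
#' @param table A [cohort_table()].
#' @param mode `"intra"` or `"inter"`.
#' @return A `data.table` with columns `subject_id`, `group`, `outcome`,
#'   `system`, `parameter`, `condition` (1/2), `value`.
#' @export
reliability_table <- function(table, mode = c("intra", "inter")) {
  mode <- match.arg(mode)
  dt <- as.data.table(cohort_table(table))
  dt <- if (mode == "intra") {
    d <- dt[operator == "A" & session %in% c(1L, 2L)]
    d[, condition := session]
    d
  } else {
    d <- dt[session == 2L]
    d[, condition := match(operator, c("A", "B"))]
    d
  }
  if (length(unique(dt$condition)) < 2L) {
    abort_design(sprintf(
      "reliability design incomplete: %s-operator mode needs %s",
      mode,
      if (mode == "intra") "sessions 1 and 2 with operator A"
      else "session 2 with operators A and B"))
  }
  M <- sample_matrix(dt)
  params <- data.table(
    max = apply(M, 1L, max), min = apply(M, 1L, min),
    mean = rowMeans(M))
  params[, rom := max - min]
  meas <- cbind(dt[, .(subject_id, group, outcome, system, condition)], params)
  long <- melt(meas, id.vars = c("subject_id", "group", "outcome", "system",
                                 "condition"),
               measure.vars = DISCRETE_PARAMETERS,
               variable.name = "parameter", variable.factor = FALSE,
               value.name = "value")
  agg <- long[, .(value = mean(value)),
              by = .(subject_id, group, outcome, system, parameter, condition)]
  complete <- agg[, .(n_cond = uniqueN(condition)), by = subject_id]
  dropped <- complete[n_cond < 2L, subject_id]
  if (length(dropped)) {
    gv_log("reliability", sprintf("dropped subject(s) missing a condition: %s",
                                  paste(dropped, collapse = ", ")))
    agg <- agg[!subject_id %in% dropped]
  }
  agg[]
}

# Balanced two-way ANOVA (subjects x conditions, one value per cell)
# method-of-moments variance components.
anova_components <- function(wide) {
  n <- nrow(wide); k <- ncol(wide)
  g <- mean(wide)
  subj_means <- rowMeans(wide); cond_means <- colMeans(wide)
  msr <- k * sum((subj_means - g)^2) / (n - 1)
  msc <- n * sum((cond_means - g)^2) / (k - 1)
  resid <- wide - outer(subj_means, rep(1, k)) -
    outer(rep(1, n), cond_means) + g
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  list(sigma2_subject = (msr - mse) / k,
       sigma2_class = (msc - mse) / n,
       sigma2_residual = mse)
}

#' Variance-component ICC from a two-way mixed-effects model
#'
#' Fits `value ~ condition + (1 | subject)` by restricted maximum likelihood
#' (conditions as a fixed two-level class, random subject intercepts, no
#' interaction), extracts the subject and residual variances, estimates the
#' class (condition) variance from the fitted condition means corrected for
#' residual sampling error, truncates negative estimates at zero and forms
#'
#' `ICC = sigma2_subject / (sigma2_subject + sigma2_class + sigma2_residual)`
#'
#' i.e. a two-way mixed, absolute-agreement, single-measurement ICC. If the
#' mixed-model fit fails to converge, a balanced-ANOVA method-of-moments
#' estimator is used instead and flagged (`method = "mom"`).
#'
#' @param measurements A data.frame with columns `subject` (or `subject_id`),
#'   `condition` and `value`; at least 5 subjects with both conditions.
#' @param mode Label carried into the result (`"intra"` or `"inter"`).
#' @return A list of class `reliability_result`: the three variance
#'   components (deg^2), `icc`, `band` (Koo & Li label), `mode`, `method`,
#'   `n_subjects`.
#' @export
fit_icc <- function(measurements, mode = "intra") {
  m <- as.data.table(measurements)
  if ("subject_id" %in% names(m) && !"subject" %in% names(m)) {
    setnames(m, "subject_id", "subject")
  }
  if (!all(c("subject", "condition", "value") %in% names(m))) {
    abort_validation("'measurements' needs columns subject, condition, value")
  }
  wide_dt <- dcast(m, subject ~ condition, value.var = "value")
  wide <- as.matrix(wide_dt[, -1L])
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  if (ncol(wide) != 2L) {
    abort_design("exactly 2 conditions are required for the ICC model")
  }
  if (nrow(wide) < 5L) {
    abort_validation("at least 5 complete subjects are required for the ICC model")
  }
  n <- nrow(wide)
  fit <- tryCatch({
    long <- data.frame(
      subject = factor(rep(seq_len(n), 2L)),
      condition = factor(rep(1:2, each = n)),
      value = c(wide))
    mod <- suppressMessages(suppressWarnings(
      lme4::lmer(value ~ condition + (1 | subject), data = long, REML = TRUE)))
    vc <- as.data.frame(lme4::VarCorr(mod))
    s2_subj <- vc$vcov[vc$grp == "subject"]
    s2_res <- vc$vcov[vc$grp == "Residual"]
    delta <- unname(lme4::fixef(mod)[2L])
    # sample variance of the two condition means is delta^2/2; subtract the
    # residual sampling contribution so the class component is unbiased
    s2_class <- delta^2 / 2 - s2_res / n
    list(sigma2_subject = s2_subj, sigma2_class = s2_class,
         sigma2_residual = s2_res, method = "reml")
  }, error = function(e) NULL)
  if (is.null(fit)) {
    fit <- c(anova_components(wide), method = "mom")
  }
  s <- pmax(c(fit$sigma2_subject, fit$sigma2_class, fit$sigma2_residual), 0)
  icc <- if (sum(s) <= 0) 0 else s[1L] / sum(s)
  structure(list(sigma2_subject = s[1L], sigma2_class = s[2L],
                 sigma2_residual = s[3L], icc = icc,
                 band = interpret_icc_koo(icc), mode = mode,
                 method = fit$method, n_subjects = n),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf(
    "<reliability_result> %s: ICC %.3f (%s) | var subj %.3g, class %.3g, resid %.3g | %s, n=%d\n",
    x$mode, x$icc, x$band, x$sigma2_subject, x$sigma2_class,
    x$sigma2_residual, x$method, x$n_subjects))
  invisible(x)
}

#' Interpret an ICC with Koo and Li's bands
#'
#' poor `< 0.50`, moderate `[0.50, 0.75)`, good `[0.75, 0.90)`,
#' excellent `>= 0.90` (inclusive lower bounds).
#'
#' @param icc ICC value(s) in `[0, 1]`.
#' @return Character vector of band labels.
#' @export
interpret_icc_koo <- function(icc) {
  if (any(!is.finite(icc)) || any(icc < 0) || any(icc > 1)) {
    abort_validation("ICC values must lie in [0, 1]")
  }
  as.character(cut(icc, breaks = c(-Inf, 0.50, 0.75, 0.90, Inf),
                   labels = c("poor", "moderate", "good", "excellent"),
                   right = FALSE))
}

#' Full reliability summary across outcomes, parameters and systems
#'
#' Runs [reliability_table()] and [fit_icc()] for every outcome, discrete
#' parameter and system, shaping the result like a plane x joint x parameter
#' reliability table.
#'
#' @param table A [cohort_table()] with a reliability design.
#' @param mode `"intra"` or `"inter"`.
#' @return A `data.table` with plane, joint, outcome, parameter, system,
#'   variance components, `icc`, `band`, `method` and `n_subjects`.
#' @export
reliability_summary <- function(table, mode = c("intra", "inter")) {
  mode <- match.arg(mode)
  meas <- reliability_table(table, mode)
  grid <- unique(meas[, .(outcome, system, parameter)])
  res <- grid[, {
    o <- .BY$outcome; sys <- .BY$system; par <- .BY$parameter
    sub <- meas[outcome == o & system == sys & parameter == par]
    r <- fit_icc(sub[, .(subject = subject_id, condition, value)], mode = mode)
    .(sigma2_subject = r$sigma2_subject, sigma2_class = r$sigma2_class,
      sigma2_residual = r$sigma2_residual, icc = r$icc, band = r$band,
      method = r$method, n_subjects = r$n_subjects)
  }, by = .(outcome, system, parameter)]
  res[, plane := OUTCOME_PLANES[outcome]]
  res[, joint := OUTCOME_JOINTS[outcome]]
  setcolorder(res, c("plane", "joint", "outcome", "parameter", "system"))
  setorderv(res, c("plane", "joint", "parameter", "system"))
  res[]
}
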