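#' Maximum safe stimulus amplitude for a disc electrode
#'
#' Converts a charge-density safety limit (mC/cm^2 per phase) into the
#' maximum rectangular-pulse current: `I = limit * area / pulse_width`.
#' For the standard 1.0 mC/cm^2/phase limit, a 0.45 ms phase, and a 200 um
#' disc this gives about 698 uA; clinical practice uses an operational
#' cutoff of 677 uA for the same limit (see [inclusion_filter()]), the small
#' difference presumably reflecting device amplitude quantisation.
#'
#' @param charge_density_limit_mC_cm2 charge density limit per phase.
#' @param pulse_width_ms phase duration (ms).
#' @param diameter_um electrode diameter (um).
#' @return maximum amplitude in uA.
#' @export
max_safe_amplitude <- function(charge_density_limit_mC_cm2 = 1.0,
                               pulse_width_ms = 0.45, diameter_um = 200) {
  stopifnot(charge_density_limit_mC_cm2 > 0, pulse_width_ms > 0,
            diameter_um > 0)
  area_cm2 <- pi * (diameter_um / 2 * 1e-4)^2
  charge_mC <- charge_density_limit_mC_cm2 * area_cm2
  charge_mC / (pulse_width_ms / 1000) * 1000   # mC/s = mA -> uA
}

#' Charge density of a rectangular pulse on a disc electrode
#'
#' @param amplitude_uA pulse amplitude (uA).
#' @param pulse_width_ms phase duration (ms).
#' @param diameter_um electrode diameter (um).
#' @return charge density in mC/cm^2 per phase.
#' @export
charge_density <- function(amplitude_uA, pulse_width_ms = 0.45,
                           diameter_um = 200) {
  area_cm2 <- pi * (diameter_um / 2 * 1e-4)^2
  amplitude_uA * 1e-3 * pulse_width_ms * 1e-3 / area_cm2
}

#' Electrode inclusion filter for threshold analyses
#'
#' Retains electrodes that are visible (measurable on the imaging analogue)
#' and whose perceptual threshold is strictly below the safety cutoff
#' (677 uA, the operational value corresponding to the 1.0 mC/cm^2/phase
#' charge-density limit of 200 um electrodes).
#'
#' @param measurements data.frame with at least `threshold_uA` and
#'   `visible` columns.
#' @param threshold_cap_uA exclusion cutoff (uA, strict).
#' @return retained rows; excluded counts attached as attribute
#'   `excluded_counts` (`not_visible`, `over_cap`, `no_threshold`).
#' @export
inclusion_filter <- function(measurements, threshold_cap_uA = 677) {
  stopifnot(all(c("threshold_uA", "visible") %in% names(measurements)))
  vis <- measurements$visible
  has_thr <- !is.na(measurements$threshold_uA)
  keep <- vis & has_thr & measurements$threshold_uA < threshold_cap_uA
  out <- measurements[keep, , drop = FALSE]
  attr(out, "excluded_counts") <- c(
    not_visible = sum(!vis),
    no_threshold = sum(vis & !has_thr),
    over_cap = sum(vis & has_thr & measurements$threshold_uA >= threshold_cap_uA)
  )
  out
}

#' Ordinary least-squares threshold regression
#'
#' Fits perceptual threshold against one covariate (individual regression)
#' or several (multiple regression), reporting slopes, the coefficient of
#' determination, and p-values: two-sided t-test p-values per coefficient
#' and, for multiple regression, the overall F-test p-value.  Significance
#' is flagged at alpha = 0.05.
#'
#' @param x numeric vector, matrix, or data.frame of covariates.
#' @param y numeric response (threshold, uA).
#' @param alpha significance level for the `significant` flag.
#' @return object of class `regression_result`: `coefficients` data.frame
#'   (term, estimate, std_error, p_value), `intercept`, `r_squared`,
#'   `p_value` (overall), `n`, `significant`.
#' @export
ols <- function(x, y, alpha = 0.05) {
  if (is.null(dim(x))) x <- data.frame(x = x)
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y))
  ok <- stats::complete.cases(x) & !is.na(y)
  x <- x[ok, , drop = FALSE]; y <- y[ok]
  p <- ncol(x)
  if (length(y) <= p + 1)
    stop("need more observations than covariates plus one")
  if (p > 1) {
    const <- vapply(x, function(v) var(v) == 0, logical(1))
    if (any(const))
      stop("constant covariate(s) in multiple regression: ",
           paste(names(x)[const], collapse = ", "))
  }
  dat <- cbind(x, .y = y)
  fit <- lm(.y ~ ., data = dat)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear covariate(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- suppressWarnings(summary(fit))   # exact fits trigger a benign warning
  ct <- sm$coefficients
  overall_p <- if (p == 1) ct[2, 4] else
    pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
       lower.tail = FALSE)
  structure(list(
    coefficients = data.frame(term = rownames(ct)[-1],
                              estimate = ct[-1, 1],
                              std_error = ct[-1, 2],
                              p_value = ct[-1, 4],
                              row.names = NULL),
    intercept = ct[1, 1],
    r_squared = sm$r.squared,
    p_value = unname(overall_p),
    n = length(y),
    alpha = alpha,
    significant = unname(overall_p) < alpha,
    fit = fit
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n = %d, R^2 = %.3f, p = %.3g%s\n",
              x$n, x$r_squared, x$p_value,
              if (x$significant) " *" else ""))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Table of per-covariate and multiple regressions
#'
#' Reproduces the structure of an electrode-level regression summary: one
#' individual OLS per covariate plus one multiple regression over all of
#' them, each reporting R^2 and p.
#'
#' @param measurements filtered electrode table (see [inclusion_filter()]).
#' @param covariates character vector of covariate column names.
#' @return data.frame with `model`, `r_squared`, `p_value`, `n`,
#'   `significant`.
#' @export
regression_table <- function(measurements,
                             covariates = c("distance_mm", "thickness_mm",
                                            "impedance_kohm",
                                            "fibrosis_mm")) {
  y <- measurements$threshold_uA
  ## covariates with no variation (e.g. no fibrosis anywhere) are reported
  ## as n/a rather than fitted
  usable <- vapply(covariates, function(v) {
    x <- measurements[[v]]
    sum(stats::complete.cases(x, y)) > 2 &&
      stats::sd(x, na.rm = TRUE) >
        1e-8 * max(1, abs(mean(x, na.rm = TRUE)))
  }, logical(1))
  na_row <- function(name) data.frame(
    model = name, r_squared = NA_real_, p_value = NA_real_,
    n = sum(stats::complete.cases(y)), significant = NA,
    stringsAsFactors = FALSE)
  rows <- lapply(covariates, function(v) {
    if (!usable[[v]]) return(na_row(v))
    r <- ols(measurements[[v]], y)
    data.frame(model = v, r_squared = r$r_squared, p_value = r$p_value,
               n = r$n, significant = r$significant,
               stringsAsFactors = FALSE)
  })
  multi_cov <- covariates[usable]
  rows <- c(rows, list(
    if (length(multi_cov) >= 1) {
      multi <- ols(measurements[, multi_cov, drop = FALSE], y)
      data.frame(model = "multiple", r_squared = multi$r_squared,
                 p_value = multi$p_value, n = multi$n,
                 significant = multi$significant, stringsAsFactors = FALSE)
    } else na_row("multiple")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear mixed model of threshold across participants
#'
#' Random intercept-and-slope model `threshold ~ covariate +
#' (covariate | participant)` fitted with `lme4`/`lmerTest` (Satterthwaite
#' degrees of freedom for the fixed effect; likelihood-ratio test for the
#' random slope), for multi-participant electrode tables.
#'
#' @param data data.frame with `threshold_uA`, the covariate column, and a
#'   `participant` column.
#' @param covariate covariate column name.
#' @return list with `fixed_effect`, `fixed_se`, `fixed_p` (Satterthwaite),
#'   `random_slope_p` (LRT), and the fitted model.
#' @export
lmm_threshold <- function(data, covariate) {
  if (!requireNamespace("lmerTest", quietly = TRUE) ||
      !requireNamespace("lme4", quietly = TRUE))
    stop("lmm_threshold requires the lme4 and lmerTest packages")
  fml <- stats::as.formula(sprintf(
    "threshold_uA ~ %s + (%s | participant)", covariate, covariate))
  fit <- lmerTest::lmer(fml, data = data, REML = TRUE)
  ct <- coef(summary(fit))
  reduced <- lme4::lmer(stats::as.formula(sprintf(
    "threshold_uA ~ %s + (1 | participant)", covariate)),
    data = data, REML = FALSE)
  full_ml <- lme4::lmer(fml, data = data, REML = FALSE)
  lrt <- stats::anova(reduced, full_ml)
  list(fixed_effect = ct[covariate, "Estimate"],
       fixed_se = ct[covariate, "Std. Error"],
       fixed_p = ct[covariate, "Pr(>|t|)"],
       random_slope_p = lrt$`Pr(>Chisq)`[2],
       model = fit)
}
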