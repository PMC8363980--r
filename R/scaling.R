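# Allometric scaling: standard major axis (Model II) and OLS line fitting on
# log-log data, analytic confidence intervals, and classification against
# geometric null slopes.

new_scaling_fit <- function(method, slope, ci_low, ci_high, intercept,
                            r_squared, n, h0_slope = NA_real_,
                            classification = NA_character_, n_dropped = 0L) {
  structure(list(
    method = method, slope = slope, ci_low = ci_low, ci_high = ci_high,
    intercept = intercept, r_squared = r_squared, n = n,
    h0_slope = h0_slope, classification = classification,
    n_dropped = n_dropped
  ), class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): slope %.4g  [%.4g, %.4g]  intercept %.4g  R^2 %.3g\n",
              x$method, x$n, x$slope, x$ci_low, x$ci_high, x$intercept,
              x$r_squared))
  if (!is.na(x$h0_slope))
    cat(sprintf("  H0 slope %g -> %s\n", x$h0_slope, x$classification))
  invisible(x)
}

#' Standard major axis (Model II) regression
#'
#' Fits the SMA line to a bivariate sample, appropriate when both variables
#' carry error: the slope is `sign(r) * s_y / s_x`, with the analytic
#' `(1 - alpha)` confidence interval
#' `b * (sqrt(B + 1) +/- sqrt(B))`, where
#' `B = F(1 - alpha; 1, n - 2) * (1 - r^2) / (n - 2)`.
#' For allometric analysis pass log-transformed values; slope, CI and R^2 are
#' then invariant to the log base and to unit changes of the raw variables.
#'
#' @param x,y Numeric vectors of equal length (typically log10 of the raw
#'   measurements), n >= 3, neither constant.
#' @param alpha Two-sided significance level for the CI (default 0.05).
#' @param h0 Optional null slope; when supplied the fit is classified against
#'   it (see [classify_scaling()]).
#' @return Object of class `scaling_fit` with elements `method`, `slope`,
#'   `ci_low`, `ci_high`, `intercept`, `r_squared`, `n`, `h0_slope`,
#'   `classification`.
#' @examples
#' x <- log10(c(2.5, 5, 11, 20, 35))
#' sma_fit(x, 1.2 * x - 0.4 + c(0.02, -0.01, 0.03, -0.02, 0), h0 = 1)
#' @export
sma_fit <- function(x, y, alpha = 0.05, h0 = NULL) {
  keep <- is.finite(x) & is.finite(y)
  dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (length(y) != n) stop_invalid_spec("x and y must have equal length")
  if (n < 3L) stop_too_few_points(n, 3L)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    stop_degenerate_input("constant x or y: SMA slope undefined")
  r <- stats::cor(x, y)
  if (abs(r) < 1e-12) stop_ambiguous_sign()
  b <- sign(r) * sy / sx
  a <- mean(y) - b * mean(x)
  # rounding in cor() leaves 1 - r^2 at ~1e-15 on exactly collinear data;
  # snap to zero so a perfect fit reports a degenerate CI
  omr2 <- max(0, 1 - r^2)
  if (omr2 < 1e-12) omr2 <- 0
  B <- stats::qf(1 - alpha, 1, n - 2) * omr2 / (n - 2)
  bounds <- sort(b * (sqrt(B + 1) + c(-1, 1) * sqrt(B)))
  fit <- new_scaling_fit("SMA", b, bounds[1L], bounds[2L], a, r^2, n,
                         n_dropped = dropped)
  if (!is.null(h0)) {
    fit$h0_slope <- h0
    fit$classification <- classify_scaling(fit)
  }
  fit
}

#' Ordinary least squares regression with a t-based slope CI
#'
#' Thin wrapper around [stats::lm()] returning the same `scaling_fit`
#' structure as [sma_fit()]. Used for extensibility (strain at failure), a
#' dimensionless derived quantity for which Model II fitting is not needed.
#'
#' @inheritParams sma_fit
#' @return Object of class `scaling_fit`.
#' @export
ols_fit <- function(x, y, alpha = 0.05, h0 = NULL) {
  keep <- is.finite(x) & is.finite(y)
  dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (length(y) != n) stop_invalid_spec("x and y must have equal length")
  if (n < 3L) stop_too_few_points(n, 3L)
  if (stats::sd(x) == 0) stop_degenerate_input("constant x: OLS slope undefined")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an essentially perfect fit (e.g. constant y); the
  # degenerate CI it yields ([b, b]) is exactly what we want
  ci <- suppressWarnings(stats::confint(fit, "x", level = 1 - alpha))
  r2 <- if (stats::sd(y) == 0) 0 else suppressWarnings(summary(fit)$r.squared)
  out <- new_scaling_fit("OLS", unname(stats::coef(fit)[2L]),
                         ci[1L], ci[2L], unname(stats::coef(fit)[1L]),
                         r2, n, n_dropped = dropped)
  if (!is.null(h0)) {
    out$h0_slope <- h0
    out$classification <- classify_scaling(out)
  }
  out
}

#' Classify a scaling fit against its null slope
#'
#' A slope is called isometric when the geometric null slope falls inside the
#' confidence interval (or "independent" when the null slope is 0, i.e. the
#' property does not change with size); positive allometry when the whole CI
#' lies above the null slope, negative allometry when it lies below.
#'
#' @param fit A `scaling_fit` with `h0_slope` set, or a list with `ci_low`,
#'   `ci_high`, `h0_slope`.
#' @return One of `"isometric"`, `"independent"`, `"positive_allometry"`,
#'   `"negative_allometry"`.
#' @export
classify_scaling <- function(fit) {
  h0 <- fit$h0_slope
  if (is.null(h0) || is.na(h0))
    stop_invalid_spec("fit has no null slope (h0_slope) to classify against")
  if (fit$ci_low > h0) return("positive_allometry")
  if (fit$ci_high < h0) return("negative_allometry")
  if (h0 == 0) "independent" else "isometric"
}

#' Default regression specifications for the scaling table
#'
#' The nine regressions of the standard analysis, each of a morphometric or
#' material property against log10 stipe length: bulb width for adults and
#' juveniles against a null slope of 1 (length vs length), break surface area
#' and failure force against 2 (area vs length), work to failure against 3
#' (volume vs length), and the material properties (Young's modulus, maximum
#' stress, toughness by SMA; strain at failure by OLS) against 0, since a true
#' material property should not change with size. All variables are
#' log10-transformed except strain at failure, which is dimensionless and
#' enters raw.
#'
#' @return Data frame with columns `regression`, `y`, `h0`, `method`,
#'   `log_y`, `subset`.
#' @export
default_regression_specs <- function() {
  data.frame(
    regression = c("bulb_vs_stipe_adult", "bulb_vs_stipe_juvenile",
                   "break_area_vs_stipe", "youngs_modulus_vs_stipe",
                   "sigma_max_vs_stipe", "epsilon_fail_vs_stipe",
                   "toughness_vs_stipe", "F_fail_vs_stipe", "W_fail_vs_stipe"),
    y = c("bulb_width_mm", "bulb_width_mm", "fracture_area", "youngs_modulus",
          "sigma_max", "epsilon_fail", "toughness", "F_fail", "W_fail"),
    h0 = c(1, 1, 2, 0, 0, 0, 0, 2, 3),
    method = c("sma", "sma", "sma", "sma", "sma", "ols", "sma", "sma", "sma"),
    log_y = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    subset = c("adult", "juvenile", "juvenile", "juvenile", "juvenile",
               "juvenile", "juvenile", "juvenile", "juvenile"),
    stringsAsFactors = FALSE
  )
}

#' Run a table of scaling regressions
#'
#' Assembles a per-specimen analysis table by joining morphometrics with
#' extracted material properties on `specimen_id`, then fits each requested
#' regression of a (log10) response on log10 stipe length within the requested
#' life-stage subset. Rows that fail (missing variable, too few points,
#' degenerate input) are reported with `NA` estimates and the error message;
#' other rows are unaffected.
#'
#' @param morphometrics Data frame with at least `specimen_id` and
#'   `stipe_length_cm`; `bulb_width_mm` is needed for the bulb regressions.
#' @param properties Data frame from [extract_properties_table()] (may be
#'   `NULL` or empty for a morphology-only analysis).
#' @param specs Data frame of regression specifications; see
#'   [default_regression_specs()].
#' @param alpha Two-sided CI level, default 0.05.
#' @param juvenile_max_cm,adult_min_cm Stage thresholds in cm: juveniles have
#'   stipes shorter than `juvenile_max_cm`, adults longer than `adult_min_cm`;
#'   specimens in between enter neither stage subset.
#' @return Data frame with one row per spec:
#'   `regression, h0, method, n, slope, ci_low, ci_high, classification,
#'   intercept, r_squared` (plus `note` for failed rows, `NA` otherwise).
#' @export
run_scaling_table <- function(morphometrics, properties = NULL,
                              specs = default_regression_specs(),
                              alpha = 0.05,
                              juvenile_max_cm = 40, adult_min_cm = 200) {
  empty <- data.frame(regression = character(), h0 = numeric(),
                      method = character(), n = integer(), slope = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      classification = character(), intercept = numeric(),
                      r_squared = numeric(), note = character(),
                      stringsAsFactors = FALSE)
  if (is.null(specs) || nrow(specs) == 0L) return(empty)
  if (!all(c("specimen_id", "stipe_length_cm") %in% names(morphometrics)))
    stop_schema_error("morphometrics", setdiff(c("specimen_id", "stipe_length_cm"),
                                               names(morphometrics)))
  tab <- morphometrics
  if (!is.null(properties) && nrow(properties) > 0L)
    tab <- merge(tab, properties, by = "specimen_id", all.x = TRUE)

  rows <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    rows[[i]] <- tryCatch({
      if (!sp$y %in% names(tab)) stop_missing_variable(sp$y)
      sub <- switch(sp$subset,
        juvenile = tab[tab$stipe_length_cm < juvenile_max_cm, ],
        adult = tab[tab$stipe_length_cm > adult_min_cm, ],
        all = tab)
      x <- log10(sub$stipe_length_cm)
      y <- if (isTRUE(sp$log_y)) log10(sub[[sp$y]]) else sub[[sp$y]]
      fit <- if (sp$method == "sma") sma_fit(x, y, alpha = alpha, h0 = sp$h0)
             else ols_fit(x, y, alpha = alpha, h0 = sp$h0)
      data.frame(regression = sp$regression, h0 = sp$h0,
                 method = fit$method, n = fit$n, slope = fit$slope,
                 ci_low = fit$ci_low, ci_high = fit$ci_high,
                 classification = fit$classification,
                 intercept = fit$intercept, r_squared = fit$r_squared,
                 note = NA_character_, stringsAsFactors = FALSE)
    }, kelpmech_error = function(e) {
      data.frame(regression = sp$regression, h0 = sp$h0,
                 method = toupper(sp$method), n = NA_integer_,
                 slope = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 classification = NA_character_, intercept = NA_real_,
                 r_squared = NA_real_, note = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, rows)
}
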