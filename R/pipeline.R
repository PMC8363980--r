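# Pipeline orchestration: configuration, the full analysis
# (mechanics -> scaling table -> breakpoint), and deterministic report output.

#' Analysis configuration
#'
#' Collects every tunable constant of the pipeline with the conventional
#' defaults: 95% confidence intervals, a 50% force-drop failure criterion,
#' base-10 logs, juveniles below 40 cm and adults above 200 cm of stipe
#' length.
#'
#' @param alpha Two-sided significance level for CIs.
#' @param drop_fraction Fractional force drop defining failure.
#' @param modulus_window Modulus window in samples, or `NULL` for automatic.
#' @param juvenile_max_cm,adult_min_cm Life-stage thresholds (cm).
#' @param tare Force baseline handling, see [extract_properties()].
#' @param min_peak Noise floor for failure detection (N).
#' @param seed Optional integer seed recorded with the report.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, drop_fraction = 0.5,
                            modulus_window = NULL,
                            juvenile_max_cm = 40, adult_min_cm = 200,
                            tare = "first", min_peak = 0.1, seed = NULL) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop_invalid_spec("alpha must lie strictly between 0 and 1")
  if (!is.finite(drop_fraction) || drop_fraction <= 0 || drop_fraction >= 1)
    stop_invalid_spec("drop_fraction must lie strictly between 0 and 1")
  if (juvenile_max_cm >= adult_min_cm)
    stop_invalid_spec("juvenile_max_cm must be below adult_min_cm")
  structure(list(alpha = alpha, drop_fraction = drop_fraction,
                 modulus_window = modulus_window,
                 juvenile_max_cm = juvenile_max_cm,
                 adult_min_cm = adult_min_cm,
                 tare = tare, min_peak = min_peak, seed = seed),
            class = "analysis_config")
}

#' Run the full analysis
#'
#' Extracts material properties from every non-excluded tensile record, fits
#' the default scaling table, and estimates the isometry-to-allometry
#' breakpoint on the pooled log10 bulb-width vs log10 stipe-length data. The
#' result is deterministic given inputs and configuration. Per-specimen and
#' per-regression failures are logged, never fatal; only a wholly infeasible
#' analysis (no morphometrics at all) aborts.
#'
#' @param morphometrics Data frame in the morphometric schema (see
#'   [read_morphometrics_csv()]).
#' @param tensile_records List of [tensile_record()] objects (may be empty
#'   for a morphology-only analysis).
#' @param config An [analysis_config()].
#' @param specs Regression specifications, default
#'   [default_regression_specs()].
#' @return Object of class `analysis_report` with elements `scaling`
#'   (data frame), `breakpoint` (a `breakpoint_fit` or `NULL`), `properties`,
#'   `exclusions`, `config`.
#' @examples
#' morph <- simulate_morphometrics(seed = 7)$records
#' tens <- lapply(1:5, function(i)
#'   simulate_tensile_test(seed = i, specimen_id = morph$specimen_id[i])$record)
#' run_full_analysis(morph, tens)
#' @export
run_full_analysis <- function(morphometrics, tensile_records = list(),
                              config = analysis_config(),
                              specs = default_regression_specs()) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(morphometrics) || nrow(morphometrics) == 0L)
    stop_invalid_spec("no morphometric records: every regression is infeasible")

  mech <- extract_properties_table(tensile_records,
                                   drop_fraction = config$drop_fraction,
                                   window = config$modulus_window,
                                   tare = config$tare,
                                   min_peak = config$min_peak)
  # tensile specimens need a stipe length (cm) for the biomechanical rows;
  # take it from the record geometry when absent from the morphometric table
  props <- mech$properties
  if (nrow(props) > 0L &&
      !all(props$specimen_id %in% morphometrics$specimen_id)) {
    extra <- props[!props$specimen_id %in% morphometrics$specimen_id, ]
    add <- data.frame(specimen_id = extra$specimen_id,
                      life_stage = "juvenile",
                      stipe_length_cm = extra$initial_length / 10,
                      bulb_width_mm = NA_real_,
                      stringsAsFactors = FALSE)
    for (nm in setdiff(names(morphometrics), names(add))) add[[nm]] <- NA
    morphometrics <- rbind(morphometrics[names(morphometrics)],
                           add[names(morphometrics)])
  }

  scaling <- run_scaling_table(morphometrics, props, specs = specs,
                               alpha = config$alpha,
                               juvenile_max_cm = config$juvenile_max_cm,
                               adult_min_cm = config$adult_min_cm)

  pooled <- morphometrics[is.finite(morphometrics$stipe_length_cm) &
                          is.finite(morphometrics$bulb_width_mm) &
                          morphometrics$bulb_width_mm > 0, ]
  bp <- tryCatch(
    segmented_fit(log10(pooled$stipe_length_cm), log10(pooled$bulb_width_mm)),
    kelpmech_error = function(e) NULL)

  structure(list(scaling = scaling, breakpoint = bp,
                 properties = props, exclusions = mech$exclusions,
                 config = config),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Kelp stipe scaling analysis\n")
  cat(sprintf("  %d specimens with material properties, %d excluded\n",
              nrow(x$properties), nrow(x$exclusions)))
  cat("  Scaling table:\n")
  print(x$scaling[, c("regression", "h0", "method", "n", "slope",
                      "ci_low", "ci_high", "classification")],
        row.names = FALSE, digits = 3)
  if (!is.null(x$breakpoint))
    cat(sprintf("  Breakpoint: %.1f cm (SE %.1f cm)\n",
                x$breakpoint$psi_raw, x$breakpoint$se_psi_raw))
  invisible(x)
}

#' Write an analysis report to a directory
#'
#' Emits `scaling.csv` (the publication-style scaling table with exactly the columns
#' `regression,h0,method,n,slope,ci_low,ci_high,classification,intercept,
#' r_squared`), `breakpoint.csv`, `properties.csv`, `exclusions.csv` and
#' `config.json`. Serialization is deterministic: identical reports yield
#' byte-identical files.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(scaling = file.path(dir, "scaling.csv"),
             breakpoint = file.path(dir, "breakpoint.csv"),
             properties = file.path(dir, "properties.csv"),
             exclusions = file.path(dir, "exclusions.csv"),
             config = file.path(dir, "config.json"))
  scaling_cols <- c("regression", "h0", "method", "n", "slope", "ci_low",
                    "ci_high", "classification", "intercept", "r_squared")
  write_csv_precise(report$scaling[, scaling_cols, drop = FALSE],
                    paths["scaling"])
  bp <- report$breakpoint
  bp_df <- if (is.null(bp)) {
    data.frame(psi_cm = NA_real_, se_cm = NA_real_, slope_left = NA_real_,
               slope_right = NA_real_, converged = NA, iterations = NA_integer_,
               sse = NA_real_)
  } else {
    data.frame(psi_cm = bp$psi_raw, se_cm = bp$se_psi_raw,
               slope_left = bp$slope_left, slope_right = bp$slope_right,
               converged = bp$converged, iterations = bp$iterations,
               sse = bp$sse)
  }
  write_csv_precise(bp_df, paths["breakpoint"])
  write_csv_precise(report$properties, paths["properties"])
  write_csv_precise(report$exclusions, paths["exclusions"])
  cfg <- report$config
  jsonlite::write_json(unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
                       paths["config"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Rebuild an analysis configuration from a report's config.json
#'
#' @param path Path to a `config.json` written by [write_report()].
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, vals)
}
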