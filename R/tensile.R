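# Tensile mechanics: from raw force-extension records to material properties.
#
# Unit conventions are fixed package-wide: extensions in mm, forces in N,
# lengths (L0) in mm, areas in mm^2. Derived quantities: work in J
# (N.mm x 1e-3), stress in Pa (N/mm^2 x 1e6), toughness in MJ m^-3
# (Pa x 1e-6). With these conventions toughness * area * L0 * 1e-3 = W_fail
# exactly when both integrals share the same bounds.

#' Construct a tensile test record
#'
#' A `tensile_record` holds one specimen's force-extension time series from a
#' tensile pull to failure, together with the geometry needed to convert it to
#' a stress-strain curve: the initial stipe length and the cross-sectional
#' (fracture surface) area at the break.
#'
#' @param specimen_id Character scalar identifying the specimen.
#' @param extension Numeric vector, crosshead extension in mm; non-decreasing.
#' @param force Numeric vector, measured force in N; same length as
#'   `extension`, all finite.
#' @param initial_length Initial stipe length L0 in mm (> 0).
#' @param fracture_area Cross-sectional area of the break in mm^2 (> 0).
#' @param sampling_rate Nominal sampling rate in Hz (default 100).
#' @param crosshead_rate Nominal crosshead speed in mm/min (default 50.8).
#' @param excluded Logical; `TRUE` if the specimen failed at the clamp or in
#'   the cradle and must be excluded from analysis.
#' @return An object of class `tensile_record`.
#' @examples
#' rec <- tensile_record("demo", extension = 0:10, force = 0:10 / 2,
#'                       initial_length = 100, fracture_area = 2)
#' rec
#' @export
tensile_record <- function(specimen_id, extension, force,
                           initial_length, fracture_area,
                           sampling_rate = 100, crosshead_rate = 50.8,
                           excluded = FALSE) {
  if (!is.character(specimen_id) || length(specimen_id) != 1L)
    stop_invalid_spec("specimen_id must be a single character string")
  extension <- as.numeric(extension)
  force <- as.numeric(force)
  n <- length(extension)
  if (length(force) != n)
    stop_invalid_spec("extension and force must have equal length")
  if (n < 3L)
    stop_degenerate_record(sprintf("record '%s' has %d samples; need >= 3",
                                   specimen_id, n))
  if (!all(is.finite(force)))
    stop_invalid_spec(sprintf("record '%s': non-finite force values", specimen_id))
  if (!all(is.finite(extension)))
    stop_invalid_spec(sprintf("record '%s': non-finite extension values", specimen_id))
  if (any(diff(extension) < 0))
    stop_invalid_spec(sprintf("record '%s': extension must be non-decreasing",
                              specimen_id))
  if (!is.finite(initial_length) || initial_length <= 0)
    stop_invalid_spec(sprintf("record '%s': initial_length must be > 0", specimen_id))
  if (!is.finite(fracture_area) || fracture_area <= 0)
    stop_invalid_spec(sprintf("record '%s': fracture_area must be > 0", specimen_id))
  structure(list(
    specimen_id = specimen_id,
    extension = extension,
    force = force,
    initial_length = initial_length,
    fracture_area = fracture_area,
    sampling_rate = sampling_rate,
    crosshead_rate = crosshead_rate,
    excluded = isTRUE(excluded)
  ), class = "tensile_record")
}

#' @export
print.tensile_record <- function(x, ...) {
  cat(sprintf("Tensile record '%s': %d samples, L0 = %.1f mm, A = %.3f mm^2%s\n",
              x$specimen_id, length(x$force), x$initial_length, x$fracture_area,
              if (x$excluded) " [EXCLUDED]" else ""))
  cat(sprintf("  extension %.3f-%.3f mm, peak force %.3f N\n",
              min(x$extension), max(x$extension), max(x$force)))
  invisible(x)
}

#' Detect catastrophic failure as a fractional drop from the running peak
#'
#' Failure is declared at the first sample whose force has fallen to
#' `(1 - drop_fraction)` of the running maximum force seen so far (default: a
#' 50% drop). Using the running maximum, rather than the global maximum, means
#' noise recorded after the break can never move the detected failure earlier
#' or later. `F_fail` is the peak force preceding the qualifying drop.
#'
#' A centred median filter (width 5) is applied to the force trace for
#' detection only, and the running peak must exceed `min_peak` before a drop
#' can qualify; both guard against load-cell noise, in the toe region
#' especially, where the running maximum is itself noise-sized.
#'
#' @param record A [tensile_record()].
#' @param drop_fraction Fractional force drop that defines failure, in (0, 1).
#' @param smooth Apply the width-5 median filter before detection? The
#'   returned `F_fail` always comes from the unfiltered trace.
#' @param min_peak Minimum running-peak force (N) for a drop to qualify.
#' @return List with `failure_index` (1-based sample index of the qualifying
#'   drop) and `F_fail` (N, the running-maximum force at that index).
#' @export
detect_failure <- function(record, drop_fraction = 0.5, smooth = TRUE,
                           min_peak = 0.1) {
  stopifnot(inherits(record, "tensile_record"))
  if (!is.finite(drop_fraction) || drop_fraction <= 0 || drop_fraction >= 1)
    stop_invalid_spec("drop_fraction must lie strictly between 0 and 1")
  force <- record$force
  n <- length(force)
  if (n < 3L) stop_degenerate_record("fewer than 3 samples")
  f_det <- force
  if (isTRUE(smooth) && n >= 5L)
    f_det <- stats::runmed(force, k = 5L, endrule = "median")
  runmax <- cummax(f_det)
  qualifies <- runmax > min_peak & f_det <= (1 - drop_fraction) * runmax
  if (!any(qualifies)) stop_no_failure()
  idx <- which(qualifies)[1L]
  list(failure_index = idx, F_fail = max(force[seq_len(idx)]))
}

#' Work to failure: area under the force-extension curve
#'
#' Trapezoidal integral of force over extension from the first sample to
#' `peak_index`, converted from N.mm to J.
#'
#' @param record A [tensile_record()].
#' @param peak_index Integration endpoint (1-based sample index), normally the
#'   peak-force sample preceding failure.
#' @return Work in J.
#' @export
work_to_failure <- function(record, peak_index) {
  stopifnot(inherits(record, "tensile_record"))
  n <- length(record$force)
  if (peak_index > n) stop_invalid_spec("peak_index beyond record length")
  if (peak_index < 2L)
    stop_degenerate_record("peak_index < 2: no interval to integrate")
  i <- seq_len(peak_index)
  pracma::trapz(record$extension[i], record$force[i]) * 1e-3
}

#' Convert a tensile record to a stress-strain series
#'
#' Engineering (conventional) definitions: stress is force over the fracture
#' surface area, sigma = F/A (N/mm^2, reported in Pa); strain is extension
#' relative to the first sample over the initial stipe length,
#' eps = (x - x\[1\]) / L0 (dimensionless).
#'
#' @param record A [tensile_record()].
#' @return Data frame with columns `strain` (dimensionless) and `stress` (Pa),
#'   one row per sample.
#' @export
to_stress_strain <- function(record) {
  stopifnot(inherits(record, "tensile_record"))
  data.frame(
    strain = (record$extension - record$extension[1L]) / record$initial_length,
    stress = record$force / record$fracture_area * 1e6
  )
}

#' Young's modulus as the steepest local slope of the stress-strain curve
#'
#' Fits an OLS line of stress on strain in every contiguous window of
#' `window` samples up to `peak_index` and returns the maximum slope — the
#' tangent modulus of the stiffest (linear-elastic) region, which a toe region
#' of lower slope cannot contaminate. Exact on noiseless linear curves for any
#' valid window.
#'
#' @param stress_strain Data frame from [to_stress_strain()].
#' @param peak_index Last sample to consider (1-based).
#' @param window Window width in samples (>= 3).
#' @return Young's modulus in Pa.
#' @export
estimate_modulus <- function(stress_strain, peak_index, window) {
  if (window < 3L) stop_invalid_spec("window must be >= 3 samples")
  n <- min(peak_index, nrow(stress_strain))
  if (n < window)
    stop_degenerate_record(sprintf(
      "only %d pre-peak samples for a window of %d", n, window))
  # centre to tame cancellation in the rolling sums
  x <- stress_strain$strain[seq_len(n)]
  y <- stress_strain$stress[seq_len(n)]
  x <- x - mean(x)
  y <- y - mean(y)
  cx <- c(0, cumsum(x)); cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(x * x)); cxy <- c(0, cumsum(x * y))
  lo <- seq_len(n - window + 1L)   # window start indices
  hi <- lo + window - 1L
  sx <- cx[hi + 1L] - cx[lo]
  sy <- cy[hi + 1L] - cy[lo]
  sxx <- cxx[hi + 1L] - cxx[lo]
  sxy <- cxy[hi + 1L] - cxy[lo]
  denom <- window * sxx - sx^2
  num <- window * sxy - sx * sy
  ok <- denom > .Machine$double.eps * window * pmax(sxx, 1)
  if (!any(ok)) stop_zero_strain_range()
  max(num[ok] / denom[ok])
}

#' Toughness: area under the stress-strain curve
#'
#' Trapezoidal integral of stress over strain from the first sample to
#' `peak_index`, converted from Pa (J m^-3) to MJ m^-3.
#'
#' @inheritParams estimate_modulus
#' @return Toughness in MJ m^-3.
#' @export
compute_toughness <- function(stress_strain, peak_index) {
  if (peak_index < 2L)
    stop_degenerate_record("peak_index < 2: no interval to integrate")
  i <- seq_len(min(peak_index, nrow(stress_strain)))
  pracma::trapz(stress_strain$strain[i], stress_strain$stress[i]) * 1e-6
}

#' Extract all material and structural properties from a tensile record
#'
#' Composite of the tensile-mechanics operations: tares the force trace,
#' detects the catastrophic failure drop, locates the peak-force sample
#' preceding it, and computes the seven properties. All integrals and the
#' failure strain share the peak-force sample as their endpoint, so the energy
#' identity `toughness * fracture_area * L0 * 1e-3 = W_fail` holds exactly.
#'
#' @param record A [tensile_record()]; must not be flagged excluded.
#' @param drop_fraction Passed to [detect_failure()].
#' @param window Modulus window in samples, or `NULL` for the default
#'   `max(5, round(0.1 * peak_index))`.
#' @param smooth Median-filter the force trace for failure detection?
#' @param tare Baseline handling for force: `"first"` subtracts the first
#'   sample's force (default; exact on records that start at zero load),
#'   `"mean5"` subtracts the mean of the first five samples, `"none"` leaves
#'   the trace untouched. Tared forces are floored at zero.
#' @param min_peak Passed to [detect_failure()].
#' @return Object of class `material_properties`: a list with `specimen_id`,
#'   `F_max` and `F_fail` (N), `W_fail` (J), `epsilon_fail` (dimensionless),
#'   `sigma_max` (Pa), `youngs_modulus` (Pa), `toughness` (MJ m^-3),
#'   `failure_index` and `peak_index` (1-based sample indices).
#' @examples
#' sim <- simulate_tensile_test(seed = 1)
#' props <- extract_properties(sim$record)
#' props
#' @export
extract_properties <- function(record, drop_fraction = 0.5, window = NULL,
                               smooth = TRUE, tare = c("first", "mean5", "none"),
                               min_peak = 0.1) {
  stopifnot(inherits(record, "tensile_record"))
  if (record$excluded) stop_excluded(record$specimen_id)
  tare <- match.arg(tare)
  baseline <- switch(tare,
    first = record$force[1L],
    mean5 = mean(record$force[seq_len(min(5L, length(record$force)))]),
    none = 0)
  rec <- record
  rec$force <- pmax(record$force - baseline, 0)

  fail <- detect_failure(rec, drop_fraction = drop_fraction, smooth = smooth,
                         min_peak = min_peak)
  peak_index <- which.max(rec$force[seq_len(fail$failure_index)])
  F_max <- rec$force[peak_index]

  ss <- to_stress_strain(rec)
  if (is.null(window)) window <- max(5L, as.integer(round(0.1 * peak_index)))

  structure(list(
    specimen_id = rec$specimen_id,
    F_max = F_max,
    F_fail = fail$F_fail,
    W_fail = work_to_failure(rec, peak_index),
    epsilon_fail = ss$strain[peak_index],
    sigma_max = F_max / rec$fracture_area * 1e6,
    youngs_modulus = estimate_modulus(ss, peak_index, window),
    toughness = compute_toughness(ss, peak_index),
    failure_index = fail$failure_index,
    peak_index = peak_index,
    fracture_area = rec$fracture_area,
    initial_length = rec$initial_length
  ), class = "material_properties")
}

#' @export
print.material_properties <- function(x, ...) {
  cat(sprintf("Material properties for '%s'\n", x$specimen_id))
  cat(sprintf("  F_max   %8.3f N     F_fail    %8.3f N     W_fail %10.4g J\n",
              x$F_max, x$F_fail, x$W_fail))
  cat(sprintf("  sigma_max %8.4g Pa  E %10.4g Pa  eps_fail %6.3f  toughness %8.4g MJ/m^3\n",
              x$sigma_max, x$youngs_modulus, x$epsilon_fail, x$toughness))
  invisible(x)
}

#' Tabulate material properties for a list of records
#'
#' Runs [extract_properties()] over a list of tensile records, collecting
#' failures (excluded specimens, records with no detectable failure drop) into
#' an exclusions log instead of aborting.
#'
#' @param records List of [tensile_record()] objects.
#' @param ... Passed to [extract_properties()].
#' @return List with `properties` (data frame, one row per analysed specimen)
#'   and `exclusions` (data frame with `specimen_id`, `reason`).
#' @export
extract_properties_table <- function(records, ...) {
  rows <- list(); excl <- list()
  for (rec in records) {
    res <- tryCatch(extract_properties(rec, ...), kelpmech_error = function(e) e)
    if (inherits(res, "kelpmech_error")) {
      excl[[length(excl) + 1L]] <- data.frame(
        specimen_id = rec$specimen_id,
        reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- as.data.frame(unclass(res),
                                                 stringsAsFactors = FALSE)
    }
  }
  empty_props <- data.frame(specimen_id = character(), F_max = numeric(),
                            F_fail = numeric(), W_fail = numeric(),
                            epsilon_fail = numeric(), sigma_max = numeric(),
                            youngs_modulus = numeric(), toughness = numeric(),
                            failure_index = integer(), peak_index = integer(),
                            fracture_area = numeric(), initial_length = numeric(),
                            stringsAsFactors = FALSE)
  list(
    properties = if (length(rows)) do.call(rbind, rows) else empty_props,
    exclusions = if (length(excl)) do.call(rbind, excl)
                 else data.frame(specimen_id = character(), reason = character(),
                                 stringsAsFactors = FALSE)
  )
}
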