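# Seeded synthetic-data generators with known ground truth. These emulate the
# study design the pipeline targets: a two-segment log-log bulb-vs-stipe
# relationship with a breakpoint near the top of the juvenile size range, and
# tensile force-extension curves with a toe region, a linear elastic region,
# and a catastrophic force drop at failure.

#' Simulate a two-stage morphometric dataset
#'
#' Draws stipe lengths log-uniformly within a juvenile and an adult range and
#' generates bulb widths from a continuous piecewise log-log power law: slope
#' `slope_juvenile` below the breakpoint `psi_cm`, `slope_adult` above it,
#' with Gaussian noise on the log10 scale (multiplicative biological
#' variation). Stipe widths are generated from auxiliary power laws so records
#' carry the full morphometric schema. Defaults encode the study design:
#' 22 juveniles (2.1-36.1 cm) and 27 adults (200-3000 cm), slopes 1.19 and
#' 0.70 around a 33.2 cm breakpoint, log10 noise sd 0.08.
#'
#' @param n_juvenile,n_adult Specimens per stage.
#' @param psi_cm Breakpoint stipe length, cm.
#' @param slope_juvenile,slope_adult Log-log slopes below/above the breakpoint.
#' @param intercept_log Intercept of the juvenile segment, log10(mm) at
#'   stipe length 1 cm.
#' @param noise_sd_log Gaussian noise sd on log10 bulb width.
#' @param stipe_range_juvenile,stipe_range_adult Stipe-length ranges (cm).
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `records` (data frame in the morphometric CSV schema)
#'   and `truth` (the generating parameters).
#' @examples
#' sim <- simulate_morphometrics(seed = 1)
#' head(sim$records)
#' @export
simulate_morphometrics <- function(n_juvenile = 22, n_adult = 27,
                                   psi_cm = 33.2,
                                   slope_juvenile = 1.19, slope_adult = 0.70,
                                   intercept_log = -0.3, noise_sd_log = 0.08,
                                   stipe_range_juvenile = c(2.1, 36.1),
                                   stipe_range_adult = c(200, 3000),
                                   seed = NULL) {
  if (n_juvenile < 0 || n_adult < 0 || n_juvenile + n_adult < 1)
    stop_invalid_spec("need at least one specimen")
  if (!is.finite(noise_sd_log) || noise_sd_log < 0)
    stop_invalid_spec("noise_sd_log must be >= 0")
  for (rg in list(stipe_range_juvenile, stipe_range_adult))
    if (length(rg) != 2 || any(rg <= 0) || rg[1] > rg[2])
      stop_invalid_spec("stipe ranges must be positive and ordered")
  if (!is.finite(psi_cm) || psi_cm <= 0) stop_invalid_spec("psi_cm must be > 0")
  if (!is.null(seed)) set.seed(seed)

  draw_loguniform <- function(n, rg) 10^stats::runif(n, log10(rg[1]), log10(rg[2]))
  stipe <- c(draw_loguniform(n_juvenile, stipe_range_juvenile),
             draw_loguniform(n_adult, stipe_range_adult))
  lt <- log10(stipe)
  Tpsi <- log10(psi_cm)
  mu <- ifelse(lt <= Tpsi,
               intercept_log + slope_juvenile * lt,
               intercept_log + slope_juvenile * Tpsi + slope_adult * (lt - Tpsi))
  bulb <- 10^(mu + stats::rnorm(length(lt), 0, noise_sd_log))

  # auxiliary width measurements: plausible power laws, not analysis targets
  below <- 10^(-0.55 + 0.75 * lt + stats::rnorm(length(lt), 0, 0.05))
  narrow <- below * 10^(-0.15 + stats::rnorm(length(lt), 0, 0.03))
  above <- below * 10^(-0.05 + stats::rnorm(length(lt), 0, 0.04))

  records <- data.frame(
    specimen_id = sprintf("sim%03d", seq_along(stipe)),
    life_stage = ifelse(stipe < 40, "juvenile", "adult"),
    stipe_length_cm = stipe,
    bulb_width_mm = bulb,
    stipe_width_below_bulb_mm = below,
    stipe_width_narrowest_mm = narrow,
    stipe_width_above_holdfast_mm = above,
    stringsAsFactors = FALSE
  )
  list(records = records,
       truth = list(psi_cm = psi_cm, psi_log = Tpsi,
                    slope_juvenile = slope_juvenile, slope_adult = slope_adult,
                    intercept_log = intercept_log, noise_sd_log = noise_sd_log,
                    n_juvenile = n_juvenile, n_adult = n_adult))
}

#' Simulate a tensile test to failure
#'
#' Builds a force-extension record sampled at `sampling_rate` while the
#' crosshead advances at `crosshead_rate`. The noiseless stress-strain curve
#' has a quadratic toe over strains `[0, toe_fraction * epsilon_fail]` joined
#' with continuous slope to a linear elastic region of slope
#' `youngs_modulus`, reaching `sigma_max` at `epsilon_fail`; the force then
#' collapses to 10% of its peak (a catastrophic >50% drop). Gaussian noise of
#' sd `noise_sd` is added to the force trace.
#'
#' The four curve parameters are redundant: geometry requires
#' `sigma_max = youngs_modulus * epsilon_fail * (1 - toe_fraction / 2)`.
#' Supply any three (leave one `NULL`) and the fourth is derived; supplying
#' all four raises an error unless they are consistent.
#'
#' @param youngs_modulus Elastic-region slope E, Pa.
#' @param sigma_max Stress at failure, Pa, or `NULL` to derive.
#' @param epsilon_fail Strain at failure (dimensionless).
#' @param toe_fraction Fraction of `epsilon_fail` spent in the toe region, in
#'   \[0, 0.5), or `NULL` to derive from `sigma_max`.
#' @param L0 Initial stipe length, mm.
#' @param area Fracture surface area, mm^2.
#' @param sampling_rate Hz. @param crosshead_rate mm/min.
#' @param noise_sd Gaussian force noise sd, N.
#' @param seed Integer seed. @param specimen_id Identifier for the record.
#' @return List with `record` (a [tensile_record()]) and `truth`: the
#'   generating `youngs_modulus`, `sigma_max`, `epsilon_fail`, `toe_fraction`,
#'   `F_max` (N), and the analytic `toughness` (MJ m^-3) and `W_fail` (J) of
#'   the noiseless continuous curve.
#' @examples
#' sim <- simulate_tensile_test(seed = 42)
#' extract_properties(sim$record)
#' @export
simulate_tensile_test <- function(youngs_modulus = 4e6, sigma_max = NULL,
                                  epsilon_fail = 0.45, toe_fraction = 0.2,
                                  L0 = 100, area = 2,
                                  sampling_rate = 100, crosshead_rate = 50.8,
                                  noise_sd = 0.02, seed = NULL,
                                  specimen_id = "sim") {
  E <- youngs_modulus
  if (is.null(E) || !is.finite(E) || E <= 0)
    stop_invalid_spec("youngs_modulus must be a positive number")
  if (!is.finite(epsilon_fail) || epsilon_fail <= 0)
    stop_invalid_spec("epsilon_fail must be > 0")
  for (v in list(L0, area, sampling_rate, crosshead_rate))
    if (!is.finite(v) || v <= 0) stop_invalid_spec("geometry and rates must be > 0")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop_invalid_spec("noise_sd must be >= 0")

  # resolve the redundant (E, sigma_max, epsilon_fail, toe_fraction) set
  if (is.null(toe_fraction) && is.null(sigma_max))
    stop_invalid_spec("supply at least one of toe_fraction and sigma_max")
  if (is.null(toe_fraction))
    toe_fraction <- 2 * (1 - sigma_max / (E * epsilon_fail))
  consistent_sigma <- E * epsilon_fail * (1 - toe_fraction / 2)
  if (is.null(sigma_max)) sigma_max <- consistent_sigma
  if (!is.finite(toe_fraction) || toe_fraction < 0 || toe_fraction >= 0.5)
    stop_inconsistent_spec(sprintf(
      "implied toe fraction %.3g outside [0, 0.5): sigma_max unreachable at epsilon_fail with this modulus",
      toe_fraction))
  if (abs(sigma_max - consistent_sigma) > 1e-8 * consistent_sigma)
    stop_inconsistent_spec(
      "sigma_max, youngs_modulus, epsilon_fail and toe_fraction are inconsistent; leave one NULL to derive it")

  if (!is.null(seed)) set.seed(seed)
  eps_t <- toe_fraction * epsilon_fail
  sigma_at <- function(eps) {
    ifelse(eps <= eps_t & eps_t > 0,
           E / (2 * eps_t) * eps^2,
           sigma_max + E * (eps - epsilon_fail))
  }
  step_mm <- crosshead_rate / 60 / sampling_rate
  x_fail <- epsilon_fail * L0
  x <- seq(0, x_fail, by = step_mm)
  if (x[length(x)] < x_fail) x <- c(x, x_fail)  # sample exactly at failure
  eps <- x / L0
  force <- sigma_at(eps) * area * 1e-6          # Pa * mm^2 -> N
  F_peak <- force[length(force)]
  # catastrophic drop: three post-failure samples at 10% of peak
  x <- c(x, x_fail + step_mm * (1:3))
  force <- c(force, rep(0.1 * F_peak, 3))
  if (noise_sd > 0) force <- force + stats::rnorm(length(force), 0, noise_sd)

  record <- tensile_record(specimen_id, extension = x, force = force,
                           initial_length = L0, fracture_area = area,
                           sampling_rate = sampling_rate,
                           crosshead_rate = crosshead_rate)
  toe_area <- if (eps_t > 0) E * eps_t^2 / 6 else 0          # int a*eps^2
  lin_area <- (sigma_at(eps_t) + sigma_max) / 2 * (epsilon_fail - eps_t)
  toughness <- (toe_area + lin_area) * 1e-6                  # Pa -> MJ/m^3
  list(record = record,
       truth = list(youngs_modulus = E, sigma_max = sigma_max,
                    epsilon_fail = epsilon_fail, toe_fraction = toe_fraction,
                    F_max = sigma_max * area * 1e-6,
                    toughness = toughness,
                    W_fail = toughness * area * L0 * 1e-3))
}

#' Simulate a power-law property-vs-length sample
#'
#' Draws `n` stipe lengths log-uniformly on `x_range` and generates
#' `log10(y) = intercept_log + slope * log10(x) + N(0, noise_sd_log)`.
#' Returns raw-scale vectors; log10-transform before fitting.
#'
#' @param n Sample size (>= 3).
#' @param slope,intercept_log Generating power law (log10 scale).
#' @param noise_sd_log Gaussian noise sd on log10(y).
#' @param seed Integer seed.
#' @param x_range Range of x (default the juvenile stipe range, cm).
#' @return List with `x`, `y` (raw scale) and `truth`.
#' @export
simulate_property_scaling <- function(n, slope, intercept_log = 0,
                                      noise_sd_log = 0.1, seed = NULL,
                                      x_range = c(2.1, 36.1)) {
  if (n < 3) stop_invalid_spec("n must be >= 3")
  if (!is.finite(slope)) stop_invalid_spec("slope must be finite")
  if (!is.finite(noise_sd_log) || noise_sd_log < 0)
    stop_invalid_spec("noise_sd_log must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  x <- 10^stats::runif(n, log10(x_range[1]), log10(x_range[2]))
  y <- 10^(intercept_log + slope * log10(x) + stats::rnorm(n, 0, noise_sd_log))
  list(x = x, y = y,
       truth = list(slope = slope, intercept_log = intercept_log,
                    noise_sd_log = noise_sd_log))
}

#' Simulate a complete study: morphometrics plus juvenile tensile tests
#'
#' Couples [simulate_morphometrics()] with one [simulate_tensile_test()] per
#' juvenile specimen, drawing fracture area, Young's modulus and strain at
#' failure from size power laws so the biomechanical scaling regressions see
#' realistic structure: break area scales with exponent 0.66, the modulus
#' with -1.23, strain at failure is size-independent. Adults carry
#' morphometrics only, mirroring a design in which drift-collected adults are
#' not mechanically tested.
#'
#' @inheritParams simulate_morphometrics
#' @param area_law,modulus_law Named vectors `c(intercept_log, slope, sd)`
#'   giving the log10 power law (vs log10 stipe length in cm) for fracture
#'   area (mm^2) and Young's modulus (Pa).
#' @param epsilon_mean,epsilon_sd Mean and sd of strain at failure.
#' @param noise_sd Force noise sd (N) for the tensile records.
#' @param ... Passed to [simulate_morphometrics()].
#' @return List with `morphometrics` (data frame), `tensile_records` (list of
#'   [tensile_record()]), and `truth` (generating parameters, including one
#'   entry per tensile specimen).
#' @examples
#' study <- simulate_study(seed = 7)
#' report <- run_full_analysis(study$morphometrics, study$tensile_records)
#' @export
simulate_study <- function(seed = NULL,
                           area_law = c(intercept_log = -0.36, slope = 0.66,
                                        sd = 0.1),
                           modulus_law = c(intercept_log = 7.83, slope = -1.23,
                                           sd = 0.08),
                           epsilon_mean = 0.45, epsilon_sd = 0.04,
                           noise_sd = 0.016, ...) {
  if (!is.null(seed)) set.seed(seed)
  morph <- simulate_morphometrics(seed = NULL, ...)
  juv <- morph$records[morph$records$life_stage == "juvenile", , drop = FALSE]
  tens <- vector("list", nrow(juv))
  truth_tens <- vector("list", nrow(juv))
  for (i in seq_len(nrow(juv))) {
    ls_log <- log10(juv$stipe_length_cm[i])
    area <- 10^(area_law[["intercept_log"]] + area_law[["slope"]] * ls_log +
                stats::rnorm(1, 0, area_law[["sd"]]))
    E <- 10^(modulus_law[["intercept_log"]] + modulus_law[["slope"]] * ls_log +
             stats::rnorm(1, 0, modulus_law[["sd"]]))
    eps <- max(0.1, stats::rnorm(1, epsilon_mean, epsilon_sd))
    sim <- simulate_tensile_test(
      youngs_modulus = E, sigma_max = NULL, epsilon_fail = eps,
      toe_fraction = 0.2, L0 = juv$stipe_length_cm[i] * 10, area = area,
      noise_sd = noise_sd, seed = NULL, specimen_id = juv$specimen_id[i])
    tens[[i]] <- sim$record
    truth_tens[[i]] <- sim$truth
  }
  names(truth_tens) <- juv$specimen_id
  list(morphometrics = morph$records, tensile_records = tens,
       truth = c(morph$truth,
                 list(area_law = area_law, modulus_law = modulus_law,
                      epsilon_mean = epsilon_mean, tensile = truth_tens)))
}
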