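# Segmented (broken-stick) regression: a single breakpoint between two linear
# regimes, estimated by iterative linearization, plus a brute-force grid
# search used as an independent oracle.

new_breakpoint_fit <- function(psi_log, se_psi_log, slope_left, slope_right,
                               intercept, iterations, converged, sse, n,
                               boundary = FALSE, method = "segmented") {
  psi_raw <- 10^psi_log
  structure(list(
    psi_log = psi_log,
    psi_raw = psi_raw,
    se_psi_log = se_psi_log,
    se_psi_raw = log(10) * psi_raw * se_psi_log,   # delta method
    slope_left = slope_left, slope_right = slope_right,
    intercept = intercept, iterations = iterations, converged = converged,
    sse = sse, n = n, boundary = boundary, method = method
  ), class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf("Breakpoint fit (%s, n = %d)\n", x$method, x$n))
  cat(sprintf("  psi = %.4g (log10 scale)  ->  %.4g raw", x$psi_log, x$psi_raw))
  if (is.finite(x$se_psi_raw)) cat(sprintf("  (SE %.3g raw)", x$se_psi_raw))
  cat("\n")
  cat(sprintf("  slopes: %.4g -> %.4g   SSE %.4g   %s after %s iterations%s\n",
              x$slope_left, x$slope_right, x$sse,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              ifelse(is.na(x$iterations), "-", x$iterations),
              if (x$boundary) " [breakpoint clamped at boundary]" else ""))
  invisible(x)
}

seg_ols <- function(x, y, psi, with_v = FALSE) {
  U <- pmax(x - psi, 0)
  X <- if (with_v) cbind(1, x, U, -(x > psi)) else cbind(1, x, U)
  fit <- stats::lm.fit(X, y)
  fit$sse <- sum(fit$residuals^2)
  fit
}

#' Segmented regression by iterative linearization
#'
#' Fits a continuous two-segment linear model with an estimated breakpoint
#' psi. At each step, `y` is regressed on `{1, x, (x - psi)+, -1[x > psi]}`;
#' the ratio of the indicator coefficient (gamma) to the slope-change
#' coefficient (beta) gives the update `psi <- psi + gamma/beta`, iterated to
#' convergence with step-halving whenever a full step would increase the
#' residual sum of squares. At convergence `SE(psi) = SE(gamma)/|beta|`.
#'
#' The fit is intended for log10-log10 allometry data: `psi_raw = 10^psi_log`
#' back-transforms the breakpoint to the measurement scale (cm for stipe
#' lengths), with a delta-method standard error
#' `ln(10) * 10^psi_log * SE(psi_log)`.
#'
#' @param x,y Numeric vectors (log10 scale), n >= 6, with at least two
#'   distinct `x` on each side of the starting value.
#' @param psi0 Starting breakpoint. The default (`NULL`) scans the SSE
#'   profile at the midpoints between consecutive distinct `x` values and
#'   starts from the best one; the SSE surface is only piecewise smooth, and a
#'   fixed start (e.g. the median) can strand the iteration in a local
#'   minimum.
#' @param tol Convergence tolerance on the change in psi (default 1e-8).
#' @param max_iter Maximum iterations (default 100). If exceeded the best
#'   iterate is returned with `converged = FALSE`.
#' @return Object of class `breakpoint_fit`: `psi_log`, `psi_raw`,
#'   `se_psi_log`, `se_psi_raw`, `slope_left`, `slope_right`, `intercept`,
#'   `iterations`, `converged`, `sse`, `n`, `boundary`.
#' @examples
#' x <- seq(0, 3, length.out = 60)
#' y <- ifelse(x < 1.5, x, 1.5 + 0.7 * (x - 1.5))
#' segmented_fit(x, y)
#' @export
segmented_fit <- function(x, y, psi0 = NULL, tol = 1e-8,
                          max_iter = 100L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 6L) stop_too_few_points(n, 6L)
  xs <- sort(unique(x))
  if (length(xs) < 4L)
    stop_degenerate_input("need at least 4 distinct x values")
  lo <- xs[2L]; hi <- xs[length(xs) - 1L]   # keep both segments identifiable
  clamp <- function(p) min(max(p, lo), hi)

  iterate <- function(psi) {
    converged <- FALSE
    sse_cur <- seg_ols(x, y, psi)$sse
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      fit <- seg_ols(x, y, psi, with_v = TRUE)
      beta <- fit$coefficients[3L]
      gamma <- fit$coefficients[4L]
      if (!is.finite(beta) || !is.finite(gamma) || abs(beta) < 1e-12) break
      step <- gamma / beta
      h <- 1
      psi_new <- clamp(psi + step)
      sse_new <- seg_ols(x, y, psi_new)$sse
      while (sse_new > sse_cur && h > 1 / 1024) { # damp steps that worsen fit
        h <- h / 2
        psi_new <- clamp(psi + h * step)
        sse_new <- seg_ols(x, y, psi_new)$sse
      }
      if (sse_new > sse_cur) { converged <- TRUE; break } # no improving step
      moved <- abs(psi_new - psi)
      improved <- sse_cur - sse_new
      psi <- psi_new
      sse_cur <- sse_new
      # stop on a stationary breakpoint or a stalled objective (the update
      # can oscillate within rounding error of the SSE minimum)
      if (moved < tol || improved < tol * (1 + sse_cur)) {
        converged <- TRUE
        break
      }
    }
    list(psi = psi, sse = sse_cur, iterations = it, converged = converged)
  }

  if (is.null(psi0)) {
    # multi-start: refine from the best few points of a coarse SSE scan.
    # Inter-point midpoints cover every data-defined basin; the uniform grid
    # resolves wide gaps in x, where a basin's minimum can sit far from its
    # midpoint and be misranked by a midpoint-only scan.
    cand <- c((xs[-1L] + xs[-length(xs)]) / 2,
              seq(lo, hi, length.out = 64L))
    cand <- sort(unique(cand[cand >= lo & cand <= hi]))
    if (!length(cand)) cand <- (lo + hi) / 2
    sse0 <- vapply(cand, function(p) seg_ols(x, y, p)$sse, numeric(1))
    starts <- cand[order(sse0)[seq_len(min(5L, length(cand)))]]
  } else {
    starts <- clamp(psi0)
  }
  runs <- lapply(starts, iterate)
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "sse"))]]
  psi <- best$psi
  converged <- best$converged
  it <- best$iterations
  boundary <- psi <= lo + 1e-12 || psi >= hi - 1e-12

  final <- seg_ols(x, y, psi)
  # SE of psi from the indicator-augmented fit at the solution
  vfit <- seg_ols(x, y, psi, with_v = TRUE)
  se_psi <- NA_real_
  beta <- vfit$coefficients[3L]
  p <- vfit$rank
  if (is.finite(beta) && abs(beta) > 1e-12 && n > p) {
    X <- cbind(1, x, pmax(x - psi, 0), -(x > psi))
    xtx <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
    if (!is.null(xtx)) {
      s2 <- vfit$sse / (n - p)
      se_gamma <- sqrt(s2 * xtx[4L, 4L])
      se_psi <- se_gamma / abs(beta)
    }
  }
  new_breakpoint_fit(
    psi_log = unname(psi), se_psi_log = unname(se_psi),
    slope_left = unname(final$coefficients[2L]),
    slope_right = unname(final$coefficients[2L] + final$coefficients[3L]),
    intercept = unname(final$coefficients[1L]),
    iterations = it, converged = converged, sse = final$sse, n = n,
    boundary = boundary, method = "segmented")
}

#' Brute-force breakpoint search on a grid
#'
#' Independent oracle for [segmented_fit()]: evaluates the two-segment OLS
#' fit at `n_grid` candidate breakpoints spaced uniformly between the
#' second-smallest and second-largest `x` and returns the SSE-minimizing fit.
#' No standard error is computed.
#'
#' @inheritParams segmented_fit
#' @param n_grid Number of grid candidates (default 10000).
#' @return Object of class `breakpoint_fit` (with `se_psi_log = NA`).
#' @export
grid_breakpoint <- function(x, y, n_grid = 10000L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 6L) stop_too_few_points(n, 6L)
  xs <- sort(unique(x))
  if (length(xs) < 4L)
    stop_degenerate_input("need at least 4 distinct x values")
  grid <- seq(xs[2L], xs[length(xs) - 1L], length.out = n_grid)
  sse <- vapply(grid, function(p) seg_ols(x, y, p)$sse, numeric(1))
  psi <- grid[which.min(sse)]
  final <- seg_ols(x, y, psi)
  new_breakpoint_fit(
    psi_log = psi, se_psi_log = NA_real_,
    slope_left = unname(final$coefficients[2L]),
    slope_right = unname(final$coefficients[2L] + final$coefficients[3L]),
    intercept = unname(final$coefficients[1L]),
    iterations = NA_integer_, converged = NA, sse = final$sse, n = n,
    method = "grid")
}
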