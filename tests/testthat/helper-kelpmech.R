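# Shared fixtures and independent mini-oracles. Oracles here are deliberately
# naive (loops, enumerations) and share no code with the implementation paths
# they check.

# Build a minimal tensile record from raw vectors.
make_record <- function(force, extension = seq_along(force) - 1,
                        L0 = 100, area = 2, id = "t", excluded = FALSE) {
  tensile_record(id, extension = extension, force = force,
                 initial_length = L0, fracture_area = area,
                 excluded = excluded)
}

# Brute-force failure scan: first index whose force has dropped to
# (1 - drop) of the running maximum (no smoothing, no noise floor).
oracle_failure_index <- function(force, drop = 0.5) {
  peak <- -Inf
  for (i in seq_along(force)) {
    peak <- max(peak, force[i])
    if (peak > 0 && force[i] <= (1 - drop) * peak) return(i)
  }
  NA_integer_
}

# Panel-by-panel trapezoid sum.
oracle_trapz <- function(x, y) {
  s <- 0
  for (i in seq_along(x)[-1]) s <- s + (x[i] - x[i - 1]) * (y[i] + y[i - 1]) / 2
  s
}

# All window OLS slopes of y on x, one lm() per window.
oracle_window_slopes <- function(x, y, w) {
  starts <- seq_len(length(x) - w + 1)
  vapply(starts, function(s) {
    i <- s:(s + w - 1)
    unname(coef(lm(y[i] ~ x[i]))[2])
  }, numeric(1))
}
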