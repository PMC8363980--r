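# Structured error conditions. Every kelpmech error carries a subclass so
# callers (and the pipeline's per-row error handling) can branch on the cause
# rather than match message strings.

km_stop <- function(class, message, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "kelpmech_error"),
                      call = call))
}

#' @keywords internal
stop_no_failure <- function(msg = "no qualifying force drop found") {
  km_stop("kelpmech_no_failure_detected", msg)
}

stop_degenerate_record <- function(msg) km_stop("kelpmech_degenerate_record", msg)
stop_excluded <- function(id) {
  km_stop("kelpmech_excluded_specimen",
          sprintf("specimen '%s' is flagged excluded (clamp/cradle failure)", id))
}
stop_degenerate_input <- function(msg) km_stop("kelpmech_degenerate_input", msg)
stop_ambiguous_sign <- function() {
  km_stop("kelpmech_ambiguous_sign",
          "correlation is zero within tolerance; SMA slope sign is undefined")
}
stop_too_few_points <- function(n, need) {
  km_stop("kelpmech_too_few_points",
          sprintf("need at least %d points, got %d", need, n))
}
stop_zero_strain_range <- function() {
  km_stop("kelpmech_zero_strain_range",
          "strain is constant within every window; modulus undefined")
}
stop_invalid_spec <- function(msg) km_stop("kelpmech_invalid_spec", msg)
stop_inconsistent_spec <- function(msg) km_stop("kelpmech_inconsistent_spec", msg)
stop_missing_variable <- function(var) {
  km_stop("kelpmech_missing_variable", sprintf("variable '%s' not found", var))
}
stop_parse_error <- function(msg) km_stop("kelpmech_parse_error", msg)
stop_schema_error <- function(file, missing) {
  km_stop("kelpmech_schema_error",
          sprintf("%s: missing required column(s): %s",
                  file, paste(missing, collapse = ", ")))
}
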