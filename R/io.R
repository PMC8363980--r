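# CSV dialects. All files are UTF-8, comma-separated, with a mandatory header
# row. Numeric output is written with 17 significant digits so a write/read
# round trip preserves doubles exactly.

fmt_precise <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  df
}

write_csv_precise <- function(df, path) {
  utils::write.csv(fmt_precise(df), path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) stop_schema_error(file, missing)
  invisible(df)
}

#' Read a morphometric CSV
#'
#' Expected columns: `specimen_id, life_stage, stipe_length_cm,
#' bulb_width_mm, stipe_width_below_bulb_mm, stipe_width_narrowest_mm,
#' stipe_width_above_holdfast_mm` (the width columns may be absent or NA).
#' Rows with non-positive stipe length or bulb width are rejected; the
#' returned data frame carries a `rejected` attribute logging each dropped row
#' and the invariant it violated.
#'
#' @param path Path to the CSV file.
#' @return Data frame of validated records, with attribute `rejected`.
#' @export
read_morphometrics_csv <- function(path) {
  if (!file.exists(path)) stop_parse_error(sprintf("file not found: %s", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 fileEncoding = "UTF-8"),
                 error = function(e) stop_parse_error(
                   sprintf("%s: %s", path, conditionMessage(e))))
  require_columns(df, c("specimen_id", "life_stage", "stipe_length_cm",
                        "bulb_width_mm"), path)
  bad <- list()
  ok <- rep(TRUE, nrow(df))
  check <- function(cond, reason) {
    idx <- which(ok & cond)
    for (i in idx) bad[[length(bad) + 1L]] <<- data.frame(
      row = i, specimen_id = as.character(df$specimen_id[i]), reason = reason,
      stringsAsFactors = FALSE)
    ok[idx] <<- FALSE
  }
  check(!is.finite(df$stipe_length_cm) | df$stipe_length_cm <= 0,
        "stipe_length_cm must be > 0")
  check(!is.na(df$bulb_width_mm) & df$bulb_width_mm <= 0,
        "bulb_width_mm must be > 0 where present")
  check(!df$life_stage %in% c("juvenile", "adult"),
        "life_stage must be 'juvenile' or 'adult'")
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- if (length(bad)) do.call(rbind, bad) else
    data.frame(row = integer(), specimen_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  out
}

#' @rdname read_morphometrics_csv
#' @param df Data frame in the morphometric schema.
#' @export
write_morphometrics_csv <- function(df, path) write_csv_precise(df, path)

#' Read tensile records from the long-format data CSV and its metadata CSV
#'
#' The data file has columns `specimen_id, time_s, extension_mm, force_N`
#' (one row per 10 ms sample); the metadata file has `specimen_id,
#' stipe_length_mm, fracture_area_mm2, excluded` with `excluded` in
#' `{true, false}`. Specimens violating record invariants (non-positive
#' geometry, fewer than 3 samples, decreasing extension, non-finite forces)
#' are rejected with a diagnostic naming the invariant; specimens flagged
#' `excluded` are retained but flagged, to be counted in the exclusions log
#' downstream.
#'
#' @param data_path Path to the long-format force-extension CSV.
#' @param metadata_path Path to the specimen metadata CSV.
#' @return List of [tensile_record()] objects, with attribute `rejected`
#'   (data frame `specimen_id, reason`).
#' @export
read_tensile_csv <- function(data_path, metadata_path) {
  for (p in c(data_path, metadata_path))
    if (!file.exists(p)) stop_parse_error(sprintf("file not found: %s", p))
  dat <- utils::read.csv(data_path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  require_columns(dat, c("specimen_id", "time_s", "extension_mm", "force_N"),
                  data_path)
  require_columns(meta, c("specimen_id", "stipe_length_mm",
                          "fracture_area_mm2", "excluded"), metadata_path)
  records <- list(); bad <- list()
  for (i in seq_len(nrow(meta))) {
    id <- as.character(meta$specimen_id[i])
    rows <- dat[dat$specimen_id == id, , drop = FALSE]
    rows <- rows[order(rows$time_s), , drop = FALSE]
    res <- tryCatch(
      tensile_record(
        specimen_id = id,
        extension = rows$extension_mm,
        force = rows$force_N,
        initial_length = meta$stipe_length_mm[i],
        fracture_area = meta$fracture_area_mm2[i],
        excluded = tolower(as.character(meta$excluded[i])) %in%
          c("true", "t", "1", "yes")),
      kelpmech_error = function(e) e)
    if (inherits(res, "kelpmech_error")) {
      bad[[length(bad) + 1L]] <- data.frame(
        specimen_id = id, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  attr(records, "rejected") <- if (length(bad)) do.call(rbind, bad) else
    data.frame(specimen_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  records
}

#' @rdname read_tensile_csv
#' @param records List of [tensile_record()] objects.
#' @export
write_tensile_csv <- function(records, data_path, metadata_path) {
  dat <- do.call(rbind, lapply(records, function(r) data.frame(
    specimen_id = r$specimen_id,
    time_s = (seq_along(r$force) - 1) / r$sampling_rate,
    extension_mm = r$extension,
    force_N = r$force,
    stringsAsFactors = FALSE)))
  meta <- do.call(rbind, lapply(records, function(r) data.frame(
    specimen_id = r$specimen_id,
    stipe_length_mm = r$initial_length,
    fracture_area_mm2 = r$fracture_area,
    excluded = ifelse(r$excluded, "true", "false"),
    stringsAsFactors = FALSE)))
  write_csv_precise(dat, data_path)
  write_csv_precise(meta, metadata_path)
  invisible(list(data = data_path, metadata = metadata_path))
}
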