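#' Read and validate a patient-level hospital event log
#'
#' Reads a delimited text file with header columns `patient_id`,
#' `provider_code`, `event_date`, `setting`, `lsoa_code` (any column order).
#' Dates must be ISO-8601 (`YYYY-MM-DD`); `setting` must be one of
#' `AE`, `IP`, `OP`. Rows with a missing `patient_id` or `provider_code`, an
#' unparseable date, or an unknown setting are dropped and counted (or, with
#' `strict = TRUE`, abort the read). `lsoa_code` values may be blank.
#'
#' @param path file path.
#' @param delim field delimiter (default comma).
#' @param strict if `TRUE`, any invalid row is an error instead of being
#'   dropped.
#' @return a `data.table` event log with an attached `provenance` attribute
#'   recording the source path, rows read, and drop counts by reason.
#' @export
read_event_log <- function(path, delim = ",", strict = FALSE) {
  required <- c("patient_id", "provider_code", "event_date", "setting", "lsoa_code")
  raw <- data.table::fread(path, sep = delim, colClasses = "character",
                           header = TRUE, na.strings = c("", "NA"))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop_carefrag("event log is missing required column(s): %s",
                  paste(missing_cols, collapse = ", "),
                  class = "carefrag_schema_error")
  raw <- raw[, required, with = FALSE]
  n_read <- nrow(raw)

  bad_id <- is.na(raw$patient_id) | is.na(raw$provider_code)
  parsed_date <- as.Date(raw$event_date, format = "%Y-%m-%d")
  bad_date <- !bad_id & is.na(parsed_date)
  bad_setting <- !bad_id & !bad_date & !(raw$setting %in% c("AE", "IP", "OP"))
  drop <- bad_id | bad_date | bad_setting
  if (strict && any(drop))
    stop_carefrag("%d invalid row(s) in %s (missing id: %d, bad date: %d, bad setting: %d)",
                  sum(drop), path, sum(bad_id), sum(bad_date), sum(bad_setting),
                  class = "carefrag_row_error")

  log <- raw[!drop]
  log[, event_date := parsed_date[!drop]]
  setattr(log, "provenance", list(
    source = path,
    n_rows_read = n_read,
    n_dropped_missing_id = sum(bad_id),
    n_dropped_bad_date = sum(bad_date),
    n_dropped_bad_setting = sum(bad_setting),
    filters = character()
  ))
  log[]
}

#' Write an event log in the package's CSV dialect
#'
#' UTF-8 CSV with header `patient_id,provider_code,event_date,setting,
#' lsoa_code` and ISO-8601 dates.
#'
#' @param log event log `data.table`.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  out <- data.table::copy(log)
  out[, event_date := format(event_date, "%Y-%m-%d")]
  data.table::fwrite(out, path)
  invisible(path)
}

assert_event_log <- function(log) {
  required <- c("patient_id", "provider_code", "event_date", "setting")
  missing_cols <- setdiff(required, names(log))
  if (length(missing_cols))
    stop_carefrag("not an event log: missing column(s) %s",
                  paste(missing_cols, collapse = ", "),
                  class = "carefrag_schema_error")
  invisible(log)
}

# carry provenance across a transformation, appending a filter note
pass_provenance <- function(new, old, note) {
  prov <- attr(old, "provenance") %||% list(filters = character())
  prov$filters <- c(prov$filters, note)
  setattr(new, "provenance", prov)
  new
}

#' Read a provider merge map
#'
#' Two-column CSV `raw_code,canonical_code` mapping historical provider codes
#' to the canonical code used across the study period (organisations that
#' merged or separated are treated as a single provider throughout).
#'
#' @param path file path.
#' @return named character vector: `raw_code -> canonical_code`.
#' @export
read_merge_map <- function(path) {
  m <- data.table::fread(path, colClasses = "character", header = TRUE)
  if (!all(c("raw_code", "canonical_code") %in% names(m)))
    stop_carefrag("merge map must have columns raw_code, canonical_code",
                  class = "carefrag_schema_error")
  stats::setNames(m$canonical_code, m$raw_code)
}

#' Apply a provider merge map to an event log
#'
#' Replaces every `provider_code` by its canonical code; codes absent from the
#' map pass through unchanged. The map must be idempotent: a canonical code
#' that itself appears as a raw key must map to itself (so applying the map
#' twice equals applying it once). Event count is unchanged.
#'
#' @param log event log.
#' @param merge_map named character vector `raw -> canonical` (e.g. from
#'   [read_merge_map()]).
#' @return the relabelled event log.
#' @export
apply_merge_map <- function(log, merge_map) {
  assert_event_log(log)
  if (!length(merge_map)) return(log)
  targets <- unname(merge_map)
  remapped <- targets %in% names(merge_map) & merge_map[targets] != targets
  remapped[is.na(remapped)] <- FALSE
  if (any(remapped))
    stop_carefrag("merge map is not idempotent (e.g. %s -> %s -> %s)",
                  names(merge_map)[remapped][1L], targets[remapped][1L],
                  merge_map[targets[remapped][1L]],
                  class = "carefrag_invalid_map")
  out <- data.table::copy(log)
  hit <- out$provider_code %in% names(merge_map)
  out[hit, provider_code := unname(merge_map[provider_code])]
  pass_provenance(out, log, "merge_map")[]
}

#' Restrict each patient to a follow-up window from their first event
#'
#' Keeps, for each patient, the events dated no later than
#' `first_date + window_days` (inclusive boundary). The first event is always
#' retained, so no patient disappears.
#'
#' @param log event log.
#' @param window_days window width in days; default 365 (12-month follow-up).
#' @return the windowed event log.
#' @export
apply_patient_window <- function(log, window_days = 365L) {
  assert_event_log(log)
  out <- log[log[, .I[event_date <= min(event_date) + window_days], by = patient_id]$V1]
  pass_provenance(out, log, sprintf("patient_window_%dd", as.integer(window_days)))[]
}

# declared intra-day order: emergency, then inpatient, then outpatient
.setting_rank <- c(AE = 1L, IP = 2L, OP = 3L)

#' Canonically sort an event log
#'
#' Stable total order by `(patient_id, event_date, setting rank AE < IP < OP,
#' provider_code)`. Any permutation of the same rows sorts to the same output,
#' which fixes the transition sequence when a patient has several events on
#' one date.
#'
#' @param log event log.
#' @return the sorted event log.
#' @export
canonical_sort <- function(log) {
  assert_event_log(log)
  out <- data.table::copy(log)
  out[, setting_rank := .setting_rank[setting]]
  setorder(out, patient_id, event_date, setting_rank, provider_code)
  out[, setting_rank := NULL]
  pass_provenance(out, log, "canonical_sort")[]
}

# TRUE when patients form contiguous blocks with non-decreasing dates inside
# each block — the precondition for transition extraction.
is_canonically_ordered <- function(log) {
  if (nrow(log) < 2L) return(TRUE)
  pid <- log$patient_id
  if (anyDuplicated(rle(pid)$values)) return(FALSE)
  same <- pid[-1L] == pid[-length(pid)]
  !any(same & diff(as.integer(log$event_date)) < 0)
}
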