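#' Extract per-patient consecutive-attendance transitions
#'
#' For each patient with `k >= 2` events (in canonical order), produces the
#' `k - 1` ordered pairs of consecutive events. A transition is *fragmented*
#' when the two events occurred at different providers — i.e. the patient's
#' most recent record is held elsewhere when they present.
#'
#' @param log event log, canonically sorted (see [canonical_sort()]) and
#'   windowed; unsorted input is a contract error.
#' @return `data.table` with columns `patient_id`, `from_provider`,
#'   `to_provider`, `from_date`, `to_date`, `fragmented`.
#' @export
extract_transitions <- function(log) {
  assert_event_log(log)
  if (!is_canonically_ordered(log))
    stop_carefrag("event log must be canonically sorted before extracting transitions",
                  class = "carefrag_contract_error")
  if (nrow(log) == 0L) {
    return(data.table(patient_id = character(),
                      from_provider = character(), to_provider = character(),
                      from_date = as.Date(character()), to_date = as.Date(character()),
                      fragmented = logical()))
  }
  tr <- log[, {
    if (.N >= 2L) list(
      from_provider = provider_code[-.N],
      to_provider = provider_code[-1L],
      from_date = event_date[-.N],
      to_date = event_date[-1L]
    ) else list(
      from_provider = character(), to_provider = character(),
      from_date = as.Date(character()), to_date = as.Date(character())
    )
  }, by = patient_id]
  tr[, fragmented := from_provider != to_provider]
  tr[]
}

#' National descriptive statistics of care fragmentation
#'
#' Computes the headline accounting of a fragmentation analysis: patient and
#' interaction totals, multi-presenters (patients with more than one
#' interaction), multi-provider patients (multi-presenters attending more than
#' one provider), the interactions attributable to each group, and fragmented
#' presentations. The headline fragmented percentage uses *all interactions of
#' multi-presenters* as its denominator; the per-transition rate is also
#' reported as a secondary figure.
#'
#' @param log event log.
#' @param transitions transitions extracted from the same log.
#' @return a `descriptive_stats` list of counts and percentages; see
#'   [descriptive_percentages()] for the percentage definitions.
#' @export
descriptive_stats <- function(log, transitions) {
  assert_event_log(log)
  per_patient <- log[, .(k_events = .N, n_providers = uniqueN(provider_code)),
                     by = patient_id]
  counts <- list(
    n_patients = nrow(per_patient),
    n_interactions = nrow(log),
    n_multi_presenters = per_patient[k_events > 1L, .N],
    n_multi_provider_patients = per_patient[k_events > 1L & n_providers > 1L, .N],
    n_interactions_multi = per_patient[k_events > 1L, sum(k_events)],
    n_interactions_multi_provider = per_patient[k_events > 1L & n_providers > 1L, sum(k_events)],
    n_transitions = nrow(transitions),
    n_fragmented = sum(transitions$fragmented)
  )
  descriptive_percentages(counts)
}

#' Percentage fields of the descriptive statistics
#'
#' Completes a set of descriptive counts with the derived percentages:
#' \itemize{
#'   \item `pct_multi_presenters` = multi-presenters / patients;
#'   \item `pct_multi_provider` = multi-provider patients / multi-presenters;
#'   \item `pct_interactions_multi` = interactions of multi-presenters / all
#'     interactions;
#'   \item `pct_interactions_multi_provider` = interactions of multi-provider
#'     patients / interactions of multi-presenters;
#'   \item `pct_fragmented` = fragmented presentations / interactions of
#'     multi-presenters (the headline rate);
#'   \item `pct_fragmented_transitions` = fragmented / all transitions
#'     (secondary, per-transition rate).
#' }
#' All percentages are `100 * numerator / denominator`, defined as 0 when the
#' denominator is 0. Exposed separately so the same arithmetic can be applied
#' to externally reported count tables.
#'
#' @param counts list or named vector with the count fields of
#'   [descriptive_stats()] (`n_transitions` optional).
#' @return a `descriptive_stats` list: the counts plus percentage fields.
#' @export
descriptive_percentages <- function(counts) {
  counts <- as.list(counts)
  s <- counts
  s$pct_multi_presenters <- pct_of(counts$n_multi_presenters, counts$n_patients)
  s$pct_multi_provider <- pct_of(counts$n_multi_provider_patients, counts$n_multi_presenters)
  s$pct_interactions_multi <- pct_of(counts$n_interactions_multi, counts$n_interactions)
  s$pct_interactions_multi_provider <-
    pct_of(counts$n_interactions_multi_provider, counts$n_interactions_multi)
  s$pct_fragmented <- pct_of(counts$n_fragmented, counts$n_interactions_multi)
  if (!is.null(counts$n_transitions))
    s$pct_fragmented_transitions <- pct_of(counts$n_fragmented, counts$n_transitions)
  structure(s, class = "descriptive_stats")
}

#' @export
print.descriptive_stats <- function(x, ...) {
  cat("Care-fragmentation descriptive statistics\n")
  cat(sprintf("  patients: %s; interactions: %s\n",
              format(x$n_patients, big.mark = ","),
              format(x$n_interactions, big.mark = ",")))
  cat(sprintf("  multi-presenters: %s (%.1f%%); of whom multi-provider: %s (%.1f%%)\n",
              format(x$n_multi_presenters, big.mark = ","), x$pct_multi_presenters,
              format(x$n_multi_provider_patients, big.mark = ","), x$pct_multi_provider))
  cat(sprintf("  fragmented presentations: %s (%.1f%% of multi-presenter interactions)\n",
              format(x$n_fragmented, big.mark = ","), x$pct_fragmented))
  invisible(x)
}

#' Per-provider share of fragmented arrivals
#'
#' An *arrival* at provider P is a transition whose destination is P. For each
#' provider with at least one arrival, reports the number of fragmented
#' arrivals, total arrivals, and their ratio — the proportion of the
#' provider's clinical encounters (after the first) at which the patient's
#' previous record is held elsewhere.
#'
#' @param transitions transition table from [extract_transitions()].
#' @return `data.table` with columns `provider_code`, `n_arrivals_fragmented`,
#'   `n_arrivals_total`, `proportion`, sorted by provider.
#' @export
provider_fragmented_share <- function(transitions) {
  out <- transitions[, .(
    n_arrivals_fragmented = sum(fragmented),
    n_arrivals_total = .N
  ), by = .(provider_code = to_provider)]
  out[, proportion := n_arrivals_fragmented / n_arrivals_total]
  setorder(out, provider_code)
  out[]
}

#' Median patient-level fragmentation by residential area
#'
#' Each patient is attributed to one LSOA — the mode of the `lsoa_code` values
#' on their events, ties resolved to the lexicographically smallest code;
#' patients with no recorded LSOA are excluded. A patient's fragmentation
#' proportion is their number of fragmented transitions divided by their total
#' interactions (single-event patients score 0). Each LSOA's value is the
#' median of its resident patients' proportions (even counts: mean of the two
#' central values).
#'
#' @param log event log carrying `lsoa_code`.
#' @param transitions transitions from the same log.
#' @return `data.table` with columns `lsoa_code`,
#'   `median_fragmented_proportion`, `n_patients`; empty if no event carries
#'   an LSOA.
#' @export
lsoa_fragmentation <- function(log, transitions) {
  assert_event_log(log)
  if (!"lsoa_code" %in% names(log) || !any(!is.na(log$lsoa_code))) {
    return(data.table(lsoa_code = character(),
                      median_fragmented_proportion = numeric(),
                      n_patients = integer()))
  }
  # modal LSOA per patient; ties -> lexicographically smallest code
  modal <- log[!is.na(lsoa_code),
               .(n = .N), by = .(patient_id, lsoa_code)][
               order(patient_id, -n, lsoa_code)][
               , .(home_lsoa = lsoa_code[1L]), by = patient_id]
  k <- log[, .(k_events = .N), by = patient_id]
  fr <- transitions[, .(n_frag = sum(fragmented)), by = patient_id]
  pp <- merge(modal, k, by = "patient_id")
  pp <- merge(pp, fr, by = "patient_id", all.x = TRUE)
  pp[is.na(n_frag), n_frag := 0L]
  pp[, proportion := n_frag / k_events]
  out <- pp[, .(median_fragmented_proportion = median(proportion),
                n_patients = .N), by = .(lsoa_code = home_lsoa)]
  setorder(out, lsoa_code)
  out[]
}

#' Write transitions as CSV
#'
#' Columns `patient_id,from_provider,to_provider,from_date,to_date,fragmented`
#' with ISO-8601 dates and lowercase logical `fragmented`.
#'
#' @param transitions transition table.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_transitions <- function(transitions, path) {
  out <- data.table::copy(transitions)
  out[, `:=`(from_date = format(from_date, "%Y-%m-%d"),
             to_date = format(to_date, "%Y-%m-%d"),
             fragmented = tolower(as.character(fragmented)))]
  data.table::fwrite(out, path)
  invisible(path)
}
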