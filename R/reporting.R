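#' Community continuity table
#'
#' Attributes every fragmented transition to the community of its
#' *destination* provider and splits it by whether the previous (origin)
#' provider lies inside or outside that community. `pct_within` is the share
#' of a community's fragmented arrivals whose previous record was already
#' held within the community — the continuity of data sharing that a
#' community-wide record exchange would achieve.
#'
#' @param transitions transition table from [extract_transitions()].
#' @param partition named vector mapping provider codes to community labels;
#'   every provider occurring in a fragmented transition must be assigned.
#' @return a `data.table` with one row per community label (sorted):
#'   `community`, `n_hospitals`, `total_fragmented`, `previous_within`,
#'   `previous_outside`, `pct_within`.
#' @export
community_table <- function(transitions, partition) {
  frag <- transitions[fragmented == TRUE]
  used <- unique(c(frag$from_provider, frag$to_provider))
  unassigned <- setdiff(used, names(partition))
  if (length(unassigned))
    stop_carefrag("provider(s) not assigned to any community: %s",
                  paste(head(unassigned, 5L), collapse = ", "),
                  class = "carefrag_invalid_partition")
  hosp <- data.table(community = unname(partition))[, .(n_hospitals = .N), by = community]
  counts <- frag[, .(
    community = unname(partition[to_provider]),
    within = unname(partition[from_provider]) == unname(partition[to_provider])
  )][, .(total_fragmented = .N, previous_within = sum(within)), by = community]
  tab <- merge(hosp, counts, by = "community", all.x = TRUE)
  tab[is.na(total_fragmented), `:=`(total_fragmented = 0L, previous_within = 0L)]
  setorder(tab, community)
  community_table_from_counts(tab)
}

#' Complete a community continuity table from its counts
#'
#' Given per-community counts (`community`, `n_hospitals`,
#' `total_fragmented`, `previous_within`), derives `previous_outside` and
#' `pct_within = 100 * previous_within / total_fragmented`. Used internally
#' by [community_table()] and directly applicable to externally reported
#' count tables.
#'
#' @param counts data.frame/data.table with the four count columns.
#' @return the completed `data.table`.
#' @export
community_table_from_counts <- function(counts) {
  tab <- as.data.table(counts)
  need <- c("community", "n_hospitals", "total_fragmented", "previous_within")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop_carefrag("community counts missing column(s): %s",
                  paste(missing_cols, collapse = ", "),
                  class = "carefrag_schema_error")
  if (any(tab$previous_within > tab$total_fragmented))
    stop_carefrag("previous_within exceeds total_fragmented",
                  class = "carefrag_invalid_counts")
  tab[, previous_outside := total_fragmented - previous_within]
  tab[, pct_within := pct_of(previous_within, total_fragmented)]
  tab[]
}

#' Continuity gained by community-wide data sharing
#'
#' Summarises a community continuity table: the minimum, maximum, and
#' weighted mean of `pct_within` over communities (weights = each
#' community's fragmented arrivals, so the weighted mean equals the pooled
#' percentage). The baseline is 0: without any cross-provider sharing, none
#' of these fragmented presentations has the previous record available.
#'
#' @param table output of [community_table()] (non-empty).
#' @return list with `baseline_pct`, `min_pct`, `max_pct`,
#'   `weighted_mean_pct`.
#' @export
continuity_gain <- function(table) {
  if (!nrow(table))
    stop_carefrag("continuity_gain needs a non-empty community table",
                  class = "carefrag_invalid_counts")
  list(
    baseline_pct = 0,
    min_pct = min(table$pct_within),
    max_pct = max(table$pct_within),
    weighted_mean_pct = pct_of(sum(table$previous_within), sum(table$total_fragmented))
  )
}

#' Run the full fragmentation pipeline
#'
#' Executes the whole analysis: read (or simulate) the event log, apply the
#' provider merge map, restrict each patient to the follow-up window,
#' canonically sort, extract transitions, compute descriptive statistics,
#' build the patient-sharing network, partition it with Louvain, and produce
#' the community continuity and LSOA tables. When the network has no edges
#' (no fragmented transitions) the community stage is skipped with a warning.
#'
#' @param input either a [simulation_config()] (the log is generated) or a
#'   path to an event-log CSV.
#' @param merge_map optional named vector or path to a merge-map CSV.
#' @param window_days per-patient follow-up window (days).
#' @param gamma Louvain resolution parameter.
#' @param seed Louvain sweep-order seed.
#' @param min_weight optional edge threshold (strict `>`) applied before
#'   community detection; 0 keeps every edge.
#' @param out_dir optional directory: when given, all artifacts (event log if
#'   simulated, transitions, descriptive stats, edge list, GraphML,
#'   partition, community table, LSOA table) and a JSON manifest with
#'   versions, parameters and per-stage row counts are written there.
#' @param strict passed to [read_event_log()].
#' @return a report bundle (list) with elements `log`, `transitions`,
#'   `stats`, `network`, `louvain` (or `NULL`), `community_table`,
#'   `lsoa_table`, `manifest`, invisibly.
#' @export
run_pipeline <- function(input, merge_map = NULL, window_days = 365L,
                         gamma = 1, seed = 0L, min_weight = 0,
                         out_dir = NULL, strict = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_carefrag("pipeline stage '%s' failed: %s", name, conditionMessage(e),
                    class = "carefrag_pipeline_error")
    })
  }
  simulated <- inherits(input, "simulation_config")
  truth <- NULL
  if (simulated) {
    sim <- stage("simulate", generate_event_log(input))
    log <- sim$events
    truth <- sim$truth
    node_universe <- names(truth$provider_community)
  } else {
    log <- stage("read", read_event_log(input, strict = strict))
    node_universe <- NULL
  }
  if (!is.null(merge_map)) {
    if (is.character(merge_map) && length(merge_map) == 1L && file.exists(merge_map))
      merge_map <- read_merge_map(merge_map)
    log <- stage("merge_map", apply_merge_map(log, merge_map))
  }
  n_read <- nrow(log)
  log <- stage("window", apply_patient_window(log, window_days))
  log <- stage("sort", canonical_sort(log))
  transitions <- stage("transitions", extract_transitions(log))
  stats <- stage("descriptive_stats", descriptive_stats(log, transitions))
  net <- stage("network", build_network(transitions, node_universe = node_universe))
  if (min_weight > 0) net <- stage("threshold", threshold_network(net, min_weight))
  lsoa_tab <- stage("lsoa", lsoa_fragmentation(log, transitions))

  if (nrow(net$edges) == 0L) {
    warning("patient-sharing network has no edges; community detection skipped")
    lv <- NULL
    comm_tab <- data.table(community = integer(), n_hospitals = integer(),
                           total_fragmented = integer(), previous_within = integer(),
                           previous_outside = integer(), pct_within = numeric())
  } else {
    lv <- stage("louvain", louvain(net, gamma = gamma, seed = seed))
    comm_tab <- stage("community_table", community_table(transitions, lv$partition))
  }

  manifest <- list(
    package = "carefrag",
    package_version = as.character(packageVersion("carefrag")),
    input = if (simulated) "synthetic" else as.character(input),
    seed = if (simulated) input$seed else as.integer(seed),
    louvain_seed = as.integer(seed),
    gamma = gamma,
    window_days = as.integer(window_days),
    min_weight = min_weight,
    rows = list(
      events_in = n_read,
      events_windowed = nrow(log),
      transitions = nrow(transitions),
      fragmented = sum(transitions$fragmented),
      network_nodes = length(net$nodes),
      network_edges = nrow(net$edges),
      communities = if (is.null(lv)) 0L else lv$n_communities,
      lsoa_rows = nrow(lsoa_tab)
    ),
    modularity = if (is.null(lv)) NULL else lv$modularity$q
  )

  bundle <- list(log = log, transitions = transitions, stats = stats,
                 network = net, louvain = lv, community_table = comm_tab,
                 lsoa_table = lsoa_tab, truth = truth, manifest = manifest)
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir, simulated)
  invisible(bundle)
}

write_report_bundle <- function(bundle, out_dir, simulated) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  if (simulated) write_event_log(bundle$log, p("event_log.csv"))
  write_transitions(bundle$transitions, p("transitions.csv"))
  jsonlite::write_json(unclass(bundle$stats), p("descriptive_stats.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_edge_list(bundle$network, p("edge_list.tsv"))
  write_graphml(bundle$network, p("network.graphml"))
  if (!is.null(bundle$louvain)) {
    write_partition(bundle$louvain$partition, p("partition.csv"))
    write_partition(bundle$louvain$partition, p("partition.json"))
  }
  data.table::fwrite(bundle$community_table, p("community_table.csv"))
  data.table::fwrite(bundle$lsoa_table, p("lsoa_table.csv"))
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
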