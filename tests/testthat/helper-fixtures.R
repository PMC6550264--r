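library(data.table)

# small event-log builder; dates given as day offsets from 2014-01-01
make_log <- function(patient_id, provider_code, day, setting = "OP",
                     lsoa_code = NA_character_) {
  data.table(
    patient_id = patient_id,
    provider_code = provider_code,
    event_date = as.Date("2014-01-01") + day,
    setting = setting,
    lsoa_code = lsoa_code
  )
}

# transition-table builder; fragmented derived from the providers
make_transitions <- function(from, to, patient_id = "P1") {
  data.table(
    patient_id = patient_id,
    from_provider = from,
    to_provider = to,
    from_date = as.Date("2014-01-01"),
    to_date = as.Date("2014-01-02"),
    fragmented = from != to
  )
}

# random weighted network on n nodes (named a, b, c, ...), at least one edge
random_network <- function(n_nodes, seed, p_edge = 0.6, max_weight = 5L) {
  set.seed(seed)
  nodes <- letters[seq_len(n_nodes)]
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[sample.int(length(keep), 1L)] <- TRUE
  edges <- data.table(
    provider_a = pairs[keep, 1L],
    provider_b = pairs[keep, 2L],
    weight = sample.int(max_weight, sum(keep), replace = TRUE)
  )
  setorder(edges, provider_a, provider_b)
  carefrag:::new_network(nodes, edges)
}

# barbell of two unit-weight triangles joined by one unit edge; optimum
# partition is the two triangles with Q = 10/28
barbell_network <- function() {
  tr <- make_transitions(c("A", "B", "C", "D", "E", "F", "C"),
                         c("B", "C", "A", "E", "F", "D", "D"))
  build_network(tr)
}

# two k-cliques of unit weight joined by a single unit edge
two_cliques_network <- function(k = 4L) {
  a <- paste0("A", seq_len(k))
  b <- paste0("B", seq_len(k))
  clique <- function(v) {
    p <- t(combn(v, 2))
    data.table(provider_a = p[, 1L], provider_b = p[, 2L], weight = 1L)
  }
  # combn output and the A*/B* naming already give provider_a < provider_b
  edges <- rbind(clique(a), clique(b),
                 data.table(provider_a = a[k], provider_b = b[1L], weight = 1L))
  setorder(edges, provider_a, provider_b)
  carefrag:::new_network(sort(c(a, b)), edges)
}

write_log_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
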