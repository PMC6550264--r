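#' Configuration for the synthetic event-log generator
#'
#' Bundles and validates the parameters of the pseudo-HES simulator. The
#' generator plants a known community structure: providers are split into
#' `n_communities` groups, every small residential area (LSOA) belongs to one
#' group, and patients preferentially attend providers of their home group.
#' Downstream community detection can then be scored against this ground truth.
#'
#' Defaults describe a national secondary-care system in miniature: 81.3% of
#' patients present more than once (`p_single_event = 0.187`) and
#' multi-presenters accrue a shifted-Poisson number of events with mean
#' `mean_events_per_patient = 7.9`, giving roughly 6.6 interactions per patient
#' overall — the rates observed in English hospital attendance data for
#' 2013-14.
#'
#' @param n_providers number of hospital providers (trusts).
#' @param n_communities number of planted provider communities
#'   (`<= n_providers`).
#' @param n_patients number of simulated patients.
#' @param mean_events_per_patient mean event count of the multi-presenter
#'   branch; multi-presenters draw `2 + Poisson(mean_events_per_patient - 2)`
#'   events.
#' @param p_single_event probability a patient has exactly one event.
#' @param p_within_community probability that a provider switch stays inside
#'   the patient's home community.
#' @param p_switch_provider probability that an event occurs at a different
#'   provider than the previous one.
#' @param n_lsoas number of residential areas; each is assigned to one planted
#'   community.
#' @param date_start first possible event date (`Date` or ISO-8601 string).
#' @param date_span_days width of the event-date window in days.
#' @param allow_same_day if `TRUE`, a patient may have several events on the
#'   same date (used to exercise same-day tie-breaking rules); default draws
#'   strictly increasing dates.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_providers = 40L,
                              n_communities = 4L,
                              n_patients = 5000L,
                              mean_events_per_patient = 7.9,
                              p_single_event = 0.187,
                              p_within_community = 0.95,
                              p_switch_provider = 0.3,
                              n_lsoas = 25L * n_communities,
                              date_start = as.Date("2013-04-01"),
                              date_span_days = 365L,
                              allow_same_day = FALSE,
                              seed = 0L) {
  cfg <- list(
    n_providers = as.integer(n_providers),
    n_communities = as.integer(n_communities),
    n_patients = as.integer(n_patients),
    mean_events_per_patient = as.numeric(mean_events_per_patient),
    p_single_event = as.numeric(p_single_event),
    p_within_community = as.numeric(p_within_community),
    p_switch_provider = as.numeric(p_switch_provider),
    n_lsoas = as.integer(n_lsoas),
    date_start = as.Date(date_start),
    date_span_days = as.integer(date_span_days),
    allow_same_day = isTRUE(allow_same_day),
    seed = as.integer(seed)
  )
  counts <- c("n_providers", "n_communities", "n_patients", "n_lsoas")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop_carefrag("'%s' must be a count >= 1", f, class = "carefrag_invalid_config")
  }
  probs <- c("p_single_event", "p_within_community", "p_switch_provider")
  for (f in probs) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_carefrag("'%s' must be a probability in [0, 1]", f, class = "carefrag_invalid_config")
  }
  if (cfg$n_communities > cfg$n_providers)
    stop_carefrag("n_communities (%d) exceeds n_providers (%d)",
                  cfg$n_communities, cfg$n_providers, class = "carefrag_invalid_config")
  if (!is.finite(cfg$mean_events_per_patient) || cfg$mean_events_per_patient <= 0)
    stop_carefrag("'mean_events_per_patient' must be positive", class = "carefrag_invalid_config")
  if (is.na(cfg$date_span_days) || cfg$date_span_days < 0)
    stop_carefrag("'date_span_days' must be >= 0", class = "carefrag_invalid_config")
  structure(cfg, class = "simulation_config")
}

# Split n items over k groups as equally as possible, remainder handed out
# from group 0 upward. Returns the 0-based group of each item, contiguous.
equal_split_labels <- function(n, k) {
  base <- n %/% k
  sizes <- rep.int(base, k) + c(rep.int(1L, n %% k), rep.int(0L, k - n %% k))
  rep.int(seq_len(k) - 1L, sizes)
}

# Deterministic 3-character alphanumeric provider codes: "R" + two base-36
# digits, mimicking trust-level PROCODE3 identifiers. Supports 1296 providers.
provider_codes <- function(n) {
  if (n > 36L * 36L)
    stop_carefrag("at most %d provider codes available", 36L * 36L,
                  class = "carefrag_invalid_config")
  alphabet <- c(0:9, LETTERS)
  i <- seq_len(n) - 1L
  paste0("R", alphabet[i %/% 36L + 1L], alphabet[i %% 36L + 1L])
}

#' Generate the provider table with planted communities
#'
#' Providers receive deterministic 3-character codes and are assigned to
#' `n_communities` planted communities with sizes as equal as possible
#' (any remainder spread from community 0 upward).
#'
#' @param config a [simulation_config()].
#' @return a `data.table` with columns `provider_code` and `community`
#'   (0-based integer label).
#' @export
generate_providers <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  data.table(
    provider_code = provider_codes(config$n_providers),
    community = equal_split_labels(config$n_providers, config$n_communities)
  )
}

# LSOA table: synthetic codes in the English "E01xxxxxx" shape, each area
# assigned to one planted community by the same equal-split rule.
generate_lsoas <- function(config) {
  data.table(
    lsoa_code = sprintf("E01%06d", seq_len(config$n_lsoas)),
    community = equal_split_labels(config$n_lsoas, config$n_communities)
  )
}

#' Generate a synthetic hospital event log with known ground truth
#'
#' Simulates patient-level secondary-care event logs in the five-column schema
#' `patient_id, provider_code, event_date, setting, lsoa_code`. Each patient
#' is assigned a home LSOA (hence a home community); their event count is 1
#' with probability `p_single_event`, otherwise `2 + Poisson(mean - 2)`.
#' The first event occurs at a provider drawn uniformly from the home
#' community; each later event stays at the previous provider with probability
#' `1 - p_switch_provider` and otherwise moves to a *different* provider —
#' inside the home community with probability `p_within_community`, else
#' uniformly outside it (falling back to the other pool when a pool has no
#' eligible provider). Event dates are strictly increasing within the window
#' unless `allow_same_day` is set. Care setting is uniform over AE/IP/OP.
#'
#' @param config a [simulation_config()].
#' @return a list with elements
#'   \describe{
#'     \item{events}{`data.table` event log, canonically ordered by patient
#'       and date;}
#'     \item{truth}{ground truth: `provider_community`, `patient_home_lsoa`,
#'       and `lsoa_community`, each a named vector;}
#'     \item{config}{the config used.}
#'   }
#' @export
generate_event_log <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  providers <- generate_providers(config)
  lsoas <- generate_lsoas(config)
  with_seed(config$seed, {
    sim_event_log(config, providers, lsoas)
  })
}

sim_event_log <- function(cfg, providers, lsoas) {
  n <- cfg$n_patients
  nprov <- cfg$n_providers
  # contiguous provider index range [start, end] of each community
  comm_sizes <- tabulate(providers$community + 1L, nbins = cfg$n_communities)
  comm_end <- cumsum(comm_sizes)
  comm_start <- comm_end - comm_sizes + 1L

  patient_id <- sprintf("P%06d", seq_len(n))
  home_lsoa_idx <- runif_int(rep.int(cfg$n_lsoas, n))
  home_comm <- lsoas$community[home_lsoa_idx]

  lambda <- max(cfg$mean_events_per_patient - 2, 0)
  k <- ifelse(runif(n) < cfg$p_single_event, 1L, 2L + rpois(n, lambda))
  k <- as.integer(k)

  prov <- sim_provider_sequences(cfg, k, home_comm, comm_start, comm_end, nprov)
  dates <- sim_event_dates(cfg, k)

  total <- sum(k)
  events <- data.table(
    patient_id = rep.int(patient_id, k),
    provider_code = providers$provider_code[prov],
    event_date = cfg$date_start + dates,
    setting = c("AE", "IP", "OP")[runif_int(rep.int(3L, total))],
    lsoa_code = rep.int(lsoas$lsoa_code[home_lsoa_idx], k)
  )
  truth <- list(
    provider_community = stats::setNames(providers$community, providers$provider_code),
    patient_home_lsoa = stats::setNames(lsoas$lsoa_code[home_lsoa_idx], patient_id),
    lsoa_community = stats::setNames(lsoas$community, lsoas$lsoa_code)
  )
  list(events = events, truth = truth, config = cfg)
}

# Provider index for every event, simulated position-by-position so the
# Markov switching process is vectorised across patients.
sim_provider_sequences <- function(cfg, k, home_comm, comm_start, comm_end, nprov) {
  n <- length(k)
  maxk <- max(k)
  s <- comm_start[home_comm + 1L]
  e <- comm_end[home_comm + 1L]
  size_home <- e - s + 1L

  prov <- matrix(NA_integer_, nrow = n, ncol = maxk)
  prov[, 1L] <- s + runif_int(size_home) - 1L

  if (maxk >= 2L) for (j in 2:maxk) {
    act <- which(k >= j)
    if (!length(act)) next
    prev <- prov[cbind(act, j - 1L)]
    cur <- prev
    u_switch <- runif(length(act))
    sw <- u_switch < cfg$p_switch_provider
    if (any(sw)) {
      idx <- act[sw]
      cur_sw <- sample_switch_targets(
        prev = prev[sw],
        s = s[idx], e = e[idx], size_home = size_home[idx],
        nprov = nprov, p_within = cfg$p_within_community
      )
      cur[sw] <- cur_sw
    }
    prov[cbind(act, j)] <- cur
  }
  # flatten row-wise, keeping only each patient's first k events
  idx <- cbind(rep(seq_len(n), k), unlist(lapply(k, seq_len), use.names = FALSE))
  prov[idx]
}

# Draw the destination of a provider switch: a different provider, inside the
# home block [s, e] with probability p_within, else uniformly outside it.
# Empty candidate pools (single-provider community, or no outside providers)
# fall back to the other pool; if both are empty the patient stays put.
sample_switch_targets <- function(prev, s, e, size_home, nprov, p_within) {
  nsw <- length(prev)
  prev_in_home <- prev >= s & prev <= e
  m_within <- size_home - as.integer(prev_in_home)
  m_outside <- nprov - size_home - as.integer(!prev_in_home)

  want_within <- runif(nsw) < p_within
  use_within <- (want_within & m_within > 0L) | (!want_within & m_outside == 0L & m_within > 0L)
  use_outside <- !use_within & m_outside > 0L

  out <- prev
  if (any(use_within)) {
    w <- which(use_within)
    r <- s[w] - 1L + runif_int(m_within[w])
    bump <- prev_in_home[w] & r >= prev[w]
    out[w] <- r + as.integer(bump)
  }
  if (any(use_outside)) {
    w <- which(use_outside)
    # complement of the home block, with prev (when outside) deleted:
    # list the complement in index order and take the r-th element.
    m <- m_outside[w]
    r <- runif_int(m)
    p_pos <- ifelse(prev[w] < s[w], prev[w], prev[w] - size_home[w])
    r <- r + as.integer(!prev_in_home[w] & r >= p_pos)
    out[w] <- ifelse(r <= s[w] - 1L, r, r + size_home[w])
  }
  as.integer(out)
}

# Per-patient day offsets in [0, date_span_days], strictly increasing unless
# allow_same_day; returned flattened in patient order.
sim_event_dates <- function(cfg, k) {
  span1 <- cfg$date_span_days + 1L
  if (cfg$allow_same_day) {
    offs <- lapply(k, function(ki) sort(floor(runif(ki) * span1)))
  } else {
    if (max(k) > span1)
      stop_carefrag("date_span_days too small for %d distinct event dates",
                    max(k), class = "carefrag_invalid_config")
    offs <- lapply(k, function(ki) sort(sample.int(span1, ki) - 1L))
  }
  as.integer(unlist(offs, use.names = FALSE))
}

#' Write a generated simulation to disk
#'
#' Writes the event log as CSV (the dialect read by [read_event_log()]) and
#' the ground truth as JSON with keys `provider_community`,
#' `patient_home_lsoa` and `lsoa_community`.
#'
#' @param sim result of [generate_event_log()].
#' @param events_path CSV destination for the event log.
#' @param truth_path optional JSON destination for the ground truth.
#' @return `events_path`, invisibly.
#' @export
write_simulation <- function(sim, events_path, truth_path = NULL) {
  write_event_log(sim$events, events_path)
  if (!is.null(truth_path)) {
    jsonlite::write_json(lapply(sim$truth, as.list), truth_path,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(events_path)
}
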