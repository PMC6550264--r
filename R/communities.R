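# Resolution modularity and Louvain community detection, implemented from
# scratch on the patient-sharing network representation.
#
# Internal working graphs (used during Louvain aggregation) are edge lists on
# integer node ids plus a per-node self-loop weight L_i. The convention is
# A_ii = 2 * L_i, so that the double-sum adjacency identities hold: the
# weighted degree is k_i = sum_j!=i w_ij + 2 L_i, 2m = sum_i k_i, and an
# aggregated graph whose loops carry each community's internal weight scores
# the same Q as the original graph under the induced partition.

as_work_graph <- function(net) {
  nodes <- net$nodes
  list(
    n = length(nodes),
    ea = match(net$edges$provider_a, nodes),
    eb = match(net$edges$provider_b, nodes),
    w = as.numeric(net$edges$weight),
    loop = numeric(length(nodes))
  )
}

work_degrees <- function(g) {
  k <- numeric(g$n)
  if (length(g$w)) {
    k <- k + rowsum_vec(g$w, g$ea, g$n) + rowsum_vec(g$w, g$eb, g$n)
  }
  k + 2 * g$loop
}

# sum of x by integer group id, returned as a dense length-n vector
rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

work_modularity <- function(g, comm, gamma) {
  k <- work_degrees(g)
  two_m <- sum(k)
  if (two_m <= 0)
    stop_carefrag("modularity is undefined for a network with no edge weight",
                  class = "carefrag_empty_network")
  internal <- sum(g$w[comm[g$ea] == comm[g$eb]]) + sum(g$loop)
  sum_d2 <- sum(rowsum(k, comm)^2)
  2 * internal / two_m - gamma * sum_d2 / two_m^2
}

check_partition <- function(net, partition) {
  if (is.null(names(partition)))
    stop_carefrag("partition must be a named vector (node -> label)",
                  class = "carefrag_invalid_partition")
  missing_nodes <- setdiff(net$nodes, names(partition))
  if (length(missing_nodes))
    stop_carefrag("partition does not assign node(s): %s",
                  paste(head(missing_nodes, 5L), collapse = ", "),
                  class = "carefrag_invalid_partition")
  partition[net$nodes]
}

#' Resolution modularity of a partition
#'
#' Evaluates \deqn{Q(\gamma) = \frac{1}{2m} \sum_{i,j} \left[ A_{ij} -
#' \gamma \frac{k_i k_j}{2m} \right] \delta(c_i, c_j)} for a weighted
#' undirected network, where \eqn{k_i} is the weighted degree, \eqn{m} the
#' total edge weight, and \eqn{\gamma > 0} the resolution parameter
#' (\eqn{\gamma = 1} gives classic Newman-Girvan modularity). Computed in
#' O(|E| + |V|) from per-community internal-weight and degree sums.
#'
#' @param net a `patient_sharing_network` with positive total edge weight.
#' @param partition named vector mapping every node to a community label.
#' @param gamma positive resolution parameter.
#' @return list with elements `q` and `gamma`.
#' @export
resolution_modularity <- function(net, partition, gamma = 1) {
  if (!is.numeric(gamma) || gamma <= 0)
    stop_carefrag("gamma must be a positive real", class = "carefrag_invalid_gamma")
  partition <- check_partition(net, partition)
  g <- as_work_graph(net)
  comm <- as.integer(factor(partition[net$nodes]))
  list(q = work_modularity(g, comm, gamma), gamma = gamma)
}

# Relabel a membership vector over `nodes` so labels are 0-based consecutive
# integers in order of first appearance over the lexicographically sorted
# node codes — making outputs byte-stable across seeds that find the same
# grouping.
canonicalize_partition <- function(membership, nodes) {
  ord <- order(nodes)
  first_seen <- unique(membership[ord])
  labels <- match(membership, first_seen) - 1L
  stats::setNames(labels, nodes)
}

#' Louvain optimisation of resolution modularity
#'
#' Standard two-phase Louvain heuristic, written against the resolution
#' modularity of [resolution_modularity()]: repeated single-node moves to the
#' neighbouring community with the largest positive modularity gain (sweep
#' order shuffled by `seed`; a move must beat staying put by more than `tol`
#' on the weighted gain, which avoids floating-point cycling), followed by
#' aggregation of communities into super-nodes whose self-loops carry the
#' internal weight, iterated until no further gain. Isolated nodes end in
#' their own singleton communities. Labels are canonicalized to 0-based
#' first-appearance order over sorted node codes.
#'
#' @param net a `patient_sharing_network` with positive total edge weight.
#' @param gamma positive resolution parameter (default 1).
#' @param seed integer seed for the node sweep order.
#' @param tol minimum weighted gain for accepting a move.
#' @return list with `partition` (named 0-based labels), `modularity`
#'   (list `q`, `gamma`), `n_communities`, and `q_levels` (the non-decreasing
#'   modularity after each aggregation level).
#' @export
louvain <- function(net, gamma = 1, seed = 0L, tol = 1e-12) {
  if (!is.numeric(gamma) || gamma <= 0)
    stop_carefrag("gamma must be a positive real", class = "carefrag_invalid_gamma")
  g <- as_work_graph(net)
  if (sum(g$w) + sum(g$loop) <= 0)
    stop_carefrag("Louvain requires a network with positive total edge weight",
                  class = "carefrag_empty_network")
  n0 <- g$n
  member <- seq_len(n0)   # original node -> current super-node
  q_levels <- numeric()
  with_seed(seed, {
    repeat {
      mv <- louvain_local_move(g, gamma, tol)
      q_levels <- c(q_levels, work_modularity(g, mv$comm, gamma))
      member <- mv$comm[member]
      if (!mv$moved) break
      g <- aggregate_graph(g, mv$comm)
      if (g$n == 1L) break
    }
  })
  partition <- canonicalize_partition(member, net$nodes)
  list(
    partition = partition,
    modularity = resolution_modularity(net, partition, gamma),
    n_communities = length(unique(partition)),
    q_levels = q_levels
  )
}

# Phase 1: greedy single-node moves until a full sweep makes no move.
# Returns the compacted community ids and whether anything moved.
louvain_local_move <- function(g, gamma, tol) {
  n <- g$n
  adj <- vector("list", n)
  adjw <- vector("list", n)
  if (length(g$w)) {
    ii <- c(g$ea, g$eb)
    jj <- c(g$eb, g$ea)
    ww <- c(g$w, g$w)
    o <- order(ii)
    sp <- split(seq_along(ii)[o], ii[o])
    for (nm in names(sp)) {
      i <- as.integer(nm)
      adj[[i]] <- jj[sp[[nm]]]
      adjw[[i]] <- ww[sp[[nm]]]
    }
  }
  k <- work_degrees(g)
  two_m <- sum(k)
  comm <- seq_len(n)
  sig_tot <- k
  moved_any <- FALSE
  repeat {
    improved <- FALSE
    for (i in sample.int(n)) {
      nb <- adj[[i]]
      if (is.null(nb)) next
      ci <- comm[i]
      cc <- comm[nb]
      w_ic <- rowsum(adjw[[i]], cc)          # weight from i to each nb community
      cand <- as.integer(rownames(w_ic))
      sig_tot[ci] <- sig_tot[ci] - k[i]      # detach i
      gains <- w_ic[, 1L] - gamma * k[i] * sig_tot[cand] / two_m
      stay <- if (ci %in% cand) gains[match(ci, cand)] else
        -gamma * k[i] * sig_tot[ci] / two_m
      best <- which.max(gains)
      if (gains[best] > stay + tol && cand[best] != ci) {
        comm[i] <- cand[best]
        sig_tot[cand[best]] <- sig_tot[cand[best]] + k[i]
        improved <- TRUE
        moved_any <- TRUE
      } else {
        sig_tot[ci] <- sig_tot[ci] + k[i]
      }
    }
    if (!improved) break
  }
  list(comm = match(comm, unique(comm)), moved = moved_any)
}

# Phase 2: communities become super-nodes; intra-community weight (including
# previous loops) becomes the super-node's self-loop.
aggregate_graph <- function(g, comm) {
  nc <- max(comm)
  loop_new <- rowsum_vec(g$loop, comm, nc)
  if (length(g$w)) {
    ca <- comm[g$ea]
    cb <- comm[g$eb]
    intra <- ca == cb
    if (any(intra))
      loop_new <- loop_new + rowsum_vec(g$w[intra], ca[intra], nc)
    a <- pmin(ca[!intra], cb[!intra])
    b <- pmax(ca[!intra], cb[!intra])
    if (length(a)) {
      ag <- data.table(a = a, b = b, w = g$w[!intra])[, .(w = sum(w)), by = .(a, b)]
      setorder(ag, a, b)
      return(list(n = nc, ea = ag$a, eb = ag$b, w = ag$w, loop = loop_new))
    }
  }
  list(n = nc, ea = integer(), eb = integer(), w = numeric(), loop = loop_new)
}

#' Globally optimal partition by exhaustive search
#'
#' Enumerates every set partition of the node set (Bell-number many; refused
#' above 10 nodes) and returns a partition maximising resolution modularity.
#' Ties are broken toward fewer communities, then toward the
#' lexicographically smallest restricted-growth label sequence. Serves as the
#' independent oracle against which the Louvain heuristic is validated.
#'
#' @param net a `patient_sharing_network` with at most 10 nodes and positive
#'   total edge weight.
#' @param gamma positive resolution parameter.
#' @return list with `partition` (named 0-based labels) and `modularity`
#'   (list `q`, `gamma`).
#' @export
exhaustive_best_partition <- function(net, gamma = 1) {
  if (!is.numeric(gamma) || gamma <= 0)
    stop_carefrag("gamma must be a positive real", class = "carefrag_invalid_gamma")
  n <- length(net$nodes)
  if (n > 10L)
    stop_carefrag("exhaustive search is refused above 10 nodes (Bell numbers explode)",
                  class = "carefrag_too_large")
  g <- as_work_graph(net)
  k <- work_degrees(g)
  two_m <- sum(k)
  if (two_m <= 0)
    stop_carefrag("modularity is undefined for a network with no edge weight",
                  class = "carefrag_empty_network")
  parts <- all_set_partitions(n)
  best <- NULL
  best_q <- -Inf
  eps <- 1e-12
  for (mb in parts) {
    internal <- sum(g$w[mb[g$ea] == mb[g$eb]])
    q <- 2 * internal / two_m - gamma * sum(rowsum(k, mb)^2) / two_m^2
    if (q > best_q + eps) {
      best <- mb; best_q <- q
    } else if (q > best_q - eps && !is.null(best)) {
      if (max(mb) < max(best) ||
          (max(mb) == max(best) && rgs_less(mb, best))) {
        best <- mb
        best_q <- max(best_q, q)
      }
    }
  }
  partition <- stats::setNames(best - 1L, net$nodes)
  list(partition = partition,
       modularity = list(q = best_q, gamma = gamma))
}

rgs_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1L]] < b[d[1L]]
}

# All set partitions of n items as restricted-growth strings (1-based labels,
# first-appearance order), enumerated lexicographically.
all_set_partitions <- function(n) {
  parts <- list(1L)
  if (n == 1L) return(parts)
  for (i in 2:n) {
    parts <- unlist(lapply(parts, function(p) {
      lapply(seq_len(max(p) + 1L), function(lab) c(p, lab))
    }), recursive = FALSE)
  }
  parts
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same nodes; 1
#' means identical groupings. Named vectors are aligned by name; the
#' degenerate cases where the index is 0/0 (both partitions trivial in the
#' same way) score 1.
#'
#' @param p1,p2 partitions as (optionally named) label vectors.
#' @return the ARI, a number `<= 1`.
#' @export
adjusted_rand_index <- function(p1, p2) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2)))
      stop_carefrag("partitions cover different node sets",
                    class = "carefrag_invalid_partition")
    p2 <- p2[names(p1)]
  }
  stopifnot(length(p1) == length(p2))
  r <- mclust::adjustedRandIndex(p1, p2)
  if (is.nan(r)) 1 else r
}

#' Multi-seed, multi-resolution stability sweep
#'
#' Runs [louvain()] for each resolution in `gammas` with `n_seeds` different
#' sweep-order seeds, and summarises, per resolution: the modal number of
#' communities, the mean pairwise adjusted Rand index across the seed
#' partitions, the best-modularity partition, and a `stable` flag (mean
#' pairwise ARI >= 0.95). This substitutes a reproducible stability
#' assessment for an arbitrary single run.
#'
#' @param net a `patient_sharing_network`.
#' @param gammas positive resolutions to scan.
#' @param n_seeds number of seeds per resolution (>= 2).
#' @param base_seed first seed; seeds are `base_seed + 0:(n_seeds-1)`.
#' @return list with `summary` (a data.table: `gamma`,
#'   `modal_n_communities`, `mean_pairwise_ari`, `best_q`, `stable`) and
#'   `best_partitions` (named by gamma).
#' @export
stability_sweep <- function(net, gammas = 1, n_seeds = 10L, base_seed = 1L) {
  if (any(gammas <= 0))
    stop_carefrag("gammas must be positive", class = "carefrag_invalid_gamma")
  if (n_seeds < 2L)
    stop_carefrag("n_seeds must be >= 2", class = "carefrag_invalid_config")
  seeds <- base_seed + seq_len(n_seeds) - 1L
  rows <- list()
  best_partitions <- list()
  for (gi in seq_along(gammas)) {
    gamma <- gammas[gi]
    runs <- lapply(seeds, function(s) louvain(net, gamma = gamma, seed = s))
    qs <- vapply(runs, function(r) r$modularity$q, 0)
    ncs <- vapply(runs, function(r) r$n_communities, 0L)
    pairs <- utils::combn(length(runs), 2L)
    aris <- apply(pairs, 2L, function(ij)
      adjusted_rand_index(runs[[ij[1L]]]$partition, runs[[ij[2L]]]$partition))
    tab <- table(ncs)
    modal_nc <- as.integer(names(tab)[which.max(tab)])
    rows[[gi]] <- data.table(
      gamma = gamma,
      modal_n_communities = modal_nc,
      mean_pairwise_ari = mean(aris),
      best_q = max(qs),
      stable = mean(aris) >= 0.95
    )
    best_partitions[[as.character(gamma)]] <- runs[[which.max(qs)]]$partition
  }
  list(summary = rbindlist(rows), best_partitions = best_partitions)
}

#' Write a partition as CSV or JSON
#'
#' CSV columns `provider_code,community`, rows sorted by provider; JSON is a
#' single object mapping provider to label.
#'
#' @param partition named label vector.
#' @param path destination; format chosen by extension (`.json` for JSON,
#'   otherwise CSV).
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  ord <- order(names(partition))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(stats::setNames(unname(partition)[ord],
                                                 names(partition)[ord])),
                         path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    data.table::fwrite(data.table(provider_code = names(partition)[ord],
                                  community = unname(partition)[ord]), path)
  }
  invisible(path)
}
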