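# Accessible adaptive walks: an accessible path is a sequence of observed,
# unit-step-adjacent haplotypes whose fitness increases strictly at every step.
# Intermediate nodes must carry hybrid fitness (only haplotypes observed in at
# least one hybrid enter the interior of a path); the two endpoint nodes may be
# parental-only (undefined fitness) and then impose no constraint at their own
# step.

unit_adjacency <- function(net) net$dist == 1

#' Find fitness peaks of a genotype network
#'
#' A peak is a fitness-defined node with no unit-step neighbour of strictly
#' greater defined fitness. Neighbours with undefined fitness impose no
#' constraint, and equal-fitness neighbours do not disqualify a peak.
#'
#' @param net a [build_network()] result with at least one fitness-defined
#'   node.
#' @return Integer vector of peak node indices.
#' @export
find_peaks <- function(net) {
  stopifnot(inherits(net, "genotype_network"))
  f <- net$fitness
  defined <- which(!is.na(f))
  if (length(defined) == 0)
    stop("no fitness-defined nodes; peaks undefined", call. = FALSE)
  adj <- unit_adjacency(net)
  peaks <- defined[vapply(defined, function(v) {
    nb <- which(adj[v, ])
    nbf <- f[nb]
    !any(!is.na(nbf) & nbf > f[v])
  }, logical(1))]
  peaks
}

# Directed accessible graph between two endpoints: vertex set = fitness-defined
# nodes plus the endpoints; edge u->v allowed when dist(u,v)==1 and fitness
# increases strictly (an undefined-fitness endpoint is unconstrained: an
# undefined source only emits, an undefined target only receives). Strict
# increase makes this a DAG ordered by fitness.
accessible_path_stats <- function(net, source, target, strict_increase = TRUE) {
  f <- net$fitness
  nv <- n_nodes(net)
  if (source < 1 || source > nv || target < 1 || target > nv)
    stop("endpoint node not in network", call. = FALSE)
  if (source == target)
    return(list(degenerate = TRUE, count = NA_real_, count_str = NA_character_,
                shortest_len = NA_real_))
  if (!strict_increase)
    return(accessible_paths_dfs(net, source, target))

  verts <- union(which(!is.na(f)), c(source, target))
  key <- f[verts]
  key[verts == source & is.na(f[verts])] <- -Inf
  key[verts == target & is.na(f[verts])] <- Inf
  ord <- verts[order(key)]
  k <- length(ord)
  adj <- unit_adjacency(net)

  allowed <- function(u, v) {
    if (!adj[u, v]) return(FALSE)
    fu <- f[u]; fv <- f[v]
    if (is.na(fu)) return(u == source)
    if (is.na(fv)) return(v == target)
    fu < fv
  }

  pos <- match(c(source, target), ord)
  counts <- vector("list", k)      # big-int path counts from source
  nums <- numeric(k)               # double mirror for speed / shortest check
  lens <- rep(Inf, k)              # min nodes on an accessible path
  counts[[pos[1]]] <- big_from_num(1)
  nums[pos[1]] <- 1
  lens[pos[1]] <- 1
  for (j in seq_len(k)) {
    v <- ord[j]
    if (v == source) next
    acc <- 0
    accbig <- 0
    best <- Inf
    for (i in seq_len(j - 1)) {
      u <- ord[i]
      if (nums[i] > 0 && allowed(u, v)) {
        acc <- acc + nums[i]
        accbig <- big_add(accbig, counts[[i]])
        if (lens[i] + 1 < best) best <- lens[i] + 1
      }
    }
    nums[j] <- acc
    counts[[j]] <- accbig
    lens[j] <- best
  }
  jt <- pos[2]
  cnt_big <- counts[[jt]]
  list(
    degenerate = FALSE,
    count = big_to_num(cnt_big),
    count_str = big_to_string(cnt_big),
    shortest_len = if (big_is_zero(cnt_big)) NA_real_ else lens[jt]
  )
}

# Non-strict traversal (ties passable) can cycle through equal-fitness
# plateaus, so paths are enumerated exhaustively as simple paths; only
# suitable for small networks.
accessible_paths_dfs <- function(net, source, target, max_nodes = 60) {
  if (n_nodes(net) > max_nodes)
    stop("non-strict path enumeration is limited to small networks (<= ",
         max_nodes, " nodes)", call. = FALSE)
  f <- net$fitness
  adj <- unit_adjacency(net)
  count <- 0
  shortest <- Inf
  visited <- rep(FALSE, n_nodes(net))
  step_ok <- function(u, v) {
    if (!adj[u, v]) return(FALSE)
    if (is.na(f[u])) return(u == source)
    if (is.na(f[v])) return(v == target)
    f[u] <= f[v]
  }
  recurse <- function(u, depth) {
    if (u == target) {
      count <<- count + 1
      shortest <<- min(shortest, depth)
      return(invisible())
    }
    visited[u] <<- TRUE
    for (v in seq_len(n_nodes(net))) {
      if (!visited[v] && (!is.na(f[v]) || v == target) && step_ok(u, v))
        recurse(v, depth + 1)
    }
    visited[u] <<- FALSE
  }
  recurse(source, 1)
  list(degenerate = FALSE, count = count,
       count_str = sprintf("%.0f", count),
       shortest_len = if (count == 0) NA_real_ else shortest)
}

#' Count accessible paths between two nodes
#'
#' Counts the distinct directed paths from `source` to `target` along
#' unit-step edges with strictly increasing node fitness at every step among
#' fitness-defined nodes (a parental-only endpoint with undefined fitness
#' imposes no constraint at its own step). The count is exact: dynamic
#' programming over the strict-increase DAG with arbitrary-precision
#' accumulation, returned both as a double (`Inf` if it overflows) and as a
#' decimal string.
#'
#' @param net a [build_network()] result (unit-step edges are used).
#' @param source,target node indices (see [node_of()]).
#' @param strict_increase require strictly increasing fitness (default);
#'   `FALSE` allows equal-fitness steps and falls back to exhaustive
#'   enumeration on small networks.
#' @return List with `count`, `count_str`, `shortest_len` (minimum number of
#'   nodes on an accessible path; `NA` when no path is accessible) and a
#'   `degenerate` flag (set when `source == target`).
#' @export
count_accessible_paths <- function(net, source, target, strict_increase = TRUE) {
  stopifnot(inherits(net, "genotype_network"))
  accessible_path_stats(net, source, target, strict_increase = strict_increase)
}

#' Accessible paths from a node to the peaks of the landscape
#'
#' Sums accessible-path counts from `start` to every fitness peak, scaled by
#' the number of nodes in the network, and reports the minimum accessible
#' distance (in mutational steps, i.e. nodes minus one) to any peak. A start
#' node that is itself a peak has distance 0.
#'
#' @param net a [build_network()] result.
#' @param start node index.
#' @param peaks optional pre-computed peak set (from [find_peaks()]).
#' @return List with `n_paths` (double), `n_paths_scaled`, and
#'   `min_dist_to_peak` (`NA` when no peak is accessibly reachable).
#' @export
paths_to_peaks <- function(net, start, peaks = NULL) {
  stopifnot(inherits(net, "genotype_network"))
  if (is.null(peaks)) peaks <- find_peaks(net)
  total <- 0
  min_dist <- Inf
  if (start %in% peaks) min_dist <- 0
  for (p in setdiff(peaks, start)) {
    res <- accessible_path_stats(net, start, p)
    total <- total + res$count
    if (!is.na(res$shortest_len)) min_dist <- min(min_dist, res$shortest_len - 1)
  }
  list(
    n_paths = total,
    n_paths_scaled = total / n_nodes(net),
    min_dist_to_peak = if (is.finite(min_dist)) min_dist else NA_real_
  )
}

#' Summarise a replicate network's accessibility statistics
#'
#' Computes the per-network summary used throughout the resampling analyses:
#' numbers of nodes and edges, the number of accessible paths between the
#' sampled generalist and specialist individuals (and that count scaled by
#' network size), the length in nodes of the shortest accessible path, the
#' number of fitness peaks, the scaled number of accessible paths from the
#' two endpoint nodes to peaks, and the minimum accessible distance (steps)
#' from either endpoint to a peak.
#'
#' @param net a unit-step [build_network()] result.
#' @param generalist,specialist sample ids of the endpoint individuals.
#' @param replicate_id,seed bookkeeping columns passed through to the output.
#' @return One-row data frame. When the replicate is degenerate (an endpoint
#'   was dropped for missing genotypes, or both endpoints share one node) the
#'   `degenerate` column is `TRUE`, `reason` says why, and the statistics are
#'   `NA` (the resampling engine redraws such replicates).
#' @export
summarize_network <- function(net, generalist, specialist,
                              replicate_id = NA_integer_, seed = NA_integer_) {
  stopifnot(inherits(net, "genotype_network"))
  gnode <- node_of(net, generalist)
  snode <- node_of(net, specialist)
  base <- data.frame(
    replicate_id = replicate_id, seed = seed,
    n_nodes = n_nodes(net), n_edges = nrow(net$edges),
    n_accessible_paths = NA_real_, n_accessible_paths_str = NA_character_,
    scaled_paths = NA_real_, shortest_accessible_len = NA_real_,
    n_peaks = NA_real_, n_paths_to_peaks_scaled = NA_real_,
    min_dist_to_peak = NA_real_,
    degenerate = TRUE, reason = NA_character_,
    stringsAsFactors = FALSE
  )
  if (is.na(gnode) || is.na(snode)) {
    base$reason <- "endpoint_dropped"
    return(base)
  }
  if (gnode == snode) {
    base$reason <- "shared_endpoint"
    return(base)
  }
  ps <- accessible_path_stats(net, gnode, snode)
  peaks <- find_peaks(net)
  pg <- paths_to_peaks(net, gnode, peaks = peaks)
  psp <- paths_to_peaks(net, snode, peaks = peaks)

  base$n_accessible_paths <- ps$count
  base$n_accessible_paths_str <- ps$count_str
  base$scaled_paths <- ps$count / n_nodes(net)
  base$shortest_accessible_len <- ps$shortest_len
  base$n_peaks <- length(peaks)
  base$n_paths_to_peaks_scaled <- pg$n_paths_scaled + psp$n_paths_scaled
  base$min_dist_to_peak <- suppressWarnings(
    min(pg$min_dist_to_peak, psp$min_dist_to_peak, na.rm = TRUE))
  if (!is.finite(base$min_dist_to_peak)) base$min_dist_to_peak <- NA_real_
  base$degenerate <- FALSE
  base
}
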