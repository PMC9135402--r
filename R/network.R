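#' Mutational distance between two multilocus 012 haplotypes
#'
#' One mutational step changes one allele copy at one locus, so the distance
#' between unphased diploid genotype vectors is the Manhattan distance
#' `sum(|a_i - b_i|)`: 0<->1 and 1<->2 count one step, 0<->2 counts two.
#'
#' @param a,b equal-length integer vectors over \{0, 1, 2\}.
#' @return Integer number of mutational steps.
#' @export
mutational_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("haplotypes differ in length", call. = FALSE)
  if (anyNA(a) || anyNA(b))
    stop("haplotypes must not contain missing states", call. = FALSE)
  as.integer(sum(abs(a - b)))
}

#' Build a genotypic fitness network over a set of loci
#'
#' Nodes are the distinct multilocus 012 haplotypes observed among retained
#' individuals; individuals with any missing call at the selected loci are
#' excluded (their ids are kept in the `dropped` field). Identical haplotypes
#' collapse to one node that accumulates its carriers. Node fitness is the
#' aggregate (mean by default) of the chosen fitness measure over hybrid
#' carriers; nodes carried only by parental individuals have undefined
#' (`NA`) fitness. Edges connect every node pair whose mutational distance is
#' at most `max_edge_distance` and store that distance; direction (low to
#' high fitness) is applied at traversal time by the accessibility functions.
#'
#' @param gm a [genotype_matrix()].
#' @param loci integer vector of locus (column) indices.
#' @param fitness a [fitness_records()] table covering every hybrid carrier.
#' @param measure fitness measure aggregated per node: `"composite"`
#'   (default), `"growth"` or `"survival"`.
#' @param max_edge_distance largest mutational distance joined by an edge;
#'   1 (default) for accessibility analyses, 5 for visualisation.
#' @param aggregate `"mean"` (default) or `"median"` over hybrid carriers.
#' @return An object of class `genotype_network`.
#' @export
build_network <- function(gm, loci, fitness, measure = c("composite", "growth", "survival"),
                          max_edge_distance = 1L, aggregate = c("mean", "median")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  measure <- match.arg(measure)
  aggregate <- match.arg(aggregate)
  if (length(loci) == 0) stop("loci must be non-empty", call. = FALSE)
  if (max_edge_distance < 1) stop("max_edge_distance must be >= 1", call. = FALSE)

  sub <- gm$calls[, loci, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0
  dropped <- gm$samples$sample_id[!complete]
  if (!any(complete))
    stop("no individuals with complete genotypes at the selected loci", call. = FALSE)
  sub <- sub[complete, , drop = FALSE]
  meta <- gm$samples[complete, , drop = FALSE]

  is_hybrid <- meta$role == "hybrid"
  if (any(is_hybrid)) {
    miss_fit <- setdiff(meta$sample_id[is_hybrid], fitness$sample_id)
    if (length(miss_fit))
      stop("hybrid carrier(s) without fitness record: ",
           paste(utils::head(miss_fit, 5), collapse = ", "), call. = FALSE)
  }

  keys <- apply(sub, 1, paste, collapse = "")
  uniq <- !duplicated(keys)
  haps <- sub[uniq, , drop = FALSE]
  node_key <- keys[uniq]
  rownames(haps) <- NULL
  node_idx <- match(keys, node_key)

  n_nodes <- nrow(haps)
  carriers <- split(meta$sample_id, node_idx)
  hybrid_carriers <- split(ifelse(is_hybrid, meta$sample_id, NA_character_), node_idx)
  hybrid_carriers <- lapply(hybrid_carriers, function(v) v[!is.na(v)])

  agg_fun <- if (aggregate == "mean") mean else stats::median
  fit_lookup <- stats::setNames(fitness[[measure]], fitness$sample_id)
  node_fitness <- vapply(hybrid_carriers, function(ids) {
    if (length(ids) == 0) return(NA_real_)
    v <- fit_lookup[ids]
    v <- v[!is.na(v)]            # e.g. growth is unmeasured for non-survivors
    if (length(v) == 0) return(NA_real_)
    agg_fun(v)
  }, numeric(1))

  species_counts <- t(vapply(carriers, function(ids) {
    sp <- meta$species[match(ids, meta$sample_id)]
    tabulate(factor(sp, levels = SPECIES_LEVELS), nbins = length(SPECIES_LEVELS))
  }, integer(length(SPECIES_LEVELS))))
  colnames(species_counts) <- SPECIES_LEVELS

  d <- as.matrix(stats::dist(haps, method = "manhattan"))
  pairs <- which(upper.tri(d) & d <= max_edge_distance, arr.ind = TRUE)
  edges <- data.frame(
    from = pairs[, 1], to = pairs[, 2],
    distance = as.integer(d[pairs])
  )

  sample_node <- stats::setNames(node_idx, meta$sample_id)

  structure(
    list(
      haplotypes = haps, keys = node_key, fitness = unname(node_fitness),
      carriers = unname(carriers), hybrid_carriers = unname(hybrid_carriers),
      species_counts = species_counts, edges = edges,
      dist = d, max_edge_distance = as.integer(max_edge_distance),
      measure = measure, loci = loci,
      loci_info = gm$loci[loci, , drop = FALSE],
      dropped = dropped, sample_node = sample_node
    ),
    class = "genotype_network"
  )
}

#' Node index carrying a given sample
#'
#' @param net a [build_network()] result.
#' @param sample_id a sample identifier retained in the network.
#' @return Integer node index, or `NA` if the sample was dropped for
#'   missing genotypes.
#' @export
node_of <- function(net, sample_id) {
  stopifnot(inherits(net, "genotype_network"))
  idx <- net$sample_node[sample_id]
  unname(idx)
}

n_nodes <- function(net) nrow(net$haplotypes)

#' @export
print.genotype_network <- function(x, ...) {
  cat("genotype_network:", n_nodes(x), "nodes,", nrow(x$edges), "edges",
      sprintf("(max edge distance %d, measure '%s')\n", x$max_edge_distance, x$measure))
  cat("  loci:", length(x$loci),
      "| individuals retained:", length(x$sample_node),
      "| dropped for missingness:", length(x$dropped), "\n")
  nd <- sum(!is.na(x$fitness))
  cat("  fitness-defined nodes:", nd, "of", n_nodes(x), "\n")
  invisible(x)
}

#' @export
summary.genotype_network <- function(object, ...) {
  f <- object$fitness
  out <- list(
    n_nodes = n_nodes(object),
    n_edges = nrow(object$edges),
    n_unit_edges = sum(object$edges$distance == 1L),
    n_fitness_defined = sum(!is.na(f)),
    fitness_range = if (any(!is.na(f))) range(f, na.rm = TRUE) else c(NA, NA),
    n_dropped = length(object$dropped)
  )
  class(out) <- "summary.genotype_network"
  out
}

#' @export
print.summary.genotype_network <- function(x, ...) {
  cat("Genotypic fitness network\n")
  cat("  nodes:", x$n_nodes, " edges:", x$n_edges,
      " (unit-step:", x$n_unit_edges, ")\n")
  cat("  fitness-defined nodes:", x$n_fitness_defined, "\n")
  if (!is.na(x$fitness_range[1]))
    cat(sprintf("  node fitness range: [%.4g, %.4g]\n",
                x$fitness_range[1], x$fitness_range[2]))
  cat("  individuals dropped for missingness:", x$n_dropped, "\n")
  invisible(x)
}

#' Convert a genotype network to an igraph object
#'
#' Nodes carry the haplotype string, fitness, carrier counts and per-species
#' carrier counts; edges carry mutational distance. Undirected: traversal
#' direction (low to high fitness) is a query-time notion.
#'
#' @param net a [build_network()] result.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "genotype_network"))
  g <- igraph::make_empty_graph(n = n_nodes(net), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "haplotype", value = net$keys)
  g <- igraph::set_vertex_attr(g, "fitness", value = net$fitness)
  g <- igraph::set_vertex_attr(g, "n_carriers",
                               value = vapply(net$carriers, length, integer(1)))
  g <- igraph::set_vertex_attr(g, "n_hybrid_carriers",
                               value = vapply(net$hybrid_carriers, length, integer(1)))
  for (sp in colnames(net$species_counts))
    g <- igraph::set_vertex_attr(g, paste0("n_", sp), value = net$species_counts[, sp])
  if (nrow(net$edges) > 0) {
    g <- igraph::add_edges(g, rbind(net$edges$from, net$edges$to))
    g <- igraph::set_edge_attr(g, "distance", value = net$edges$distance)
  }
  g
}

#' Export a genotype network to GraphML or a TSV edge list
#'
#' @param net a [build_network()] result with at least one node.
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist"` (TSV with node attributes in a
#'   companion `<path>.nodes.tsv` table).
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (n_nodes(net) == 0) stop("empty network", call. = FALSE)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
    nodes <- data.frame(
      node = seq_len(n_nodes(net)),
      haplotype = net$keys,
      fitness = net$fitness,
      n_carriers = vapply(net$carriers, length, integer(1)),
      n_hybrid_carriers = vapply(net$hybrid_carriers, length, integer(1))
    )
    utils::write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Plot a genotype network
#'
#' Vertex size scales with node fitness (undefined-fitness nodes are drawn at
#' the minimum size), edge width shrinks with mutational distance, mirroring
#' the usual hybrid-swarm network figures.
#'
#' @param x a `genotype_network`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.genotype_network <- function(x, ...) {
  g <- as_igraph(x)
  f <- x$fitness
  rng <- range(f, na.rm = TRUE)
  size <- if (diff(rng) > 0) 4 + 10 * (f - rng[1]) / diff(rng) else rep(7, length(f))
  size[is.na(size)] <- 4
  ew <- if (nrow(x$edges) > 0) 3 / x$edges$distance else NULL
  igraph::plot.igraph(g, vertex.size = size, vertex.label = NA,
                      edge.width = ew, ...)
  invisible(x)
}
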