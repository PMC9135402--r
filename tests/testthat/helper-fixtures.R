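# Fixture builders and independent oracles shared across tests.

# genotype_matrix with explicit roles: parental rows get undefined node
# fitness downstream, hybrid rows carry fitness records.
toy_gm <- function(calls, roles = rep("hybrid", nrow(calls)),
                   species = ifelse(roles == "hybrid", "hybrid", "generalist"),
                   loci = NULL) {
  n <- nrow(calls)
  ids <- sprintf("i%03d", seq_len(n))
  genotype_matrix(
    calls,
    samples = data.frame(
      sample_id = ids, species = species, lake = NA_character_,
      experiment = ifelse(roles == "hybrid", "exp2011", "none"),
      role = roles, stringsAsFactors = FALSE
    ),
    loci = loci
  )
}

# fitness records realising exact composite values: all survive, growth = w
toy_fitness <- function(ids, w) {
  fitness_records(data.frame(
    sample_id = ids, survived = 1, initial_sl = 30,
    final_sl = 30 * (1 + w), stringsAsFactors = FALSE
  ))
}

# Exhaustive DFS enumeration of accessible simple paths; independent of the
# DP: recomputes unit-step adjacency from the haplotype matrix and walks all
# simple paths with the monotonicity rule applied edge by edge.
oracle_paths <- function(haps, fitness, source, target) {
  n <- nrow(haps)
  d <- as.matrix(stats::dist(haps, method = "manhattan"))
  f <- fitness
  count <- 0
  shortest <- Inf
  visited <- rep(FALSE, n)
  step_ok <- function(u, v) {
    if (d[u, v] != 1) return(FALSE)
    if (is.na(f[u])) return(u == source)
    if (is.na(f[v])) return(v == target)
    f[u] < f[v]
  }
  dfs <- function(u, depth) {
    if (u == target) {
      count <<- count + 1
      shortest <<- min(shortest, depth)
      return(invisible())
    }
    visited[u] <<- TRUE
    for (v in seq_len(n)) {
      if (!visited[v] && (v == target || !is.na(f[v])) && step_ok(u, v))
        dfs(v, depth + 1)
    }
    visited[u] <<- FALSE
  }
  dfs(source, 1)
  list(count = count, shortest_len = if (count == 0) NA_real_ else shortest)
}

# Exhaustive peak oracle on explicit haplotypes/fitness.
oracle_peaks <- function(haps, fitness) {
  d <- as.matrix(stats::dist(haps, method = "manhattan"))
  defined <- which(!is.na(fitness))
  defined[vapply(defined, function(v) {
    nb <- which(d[v, ] == 1)
    !any(!is.na(fitness[nb]) & fitness[nb] > fitness[v])
  }, logical(1))]
}

# Random observed network over m loci with <= n_max distinct haplotypes;
# a fraction of nodes is parental-only (undefined fitness).
random_net_case <- function(m = 3, n_max = 20, p_parental = 0.15) {
  space <- as.matrix(expand.grid(rep(list(0:2), m)))
  colnames(space) <- NULL
  n <- sample(4:min(n_max, nrow(space)), 1)
  rows <- sample(nrow(space), n)
  haps <- space[rows, , drop = FALSE]
  roles <- ifelse(stats::runif(n) < p_parental, "parental", "hybrid")
  if (all(roles == "parental")) roles[1] <- "hybrid"
  gm <- toy_gm(haps, roles = roles)
  fit <- toy_fitness(gm$samples$sample_id[roles == "hybrid"],
                     round(stats::runif(sum(roles == "hybrid")), 3))
  net <- build_network(gm, seq_len(m), fit)
  ends <- sample(n_nodes_of(net), 2)
  list(net = net, source = ends[1], target = ends[2])
}

n_nodes_of <- function(net) nrow(net$haplotypes)

# small VCF text fixture written to a temp file
write_vcf_text <- function(records, sample_ids) {
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}
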