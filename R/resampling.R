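#' Configuration for the accessibility resampling ensemble
#'
#' Defaults mirror the study design: 5000 replicate networks, five adaptive
#' SNPs per network, and (when more than one source of variation is pooled) a
#' rejection-sampling requirement that every requested source be represented
#' in each draw.
#'
#' @param specialist focal specialist (`"molluscivore"` or `"scale_eater"`).
#' @param sources sources of adaptive variation forming the SNP pool.
#' @param n_replicates number of replicate networks (default 5000).
#' @param snps_per_network SNPs sampled per network (default 5).
#' @param require_each_source require at least one SNP per requested source in
#'   every draw (default: on when more than one source is requested).
#' @param measure fitness measure for node fitness (default `"composite"`).
#' @param seed master seed; per-replicate streams derive from it.
#' @param max_resample_attempts redraw budget per replicate for degenerate
#'   draws (shared or dropped endpoints).
#' @return A list of class `resampling_config`.
#' @export
resampling_config <- function(specialist, sources,
                              n_replicates = 5000L, snps_per_network = 5L,
                              require_each_source = length(sources) > 1,
                              measure = "composite", seed = 1L,
                              max_resample_attempts = 100L) {
  stopifnot(n_replicates >= 1, snps_per_network >= 1)
  specialist <- match.arg(specialist, c("molluscivore", "scale_eater"))
  check_level(sources, SOURCE_LEVELS, "source")
  structure(list(
    specialist = specialist, sources = sources,
    n_replicates = as.integer(n_replicates),
    snps_per_network = as.integer(snps_per_network),
    require_each_source = isTRUE(require_each_source),
    measure = measure, seed = as.integer(seed),
    max_resample_attempts = as.integer(max_resample_attempts)
  ), class = "resampling_config")
}

#' Sample a SNP set from an adaptive-locus pool
#'
#' Draws `k` distinct loci uniformly without replacement. When `require_each`
#' is set, draws are rejection-sampled until every requested source of
#' variation is represented at least once, matching the study's constraint
#' without biasing marginal inclusion beyond it.
#'
#' @param pool integer locus indices.
#' @param pool_sources character vector of the source of each pool locus.
#' @param k number of SNPs to draw.
#' @param sources requested sources (used by the representation check).
#' @param require_each enforce >= 1 locus per requested source.
#' @param max_attempts rejection-sampling budget.
#' @return Integer vector of `k` locus indices.
#' @export
sample_snp_set <- function(pool, pool_sources, k, sources,
                           require_each = length(sources) > 1,
                           max_attempts = 1000L) {
  if (k > length(pool))
    stop("cannot draw ", k, " SNPs from a pool of ", length(pool), call. = FALSE)
  if (require_each) {
    have <- unique(pool_sources)
    lacking <- setdiff(sources, have)
    if (length(lacking))
      stop("source(s) with no loci in pool: ", paste(lacking, collapse = ", "),
           call. = FALSE)
    if (length(sources) > k)
      stop("cannot represent ", length(sources), " sources with k = ", k, call. = FALSE)
    for (i in seq_len(max_attempts)) {
      idx <- sample.int(length(pool), k)
      if (all(sources %in% pool_sources[idx])) return(pool[idx])
    }
    stop("rejection sampling exceeded ", max_attempts, " attempts", call. = FALSE)
  }
  pool[sample.int(length(pool), k)]
}

#' Run the replicate accessibility ensemble
#'
#' For each replicate: draw a SNP set from the specialist's adaptive pool
#' (with source-representation rejection sampling when configured), draw one
#' generalist and one specialist individual uniformly from the sequenced
#' parentals, build the unit-step genotype network over all samples, and emit
#' an accessibility summary row. Degenerate replicates (shared endpoint node,
#' endpoint dropped for missingness) are redrawn up to
#' `max_resample_attempts` times and the attempts counted. Fully reproducible
#' from the master seed: replicate `i` runs on its own derived RNG stream.
#'
#' @param gm a [genotype_matrix()] containing parentals and hybrids.
#' @param fitness a [fitness_records()] table for the hybrids.
#' @param config a [resampling_config()].
#' @return A data frame of class `accessibility_ensemble`: one row per
#'   replicate (columns of [summarize_network()] plus `species`, `sources`
#'   and `attempts`).
#' @export
run_accessibility_ensemble <- function(gm, fitness, config) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(config, "resampling_config"))
  pool <- select_adaptive_loci(gm, config$specialist, config$sources)
  pool_sources <- gm$loci$source[pool]

  gen_ids <- gm$samples$sample_id[gm$samples$role == "parental" &
                                    gm$samples$species == "generalist"]
  spec_ids <- gm$samples$sample_id[gm$samples$role == "parental" &
                                     gm$samples$species == config$specialist]
  if (length(gen_ids) == 0 || length(spec_ids) == 0)
    stop("need sequenced generalist and ", config$specialist, " parentals", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$n_replicates)

  rows <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    set.seed(rep_seeds[r])
    row <- NULL
    for (attempt in seq_len(config$max_resample_attempts)) {
      snps <- sample_snp_set(pool, pool_sources, config$snps_per_network,
                             config$sources,
                             require_each = config$require_each_source)
      g <- sample(gen_ids, 1)
      s <- sample(spec_ids, 1)
      net <- build_network(gm, snps, fitness, measure = config$measure,
                           max_edge_distance = 1L)
      cand <- summarize_network(net, g, s, replicate_id = r, seed = rep_seeds[r])
      if (!cand$degenerate) {
        row <- cand
        row$attempts <- attempt
        break
      }
      row <- cand
      row$attempts <- attempt
    }
    rows[[r]] <- row
  }
  out <- do.call(rbind, rows)
  if (all(out$degenerate))
    stop("every replicate was degenerate; check endpoint individuals", call. = FALSE)
  out$species <- config$specialist
  out$sources <- paste(sort(config$sources), collapse = "+")
  attr(out, "config") <- config
  attr(out, "n_degenerate_final") <- sum(out$degenerate)
  class(out) <- c("accessibility_ensemble", "data.frame")
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Replicate interspecies mutational distances over random SNP panels
#'
#' Randomly samples `k` adaptive loci `n_replicates` times; per replicate,
#' computes the mutational distance between all pairs of parental individuals
#' with complete genotypes over the panel and averages within the six
#' species-pair classes (three within-species, three between-species).
#' Reports per-class mean, median and standard error over replicates
#' (`SE = sd / sqrt(n_replicates)`), and runs pairwise Tukey HSD across
#' classes on the replicate-level class means.
#'
#' @param gm a [genotype_matrix()] with parental samples of all three species.
#' @param pool integer locus indices to draw panels from (e.g. the union of
#'   both specialists' adaptive pools).
#' @param k loci per panel (default 10).
#' @param n_replicates number of panels (default 100).
#' @param seed RNG seed.
#' @return A list of class `interspecies_distances` with `replicates` (long
#'   data frame: replicate, class, mean_steps), `summary` (per-class mean,
#'   median, SE) and `tukey` (pairwise Tukey HSD with BH-adjusted p-values).
#' @export
interspecies_distances <- function(gm, pool, k = 10L, n_replicates = 100L,
                                   seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (k > length(pool))
    stop("cannot draw ", k, " loci from a pool of ", length(pool), call. = FALSE)
  par_idx <- gm$samples$role == "parental" & gm$samples$species != "hybrid"
  species <- gm$samples$species[par_idx]
  for (sp in c("generalist", "molluscivore", "scale_eater"))
    if (!sp %in% species) stop("no parental samples of species ", sp, call. = FALSE)
  calls <- gm$calls[par_idx, , drop = FALSE]

  abbrev <- c(generalist = "G", molluscivore = "M", scale_eater = "S")
  sp_code <- abbrev[species]
  n <- length(sp_code)
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  cls <- vapply(seq_along(pair_i), function(t) {
    a <- sp_code[pair_i[t]]; b <- sp_code[pair_j[t]]
    if (a == b) paste0("within-", a) else paste(sort(c(a, b)), collapse = "-")
  }, character(1))
  class_levels <- c("within-G", "within-M", "within-S", "G-M", "G-S", "M-S")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)

  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    panel <- pool[sample.int(length(pool), k)]
    sub <- calls[, panel, drop = FALSE]
    complete <- rowSums(is.na(sub)) == 0
    d <- as.matrix(stats::dist(sub[complete, , drop = FALSE], method = "manhattan"))
    keep_pair <- complete[pair_i] & complete[pair_j]
    # remap pair indices into the complete-case distance matrix
    remap <- cumsum(complete)
    vals <- d[cbind(remap[pair_i[keep_pair]], remap[pair_j[keep_pair]])]
    cm <- tapply(vals, factor(cls[keep_pair], levels = class_levels), mean)
    reps[[r]] <- data.frame(replicate = r, class = class_levels,
                            mean_steps = as.numeric(cm),
                            stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, reps)

  agg <- function(f) tapply(long$mean_steps, factor(long$class, class_levels), f)
  summary_df <- data.frame(
    class = class_levels,
    mean_steps = as.numeric(agg(mean)),
    median_steps = as.numeric(agg(stats::median)),
    se_steps = as.numeric(agg(stats::sd)) / sqrt(n_replicates),
    stringsAsFactors = FALSE
  )
  tk <- tukey_hsd(long$mean_steps, long$class)
  structure(list(replicates = long, summary = summary_df, tukey = tk,
                 k = k, n_replicates = n_replicates),
            class = "interspecies_distances")
}

#' @export
print.interspecies_distances <- function(x, ...) {
  cat("Interspecies mutational distances:", x$n_replicates, "replicates of",
      x$k, "loci\n")
  df <- x$summary
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-9s %6.2f +/- %.3f steps (median %.2f)\n",
                df$class[i], df$mean_steps[i], df$se_steps[i], df$median_steps[i]))
  invisible(x)
}
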