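#' Configuration for the synthetic hybrid-swarm generator
#'
#' Defaults emulate the study conditions: three divergent parental populations
#' (17 generalists, 27 molluscivores, 25 scale-eaters) with fixed differences
#' (F_ST >= 0.95 by construction) at adaptive loci, 139 outbred hybrids from
#' F2-style crosses, adaptive-locus source labels mixed as in the scale-eater
#' pool (92% standing variation, 6% introgression, 2% de novo), and a
#' configurable genotype-to-fitness map driving survival (~60% of hybrids
#' survive at the default calibration) and growth.
#'
#' @param m_loci number of adaptive loci.
#' @param n_generalist,n_specialist1,n_specialist2 parental sample sizes
#'   (specialist1 = molluscivore, specialist2 = scale-eater).
#' @param n_hybrids number of hybrid individuals.
#' @param cross_design `"F2"`, `"backcross"` or `"F4F5"`.
#' @param source_proportions named fractions over
#'   `c(SGV, introgression, de_novo)` summing to 1.
#' @param prop_molluscivore fraction of loci swept in the molluscivore (the
#'   rest sweep in the scale-eater; de novo labels are restricted to
#'   scale-eater loci).
#' @param fitness_model `"additive"`, `"NK"` or `"two_peak"`.
#' @param K number of epistatic partner loci per locus (NK model).
#' @param effect_sizes optional per-locus additive effects (default `1/(2m)`
#'   each, so the additive score spans `[0, 1]`).
#' @param backcross_to species receiving the backcross (`"random"` draws a
#'   parental species per hybrid; the classic design is `"generalist"`).
#' @param f1_specialist specialist parent of the F1 founders: `"both"`
#'   (default, families from each specialist cross as in the pooled field
#'   cohorts) or a single species for single-family designs.
#' @param survival_rate target mean survival at median latent fitness.
#' @param survival_slope logistic slope of survival on standardised latent
#'   fitness.
#' @param growth_intercept,growth_slope linear map from (0-1 scaled) latent
#'   fitness to proportional growth.
#' @param growth_noise_sd Gaussian noise sd on growth.
#' @param sgv_generalist_freq frequency at which standing-variation alleles
#'   segregate in the generalist population (standing variation is, by
#'   definition, present in the ancestral generalist gene pool; the study's
#'   observed within-generalist and generalist-specialist mutational
#'   distances imply appreciable segregation).
#' @param generalist_alt_freq frequency of the specialist allele in the
#'   generalist population at introgressed and de novo loci (0 = absent, the
#'   behavioural meaning of those labels).
#' @param seed master seed; all stages derive their streams from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(m_loci = 10L,
                             n_generalist = 17L, n_specialist1 = 27L,
                             n_specialist2 = 25L, n_hybrids = 139L,
                             cross_design = c("mixed", "F2", "backcross", "F4F5"),
                             backcross_to = "random",
                             f1_specialist = c("both", "molluscivore", "scale_eater"),
                             source_proportions = c(SGV = 0.92,
                                                    introgression = 0.06,
                                                    de_novo = 0.02),
                             prop_molluscivore = 0,
                             fitness_model = c("additive", "NK", "two_peak"),
                             K = 2L, effect_sizes = NULL,
                             survival_rate = 0.6, survival_slope = 1,
                             growth_intercept = 0.02, growth_slope = 0.3,
                             growth_noise_sd = 0.05,
                             sgv_generalist_freq = 0.15,
                             generalist_alt_freq = 0, seed = 1L) {
  cross_design <- match.arg(cross_design)
  fitness_model <- match.arg(fitness_model)
  if (abs(sum(source_proportions) - 1) > 1e-9)
    stop("source_proportions must sum to 1", call. = FALSE)
  if (!all(names(source_proportions) %in% c("SGV", "introgression", "de_novo")))
    stop("source_proportions names must be SGV/introgression/de_novo", call. = FALSE)
  if (fitness_model == "NK" && K >= m_loci)
    stop("K must be < m_loci", call. = FALSE)
  if (min(n_generalist, n_specialist1, n_specialist2, n_hybrids) < 1)
    stop("all sample counts must be >= 1", call. = FALSE)
  if (growth_noise_sd < 0) stop("growth_noise_sd must be >= 0", call. = FALSE)
  backcross_to <- match.arg(backcross_to,
                            c("random", "generalist", "molluscivore", "scale_eater"))
  f1_specialist <- match.arg(f1_specialist)
  structure(list(
    m_loci = as.integer(m_loci), n_generalist = as.integer(n_generalist),
    n_specialist1 = as.integer(n_specialist1),
    n_specialist2 = as.integer(n_specialist2),
    n_hybrids = as.integer(n_hybrids), cross_design = cross_design,
    backcross_to = backcross_to, f1_specialist = f1_specialist,
    source_proportions = source_proportions,
    prop_molluscivore = prop_molluscivore,
    fitness_model = fitness_model, K = as.integer(K),
    effect_sizes = effect_sizes,
    survival_rate = survival_rate, survival_slope = survival_slope,
    growth_intercept = growth_intercept, growth_slope = growth_slope,
    growth_noise_sd = growth_noise_sd,
    sgv_generalist_freq = sgv_generalist_freq,
    generalist_alt_freq = generalist_alt_freq, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Simulate the three parental populations
#'
#' The specialist in which a locus swept is fixed for the alternate allele
#' (dosage 2) and the other specialist is fixed reference, so the
#' specialist-differentiating Hudson F_ST -- the statistic behind the
#' sweep-based locus filter -- is 1 (>= 0.95) by construction; the realised
#' value is stored in the `fst` annotation column. The generalist segregates
#' standing-variation alleles at `sgv_generalist_freq` (standing variation is
#' ancestrally present by definition) and carries introgressed/de novo
#' alleles at `generalist_alt_freq` (0 by default: those alleles entered the
#' specialist lineage only). Loci are labelled with sources of adaptive
#' variation drawn from `source_proportions` (de novo restricted to
#' scale-eater loci).
#'
#' @param config a [synthetic_config()].
#' @return A [genotype_matrix()] of parental individuals.
#' @export
simulate_parentals <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  m <- config$m_loci

  n_moll_loci <- round(config$prop_molluscivore * m)
  swept_in <- c(rep("molluscivore", n_moll_loci),
                rep("scale_eater", m - n_moll_loci))
  source <- character(m)
  for (i in seq_len(m)) {
    pr <- config$source_proportions
    if (swept_in[i] == "molluscivore") {
      pr <- pr[names(pr) != "de_novo"]
      pr <- pr / sum(pr)
    }
    source[i] <- sample(names(pr), 1, prob = pr)
  }

  ng <- config$n_generalist; nm <- config$n_specialist1; ns <- config$n_specialist2
  gen_freq_cfg <- ifelse(source == "SGV", config$sgv_generalist_freq,
                         config$generalist_alt_freq)
  gen <- vapply(seq_len(m), function(j) stats::rbinom(ng, 2, gen_freq_cfg[j]),
                integer(ng))
  gen <- matrix(gen, nrow = ng)
  moll <- matrix(0L, nm, m)
  scal <- matrix(0L, ns, m)
  moll[, swept_in == "molluscivore"] <- 2L
  scal[, swept_in == "scale_eater"] <- 2L
  calls <- rbind(gen, moll, scal)

  # specialist-pair differentiation (the sweep-filter contrast)
  moll_freq <- colMeans(moll) / 2
  scal_freq <- colMeans(scal) / 2
  fst <- hudson_fst(pmax(moll_freq, scal_freq), pmin(moll_freq, scal_freq), nm, ns)

  samples <- data.frame(
    sample_id = c(sprintf("G%03d", seq_len(ng)), sprintf("M%03d", seq_len(nm)),
                  sprintf("S%03d", seq_len(ns))),
    species = c(rep("generalist", ng), rep("molluscivore", nm),
                rep("scale_eater", ns)),
    lake = "crescent_pond",
    experiment = "none",
    role = "parental",
    stringsAsFactors = FALSE
  )
  loci <- data.frame(
    scaffold = sprintf("scaffold%d", ((seq_len(m) - 1) %/% 4) + 1),
    position = 1000L * (((seq_len(m) - 1) %% 4) + 1L) + ((seq_len(m) - 1) %/% 4),
    ref = "A", alt = "T",
    swept_in = swept_in, source = source, fst = fst,
    stringsAsFactors = FALSE
  )
  genotype_matrix(calls, samples = samples, loci = loci)
}

#' Hudson's F_ST estimator from allele frequencies
#'
#' `((p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)) / (p1(1-p2) + p2(1-p1))`,
#' with sample sizes in individuals converted to allele counts internally.
#' Fixed differences give 1.
#'
#' @param p1,p2 alternate-allele frequencies in the two populations.
#' @param n1,n2 numbers of diploid individuals sampled.
#' @return Numeric F_ST values (NaN when both populations are fixed for the
#'   same allele).
#' @export
hudson_fst <- function(p1, p2, n1, n2) {
  a1 <- 2 * n1; a2 <- 2 * n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (a1 - 1) - p2 * (1 - p2) / (a2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num / den
}

gamete <- function(g) {
  het <- g == 1L
  allele <- as.integer(g / 2L)
  if (any(het)) allele[het] <- stats::rbinom(sum(het), 1, 0.5)
  allele
}

cross_pair <- function(a, b) gamete(a) + gamete(b)

#' Simulate outbred hybrid genotypes by Mendelian crosses
#'
#' F1 individuals are produced by crossing random generalist and specialist
#' parents (heterozygous at every fixed-difference locus); later generations
#' follow random mating with independent Mendelian segregation per locus
#' (unlinked). `"F2"` crosses two random F1s per hybrid; `"backcross"`
#' crosses an F1 to a parental individual of the `backcross_to` species (a
#' random species per hybrid by default); `"F4F5"` seeds a pool with F1s from
#' all three pairwise species crosses and random-mates it for three to four
#' generations, sampling hybrids from the F4 and F5 pools; `"mixed"` -- the
#' default, emulating the pooled field cohorts -- combines an F2/backcross
#' cohort (first experiment) with an F4/F5 cohort (second experiment) in
#' roughly equal halves.
#'
#' @param parentals a [simulate_parentals()] result.
#' @param config a [synthetic_config()].
#' @return A [genotype_matrix()] of hybrid individuals.
#' @export
simulate_hybrids <- function(parentals, config) {
  stopifnot(inherits(parentals, "genotype_matrix"),
            inherits(config, "synthetic_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)

  sp <- parentals$samples$species
  pops <- list(
    generalist = parentals$calls[sp == "generalist", , drop = FALSE],
    molluscivore = parentals$calls[sp == "molluscivore", , drop = FALSE],
    scale_eater = parentals$calls[sp == "scale_eater", , drop = FALSE]
  )
  pick <- function(mat) mat[sample.int(nrow(mat), 1), ]

  n <- config$n_hybrids
  m <- config$m_loci
  spec_choices <- if (config$f1_specialist == "both")
    c("molluscivore", "scale_eater") else config$f1_specialist
  make_f1 <- function() {
    spec <- pops[[if (length(spec_choices) > 1) sample(spec_choices, 1) else spec_choices]]
    cross_pair(pick(pops$generalist), pick(spec))
  }

  sim_f2_bc <- function(n_out, design) {
    n_f1 <- max(40L, n_out)
    f1 <- t(vapply(seq_len(n_f1), function(i) make_f1(), integer(m)))
    t(vapply(seq_len(n_out), function(i) {
      if (design == "F2") {
        cross_pair(pick(f1), pick(f1))
      } else {
        bc <- config$backcross_to
        if (bc == "random") bc <- sample(names(pops), 1)
        cross_pair(pick(f1), pick(pops[[bc]]))
      }
    }, integer(m)))
  }

  sim_f4f5 <- function(n_out) {
    pool_size <- max(60L, 2L * n_out)
    combos <- list(c("generalist", "molluscivore"), c("generalist", "scale_eater"),
                   c("molluscivore", "scale_eater"))
    pool <- t(vapply(seq_len(pool_size), function(i) {
      cc <- combos[[sample.int(3, 1)]]
      cross_pair(pick(pops[[cc[1]]]), pick(pops[[cc[2]]]))
    }, integer(m)))
    for (g_i in 2:4) {                    # pool is F1; after 3 rounds -> F4
      pool <- t(vapply(seq_len(pool_size), function(i)
        cross_pair(pick(pool), pick(pool)), integer(m)))
    }
    f4 <- pool
    f5 <- t(vapply(seq_len(pool_size), function(i)
      cross_pair(pick(f4), pick(f4)), integer(m)))
    n4 <- n_out %/% 2L
    rbind(f4[sample.int(pool_size, n4), , drop = FALSE],
          f5[sample.int(pool_size, n_out - n4), , drop = FALSE])
  }

  if (config$cross_design %in% c("F2", "backcross")) {
    calls <- sim_f2_bc(n, config$cross_design)
    experiment <- rep("exp2011", n)
  } else if (config$cross_design == "F4F5") {
    calls <- sim_f4f5(n)
    experiment <- rep("exp2014", n)
  } else {                                # mixed: both field cohorts
    n1 <- n %/% 2L
    n_f2 <- n1 %/% 2L
    calls <- rbind(sim_f2_bc(n_f2, "F2"),
                   sim_f2_bc(n1 - n_f2, "backcross"),
                   sim_f4f5(n - n1))
    experiment <- c(rep("exp2011", n1), rep("exp2014", n - n1))
  }

  samples <- data.frame(
    sample_id = sprintf("H%03d", seq_len(n)),
    species = "hybrid", lake = "crescent_pond",
    experiment = experiment, role = "hybrid",
    stringsAsFactors = FALSE
  )
  genotype_matrix(calls, samples = samples, loci = parentals$loci)
}

#' Build the latent genotype-to-fitness map
#'
#' Returns a deterministic function from 012 genotype rows to latent fitness:
#' `additive` is a weighted dosage sum; `NK` averages per-locus contribution
#' tables indexed by the locus's own state and the states of `K` random
#' partner loci (contributions ~ U(0,1), fixed by the seed), producing
#' tunable ruggedness; `two_peak` is a mixture of two Gaussian bumps over the
#' scaled additive score.
#'
#' @param config a [synthetic_config()].
#' @return List of class `fitness_landscape` with elements `fun` (matrix of
#'   genotype rows -> numeric fitness), `model` and `params`.
#' @export
make_fitness_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 2L)
  m <- config$m_loci
  beta <- config$effect_sizes
  if (is.null(beta)) beta <- rep(1 / (2 * m), m)
  if (length(beta) != m) stop("effect_sizes must have length m_loci", call. = FALSE)

  if (config$fitness_model == "additive") {
    fun <- function(G) as.numeric(as.matrix(G) %*% beta)
    params <- list(beta = beta)
  } else if (config$fitness_model == "NK") {
    K <- config$K
    partners <- lapply(seq_len(m), function(i)
      if (K > 0) sample(setdiff(seq_len(m), i), K) else integer(0))
    tables <- lapply(seq_len(m), function(i) stats::runif(3^(K + 1)))
    fun <- function(G) {
      G <- as.matrix(G)
      w <- numeric(nrow(G))
      for (i in seq_len(m)) {
        idx <- G[, i]
        if (K > 0)
          idx <- idx + as.numeric(G[, partners[[i]], drop = FALSE] %*% (3^seq_len(K)))
        w <- w + tables[[i]][idx + 1]
      }
      w / m
    }
    params <- list(K = K, partners = partners, tables = tables)
  } else {                                 # two_peak
    denom <- sum(2 * beta)
    p <- list(c1 = 0.2, c2 = 0.95, h1 = 0.6, h2 = 1, width = 0.12)
    fun <- function(G) {
      t <- as.numeric(as.matrix(G) %*% beta) / denom
      p$h1 * exp(-(t - p$c1)^2 / (2 * p$width^2)) +
        p$h2 * exp(-(t - p$c2)^2 / (2 * p$width^2))
    }
    params <- p
  }
  structure(list(fun = fun, model = config$fitness_model, params = params),
            class = "fitness_landscape")
}

#' Assign survival, growth and composite fitness to hybrids
#'
#' Latent fitness `w(g)` comes from the configured landscape. Survival is
#' Bernoulli with logit `qlogis(survival_rate) + survival_slope * z(w)`
#' (z = standardised latent fitness), so the survival rate is
#' `survival_rate` at the median landscape value. Survivor growth is a linear
#' map of the 0-1 scaled latent fitness plus Gaussian noise; non-survivors
#' have no final length and composite fitness 0.
#'
#' @param hybrids a hybrid [genotype_matrix()].
#' @param config a [synthetic_config()].
#' @param landscape optional pre-built [make_fitness_landscape()] (rebuilt
#'   from the config when omitted).
#' @return A [fitness_records()] table with the latent fitness in column `w`.
#' @export
assign_fitness <- function(hybrids, config, landscape = NULL) {
  stopifnot(inherits(hybrids, "genotype_matrix"),
            inherits(config, "synthetic_config"))
  if (is.null(landscape)) landscape <- make_fitness_landscape(config)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 3L)

  w <- landscape$fun(hybrids$calls)
  n <- length(w)
  z <- if (stats::sd(w) > 0) (w - mean(w)) / stats::sd(w) else rep(0, n)
  u <- if (diff(range(w)) > 0) (w - min(w)) / diff(range(w)) else rep(0.5, n)

  p_surv <- stats::plogis(stats::qlogis(config$survival_rate) +
                            config$survival_slope * z)
  survived <- stats::rbinom(n, 1, p_surv)
  initial_sl <- pmax(stats::rnorm(n, 35, 2), 10)
  growth <- config$growth_intercept + config$growth_slope * u +
    stats::rnorm(n, 0, config$growth_noise_sd)
  final_sl <- ifelse(survived == 1, initial_sl * (1 + growth), NA_real_)

  rec <- fitness_records(data.frame(
    sample_id = hybrids$samples$sample_id,
    survived = survived,
    initial_sl = initial_sl,
    final_sl = final_sl,
    stringsAsFactors = FALSE
  ))
  rec$w <- w
  rec
}

#' Exhaustive ground truth for the full genotype space
#'
#' Enumerates all `3^m` diploid genotypes (refused for `m > 8`), evaluates the
#' latent landscape on every one, and computes the true peak set (genotypes
#' with no fitter unit-step neighbour) and the exact number of strictly
#' monotone unit-step paths from the all-reference to the all-alternate
#' genotype, with the length in nodes of the shortest such path.
#'
#' @param config a [synthetic_config()] with `m_loci <= 8`.
#' @param landscape optional pre-built landscape.
#' @return List of class `ground_truth`: `genotypes`, `fitness`, `peaks`
#'   (row indices), `n_peaks`, `path_count`, `shortest_len`.
#' @export
ground_truth <- function(config, landscape = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  m <- config$m_loci
  if (m > 8) stop("full-space enumeration refused for m_loci > 8", call. = FALSE)
  if (is.null(landscape)) landscape <- make_fitness_landscape(config)

  G <- as.matrix(expand.grid(rep(list(0:2), m)))[, m:1, drop = FALSE]
  colnames(G) <- NULL
  storage.mode(G) <- "integer"
  w <- landscape$fun(G)
  n <- nrow(G)
  pow <- 3^(rev(seq_len(m)) - 1)            # G row r has index sum(g * pow) + 1
  idx_of <- function(g) sum(g * pow) + 1

  neighbors <- function(r) {
    g <- G[r, ]
    out <- integer(0)
    for (i in seq_len(m)) {
      if (g[i] > 0) out <- c(out, r - pow[i])
      if (g[i] < 2) out <- c(out, r + pow[i])
    }
    out
  }

  peaks <- which(vapply(seq_len(n), function(r) {
    all(w[neighbors(r)] <= w[r])
  }, logical(1)))

  src <- idx_of(rep(0L, m))
  tgt <- idx_of(rep(2L, m))
  ord <- order(w)
  counts <- numeric(n)
  lens <- rep(Inf, n)
  counts[src] <- 1
  lens[src] <- 1
  for (r in ord) {
    if (counts[r] == 0) next
    for (v in neighbors(r)) {
      if (w[v] > w[r]) {
        counts[v] <- counts[v] + counts[r]
        lens[v] <- min(lens[v], lens[r] + 1)
      }
    }
  }
  if (max(counts) >= 2^52)
    warning("path counts approach double precision limit", call. = FALSE)

  structure(list(
    genotypes = G, fitness = w, peaks = peaks, n_peaks = length(peaks),
    path_count = counts[tgt],
    shortest_len = if (counts[tgt] > 0) lens[tgt] else NA_real_,
    landscape = landscape
  ), class = "ground_truth")
}

#' Simulate a complete synthetic study
#'
#' Runs the full generator: parentals, hybrids, latent landscape and fitness
#' records, optionally writing the pipeline's exact input contract to disk
#' (`study.vcf`, `samples.csv`, `loci.csv`, `fitness.csv`). Byte-identical
#' output for identical configurations.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory (created if needed).
#' @return List of class `synthetic_study`: `parentals`, `hybrids`, `gm`
#'   (combined), `fitness`, `landscape`, `config`.
#' @export
simulate_study <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  parentals <- simulate_parentals(config)
  hybrids <- simulate_hybrids(parentals, config)
  landscape <- make_fitness_landscape(config)
  fitness <- assign_fitness(hybrids, config, landscape)
  gm <- bind_genotypes(parentals, hybrids)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(gm, file.path(dir, "study.vcf"))
    utils::write.csv(gm$samples, file.path(dir, "samples.csv"), row.names = FALSE)
    utils::write.csv(gm$loci, file.path(dir, "loci.csv"), row.names = FALSE)
    utils::write.csv(
      fitness[c("sample_id", "survived", "initial_sl", "final_sl")],
      file.path(dir, "fitness.csv"), row.names = FALSE)
  }
  structure(list(parentals = parentals, hybrids = hybrids, gm = gm,
                 fitness = fitness, landscape = landscape, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", x$config$m_loci, "loci;",
      nrow(x$parentals$calls), "parentals +", nrow(x$hybrids$calls), "hybrids;",
      "fitness model:", x$config$fitness_model, "\n")
  cat(sprintf("  survival: %.1f%%; cross design: %s; seed: %d\n",
              100 * mean(x$fitness$survived), x$config$cross_design,
              x$config$seed))
  invisible(x)
}
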