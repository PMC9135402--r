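test_that("parental populations realise the specialist fixed differences", {
  cfg <- synthetic_config(m_loci = 12, seed = 5, sgv_generalist_freq = 0,
                          source_proportions = c(SGV = 0.8, introgression = 0.2),
                          prop_molluscivore = 0.5)
  p <- simulate_parentals(cfg)
  expect_true(all(p$loci$fst >= 0.95))        # specialist-pair differentiation
  sp <- p$samples$species
  scal <- p$calls[sp == "scale_eater", p$loci$swept_in == "scale_eater"]
  expect_true(all(scal == 2))
  gen <- p$calls[sp == "generalist", ]
  expect_true(all(gen == 0))                  # no segregation configured
  # focal-vs-generalist F_ST is 1 at fixed loci by the direct Hudson formula
  expect_equal(hudson_fst(1, 0, 25, 17), 1)
})

test_that("low-frequency generalist segregation keeps Hudson F_ST at sweep level", {
  # direct allele-frequency computation, independent of the generator
  expect_gte(hudson_fst(1, 0.02, 25, 17), 0.95)
  expect_gte(hudson_fst(1, 0.04, 25, 17), 0.95)
  # hand check of the estimator against its algebraic definition
  p1 <- 0.9; p2 <- 0.1; n1 <- 20; n2 <- 10
  direct <- ((p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) -
               p2 * (1 - p2) / (2 * n2 - 1)) / (p1 * (1 - p2) + p2 * (1 - p1))
  expect_equal(hudson_fst(p1, p2, n1, n2), direct)
})

test_that("source labels follow the configured proportions", {
  cfg <- synthetic_config(m_loci = 400, seed = 2,
                          source_proportions = c(SGV = 0.6, introgression = 0.3,
                                                 de_novo = 0.1))
  p <- simulate_parentals(cfg)
  counts <- table(factor(p$loci$source, c("SGV", "introgression", "de_novo")))
  expect_gt(chisq.test(counts, p = c(0.6, 0.3, 0.1))$p.value, 0.001)
})

test_that("crosses follow Mendelian expectations", {
  cfg <- synthetic_config(m_loci = 4, n_hybrids = 4000, cross_design = "F2",
                          f1_specialist = "scale_eater",
                          sgv_generalist_freq = 0, seed = 8,
                          source_proportions = c(SGV = 1))
  p <- simulate_parentals(cfg)
  h <- simulate_hybrids(p, cfg)
  # F2 genotype frequencies at a fixed-difference locus are 1:2:1
  counts <- table(factor(h$calls[, 1], levels = 0:2))
  expect_gt(chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value, 0.001)

  # backcross to the generalist cannot produce homozygous alternate calls
  cfg_bc <- synthetic_config(m_loci = 4, n_hybrids = 300, cross_design = "backcross",
                             backcross_to = "generalist", sgv_generalist_freq = 0,
                             seed = 8, source_proportions = c(SGV = 1))
  hb <- simulate_hybrids(p, cfg_bc)
  expect_true(all(hb$calls %in% 0:1))
})

test_that("allele frequencies are a martingale across random-mating generations", {
  cfg <- synthetic_config(m_loci = 5, n_hybrids = 4000, cross_design = "F4F5",
                          sgv_generalist_freq = 0, seed = 9,
                          source_proportions = c(SGV = 1))
  p <- simulate_parentals(cfg)
  h <- simulate_hybrids(p, cfg)
  # F1 pool mixes gen x moll (freq 0), gen x scale (0.5), moll x scale (0.5)
  # in equal proportion -> expected frequency 1/3 at scale-eater loci
  freq <- colMeans(h$calls) / 2
  expect_true(all(abs(freq - 1 / 3) < 0.05))
})

test_that("fitness landscape models behave as designed at their limits", {
  # additive, positive effects: single full-space peak and a monotone score
  cfg <- synthetic_config(m_loci = 4, fitness_model = "additive", seed = 3)
  gt <- ground_truth(cfg)
  expect_equal(gt$n_peaks, 1)
  expect_equal(gt$shortest_len, 2 * 4 + 1)
  # every monotone lattice route is accessible: (2m)! / 2^m
  expect_equal(gt$path_count, factorial(8) / 2^4)

  # K = 0: loci contribute independently, so the full-space peak count is the
  # product over loci of the number of coordinate-wise local maxima of each
  # per-locus contribution table (closed-form oracle)
  cfg0 <- synthetic_config(m_loci = 4, fitness_model = "NK", K = 0, seed = 3)
  land0 <- make_fitness_landscape(cfg0)
  gt0 <- ground_truth(cfg0, land0)
  loc_maxima <- vapply(land0$params$tables, function(u) {
    sum(c(u[1] > u[2],
          u[2] > u[1] && u[2] > u[3],
          u[3] > u[2]))
  }, numeric(1))
  expect_equal(gt0$n_peaks, prod(loc_maxima))

  # higher K is more rugged on average across seeds
  peaks_for <- function(K, seeds) {
    vapply(seeds, function(s) {
      ground_truth(synthetic_config(m_loci = 6, fitness_model = "NK",
                                    K = K, seed = s))$n_peaks
    }, numeric(1))
  }
  seeds <- 1:20
  expect_gt(mean(peaks_for(3, seeds)), mean(peaks_for(1, seeds)))
})

test_that("full-space enumeration sizes and guards are correct", {
  cfg1 <- synthetic_config(m_loci = 1, fitness_model = "additive", seed = 1)
  gt1 <- ground_truth(cfg1)
  expect_equal(nrow(gt1$genotypes), 3)
  expect_equal(gt1$n_peaks, 1)
  expect_equal(gt1$path_count, 1)
  expect_equal(gt1$shortest_len, 3)

  cfg5 <- synthetic_config(m_loci = 5, seed = 1)
  expect_equal(nrow(ground_truth(cfg5)$genotypes), 243)   # 3^5 potential haplotypes

  cfg9 <- synthetic_config(m_loci = 9, seed = 1)
  expect_error(ground_truth(cfg9), "m_loci > 8")
})

test_that("ground-truth path counts agree with exhaustive DFS on the full space", {
  set.seed(44)
  for (s in 1:5) {
    cfg <- synthetic_config(m_loci = 3, fitness_model = "NK", K = 2, seed = s)
    gt <- ground_truth(cfg)
    want <- oracle_paths(gt$genotypes, gt$fitness, 1, nrow(gt$genotypes))
    expect_equal(gt$path_count, want$count)
    expect_equal(gt$shortest_len, want$shortest_len)
    # peaks match the exhaustive neighbour check
    expect_setequal(gt$peaks, oracle_peaks(gt$genotypes, gt$fitness))
  }
})

test_that("survival and composite fitness follow the configured generating model", {
  cfg <- synthetic_config(m_loci = 8, seed = 21)
  st <- simulate_study(cfg)
  f <- st$fitness
  expect_true(all(f$composite[f$survived == 0] == 0))
  expect_true(all(is.na(f$final_sl[f$survived == 0])))
  expect_equal(f$composite[f$survived == 1], f$growth[f$survived == 1])
  # calibrated survival close to the 60% default
  expect_gt(mean(f$survived), 0.4)
  expect_lt(mean(f$survived), 0.8)
})

test_that("the generator is deterministic end to end", {
  cfg <- synthetic_config(m_loci = 6, seed = 33)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  simulate_study(cfg, dir = d1)
  simulate_study(cfg, dir = d2)
  for (f in c("study.vcf", "samples.csv", "loci.csv", "fitness.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # and the emitted files satisfy the pipeline's input contract
  gm <- read_vcf(file.path(d1, "study.vcf"),
                 samples = read_sample_metadata(file.path(d1, "samples.csv")),
                 loci = read_locus_annotations(file.path(d1, "loci.csv")))
  st <- simulate_study(cfg)
  expect_identical(unname(gm$calls), unname(st$gm$calls))
  expect_equal(gm$loci$source, st$gm$loci$source)
  fit <- read_fitness_table(file.path(d1, "fitness.csv"))
  expect_equal(fit$composite, st$fitness$composite)
})
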