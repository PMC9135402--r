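# worked network used throughout: 6 observed 2-locus haplotypes
worked_net <- function(f5 = 0.35) {
  calls <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(2, 1), c(2, 2))
  gm <- toy_gm(calls)
  fit <- toy_fitness(gm$samples$sample_id, c(0.1, 0.2, 0.05, 0.3, f5, 0.4))
  build_network(gm, 1:2, fit)
}

test_that("peaks are fitness-defined nodes with no fitter unit-step neighbour", {
  gm <- toy_gm(rbind(0L, 1L, 2L))
  net <- build_network(gm, 1, toy_fitness(gm$samples$sample_id, c(0.1, 0.3, 0.2)))
  pk <- find_peaks(net)
  expect_length(pk, 1)
  expect_equal(net$haplotypes[pk, ], 1L)

  # full 2-locus additive landscape: the double homozygote is the only peak
  calls <- as.matrix(expand.grid(0:2, 0:2))
  gm2 <- toy_gm(calls)
  net2 <- build_network(gm2, 1:2, toy_fitness(gm2$samples$sample_id, 0.1 * rowSums(calls)))
  pk2 <- find_peaks(net2)
  expect_length(pk2, 1)
  expect_equal(unname(net2$haplotypes[pk2, ]), c(2L, 2L))
})

test_that("expected peak count on the 1-locus chain is 4/3 over all fitness orderings", {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  gm <- toy_gm(rbind(0L, 1L, 2L))
  counts <- apply(perms, 1, function(f) {
    net <- build_network(gm, 1, toy_fitness(gm$samples$sample_id, f / 10))
    length(find_peaks(net))
  })
  expect_equal(mean(counts), 4 / 3)
})

test_that("the worked 6-node network has one accessible path of 5 nodes", {
  net <- worked_net()
  src <- node_of(net, "i001")
  tgt <- node_of(net, "i006")
  res <- count_accessible_paths(net, src, tgt)
  expect_equal(res$count, 1)
  expect_equal(res$shortest_len, 5)
  # perturbation introduces a fitness decrease on the only route
  net2 <- worked_net(f5 = 0.25)
  res2 <- count_accessible_paths(net2, node_of(net2, "i001"), node_of(net2, "i006"))
  expect_equal(res2$count, 0)
  expect_true(is.na(res2$shortest_len))
})

test_that("a strictly fitter adjacent target gives a 2-node path; equal endpoints degenerate", {
  gm <- toy_gm(rbind(c(0, 0), c(1, 0)))
  net <- build_network(gm, 1:2, toy_fitness(gm$samples$sample_id, c(0.1, 0.2)))
  res <- count_accessible_paths(net, 1, 2)
  expect_gte(res$count, 1)
  expect_equal(res$shortest_len, 2)
  expect_true(count_accessible_paths(net, 1, 1)$degenerate)
})

test_that("undefined-fitness endpoints impose no constraint at their own step", {
  # parental source (undefined) adjacent to a low-fitness hybrid chain
  gm <- toy_gm(rbind(c(0, 0), c(1, 0), c(2, 0)),
               roles = c("parental", "hybrid", "hybrid"))
  fit <- toy_fitness(c("i002", "i003"), c(0.5, 0.9))
  net <- build_network(gm, 1:2, fit)
  res <- count_accessible_paths(net, node_of(net, "i001"), node_of(net, "i003"))
  expect_equal(res$count, 1)
  # undefined interior nodes are excluded from paths entirely
  gm2 <- toy_gm(rbind(c(0, 0), c(1, 0), c(2, 0)),
                roles = c("hybrid", "parental", "hybrid"))
  fit2 <- toy_fitness(c("i001", "i003"), c(0.1, 0.9))
  net2 <- build_network(gm2, 1:2, fit2)
  res2 <- count_accessible_paths(net2, node_of(net2, "i001"), node_of(net2, "i003"))
  expect_equal(res2$count, 0)
})

test_that("DP path counts equal exhaustive DFS enumeration on random networks", {
  set.seed(71)
  for (i in 1:200) {
    cs <- random_net_case(m = sample(2:4, 1), n_max = 25)
    got <- count_accessible_paths(cs$net, cs$source, cs$target)
    want <- oracle_paths(cs$net$haplotypes, cs$net$fitness, cs$source, cs$target)
    expect_equal(got$count, want$count)
    expect_equal(got$shortest_len, want$shortest_len)
    # peak sets agree with the exhaustive neighbour check
    if (any(!is.na(cs$net$fitness)))
      expect_setequal(find_peaks(cs$net),
                      oracle_peaks(cs$net$haplotypes, cs$net$fitness))
  }
})

test_that("peak set is invariant under strictly monotone fitness transforms", {
  set.seed(5)
  for (i in 1:20) {
    cs <- random_net_case(m = 3, n_max = 20, p_parental = 0)
    f <- cs$net$fitness
    pk <- find_peaks(cs$net)
    net2 <- cs$net
    net2$fitness <- exp(3 * f) - 1
    expect_setequal(find_peaks(net2), pk)
    # the global maximum is always a peak
    expect_true(which.max(f) %in% pk)
  }
})

test_that("removing a node never increases the accessible path count", {
  set.seed(13)
  for (i in 1:30) {
    m <- 3
    cs <- random_net_case(m = m, n_max = 20, p_parental = 0)
    net <- cs$net
    base <- count_accessible_paths(net, cs$source, cs$target)$count
    drop <- setdiff(seq_len(nrow(net$haplotypes)), c(cs$source, cs$target))
    if (length(drop) == 0) next
    v <- sample(drop, 1)
    keep <- setdiff(seq_len(nrow(net$haplotypes)), v)
    sub <- oracle_paths(net$haplotypes[keep, , drop = FALSE], net$fitness[keep],
                        match(cs$source, keep), match(cs$target, keep))
    expect_lte(sub$count, base)
  }
})

test_that("paths to peaks and distances to peaks follow the accessible-walk rules", {
  # additive full 2-locus space: all monotone lattice routes reach the peak
  calls <- as.matrix(expand.grid(0:2, 0:2))
  gm <- toy_gm(calls)
  net <- build_network(gm, 1:2, toy_fitness(gm$samples$sample_id, 0.1 * rowSums(calls)))
  start <- net$sample_node[[which(rowSums(calls) == 0)]]
  res <- paths_to_peaks(net, start)
  expect_equal(res$n_paths, 6)             # 4!/(2!2!) monotone routes
  expect_equal(res$min_dist_to_peak, 4)
  expect_equal(res$n_paths_scaled, 6 / 9)
  # a start that is itself a peak has distance zero
  peak <- find_peaks(net)
  expect_equal(paths_to_peaks(net, peak)$min_dist_to_peak, 0)
})

test_that("network summaries populate all accessibility statistics", {
  net <- worked_net()
  s <- summarize_network(net, "i001", "i006", replicate_id = 1L)
  expect_false(s$degenerate)
  expect_equal(s$n_nodes, 6)
  expect_equal(s$n_accessible_paths, 1)
  expect_equal(s$scaled_paths, 1 / 6)
  expect_equal(s$shortest_accessible_len, 5)
  expect_gte(s$n_peaks, 1)

  # all-equal fitness: no strict increases, every defined node is a peak
  gm <- toy_gm(rbind(c(0, 0), c(1, 0), c(2, 0)))
  netc <- build_network(gm, 1:2, toy_fitness(gm$samples$sample_id, rep(0.2, 3)))
  sc <- summarize_network(netc, "i001", "i003")
  expect_equal(sc$n_accessible_paths, 0)
  expect_equal(sc$n_peaks, 3)

  # shared endpoint node flags a degenerate replicate
  gm2 <- toy_gm(rbind(c(0, 0), c(0, 0)))
  net2 <- build_network(gm2, 1:2, toy_fitness(gm2$samples$sample_id, c(0.1, 0.2)))
  s2 <- summarize_network(net2, "i001", "i002")
  expect_true(s2$degenerate)
  expect_equal(s2$reason, "shared_endpoint")
})

test_that("big-integer accumulation matches double arithmetic below the exact limit", {
  set.seed(2)
  for (i in 1:50) {
    a <- as.numeric(sample.int(1e9, 1)) * sample.int(1e6, 1)
    b <- as.numeric(sample.int(1e9, 1)) * sample.int(1e6, 1)
    s <- fitnet:::big_add(fitnet:::big_from_num(a), fitnet:::big_from_num(b))
    expect_equal(fitnet:::big_to_num(s), a + b)
    expect_equal(fitnet:::big_to_string(s), sprintf("%.0f", a + b))
  }
  # beyond 2^53: string arithmetic stays exact
  x <- fitnet:::big_from_num(2^52)
  s <- x
  for (i in 1:15) s <- fitnet:::big_add(s, s)
  expect_equal(fitnet:::big_to_string(s), sprintf("%.0f", 2^52 * 2^15))
})
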