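test_that("shared-neighbour probability has the right edge cases and errors", {
  expect_equal(shared_neighbor_pvalue(0, 0, 0, 10), 1.0)
  expect_equal(shared_neighbor_pvalue(0, 0, 0, 215), 1.0)
  expect_error(shared_neighbor_pvalue(3, 2, 5, 10), "m")
  expect_error(shared_neighbor_pvalue(1, 2, 11, 10), "N")
  expect_error(shared_neighbor_pvalue(-1, 2, 2, 10), "m")
  expect_error(shared_neighbor_pvalue(1.5, 2, 2, 10), "m")
})

test_that("the probability is a normalised distribution over overlaps", {
  # Vandermonde: point masses over m sum to one
  for (prm in list(c(5, 7, 30), c(2, 2, 4), c(10, 10, 12))) {
    m <- 0:min(prm[1], prm[2])
    expect_equal(sum(shared_neighbor_pvalue(m, prm[1], prm[2], prm[3])), 1,
                 tolerance = 1e-12)
  }
})

test_that("the statistic equals the hypergeometric point probability", {
  for (N in c(6, 13, 30)) {
    grid <- expand.grid(n1 = 0:N, n2 = 0:N)
    for (r in seq_len(nrow(grid))) {
      n1 <- grid$n1[r]; n2 <- grid$n2[r]
      m <- 0:min(n1, n2)
      expect_equal(shared_neighbor_pvalue(m, n1, n2, N),
                   stats::dhyper(m, n1, N - n1, n2), tolerance = 1e-12)
    }
  }
})

test_that("the statistic is symmetric and strictly decreasing in m", {
  grid <- expand.grid(m = 0:4, n1 = 4:8, n2 = 4:8)
  p12 <- shared_neighbor_pvalue(grid$m, grid$n1, grid$n2, 50)
  p21 <- shared_neighbor_pvalue(grid$m, grid$n2, grid$n1, 50)
  expect_equal(p12, p21, tolerance = 1e-14)
  for (n1 in c(3, 5, 8)) for (n2 in c(3, 6)) {
    p <- shared_neighbor_pvalue(1:min(n1, n2), n1, n2, 40)
    expect_true(all(diff(p) < 0))
  }
})

test_that("the upper-tail option dominates the point mass and ends at it", {
  p_point <- shared_neighbor_pvalue(2, 4, 5, 30)
  p_tail <- shared_neighbor_pvalue(2, 4, 5, 30, tail = TRUE)
  expect_gte(p_tail, p_point)
  # at m = min(n1, n2) the tail collapses to the point mass
  expect_equal(shared_neighbor_pvalue(4, 4, 5, 30, tail = TRUE),
               shared_neighbor_pvalue(4, 4, 5, 30), tolerance = 1e-12)
  expect_equal(shared_neighbor_pvalue(0, 3, 4, 20, tail = TRUE), 1,
               tolerance = 1e-12)
})

test_that("Monte-Carlo subset-overlap frequencies agree with the formula", {
  # urn draw vectorised across replicates: m = overlap of a random
  # n2-subset with a fixed n1-set, sampled sequentially without replacement
  urn_overlap <- function(n1, n2, N, draws, seed) {
    withr::with_seed(seed, {
      m <- integer(draws)
      for (j in seq_len(n2)) {
        p_hit <- (n1 - m) / (N - j + 1)
        m <- m + (stats::runif(draws) < p_hit)
      }
      m
    })
  }
  cases <- list(c(2, 2, 10), c(3, 4, 15), c(5, 5, 12))
  for (cs in cases) {
    draws <- 2e5
    m_sim <- urn_overlap(cs[1], cs[2], cs[3], draws, seed = sum(cs))
    for (m in 0:min(cs[1], cs[2])) {
      p_hat <- mean(m_sim == m)
      p <- shared_neighbor_pvalue(m, cs[1], cs[2], cs[3])
      se <- sqrt(p * (1 - p) / draws)
      expect_lt(abs(p_hat - p), 3 * se + 1e-12,
                label = sprintf("m=%d n1=%d n2=%d N=%d", m, cs[1], cs[2], cs[3]))
    }
  }
})

test_that("candidate pairs respect the TS and degree filters", {
  # 3 mutually similar drugs in a path: all degree >= 1, centre degree 2
  drugs <- uniform_drugs(c("a", "b", "c", "x"))
  drugs_mixed <- drug_table(c("a", "b", "c", "x"),
                            atc_codes = list("C03AA03", "C03AA01", "C03AB01",
                                             "N02BA01"))
  g <- graph_from_pairs(c("a", "b", "c"), c("b", "c", "x"))
  c1 <- candidate_pairs(g, drugs_mixed, "dcpred1")
  # x is TS-disjoint from everything: never a candidate
  expect_false(any(c("x") %in% c(c1$drug_id_1, c1$drug_id_2)))
  expect_equal(nrow(c1), 3)  # the three similar pairs

  tri_drugs <- uniform_drugs(c("a", "b", "c"))
  c2 <- candidate_pairs(triangle_graph(), tri_drugs, "dcpred2")
  expect_equal(nrow(c2), 3)

  # DCPred3 count equals a brute-force filter on a known degree sequence
  sim <- cached_sim()
  net <- suppressMessages(build_cocktail_network(sim$combinations, sim$drugs))
  c3 <- candidate_pairs(net, sim$drugs, "dcpred3")
  deg <- igraph::degree(net$graph)
  ids <- names(deg)[deg >= 3]
  tsm <- ts_matrix(sim$drugs)
  brute <- sum(utils::combn(sort(ids), 2, function(p) tsm[p[1], p[2]] > 0))
  expect_equal(nrow(c3), brute)
})

test_that("ranking is monotone in shared neighbours and TS ties break cleanly", {
  # two pairs with equal degrees; one shares both neighbours, one shares none
  g <- igraph::graph_from_edgelist(rbind(
    c("p1", "u"), c("p1", "v"), c("p2", "u"), c("p2", "v"),
    c("q1", "w"), c("q1", "x"), c("q2", "y"), c("q2", "z")
  ), directed = FALSE)
  drugs <- uniform_drugs(c("p1", "p2", "q1", "q2", "u", "v", "w", "x", "y", "z"))
  rk <- rank_candidates(g, drugs, "dcpred2")
  key <- dcpred:::pair_key(rk$drug_id_1, rk$drug_id_2)
  expect_lt(which(key == "p1|p2"), which(key == "q1|q2"))

  # DCPred1 puts the TS = 1 pair first
  drugs2 <- drug_table(c("a", "b", "c", "d"),
                       atc_codes = list("C03AA03", "C03AA03", "C03AA03",
                                        "C09AA01"))
  g2 <- graph_from_pairs(c("a", "c", "a"), c("b", "d", "d"))
  rk1 <- rank_candidates(g2, drugs2, "dcpred1")
  expect_equal(rk1$ts[1], 1)
})

test_that("full ranking equals an independent brute-force recomputation", {
  sim12 <- simulate_dataset(generator_config(n_drugs = 12), seed = 8)
  net <- suppressMessages(build_cocktail_network(sim12$combinations,
                                                 sim12$drugs))
  g <- net$graph
  rk <- rank_candidates(net, sim12$drugs, "dcpred2")
  N <- igraph::vcount(g)
  tsm <- ts_matrix(sim12$drugs)
  ids <- sort(igraph::V(g)$name)
  deg <- igraph::degree(g)
  rows <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    a <- ids[i]; b <- ids[j]
    if (deg[a] < 2 || deg[b] < 2 || tsm[a, b] <= 0) next
    m <- length(intersect(igraph::neighbors(g, a)$name,
                          igraph::neighbors(g, b)$name))
    rows[[length(rows) + 1]] <- data.frame(
      a = a, b = b, ts = tsm[a, b],
      p = stats::dhyper(m, deg[a], N - deg[a], deg[b]))
  }
  oracle <- do.call(rbind, rows)
  oracle <- oracle[order(oracle$p, -oracle$ts, paste(oracle$a, oracle$b)), ]
  expect_equal(rk$drug_id_1, oracle$a)
  expect_equal(rk$drug_id_2, oracle$b)
  expect_equal(rk$p_value, oracle$p, tolerance = 1e-12)
  expect_equal(rk$rank, seq_len(nrow(oracle)))
})

test_that("ranking is invariant to drug-table row order", {
  sim <- simulate_dataset(generator_config(n_drugs = 40), seed = 77)
  net <- suppressMessages(build_cocktail_network(sim$combinations, sim$drugs))
  rk1 <- rank_candidates(net, sim$drugs, "dcpred2")
  shuffled <- withr::with_seed(5, sim$drugs[sample(nrow(sim$drugs)), ])
  class(shuffled) <- class(sim$drugs)
  rk2 <- rank_candidates(net, shuffled, "dcpred2")
  expect_equal(as.data.frame(rk1), as.data.frame(rk2))
})

test_that("excluding the pair's own edge lowers both neighbour counts", {
  tri_drugs <- uniform_drugs(c("a", "b", "c"))
  rk <- rank_candidates(triangle_graph(), tri_drugs, "dcpred2")
  rk_x <- rank_candidates(triangle_graph(), tri_drugs, "dcpred2",
                          exclude_pair_edge = TRUE)
  expect_true(all(rk$n1 == 2 & rk$n2 == 2))
  expect_true(all(rk_x$n1 == 1 & rk_x$n2 == 1))
  expect_true(all(rk$m == 1))  # the third vertex is the shared neighbour
})
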