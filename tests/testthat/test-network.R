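test_that("network construction splits combinations into unordered pairs", {
  drugs <- uniform_drugs(c("a", "b", "c", "d"))
  net2 <- suppressMessages(
    build_cocktail_network(combination_table("c1", list(c("a", "b"))), drugs))
  expect_equal(igraph::vcount(net2$graph), 2)
  expect_equal(igraph::ecount(net2$graph), 1)

  net3 <- suppressMessages(
    build_cocktail_network(combination_table("c1", list(c("a", "b", "c"))), drugs))
  expect_equal(igraph::vcount(net3$graph), 3)
  expect_equal(igraph::ecount(net3$graph), 3)  # C(3,2)

  dup <- combination_table(c("c1", "c2"), list(c("a", "b"), c("b", "a")))
  netd <- suppressMessages(build_cocktail_network(dup, drugs))
  expect_equal(igraph::ecount(netd$graph), 1)
})

test_that("combinations with unannotated members are dropped with a warning", {
  drugs <- uniform_drugs(c("a", "b"))
  combos <- combination_table(c("c1", "c2"), list(c("a", "b"), c("a", "zz")))
  expect_warning(net <- suppressMessages(build_cocktail_network(combos, drugs)),
                 "without annotation")
  expect_equal(igraph::ecount(net$graph), 1)
  expect_equal(unname(net$exclusions["unannotated_member"]), 1)
})

test_that("the built graph is always simple, whatever the combination list", {
  ids <- sprintf("d%02d", 1:12)
  drugs <- uniform_drugs(ids)
  for (seed in 1:20) {
    combos <- withr::with_seed(seed, {
      members <- lapply(1:15, function(i) sample(ids, sample(2:4, 1)))
      combination_table(sprintf("c%02d", 1:15), members)
    })
    g <- suppressMessages(build_cocktail_network(combos, drugs))$graph
    expect_true(igraph::is_simple(g))
    expect_true(all(igraph::degree(g) >= 1))
  }
})

test_that("degree distributions are exact fractions summing to one", {
  expect_equal(degree_distribution_table(triangle_graph()),
               data.frame(degree = 2L, count = 3L, fraction = 1.0))
  st <- degree_distribution_table(star_graph("s", paste0("l", 1:4)))
  expect_equal(st$fraction[st$degree == 1], 0.8)
  expect_equal(st$fraction[st$degree == 4], 0.2)
  pa <- degree_distribution_table(path_graph(c("a", "b", "c")))
  expect_equal(pa$fraction, c(2 / 3, 1 / 3))
  g <- random_named_gnp(40, 0.15, seed = 5)
  expect_equal(sum(degree_distribution_table(g)$fraction), 1, tolerance = 1e-12)
  expect_error(degree_distribution_table(igraph::make_empty_graph(directed = FALSE)),
               "empty")
})

test_that("power-law fit recovers exponent and constant on noiseless grids", {
  for (alpha in c(1.0, 1.9, 2.5)) {
    k <- 1:20
    dist <- data.frame(degree = k, fraction = 2.1 * k^-alpha)
    fit <- fit_power_law(dist)
    expect_equal(fit$alpha, alpha, tolerance = 1e-6)
    expect_equal(fit$c, 2.1, tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
  flat <- data.frame(degree = c(1, 2, 4), fraction = rep(1 / 3, 3))
  expect_equal(fit_power_law(flat)$alpha, 0, tolerance = 1e-12)
  expect_error(fit_power_law(data.frame(degree = 1:2, fraction = c(.5, .5))),
               "3 distinct")
})

test_that("components are sorted by size with a deterministic tie-break", {
  g <- graph_from_pairs(c("a", "c"), c("b", "d"))
  comp <- connected_components(g)
  expect_length(comp, 2)
  expect_equal(lengths(comp), c(2L, 2L))
  expect_equal(comp[[1]], c("a", "b"))  # tie broken by smallest id
  expect_length(connected_components(triangle_graph()), 1)

  # fixture mirroring a six-component layout, sizes 84/29/17/9/7/5
  sizes <- c(84, 29, 17, 9, 7, 5)
  gs <- lapply(seq_along(sizes), function(i) {
    ids <- sprintf("c%d_%03d", i, seq_len(sizes[i]))
    path_graph(ids)
  })
  big <- Reduce(igraph::disjoint_union, gs)
  expect_equal(lengths(connected_components(big)), sizes)
})

test_that("star and hub drugs are degree-threshold sets", {
  expect_equal(star_drugs(path_graph(c("a", "b", "c"))), "b")
  expect_setequal(star_drugs(triangle_graph()), c("a", "b", "c"))
  expect_equal(star_drugs(star_graph("s", paste0("l", 1:4))), "s")
  expect_equal(hub_drugs(star_graph("s", paste0("l", 1:7))), "s")
  expect_length(hub_drugs(star_graph("s", paste0("l", 1:6))), 0)  # boundary
  two_hubs <- igraph::graph_from_edgelist(rbind(
    cbind("h1", paste0("x", 1:7)), cbind("h2", paste0("y", 1:6)), c("h2", "x1")
  ), directed = FALSE)
  expect_setequal(hub_drugs(two_hubs), c("h1", "h2"))
})

test_that("star-neighbour TS profile reports both pooled fractions", {
  g <- star_graph("s", c("u", "v"))
  prof_all <- star_neighbor_ts_profile(g, uniform_drugs(c("s", "u", "v")))
  expect_equal(prof_all$frac_edges_positive, 1.0)
  expect_equal(prof_all$frac_pairs_positive, 1.0)
  prof_none <- star_neighbor_ts_profile(g, disjoint_drugs(c("s", "u", "v")))
  expect_equal(prof_none$frac_edges_positive, 0.0)
  expect_equal(prof_none$frac_pairs_positive, 0.0)
  expect_error(star_neighbor_ts_profile(graph_from_pairs("a", "b"),
                                        uniform_drugs(c("a", "b"))),
               "no star drugs")
})

test_that("planted edge-similarity fraction is recovered on generated data", {
  cfg <- generator_config(n_drugs = 300, ts_assortativity = 0.8)
  drugs <- generate_drugs(cfg, seed = 31)
  nc <- generate_cocktail_network(cfg, drugs, seed = 32)
  net <- suppressMessages(build_cocktail_network(nc$combinations, drugs))
  prof <- star_neighbor_ts_profile(net, drugs)
  # closure edges join similar pairs, so the edge fraction sits at or above
  # the assortativity parameter, well away from the disjoint regime
  expect_gt(prof$frac_edges_positive, 0.7)
  expect_lte(prof$frac_edges_positive, 1.0)
})

test_that("neighbour-pair effective fraction matches brute-force enumeration", {
  drugs <- uniform_drugs(letters[1:8])
  # triangle: every neighbour pair is an edge
  tri <- neighbor_pair_effective_fraction(triangle_graph(), drugs,
                                          ts_grid = c(0, 0.5, 1))
  expect_equal(tri$fraction, rep(1, 3))
  # star: no closed triangles
  st <- neighbor_pair_effective_fraction(star_graph("a", letters[2:5]), drugs,
                                         ts_grid = c(0, 1))
  expect_equal(st$fraction, rep(0, 2))

  brute <- function(g, tsm, t) {
    ids <- igraph::V(g)$name
    seen <- character(); n_pair <- 0L; n_eff <- 0L
    for (s in ids[igraph::degree(g) >= 2]) {
      nb <- igraph::neighbors(g, s)$name
      for (i in seq_along(nb)) for (j in seq_along(nb)) {
        if (i >= j) next
        key <- paste(sort(c(nb[i], nb[j])), collapse = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        if (tsm[nb[i], nb[j]] >= t) {
          n_pair <- n_pair + 1L
          if (igraph::are_adjacent(g, nb[i], nb[j])) n_eff <- n_eff + 1L
        }
      }
    }
    if (n_pair == 0) NaN else n_eff / n_pair
  }
  mixed <- withr::with_seed(11, {
    drug_table(letters[1:8], atc_codes = as.list(
      paste0(sample(c("C", "C", "N", "A"), 8, TRUE), "03AA0",
             sample(1:4, 8, TRUE))))
  })
  tsm <- ts_matrix(mixed)
  for (seed in 1:12) {
    g <- random_named_gnp(8, 0.4, seed = seed)
    igraph::V(g)$name <- letters[1:8]
    if (!length(star_drugs(g))) next
    res <- neighbor_pair_effective_fraction(g, mixed, ts_grid = c(0, 0.3, 0.7))
    for (r in seq_len(nrow(res))) {
      expect_equal(res$fraction[r], brute(g, tsm, res$threshold[r]),
                   info = sprintf("seed %d threshold %.1f", seed, res$threshold[r]))
    }
  }
})
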