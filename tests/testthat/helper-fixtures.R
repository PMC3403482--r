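# Shared fixtures, all built in code.

# Small hand-written drug tables with realistic code shapes.
toy_drugs <- function() {
  drug_table(
    c("dA", "dB", "dC", "dD"),
    atc_codes = list("C03AA03", "C03AA01", c("A01AB02", "C03AA03"), "N02BA01")
  )
}

# A drug table where every drug shares one ATC family (TS = 1 everywhere).
uniform_drugs <- function(ids) {
  drug_table(ids, atc_codes = rep(list("C03AA03"), length(ids)))
}

# A drug table where all drugs are pairwise ATC-disjoint at every level.
# Distinct level-1 letters guarantee disjoint prefix sets throughout.
disjoint_drugs <- function(ids) {
  letters1 <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N", "P", "R")
  stopifnot(length(ids) <= length(letters1))
  drug_table(ids, atc_codes = as.list(paste0(letters1[seq_along(ids)], "01AA01")))
}

graph_from_pairs <- function(a, b) {
  igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
}

path_graph <- function(ids) {
  graph_from_pairs(ids[-length(ids)], ids[-1])
}

star_graph <- function(center, leaves) {
  graph_from_pairs(rep(center, length(leaves)), leaves)
}

triangle_graph <- function(ids = c("a", "b", "c")) {
  graph_from_pairs(ids[c(1, 1, 2)], ids[c(2, 3, 3)])
}

# Random simple graph with named vertices, for property tests.
random_named_gnp <- function(n, p, seed) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    g
  })
}

# One modest synthetic dataset reused by several test files.
fixture_cache <- new.env(parent = emptyenv())
cached_sim <- function() {
  if (is.null(fixture_cache$sim)) {
    fixture_cache$sim <- simulate_dataset(generator_config(n_drugs = 200),
                                          seed = 42L)
  }
  fixture_cache$sim
}
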