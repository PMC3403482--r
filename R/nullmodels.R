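# Degree-preserving null model and enrichment tests.

#' Degree-preserving edge rewiring
#'
#' Randomises a network by repeated double-edge swaps that keep every
#' node's degree exactly while shuffling its partners, rejecting any swap
#' that would create a self-loop or parallel edge. The number of attempted
#' swaps is `ceiling(swap_factor * |E|)`; 10 sweeps over the edge set is a
#' standard mixing heuristic. Graphs that admit no valid swap (e.g. a
#' triangle) come back unchanged with a warning.
#'
#' @param net A `cocktail_network` or igraph graph with at least 2 edges.
#' @param swap_factor Attempted swaps per edge (default 10).
#' @param seed Optional integer; same seed, same output.
#' @return A rewired igraph graph with the same vertex set and degrees.
#' @export
rewire_degree_preserving <- function(net, swap_factor = 10, seed = NULL) {
  g <- as_cocktail_graph(net)
  if (igraph::ecount(g) < 2) stop("need at least 2 edges to rewire", call. = FALSE)
  niter <- as.integer(ceiling(swap_factor * igraph::ecount(g)))
  do_rewire <- function() {
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = niter))
  }
  r <- if (is.null(seed)) do_rewire() else withr::with_seed(seed, do_rewire())
  if (setequal(edge_keys(r), edge_keys(g))) {
    # either no valid swap exists or none was accepted; caller should know
    if (!any_valid_swap(g)) {
      warning("no valid degree-preserving swap exists; graph returned unchanged",
              call. = FALSE)
    }
  }
  r
}

edge_keys <- function(g) {
  el <- igraph::as_edgelist(g)
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
}

# Exhaustively check whether any double-edge swap yields a simple graph.
# Only called on small graphs / in the unchanged-output corner case.
any_valid_swap <- function(g) {
  el <- igraph::as_edgelist(g)
  m <- nrow(el)
  if (m > 200) return(TRUE)   # large graphs essentially always admit swaps
  keys <- edge_keys(g)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    a <- el[i, ]; b <- el[j, ]
    if (length(unique(c(a, b))) < 4) next
    for (sw in list(c(a[1], b[1], a[2], b[2]), c(a[1], b[2], a[2], b[1]))) {
      k1 <- paste(min(sw[1], sw[2]), max(sw[1], sw[2]), sep = "\r")
      k2 <- paste(min(sw[3], sw[4]), max(sw[3], sw[4]), sep = "\r")
      if (!(k1 %in% keys) && !(k2 %in% keys) && k1 != k2) return(TRUE)
    }
  }
  FALSE
}

#' Mean therapeutic similarity over network edges
#'
#' The network-level TS score: the arithmetic mean of TS over all edges.
#'
#' @param net A `cocktail_network` or igraph graph with at least one edge.
#' @param drugs A `drug_table` covering the nodes, or a precomputed TS
#'   matrix from [ts_matrix()] (accepted to avoid recomputation in
#'   replicate loops).
#' @param n_levels ATC levels averaged in TS (ignored when a matrix is given).
#' @return Mean TS, a number in \[0, 1\].
#' @export
network_mean_ts <- function(net, drugs, n_levels = 3) {
  g <- as_cocktail_graph(net)
  if (igraph::ecount(g) == 0) stop("network has no edges", call. = FALSE)
  tsm <- if (is.matrix(drugs)) drugs else ts_matrix(drugs, n_levels)
  el <- igraph::as_edgelist(g)
  mean(tsm[el])
}

#' Significance of network TS against a rewiring null
#'
#' Compares the observed network-level mean TS with its distribution over
#' degree-preserving randomisations. The empirical p-value is the fraction
#' of replicates whose mean TS is greater than or equal to the observed
#' value (ties count toward the numerator, the conservative convention).
#'
#' The ATC aggregation depth `level` selects how TS is computed per "ATC
#' code level": by default the mean over levels 1..`level`
#' (`agg = "mean"`); `agg = "single"` uses the level-`level` Jaccard alone.
#'
#' @param net A `cocktail_network` or igraph graph.
#' @param drugs A `drug_table`.
#' @param n_replicates Number of randomised networks (default 1000).
#' @param level ATC aggregation depth, 1 to 4 typically.
#' @param agg `"mean"` (TS averaged over levels 1..`level`) or `"single"`.
#' @param swap_factor Attempted swaps per edge in each randomisation.
#' @param seed Integer seed; replicate seeds are derived as `seed + i`.
#' @return A `ts_randomization`: observed mean TS, replicate means,
#'   empirical p, replicate count and seed.
#' @export
ts_significance <- function(net, drugs, n_replicates = 1000, level = 3,
                            agg = c("mean", "single"), swap_factor = 10,
                            seed = 1L) {
  agg <- match.arg(agg)
  g <- as_cocktail_graph(net)
  drugs <- as_drug_table(drugs)
  tsm <- if (agg == "mean") {
    ts_matrix(drugs, n_levels = level)
  } else {
    # single-level Jaccard = difference trick: level k alone
    lk <- ts_matrix(drugs, n_levels = level)
    if (level == 1) lk else level * lk - (level - 1) * ts_matrix(drugs, level - 1)
  }
  observed <- network_mean_ts(g, tsm)
  replicate_ts <- if (igraph::ecount(g) < 2) {
    # a single edge cannot be rewired: the null collapses onto the observed
    warning("network too small to rewire; null distribution equals observed",
            call. = FALSE)
    rep(observed, n_replicates)
  } else {
    vapply(seq_len(n_replicates), function(i) {
      r <- rewire_degree_preserving(g, swap_factor, seed = seed + i)
      network_mean_ts(r, tsm)
    }, numeric(1))
  }
  structure(list(observed_ts = observed, replicate_ts = replicate_ts,
                 empirical_p = mean(replicate_ts >= observed),
                 n_replicates = n_replicates, level = level, agg = agg,
                 seed = seed),
            class = "ts_randomization")
}

#' @export
print.ts_randomization <- function(x, ...) {
  cat(sprintf(paste0("<ts_randomization> observed mean TS = %.4f; null = ",
                     "%.4f +/- %.4f (%d replicates); empirical p = %s\n"),
              x$observed_ts, mean(x$replicate_ts), stats::sd(x$replicate_ts),
              x$n_replicates,
              sprintf("%d/%d", sum(x$replicate_ts >= x$observed_ts),
                      x$n_replicates)))
  invisible(x)
}

#' ATC class enrichment of a network component
#'
#' For each level-1 ATC class, counts carrier drugs in a component and in
#' the drug universe and tests over-representation with the one-sided
#' hypergeometric tail, Benjamini-Hochberg adjusted across classes. A drug
#' carrying several level-1 codes counts once toward each class it carries.
#'
#' @param component Character vector of drug ids (a connected component).
#' @param drugs A `drug_table` covering the universe.
#' @param universe Character vector of drug ids forming the background;
#'   defaults to all drugs in `drugs`.
#' @return Data frame sorted by ascending p: `class`, `count_component`,
#'   `count_universe`, `p_value`, `q_value`.
#' @export
component_atc_enrichment <- function(component, drugs, universe = NULL) {
  drugs <- as_drug_table(drugs)
  if (is.null(universe)) universe <- drugs$drug_id
  if (!all(component %in% universe)) {
    stop("component must be a subset of the universe", call. = FALSE)
  }
  lut <- atc_lookup(drugs)
  classes_of <- function(ids) lapply(lut[ids], atc_level_set, level = 1L)
  comp_classes <- classes_of(component)
  uni_classes <- classes_of(universe)
  all_classes <- sort(unique(unlist(uni_classes)))
  k_comp <- vapply(all_classes, function(cl) {
    sum(vapply(comp_classes, function(x) cl %in% x, logical(1)))
  }, integer(1))
  k_uni <- vapply(all_classes, function(cl) {
    sum(vapply(uni_classes, function(x) cl %in% x, logical(1)))
  }, integer(1))
  n <- length(component)
  N <- length(universe)
  p <- stats::phyper(k_comp - 1L, k_uni, N - k_uni, n, lower.tail = FALSE)
  out <- data.frame(class = all_classes, count_component = k_comp,
                    count_universe = k_uni, p_value = p,
                    q_value = stats::p.adjust(p, "BH"),
                    row.names = NULL)
  out[order(out$p_value, out$class), , drop = FALSE]
}
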