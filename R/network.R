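# Cocktail network construction and topology.

#' Build the drug cocktail network
#'
#' Nodes are drugs and an edge joins two drugs that occur together in an
#' effective combination. Combinations with more than two members are split
#' into all pairwise edges; duplicate pairs across combinations collapse to
#' a single edge, so the graph is always simple. Non-effective records and
#' combinations whose members lack a drug annotation are dropped and
#' counted in the exclusion report.
#'
#' @param combinations A `combination_table`.
#' @param drugs A `drug_table` covering (at least) the member drugs.
#' @param top_components If non-`NULL`, restrict the network to the union of
#'   this many largest connected components, mirroring analyses that focus
#'   on the dominant subnetworks.
#' @return A `cocktail_network`: a list with elements `graph` (an
#'   [igraph::igraph] object), and `exclusions` (counts of dropped records).
#' @examples
#' drugs <- drug_table(c("a", "b", "c"),
#'                     atc_codes = list("C03AA03", "C03AA01", "C03BB01"))
#' combos <- combination_table("c1", list(c("a", "b", "c")))
#' net <- build_cocktail_network(combos, drugs)
#' igraph::ecount(net$graph)  # C(3,2) = 3 edges
#' @export
build_cocktail_network <- function(combinations, drugs, top_components = NULL) {
  stopifnot(inherits(combinations, "combination_table") ||
              is.data.frame(combinations))
  drugs <- as_drug_table(drugs)
  n_in <- nrow(combinations)
  eff <- combinations[combinations$effective, , drop = FALSE]
  n_ineffective <- n_in - nrow(eff)

  known <- drugs$drug_id
  has_all <- vapply(eff$members, function(m) all(m %in% known), logical(1))
  n_unannotated <- sum(!has_all)
  if (n_unannotated > 0) {
    warning(n_unannotated, " combination(s) dropped: member drug(s) without ",
            "annotation (", paste(utils::head(eff$combo_id[!has_all], 5),
                                  collapse = ", "), ")", call. = FALSE)
  }
  eff <- eff[has_all, , drop = FALSE]
  if (!nrow(eff)) stop("no usable combinations left", call. = FALSE)

  pairs <- do.call(rbind, lapply(eff$members, function(m) {
    t(utils::combn(sort(m), 2L))
  }))
  n_pairs <- nrow(pairs)
  key <- paste(pairs[, 1], pairs[, 2], sep = "\r")
  pairs <- pairs[!duplicated(key), , drop = FALSE]

  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::simplify(g)
  net <- structure(list(
    graph = g,
    exclusions = c(input = n_in, ineffective = n_ineffective,
                   unannotated_member = n_unannotated,
                   retained = nrow(eff), pairs_after_split = n_pairs,
                   edges = igraph::ecount(g))
  ), class = "cocktail_network")
  if (!is.null(top_components)) {
    comp <- connected_components(net)
    keep <- unlist(comp[seq_len(min(top_components, length(comp)))])
    net$graph <- igraph::induced_subgraph(g, keep)
  }
  message("cocktail network: ", igraph::vcount(net$graph), " drugs, ",
          igraph::ecount(net$graph), " edges (from ", nrow(eff),
          " effective combinations, ", n_pairs, " pairs after splitting)")
  net
}

#' @export
print.cocktail_network <- function(x, ...) {
  g <- x$graph
  cat("<cocktail_network> ", igraph::vcount(g), " drugs, ",
      igraph::ecount(g), " edges, ",
      igraph::count_components(g), " components\n", sep = "")
  cat("  star drugs (degree >= 2): ", length(star_drugs(x)),
      "; hub drugs (degree >= 7): ", length(hub_drugs(x)), "\n", sep = "")
  invisible(x)
}

# Accept either a cocktail_network or a bare igraph everywhere downstream.
as_cocktail_graph <- function(net) {
  if (inherits(net, "cocktail_network")) return(net$graph)
  if (inherits(net, "igraph")) return(net)
  stop("expected a cocktail_network or igraph object", call. = FALSE)
}

#' Empirical degree distribution
#'
#' @param net A `cocktail_network` or igraph graph.
#' @return Data frame with columns `degree`, `count` and `fraction`
#'   (fractions sum to 1 over observed degrees).
#' @export
degree_distribution_table <- function(net) {
  g <- as_cocktail_graph(net)
  if (igraph::vcount(g) == 0) stop("empty network", call. = FALSE)
  tab <- table(igraph::degree(g))
  data.frame(degree = as.integer(names(tab)),
             count = as.integer(tab),
             fraction = as.integer(tab) / igraph::vcount(g))
}

#' Fit a power law to a degree distribution
#'
#' Models the degree distribution as \eqn{P(k) \propto c\,k^{-\alpha}}.
#' The default estimator is ordinary least squares on the log10-log10
#' points of the empirical distribution (`alpha` = minus the slope,
#' `c` = 10^intercept), matching how such fits are usually displayed.
#' A discrete maximum-likelihood estimate of `alpha` (Clauset-style, with
#' the continuous approximation \eqn{\hat\alpha = 1 + n / \sum \ln(k_i /
#' (k_{min}-1/2))}) is available as an alternative.
#'
#' @param dist Degree distribution table from [degree_distribution_table()],
#'   or a `cocktail_network`/igraph (converted internally).
#' @param method `"ols"` (default) or `"mle"`.
#' @param min_count For `"ols"`, drop degrees observed fewer than this many
#'   times before fitting (default 1 = keep all); tail bins holding a single
#'   node dominate the scatter in log-log space, so a small floor stabilises
#'   the slope on sampled data.
#' @return A `power_law_fit` with elements `c`, `alpha`, `r_squared`.
#' @export
fit_power_law <- function(dist, method = c("ols", "mle"), min_count = 1L) {
  method <- match.arg(method)
  if (inherits(dist, c("cocktail_network", "igraph"))) {
    g <- as_cocktail_graph(dist)
    if (method == "mle") {
      k <- igraph::degree(g)
      k <- k[k >= 1]
      alpha <- 1 + length(k) / sum(log(k / 0.5))
      return(structure(list(c = NA_real_, alpha = alpha,
                            r_squared = NA_real_, method = "mle"),
                       class = "power_law_fit"))
    }
    dist <- degree_distribution_table(g)
  }
  stopifnot(is.data.frame(dist), all(c("degree", "fraction") %in% names(dist)))
  d <- dist[dist$degree > 0 & dist$fraction > 0, , drop = FALSE]
  if ("count" %in% names(d)) d <- d[d$count >= min_count, , drop = FALSE]
  if (method == "mle") {
    if (!"count" %in% names(d)) stop("mle needs a 'count' column", call. = FALSE)
    k <- rep(d$degree, d$count)
    alpha <- 1 + length(k) / sum(log(k / 0.5))
    return(structure(list(c = NA_real_, alpha = alpha, r_squared = NA_real_,
                          method = "mle"), class = "power_law_fit"))
  }
  if (nrow(d) < 3) stop("need at least 3 distinct degrees to fit", call. = FALSE)
  fit <- stats::lm(log10(fraction) ~ log10(degree), data = d)
  co <- stats::coef(fit)
  # noiseless grids fit exactly; summary.lm warns about that, harmlessly
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(c = 10^unname(co[1]), alpha = -unname(co[2]),
                 r_squared = r2, method = "ols"),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> P(k) ~ c k^-alpha: alpha = %.4g", x$alpha))
  if (!is.na(x$c)) cat(sprintf(", c = %.4g", x$c))
  if (!is.na(x$r_squared)) cat(sprintf(" (log-log R^2 = %.3f)", x$r_squared))
  cat(" [", x$method, "]\n", sep = "")
  invisible(x)
}

#' Connected components, largest first
#'
#' @param net A `cocktail_network` or igraph graph.
#' @return List of character vectors of drug ids, ordered by decreasing
#'   size; ties broken by the smallest contained drug id so the order is
#'   deterministic.
#' @export
connected_components <- function(net) {
  g <- as_cocktail_graph(net)
  memb <- igraph::components(g)$membership
  comp <- split(names(memb), memb)
  comp <- lapply(comp, sort)
  ord <- order(-lengths(comp), vapply(comp, `[`, "", 1L))
  unname(comp[ord])
}

#' Star drugs: degree at least two
#'
#' @param net A `cocktail_network` or igraph graph.
#' @param min_neighbors Minimum degree (default 2).
#' @return Character vector of drug ids.
#' @export
star_drugs <- function(net, min_neighbors = 2L) {
  g <- as_cocktail_graph(net)
  deg <- igraph::degree(g)
  sort(names(deg)[deg >= min_neighbors])
}

#' Hub drugs: degree above a hub threshold
#'
#' "More than six neighbours" is implemented as degree >= 7 by default; the
#' threshold is exposed because hub analyses sometimes restrict further
#' (e.g. to hubs with target annotations).
#'
#' @param net A `cocktail_network` or igraph graph.
#' @param min_neighbors Minimum degree to count as a hub (default 7).
#' @return Character vector of drug ids.
#' @export
hub_drugs <- function(net, min_neighbors = 7L) {
  stopifnot(min_neighbors >= 1)
  star_drugs(net, min_neighbors = min_neighbors)
}

#' TS profile of star drugs and their neighbours
#'
#' For every star drug (degree >= 2), the TS scores to each of its
#' neighbours. Two summary fractions are reported: the fraction of distinct
#' star-neighbour *edges* with TS > 0, and the fraction of (star, neighbour)
#' *ordered pairs* with TS > 0 — the two differ when both endpoints of an
#' edge are stars.
#'
#' @param net A `cocktail_network` or igraph graph.
#' @param drugs A `drug_table` covering the network's nodes.
#' @param n_levels ATC levels averaged in TS.
#' @return List with `per_star` (named list of per-neighbour TS vectors),
#'   `pooled` (all ordered-pair scores), `frac_edges_positive` and
#'   `frac_pairs_positive`.
#' @export
star_neighbor_ts_profile <- function(net, drugs, n_levels = 3) {
  g <- as_cocktail_graph(net)
  stars <- star_drugs(g)
  if (!length(stars)) stop("network has no star drugs", call. = FALSE)
  drugs <- as_drug_table(drugs)
  tsm <- ts_matrix(drugs, n_levels)
  per_star <- lapply(stars, function(s) {
    nb <- igraph::neighbors(g, s)$name
    stats::setNames(tsm[s, nb], nb)
  })
  names(per_star) <- stars
  el <- igraph::as_edgelist(g)
  star_edge <- el[, 1] %in% stars | el[, 2] %in% stars
  edge_ts <- tsm[el[star_edge, , drop = FALSE]]
  pooled <- unlist(per_star, use.names = FALSE)
  list(per_star = per_star, pooled = pooled,
       frac_edges_positive = mean(edge_ts > 0),
       frac_pairs_positive = mean(pooled > 0))
}

#' Effective fraction of star-neighbour pairs by TS threshold
#'
#' Considers unordered drug pairs that share at least one star neighbour
#' (each pair counted once however many stars it shares) and, for each TS
#' threshold `t` in `ts_grid`, reports the fraction of pairs with TS >= t
#' that are themselves edges of the network, i.e. known effective
#' combinations.
#'
#' @param net A `cocktail_network` or igraph graph.
#' @param drugs A `drug_table`.
#' @param ts_grid Numeric vector of thresholds in \[0, 1\].
#' @param n_levels ATC levels averaged in TS.
#' @return Data frame with columns `threshold`, `n_pairs`, `n_effective`,
#'   `fraction` (`NaN` where no pair reaches the threshold).
#' @export
neighbor_pair_effective_fraction <- function(net, drugs,
                                             ts_grid = seq(0, 1, 0.1),
                                             n_levels = 3) {
  stopifnot(all(ts_grid >= 0 & ts_grid <= 1))
  g <- as_cocktail_graph(net)
  drugs <- as_drug_table(drugs)
  tsm <- ts_matrix(drugs, n_levels)
  stars <- star_drugs(g)
  pair_keys <- unique(unlist(lapply(stars, function(s) {
    nb <- sort(igraph::neighbors(g, s)$name)
    if (length(nb) < 2) return(character())
    cmb <- utils::combn(nb, 2L)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  })))
  if (!length(pair_keys)) {
    return(data.frame(threshold = ts_grid, n_pairs = 0L, n_effective = 0L,
                      fraction = NaN))
  }
  parts <- do.call(rbind, strsplit(pair_keys, "\r", fixed = TRUE))
  ts <- tsm[parts]
  is_edge <- mapply(igraph::are_adjacent, parts[, 1], parts[, 2],
                    MoreArgs = list(graph = g))
  rows <- lapply(ts_grid, function(t) {
    sel <- ts >= t
    data.frame(threshold = t, n_pairs = sum(sel), n_effective = sum(is_edge[sel]),
               fraction = if (any(sel)) mean(is_edge[sel]) else NaN)
  })
  do.call(rbind, rows)
}
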