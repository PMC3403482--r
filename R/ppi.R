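# Target-protein proximity on a scored protein-protein interaction network.

#' Load a scored PPI network
#'
#' Reads a STRING-style edge table (`protein1`, `protein2`,
#' `combined_score`) and keeps interactions whose score reaches
#' `min_score` (the conventional high-confidence cutoff is 700; scores
#' strictly below are removed). Duplicate pairs collapse to one edge
#' keeping the maximum score; self-interactions are dropped.
#'
#' @param x Path to a TSV file or a data frame with three columns.
#' @param min_score Minimum retained confidence score (inclusive).
#' @return An igraph graph with edge attribute `score`.
#' @export
load_ppi <- function(x, min_score = 700) {
  df <- if (is.character(x)) read_ppi_table(x) else x
  stopifnot(is.data.frame(df), ncol(df) >= 3)
  names(df)[1:3] <- c("protein1", "protein2", "combined_score")
  if (!nrow(df)) {
    warning("empty PPI table; returning an empty network", call. = FALSE)
    return(igraph::make_empty_graph(directed = FALSE))
  }
  n_in <- nrow(df)
  df <- df[df$combined_score >= min_score, , drop = FALSE]
  df <- df[df$protein1 != df$protein2, , drop = FALSE]
  a <- pmin(df$protein1, df$protein2)
  b <- pmax(df$protein1, df$protein2)
  key <- paste(a, b, sep = "\r")
  best <- tapply(df$combined_score, key, max)
  parts <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
  message("PPI: kept ", length(best), " of ", n_in, " interactions at score >= ",
          min_score, " (", length(unique(c(parts))), " proteins)")
  g <- igraph::graph_from_edgelist(parts, directed = FALSE)
  igraph::E(g)$score <- as.numeric(best)
  g
}

#' Shortest distance between two target sets
#'
#' The minimum (default) over all cross pairs of the unweighted
#' shortest-path length between a protein of set A and one of set B; 0 when
#' the sets intersect within the graph, `Inf` (the unreachable sentinel)
#' when no cross pair is connected. Proteins absent from the PPI graph are
#' ignored with a warning. `method = "mean"` averages the finite cross-pair
#' distances instead.
#'
#' @param ppi An igraph PPI network from [load_ppi()].
#' @param targets_a,targets_b Character vectors of protein ids.
#' @param method `"min"` (default) or `"mean"`.
#' @return A non-negative number, or `Inf` if unreachable.
#' @export
target_set_distance <- function(ppi, targets_a, targets_b,
                                method = c("min", "mean")) {
  method <- match.arg(method)
  prot <- igraph::V(ppi)$name
  a <- intersect(unique(targets_a), prot)
  b <- intersect(unique(targets_b), prot)
  n_missing <- length(setdiff(unique(c(targets_a, targets_b)), prot))
  if (n_missing > 0) {
    warning(n_missing, " target protein(s) absent from the PPI graph ignored",
            call. = FALSE)
  }
  if (!length(a) || !length(b)) {
    stop("a target set is empty after filtering to the PPI graph", call. = FALSE)
  }
  d <- igraph::distances(ppi, v = a, to = b)
  if (method == "min") return(min(d))
  if (all(is.infinite(d))) return(Inf)
  mean(d[is.finite(d)])
}

#' Target proximity: combination partners vs therapeutically similar drugs
#'
#' For each hub drug with target annotations, computes the target-set
#' distance to (a) each of its combination partners (its network
#' neighbours) and (b) each therapeutically similar drug (TS > 0) it is
#' *not* combined with. Closer partner distances than similar-drug
#' distances indicate that combined drugs act on neighbouring proteins,
#' beyond what therapeutic similarity alone implies.
#'
#' @param ppi An igraph PPI network.
#' @param drugs A `drug_table` with `targets` annotations.
#' @param net A `cocktail_network` or igraph graph.
#' @param hub_set Character vector of hub drug ids; defaults to
#'   [hub_drugs()] of the network restricted to drugs with targets.
#' @param n_levels ATC levels averaged in TS.
#' @return List with `partner` and `similar` (data frames `hub`, `other`,
#'   `distance`), and `medians` (finite-distance medians of the two
#'   groups; `NA` where a group is empty, with a warning).
#' @export
proximity_comparison <- function(ppi, drugs, net, hub_set = NULL, n_levels = 3) {
  g <- as_cocktail_graph(net)
  drugs <- as_drug_table(drugs)
  targ <- target_lookup(drugs)
  if (is.null(hub_set)) {
    hub_set <- hub_drugs(g)
    hub_set <- hub_set[lengths(targ[hub_set]) > 0]
  }
  if (!length(hub_set)) stop("no hub drugs with target annotations", call. = FALSE)
  tsm <- ts_matrix(drugs, n_levels)
  with_targets <- drugs$drug_id[lengths(drugs$targets) > 0]
  dist_to <- function(hub, others) {
    if (!length(others)) {
      return(data.frame(hub = character(), other = character(),
                        distance = numeric()))
    }
    d <- vapply(others, function(o) {
      tryCatch(suppressWarnings(target_set_distance(ppi, targ[[hub]], targ[[o]])),
               error = function(e) NA_real_)
    }, numeric(1))
    data.frame(hub = hub, other = others, distance = unname(d))
  }
  partner <- do.call(rbind, lapply(hub_set, function(h) {
    nb <- intersect(igraph::neighbors(g, h)$name, with_targets)
    dist_to(h, nb)
  }))
  similar <- do.call(rbind, lapply(hub_set, function(h) {
    nb <- igraph::neighbors(g, h)$name
    sim <- colnames(tsm)[tsm[h, ] > 0]
    sim <- setdiff(intersect(sim, with_targets), c(nb, h))
    dist_to(h, sim)
  }))
  if (!nrow(similar)) {
    warning("no therapeutically similar non-partner drugs with targets",
            call. = FALSE)
  }
  med <- function(x) if (length(x) && any(is.finite(x))) {
    stats::median(x[is.finite(x)])
  } else NA_real_
  list(partner = partner, similar = similar,
       medians = c(partner = med(partner$distance),
                   similar = med(similar$distance)))
}

#' Cellular-localization tally of a drug set's targets
#'
#' Tallies the distinct target proteins of a set of drugs across cellular
#' localization classes. Targets missing from the localization table are
#' counted under `"unannotated"`.
#'
#' @param drugs A `drug_table`.
#' @param localization Data frame (`protein_id`, `localization`) or a named
#'   character vector keyed by protein id.
#' @param drug_set Character vector of drug ids; defaults to all drugs.
#' @return Named numeric vector of fractions summing to 1 over the drug
#'   set's distinct targets (empty if the set has no targets).
#' @export
localization_tally <- function(drugs, localization, drug_set = NULL) {
  drugs <- as_drug_table(drugs)
  if (is.null(drug_set)) drug_set <- drugs$drug_id
  if (is.data.frame(localization)) {
    localization <- stats::setNames(as.character(localization[[2]]),
                                    as.character(localization[[1]]))
  }
  targets <- unique(unlist(target_lookup(drugs)[drug_set]))
  if (!length(targets)) return(stats::setNames(numeric(), character()))
  cls <- localization[targets]
  cls[is.na(cls)] <- "unannotated"
  tab <- table(cls)
  frac <- as.numeric(tab) / length(targets)
  sort(stats::setNames(frac, names(tab)), decreasing = TRUE)
}
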