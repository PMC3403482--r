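# Shared-neighbour statistic and the DCPred ranking models.

#' Shared-neighbour probability for a drug pair
#'
#' The probability that two drugs with `n1` and `n2` partners among `N`
#' drugs share exactly `m` of them, were their neighbourhoods drawn at
#' random:
#' \deqn{P(m, n_1, n_2, N) =
#'   \frac{\binom{N}{m}\binom{N-m}{n_1-m}\binom{N-n_1}{n_2-m}}
#'        {\binom{N}{n_1}\binom{N}{n_2}}}
#' which is algebraically the hypergeometric point probability
#' \eqn{\binom{n_1}{m}\binom{N-n_1}{n_2-m}/\binom{N}{n_2}}. The smaller the
#' value, the more surprising the overlap, so candidate drug pairs are
#' ranked by ascending probability. Computed on the log scale via
#' `lchoose` for numerical stability; exactly symmetric in `(n1, n2)`.
#'
#' With `tail = TRUE` the upper tail \eqn{P(X \ge m)} is returned instead
#' of the point probability.
#'
#' @param m Number of shared neighbours, `0 <= m <= min(n1, n2)`.
#' @param n1,n2 Neighbour counts of the two drugs.
#' @param N Total number of drugs in the network.
#' @param tail If `TRUE`, return the upper-tail probability.
#' @return Probability in (0, 1\]. All arguments are vectorised.
#' @examples
#' shared_neighbor_pvalue(2, 2, 2, 215)   # 4.35e-05
#' @export
shared_neighbor_pvalue <- function(m, n1, n2, N, tail = FALSE) {
  args <- cbind(m = m, n1 = n1, n2 = n2, N = N)
  for (nm in colnames(args)) {
    v <- args[, nm]
    if (any(v < 0) || any(v != round(v))) {
      stop("'", nm, "' must contain non-negative integers", call. = FALSE)
    }
  }
  m <- args[, "m"]; n1 <- args[, "n1"]; n2 <- args[, "n2"]; N <- args[, "N"]
  if (any(m > pmin(n1, n2))) {
    stop("'m' must not exceed min(n1, n2)", call. = FALSE)
  }
  if (any(pmax(n1, n2) > N)) {
    stop("'n1' and 'n2' must not exceed 'N'", call. = FALSE)
  }
  point <- function(mm) {
    unname(exp(lchoose(N, mm) + lchoose(N - mm, n1 - mm) +
                 lchoose(N - n1, n2 - mm) - lchoose(N, n1) - lchoose(N, n2)))
  }
  if (!tail) return(point(m))
  # upper tail: sum the point mass from m to min(n1, n2)
  vapply(seq_along(m), function(i) {
    mm <- m[i]:min(n1[i], n2[i])
    sum(exp(lchoose(N[i], mm) + lchoose(N[i] - mm, n1[i] - mm) +
              lchoose(N[i] - n1[i], n2[i] - mm) -
              lchoose(N[i], n1[i]) - lchoose(N[i], n2[i])))
  }, numeric(1))
}

#' Candidate drug pairs for a DCPred model
#'
#' Candidates are unordered pairs of network drugs with similar ATC codes
#' (TS above `ts_min`, strictly). DCPred1 applies no degree filter; DCPred2
#' and DCPred3 additionally require both drugs to have at least 2,
#' respectively 3, neighbours. Pairs that are already edges are retained —
#' they are the known positives in evaluation.
#'
#' @param net A `cocktail_network` or igraph graph.
#' @param drugs A `drug_table` covering the nodes.
#' @param model `"dcpred1"`, `"dcpred2"` or `"dcpred3"`.
#' @param ts_min TS threshold; candidates must have TS strictly greater
#'   (default 0, i.e. any therapeutic similarity).
#' @param n_levels ATC levels averaged in TS.
#' @return Data frame with columns `drug_id_1`, `drug_id_2` (sorted within
#'   pair), `ts`.
#' @export
candidate_pairs <- function(net, drugs, model = c("dcpred2", "dcpred1", "dcpred3"),
                            ts_min = 0, n_levels = 3) {
  model <- match.arg(model)
  g <- as_cocktail_graph(net)
  drugs <- as_drug_table(drugs)
  ids <- sort(igraph::V(g)$name)
  min_deg <- c(dcpred1 = 0L, dcpred2 = 2L, dcpred3 = 3L)[[model]]
  if (min_deg > 0) {
    deg <- igraph::degree(g)
    ids <- ids[deg[ids] >= min_deg]
  }
  if (length(ids) < 2) {
    return(data.frame(drug_id_1 = character(), drug_id_2 = character(),
                      ts = numeric()))
  }
  tsm <- ts_matrix(drugs[drugs$drug_id %in% ids, , drop = FALSE], n_levels)
  tsm <- tsm[ids, ids, drop = FALSE]
  sel <- which(upper.tri(tsm) & tsm > ts_min, arr.ind = TRUE)
  data.frame(drug_id_1 = ids[sel[, 1]], drug_id_2 = ids[sel[, 2]],
             ts = tsm[sel], stringsAsFactors = FALSE)
}

#' Score and rank candidate drug pairs
#'
#' For every candidate pair the shared-neighbour statistic is computed from
#' the full neighbour sets in the cocktail network (`m` common neighbours,
#' `n1`, `n2` degrees, `N` network drugs). DCPred2/3 rank by ascending
#' p-value; DCPred1 ranks by descending TS. Ties are broken by descending
#' TS and then by the lexicographic pair id, so the order is a
#' deterministic total order independent of input row order.
#'
#' @param net A `cocktail_network` or igraph graph.
#' @param drugs A `drug_table`.
#' @param model `"dcpred1"`, `"dcpred2"` or `"dcpred3"`.
#' @param ts_min TS threshold for candidacy (strict).
#' @param n_levels ATC levels averaged in TS.
#' @param tail Use the upper-tail probability instead of the point mass.
#' @param exclude_pair_edge If `TRUE`, when a candidate pair is itself an
#'   edge, each drug's neighbour count is reduced by one so the pair's own
#'   edge does not inflate its score.
#' @param N Total drug count used in the statistic; defaults to the number
#'   of network nodes.
#' @param positives Optional character vector of pair keys
#'   (`"id1|id2"`, sorted) or 2-column matrix/data frame of pairs to label
#'   as known positives; defaults to the network's edges.
#' @return A `candidate_ranking` data frame: `rank`, `drug_id_1`,
#'   `drug_id_2`, `ts`, `m`, `n1`, `n2`, `p_value`, `known_positive`, with
#'   attributes `model` and `N`.
#' @export
rank_candidates <- function(net, drugs, model = c("dcpred2", "dcpred1", "dcpred3"),
                            ts_min = 0, n_levels = 3, tail = FALSE,
                            exclude_pair_edge = FALSE, N = NULL,
                            positives = NULL) {
  model <- match.arg(model)
  g <- as_cocktail_graph(net)
  cand <- candidate_pairs(g, drugs, model, ts_min, n_levels)
  if (!nrow(cand)) stop("no candidate pairs under model ", model, call. = FALSE)
  if (is.null(N)) N <- igraph::vcount(g)

  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  common <- adj %*% adj          # [i, j] = shared-neighbour count
  deg <- igraph::degree(g)
  i1 <- cand$drug_id_1; i2 <- cand$drug_id_2
  vnames <- rownames(adj)
  idx <- cbind(match(i1, vnames), match(i2, vnames))
  cand$m <- as.integer(common[idx])
  cand$n1 <- as.integer(deg[i1])
  cand$n2 <- as.integer(deg[i2])
  is_edge <- as.logical(adj[idx] > 0)
  if (exclude_pair_edge) {
    cand$n1 <- cand$n1 - as.integer(is_edge)
    cand$n2 <- cand$n2 - as.integer(is_edge)
  }
  cand$p_value <- shared_neighbor_pvalue(cand$m, cand$n1, cand$n2, N, tail = tail)

  if (is.null(positives)) {
    cand$known_positive <- is_edge
  } else {
    cand$known_positive <- pair_key(i1, i2) %in% as_pair_keys(positives)
  }

  key <- pair_key(i1, i2)
  ord <- if (model == "dcpred1") {
    order(-cand$ts, key)
  } else {
    order(cand$p_value, -cand$ts, key)
  }
  cand <- cand[ord, , drop = FALSE]
  cand <- cbind(rank = seq_len(nrow(cand)), cand)
  rownames(cand) <- NULL
  structure(cand, model = model, N = N,
            class = c("candidate_ranking", "data.frame"))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

as_pair_keys <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  pair_key(x[, 1], x[, 2])
}

#' @export
print.candidate_ranking <- function(x, ...) {
  cat("<candidate_ranking> model ", attr(x, "model"), ", N = ", attr(x, "N"),
      ": ", nrow(x), " candidate pairs, ", sum(x$known_positive),
      " known positives\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE,
                   digits = 6)
  if (nrow(x) > 10) cat("# ...", nrow(x) - 10, "more pairs\n")
  invisible(x)
}
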