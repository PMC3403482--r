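# ROC / AUC evaluation of ranked candidate lists.

ranking_scores <- function(ranking) {
  stopifnot(is.data.frame(ranking), "known_positive" %in% names(ranking))
  model <- attr(ranking, "model")
  if (identical(model, "dcpred1")) return(ranking$ts)
  if ("p_value" %in% names(ranking)) return(-ranking$p_value)
  if ("ts" %in% names(ranking)) return(ranking$ts)
  stop("ranking carries neither p_value nor ts scores", call. = FALSE)
}

#' ROC curve and AUC for a candidate ranking
#'
#' Sweeps the score threshold over a ranked candidate list: pairs at or
#' above a threshold are called positive, the rest negative. Score-tied
#' items cross the threshold together (ties are grouped, not broken), so
#' the curve is invariant to the ordering of tied rows; the AUC is the
#' trapezoid area, which with grouped ties equals the tie-corrected
#' rank-sum (Mann-Whitney) statistic — the probability that a random true
#' positive outscores a random negative, counting ties as half.
#'
#' @param ranking A `candidate_ranking` (or any data frame with a
#'   `known_positive` logical column and either `p_value` or `ts`), or a
#'   list with numeric `score` and logical `label` components.
#' @return An `evaluation_report`: `roc_points` (data frame `fpr`, `tpr`),
#'   `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(ranking) {
  if (is.list(ranking) && !is.data.frame(ranking) &&
      all(c("score", "label") %in% names(ranking))) {
    score <- ranking$score
    label <- as.logical(ranking$label)
  } else {
    score <- ranking_scores(ranking)
    label <- ranking$known_positive
  }
  n_pos <- sum(label); n_neg <- sum(!label)
  if (n_pos == 0 || n_neg == 0) {
    stop("need at least one positive and one negative label", call. = FALSE)
  }
  ord <- order(score, decreasing = TRUE)
  score <- score[ord]; label <- label[ord]
  # group tied scores: one ROC vertex per distinct score
  grp_last <- cumsum(rle(score)$lengths)
  tp <- cumsum(label)[grp_last]
  fp <- cumsum(!label)[grp_last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(roc_points = data.frame(fpr = fpr, tpr = tpr),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> AUC = %.4f (%d positives, %d negatives, %d ROC points)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$roc_points)))
  invisible(x)
}

#' Confusion-matrix metrics at rank cutoffs
#'
#' At cutoff `c`, the top `c` ranked pairs are predicted positive and the
#' rest negative; sensitivity, specificity and accuracy follow from the
#' resulting confusion matrix against the `known_positive` labels.
#'
#' @param ranking A `candidate_ranking` ordered by rank.
#' @param cutoffs Integer rank cutoffs; defaults to `0:nrow(ranking)`.
#' @return Data frame: `cutoff`, `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
threshold_metrics <- function(ranking, cutoffs = NULL) {
  stopifnot("known_positive" %in% names(ranking))
  label <- ranking$known_positive
  if ("rank" %in% names(ranking)) label <- label[order(ranking$rank)]
  n <- length(label)
  if (is.null(cutoffs)) cutoffs <- 0:n
  stopifnot(all(cutoffs >= 0 & cutoffs <= n))
  n_pos <- sum(label); n_neg <- n - n_pos
  cum_tp <- c(0, cumsum(label))
  tp <- cum_tp[cutoffs + 1]
  fp <- cutoffs - tp
  fn <- n_pos - tp
  tn <- n_neg - fp
  data.frame(cutoff = cutoffs, tp = tp, fp = fp, fn = fn, tn = tn,
             sensitivity = tp / n_pos, specificity = tn / n_neg,
             accuracy = (tp + tn) / n)
}

#' Held-out evaluation of a DCPred model
#'
#' Scoring known edges with a network that still contains them is
#' optimistic: the pair's own edge contributes to its endpoints'
#' neighbourhoods. This helper masks a fraction of edges, rebuilds the
#' ranking on the reduced network, and evaluates recovery of the masked
#' pairs (candidates that are masked edges are the positives; retained
#' edges are dropped from the evaluation set).
#'
#' @param net A `cocktail_network` or igraph graph.
#' @param drugs A `drug_table`.
#' @param model DCPred model tag.
#' @param holdout_frac Fraction of edges to mask.
#' @param seed Integer seed for the mask.
#' @param ... Passed on to [rank_candidates()].
#' @return List with `report` (an `evaluation_report`), `ranking`, and
#'   `masked` (the held-out edge pairs).
#' @export
holdout_evaluation <- function(net, drugs, model = "dcpred2",
                               holdout_frac = 0.2, seed = 1L, ...) {
  g <- as_cocktail_graph(net)
  m <- igraph::ecount(g)
  n_mask <- max(1L, floor(holdout_frac * m))
  mask <- withr::with_seed(seed, sample.int(m, n_mask))
  el <- igraph::as_edgelist(g)
  g_red <- igraph::delete_edges(g, mask)
  g_red <- igraph::delete_vertices(g_red, igraph::V(g_red)[igraph::degree(g_red) == 0])
  masked_keys <- pair_key(el[mask, 1], el[mask, 2])
  ranking <- rank_candidates(g_red, drugs, model = model,
                             positives = masked_keys, ...)
  kept_keys <- edge_keys_pipe(g_red)
  ranking_eval <- ranking[!(pair_key(ranking$drug_id_1, ranking$drug_id_2)
                            %in% kept_keys), , drop = FALSE]
  attr(ranking_eval, "model") <- attr(ranking, "model")
  list(report = roc_auc(ranking_eval), ranking = ranking,
       masked = masked_keys)
}

edge_keys_pipe <- function(g) {
  el <- igraph::as_edgelist(g)
  pair_key(el[, 1], el[, 2])
}

#' Planted-positive benchmark on a synthetic dataset
#'
#' Builds the cocktail network from a simulated dataset (whose generator
#' withheld a fraction of true pairs), ranks candidates with the withheld
#' pairs as the positives, and evaluates recovery on the non-edge
#' candidates (pairs already present as edges carry no prediction and are
#' excluded from the ROC).
#'
#' @param sim Output of [simulate_dataset()] (or a list with `drugs`,
#'   `combinations`, `planted`).
#' @param model DCPred model tag.
#' @param ... Passed on to [rank_candidates()].
#' @return List with `report` (an `evaluation_report`) and `ranking`.
#' @export
planted_benchmark <- function(sim, model = "dcpred2", ...) {
  net <- suppressMessages(build_cocktail_network(sim$combinations, sim$drugs))
  keys <- pair_key(sim$planted$drug_id_1, sim$planted$drug_id_2)
  ranking <- rank_candidates(net, sim$drugs, model = model,
                             positives = keys, ...)
  kept <- edge_keys_pipe(as_cocktail_graph(net))
  eval_rows <- ranking[!(pair_key(ranking$drug_id_1, ranking$drug_id_2)
                         %in% kept), , drop = FALSE]
  attr(eval_rows, "model") <- attr(ranking, "model")
  list(report = roc_auc(eval_rows), ranking = ranking)
}
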