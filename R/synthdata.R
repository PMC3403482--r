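# Deterministic generators for synthetic drugs, cocktail networks and PPIs.

# Level-1 letters deliberately outside the real ATC alphabet
# (A,B,C,D,G,H,J,L,M,N,P,R,S,V) so synthetic fixtures can never be mistaken
# for real codes.
.synthetic_atc_alphabet <- c("E", "F", "I", "K", "O", "Q",
                             "T", "U", "W", "X", "Y", "Z")

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate the statistical structure the analyses assume: a
#' scale-free combination network of modest mean degree (about 2.2 edges
#' per drug, the regime of curated combination databases), edges enriched
#' for therapeutically similar pairs, a handful of multi-member
#' combinations that split into pairwise cliques, and a small-world PPI
#' whose combination partners' targets sit close together.
#'
#' @param n_drugs Number of drugs (>= 4).
#' @param n_atc_classes Size of the synthetic level-1 ATC alphabet (<= 12).
#' @param class_probs Class sampling probabilities (default uniform).
#' @param codes_per_drug_probs Probabilities of a drug carrying 1, 2 or 3
#'   ATC codes.
#' @param degree_exponent Target exponent of the degree distribution.
#' @param mean_degree Target mean degree of the combination network.
#' @param ts_assortativity Probability an edge endpoint is drawn among
#'   drugs therapeutically similar to the other endpoint.
#' @param triangle_closure Closure edges added between similar co-neighbours
#'   of a shared partner, as a fraction of the base edge count; these are
#'   the "two similar drugs sharing a star neighbour get combined" events
#'   the predictor exploits.
#' @param multi_member_max Maximum number of 3-member combinations formed by
#'   merging triangles.
#' @param ineffective_fraction Extra non-effective records emitted (and
#'   expected to be discarded at load), as a fraction of effective ones.
#' @param planted_fraction Fraction of true pairs withheld from the emitted
#'   network and returned as evaluation positives.
#' @param ppi_proteins Number of proteins in the toy PPI (default
#'   `2 * n_drugs`).
#' @param ppi_nei,ppi_rewire_p Small-world lattice neighbourhood and rewiring
#'   probability.
#' @param ppi_score_min,ppi_score_max Confidence score range of emitted
#'   interactions.
#' @param targets_per_drug_max Each drug gets 1..this many targets.
#' @param partner_proximity Probability a combination pair's targets are
#'   placed within two hops of each other.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_drugs = 500,
                             n_atc_classes = 6,
                             class_probs = NULL,
                             codes_per_drug_probs = c(0.6, 0.3, 0.1),
                             degree_exponent = 2.1,
                             mean_degree = 2.2,
                             ts_assortativity = 0.8,
                             triangle_closure = 0.25,
                             multi_member_max = 10,
                             ineffective_fraction = 0.05,
                             planted_fraction = 0.1,
                             ppi_proteins = NULL,
                             ppi_nei = 2,
                             ppi_rewire_p = 0.1,
                             ppi_score_min = 700,
                             ppi_score_max = 999,
                             targets_per_drug_max = 2,
                             partner_proximity = 0.7) {
  stopifnot(n_drugs >= 4, n_atc_classes >= 1,
            n_atc_classes <= length(.synthetic_atc_alphabet),
            ts_assortativity >= 0, ts_assortativity <= 1,
            planted_fraction >= 0, planted_fraction <= 1,
            degree_exponent > 1)
  if (is.null(class_probs)) class_probs <- rep(1 / n_atc_classes, n_atc_classes)
  stopifnot(length(class_probs) == n_atc_classes,
            all(class_probs >= 0), abs(sum(class_probs) - 1) < 1e-8)
  if (is.null(ppi_proteins)) ppi_proteins <- 2L * n_drugs
  structure(as.list(environment()), class = "generator_config")
}

# One random level-5 code within a level-1 class of the synthetic hierarchy:
# two level-2 groups, two level-3 and two level-4 letters, four substances.
random_code_in_class <- function(class_letter) {
  paste0(class_letter,
         sprintf("%02d", sample.int(2, 1)),
         sample(c("A", "B"), 1), sample(c("A", "B"), 1),
         sprintf("%02d", sample.int(4, 1)))
}

#' Generate a synthetic drug table
#'
#' Each drug draws a primary therapeutic class from `class_probs` and 1-3
#' level-5 codes from the synthetic hierarchy (secondary codes stay within
#' the primary class with probability 0.7). Output is deterministic per
#' seed and parseable by the ATC machinery.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed.
#' @return A `drug_table` with attribute `primary_class`.
#' @export
generate_drugs <- function(cfg = generator_config(), seed = 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(seed, {
    alphabet <- .synthetic_atc_alphabet[seq_len(cfg$n_atc_classes)]
    primary <- sample(alphabet, cfg$n_drugs, replace = TRUE,
                      prob = cfg$class_probs)
    n_codes <- sample.int(length(cfg$codes_per_drug_probs), cfg$n_drugs,
                          replace = TRUE, prob = cfg$codes_per_drug_probs)
    codes <- lapply(seq_len(cfg$n_drugs), function(i) {
      cls <- c(primary[i], vapply(seq_len(n_codes[i] - 1L), function(j) {
        if (stats::runif(1) < 0.7) primary[i] else sample(alphabet, 1)
      }, character(1)))
      unique(vapply(cls, random_code_in_class, character(1)))
    })
    ids <- sprintf("SD%04d", seq_len(cfg$n_drugs))
    out <- drug_table(ids, name = paste0("synthetic_", ids), atc_codes = codes)
    attr(out, "primary_class") <- stats::setNames(primary, ids)
    out
  })
}

# drug-by-drug logical matrix: do two drugs share a level-1 class?
shares_class_matrix <- function(drugs) {
  sets <- lapply(drugs$atc_codes, atc_level_set, level = 1L)
  classes <- sort(unique(unlist(sets)))
  inc <- matrix(0L, nrow(drugs), length(classes),
                dimnames = list(drugs$drug_id, classes))
  for (i in seq_len(nrow(drugs))) inc[i, sets[[i]]] <- 1L
  tcrossprod(inc) > 0
}

#' Generate a synthetic cocktail network and combination table
#'
#' Draws a scale-free combination network by weighted endpoint sampling:
#' drug weights follow \eqn{w_i \propto i^{-1/(\gamma-1)}} so that expected
#' degrees follow a power law with exponent near `degree_exponent`. With
#' probability `ts_assortativity` the second endpoint is resampled among
#' drugs sharing a therapeutic class with the first, planting the
#' similarity enrichment the null-model test detects. Additional closure
#' edges join similar co-neighbours of a shared partner, creating the
#' shared-neighbour signal the ranking models exploit. A
#' `planted_fraction` of the true pairs is withheld from the emitted table
#' and returned as evaluation positives; some triangles are merged into
#' 3-member combinations and a few non-effective records are appended so
#' loaders have something to discard.
#'
#' @param cfg A [generator_config()].
#' @param drugs A `drug_table` from [generate_drugs()].
#' @param seed Integer seed.
#' @return List with `combinations` (a `combination_table`), `planted`
#'   (data frame `drug_id_1`, `drug_id_2` of withheld true pairs) and
#'   `edges` (the full true edge list before withholding).
#' @export
generate_cocktail_network <- function(cfg = generator_config(),
                                      drugs, seed = 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  drugs <- as_drug_table(drugs)
  n <- nrow(drugs)
  withr::with_seed(seed, {
    ids <- drugs$drug_id
    # degree weights detached from class membership via a random permutation
    w <- stats::setNames(sample(seq_len(n))^(-1 / (cfg$degree_exponent - 1)), ids)
    similar <- shares_class_matrix(drugs)
    n_edges <- round(cfg$mean_degree * n / 2)
    edge_set <- new.env(hash = TRUE, parent = emptyenv())
    edges <- matrix(character(), 0, 2)
    attempts <- 0L
    while (nrow(edges) < n_edges && attempts < 50L * n_edges) {
      attempts <- attempts + 1L
      u <- sample(ids, 1, prob = w)
      pool <- if (stats::runif(1) < cfg$ts_assortativity) {
        setdiff(ids[similar[u, ]], u)
      } else {
        setdiff(ids, u)
      }
      if (!length(pool)) next
      v <- if (length(pool) == 1) pool else sample(pool, 1, prob = w[pool])
      key <- pair_key(u, v)
      if (is.null(edge_set[[key]])) {
        edge_set[[key]] <- TRUE
        edges <- rbind(edges, sort(c(u, v)))
      }
    }
    # triangle closure between similar co-neighbours of a shared partner
    n_close <- round(cfg$triangle_closure * nrow(edges))
    deg_tab <- table(c(edges))
    added <- 0L; attempts <- 0L
    while (added < n_close && attempts < 50L * max(n_close, 1L)) {
      attempts <- attempts + 1L
      stars <- names(deg_tab)[deg_tab >= 2]
      if (!length(stars)) break
      s <- sample(stars, 1, prob = as.numeric(deg_tab[stars]))
      nb <- setdiff(unique(c(edges[edges[, 1] == s, 2],
                             edges[edges[, 2] == s, 1])), s)
      if (length(nb) < 2) next
      uv <- sample(nb, 2)
      if (!similar[uv[1], uv[2]]) next
      key <- pair_key(uv[1], uv[2])
      if (!is.null(edge_set[[key]])) next
      edge_set[[key]] <- TRUE
      edges <- rbind(edges, sort(uv))
      deg_tab <- table(c(edges))
      added <- added + 1L
    }
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]

    # withhold planted evaluation positives
    n_plant <- round(cfg$planted_fraction * nrow(edges))
    plant_idx <- sort(sample.int(nrow(edges), n_plant))
    planted <- data.frame(drug_id_1 = edges[plant_idx, 1],
                          drug_id_2 = edges[plant_idx, 2],
                          stringsAsFactors = FALSE)
    kept <- edges[setdiff(seq_len(nrow(edges)), plant_idx), , drop = FALSE]

    # merge a few triangles of kept edges into 3-member combinations
    g_kept <- igraph::graph_from_edgelist(kept, directed = FALSE)
    tri <- matrix(igraph::triangles(g_kept)$name, nrow = 3)
    members <- lapply(seq_len(nrow(kept)), function(i) kept[i, ])
    if (ncol(tri) && cfg$multi_member_max > 0) {
      kept_keys <- pair_key(kept[, 1], kept[, 2])
      used <- character()
      taken <- 0L
      for (j in sample.int(ncol(tri))) {
        trio <- sort(tri[, j])
        tri_keys <- pair_key(trio[c(1, 1, 2)], trio[c(2, 3, 3)])
        if (any(tri_keys %in% used) || taken >= cfg$multi_member_max) next
        used <- c(used, tri_keys)
        members <- members[!(pair_key(vapply(members, `[`, "", 1),
                                      vapply(members, `[`, "", 2))
                             %in% tri_keys)]
        members <- c(members, list(trio))
        taken <- taken + 1L
      }
    }
    members <- members[order(vapply(members, paste, "", collapse = "|"))]

    n_comb <- length(members)
    status <- sample(c("approved", "clinical", "preclinical"), n_comb,
                     replace = TRUE, prob = c(0.39, 0.33, 0.28))
    effective <- rep(TRUE, n_comb)
    # non-effective decoys: random pairs, to be discarded at load time
    n_bad <- round(cfg$ineffective_fraction * n_comb)
    if (n_bad > 0) {
      bad <- replicate(n_bad, sort(sample(ids, 2)), simplify = FALSE)
      members <- c(members, bad)
      status <- c(status, sample(c("clinical", "preclinical"), n_bad, TRUE))
      effective <- c(effective, rep(FALSE, n_bad))
    }
    combos <- combination_table(sprintf("SC%04d", seq_along(members)),
                                members, status, effective)
    list(combinations = combos, planted = planted,
         edges = data.frame(drug_id_1 = edges[, 1], drug_id_2 = edges[, 2],
                            stringsAsFactors = FALSE))
  })
}

#' Generate a toy PPI network and drug-target assignment
#'
#' Builds a small-world protein graph (Watts-Strogatz ring lattice with
#' rewiring), assigns each drug a small random target set, then pulls the
#' targets of combination partners together: with probability
#' `partner_proximity` one partner's first target is moved to within two
#' hops of the other's. Emitted scores all pass the default confidence
#' threshold.
#'
#' @param cfg A [generator_config()].
#' @param drugs A `drug_table`; its `targets` column is replaced.
#' @param combinations Optional `combination_table` whose effective pairs
#'   get proximal targets.
#' @param seed Integer seed.
#' @return List with `edges` (data frame `protein1`, `protein2`,
#'   `combined_score`) and `drugs` (the input table with targets filled).
#' @export
generate_ppi <- function(cfg = generator_config(), drugs,
                         combinations = NULL, seed = 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  drugs <- as_drug_table(drugs)
  withr::with_seed(seed, {
    np <- cfg$ppi_proteins
    g <- igraph::sample_smallworld(1, np, cfg$ppi_nei, cfg$ppi_rewire_p)
    g <- igraph::simplify(g)
    prot <- sprintf("SP%05d", seq_len(np))
    igraph::V(g)$name <- prot
    targets <- lapply(seq_len(nrow(drugs)), function(i) {
      sample(prot, sample.int(cfg$targets_per_drug_max, 1))
    })
    names(targets) <- drugs$drug_id
    if (!is.null(combinations)) {
      eff <- combinations[combinations$effective, , drop = FALSE]
      for (m in eff$members) {
        pairs <- utils::combn(m, 2)
        for (j in seq_len(ncol(pairs))) {
          if (stats::runif(1) >= cfg$partner_proximity) next
          anchor <- targets[[pairs[1, j]]][1]
          near <- igraph::ego(g, order = 2, nodes = anchor)[[1]]$name
          targets[[pairs[2, j]]][1] <- sample(near, 1)
        }
      }
    }
    drugs$targets <- unname(lapply(targets, unique))
    el <- igraph::as_edgelist(g)
    scores <- sample(seq(cfg$ppi_score_min, cfg$ppi_score_max),
                     nrow(el), replace = TRUE)
    ord <- order(el[, 1], el[, 2])
    list(edges = data.frame(protein1 = pmin(el[, 1], el[, 2]),
                            protein2 = pmax(el[, 1], el[, 2]),
                            combined_score = scores,
                            stringsAsFactors = FALSE)[ord, ],
         drugs = drugs)
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs the three generators from a single seed and optionally writes the
#' tables in the package's TSV dialects (plus the configuration as YAML)
#' to a directory, so simulated fixtures double as format-conformance
#' inputs for the readers.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer master seed; the three generators use `seed`,
#'   `seed + 1` and `seed + 2`.
#' @param out_dir Optional output directory (created if missing); writes
#'   `drugs.tsv`, `combos.tsv`, `ppi.tsv`, `planted.tsv`, `config.yaml`.
#' @return List with `drugs`, `combinations`, `planted`, `edges`,
#'   `ppi_edges`, `config`.
#' @export
simulate_dataset <- function(cfg = generator_config(), seed = 1L,
                             out_dir = NULL) {
  drugs <- generate_drugs(cfg, seed = seed)
  nc <- generate_cocktail_network(cfg, drugs, seed = seed + 1L)
  ppi <- generate_ppi(cfg, drugs, nc$combinations, seed = seed + 2L)
  out <- list(drugs = ppi$drugs, combinations = nc$combinations,
              planted = nc$planted, edges = nc$edges,
              ppi_edges = ppi$edges, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_drug_table(out$drugs, file.path(out_dir, "drugs.tsv"))
    write_combination_table(out$combinations, file.path(out_dir, "combos.tsv"))
    utils::write.table(out$ppi_edges, file.path(out_dir, "ppi.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$planted, file.path(out_dir, "planted.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg_plain <- unclass(cfg)
    yaml::write_yaml(c(cfg_plain, list(seed = seed)),
                     file.path(out_dir, "config.yaml"))
  }
  out
}
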