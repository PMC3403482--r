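# Readers and writers for the package's TSV dialects.
# All tables are UTF-8, tab-separated, header required, "#" comment lines
# ignored, semicolon as the intra-cell list separator.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, " file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

split_cell <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE),
         function(v) v[nzchar(trimws(v))])
}

#' Read a drug annotation table
#'
#' Expects columns `drug_id`, `name`, `atc_codes` (semicolon-separated
#' level-5 codes) and `targets` (semicolon-separated protein ids, may be
#' empty). Drugs without any ATC code cannot enter similarity analyses and
#' are dropped, with their ids recorded in the `"excluded_no_atc"`
#' attribute; malformed ATC codes raise a line-numbered error.
#'
#' @param path Path to a TSV file.
#' @return A `drug_table`; attribute `excluded_no_atc` lists dropped ids.
#' @export
read_drug_table <- function(path) {
  df <- read_tsv_checked(path, c("drug_id", "name", "atc_codes"), "drug")
  codes <- split_cell(df$atc_codes)
  for (i in seq_along(codes)) {
    bad <- codes[[i]][!grepl(.atc_pattern, codes[[i]])]
    if (length(bad)) {
      stop("malformed ATC code in ", path, ", data row ", i, " (drug ",
           df$drug_id[i], "): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  no_atc <- lengths(codes) == 0L
  excluded <- df$drug_id[no_atc]
  if (any(no_atc)) {
    message("dropped ", sum(no_atc), " drug(s) without ATC codes: ",
            paste(utils::head(excluded, 5), collapse = ", "))
  }
  targets <- if ("targets" %in% names(df)) {
    split_cell(df$targets)
  } else {
    rep(list(character()), nrow(df))
  }
  out <- drug_table(df$drug_id[!no_atc], df$name[!no_atc],
                    codes[!no_atc], targets[!no_atc])
  attr(out, "excluded_no_atc") <- excluded
  out
}

#' Write a drug annotation table
#' @param drugs A `drug_table`.
#' @param path Output TSV path.
#' @export
write_drug_table <- function(drugs, path) {
  drugs <- as_drug_table(drugs)
  df <- data.frame(drug_id = drugs$drug_id, name = drugs$name,
                   atc_codes = vapply(drugs$atc_codes, paste, "", collapse = ";"),
                   targets = vapply(drugs$targets, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a combination table
#'
#' Expects columns `combo_id`, `members` (semicolon-separated drug ids),
#' `status` and `effective` (`true`/`false`).
#'
#' @param path Path to a TSV file.
#' @return A `combination_table` (all rows; efficacy filtering happens in
#'   [load_dataset()] / [build_cocktail_network()]).
#' @export
read_combination_table <- function(path) {
  df <- read_tsv_checked(path, c("combo_id", "members", "status", "effective"),
                         "combination")
  eff <- tolower(df$effective) %in% c("true", "t", "1", "yes")
  combination_table(df$combo_id, split_cell(df$members), df$status, eff)
}

#' Write a combination table
#' @param combos A `combination_table`.
#' @param path Output TSV path.
#' @export
write_combination_table <- function(combos, path) {
  df <- data.frame(combo_id = combos$combo_id,
                   members = vapply(combos$members, paste, "", collapse = ";"),
                   status = combos$status,
                   effective = tolower(as.character(combos$effective)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a STRING-style PPI edge table
#'
#' Three columns: `protein1`, `protein2`, `combined_score` (integer).
#' Malformed (non-numeric) scores raise a line-numbered error. Filtering by
#' score happens in [load_ppi()].
#'
#' @param path Path to a TSV file.
#' @return Data frame with the three columns.
#' @export
read_ppi_table <- function(path) {
  df <- read_tsv_checked(path, c("protein1", "protein2", "combined_score"),
                         "PPI")
  score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(is.na(score) & nzchar(df$combined_score))
  if (length(bad)) {
    stop("non-numeric combined_score in ", path, ", data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  df$combined_score <- score
  df
}

#' Load and filter a drugs + combinations dataset
#'
#' Applies the curation rules in one place: drugs without ATC codes are
#' dropped, non-effective combinations are discarded, and combinations
#' with an unannotated member are excluded. Returns the retained tables
#' with a full exclusion report.
#'
#' @param drugs_path Path to the drug annotation TSV.
#' @param combos_path Path to the combination TSV.
#' @return List with `drugs`, `combinations` (retained, effective only)
#'   and `exclusions` (named counts: `combos_input`, `dropped_ineffective`,
#'   `dropped_unannotated_member`, `drugs_without_atc`, `retained`,
#'   `pairs_after_split`).
#' @export
load_dataset <- function(drugs_path, combos_path) {
  drugs <- read_drug_table(drugs_path)
  combos <- read_combination_table(combos_path)
  n_in <- nrow(combos)
  eff <- combos[combos$effective, , drop = FALSE]
  known <- drugs$drug_id
  has_all <- vapply(eff$members, function(m) all(m %in% known), logical(1))
  retained <- eff[has_all, , drop = FALSE]
  n_pairs <- sum(vapply(retained$members,
                        function(m) choose(length(m), 2), numeric(1)))
  report <- c(combos_input = n_in,
              dropped_ineffective = n_in - nrow(eff),
              dropped_unannotated_member = sum(!has_all),
              drugs_without_atc = length(attr(drugs, "excluded_no_atc")),
              retained = nrow(retained),
              pairs_after_split = as.integer(n_pairs))
  message("dataset: retained ", report[["retained"]], "/", n_in,
          " combinations (", report[["dropped_ineffective"]],
          " non-effective, ", report[["dropped_unannotated_member"]],
          " with unannotated members dropped); ",
          report[["pairs_after_split"]], " pairs after splitting")
  list(drugs = drugs, combinations = retained, exclusions = report)
}

#' Export a cocktail network
#'
#' Writes a two-column edge TSV (with an edge TS attribute when a drug
#' table is supplied) and, optionally, GraphML with node attributes
#' `degree`, `star`, `hub` and edge attribute `ts`.
#'
#' @param net A `cocktail_network` or igraph graph.
#' @param edge_path Output TSV path.
#' @param graphml_path Optional GraphML output path.
#' @param drugs Optional `drug_table` used to annotate edges with TS.
#' @param n_levels ATC levels averaged in TS.
#' @return Invisibly, the edge data frame written.
#' @export
write_cocktail_network <- function(net, edge_path, graphml_path = NULL,
                                   drugs = NULL, n_levels = 3) {
  g <- as_cocktail_graph(net)
  el <- igraph::as_edgelist(g)
  df <- data.frame(drug_id_1 = pmin(el[, 1], el[, 2]),
                   drug_id_2 = pmax(el[, 1], el[, 2]),
                   stringsAsFactors = FALSE)
  if (!is.null(drugs)) {
    tsm <- ts_matrix(drugs, n_levels)
    df$ts <- tsm[as.matrix(df[, 1:2])]
  }
  df <- df[order(df$drug_id_1, df$drug_id_2), , drop = FALSE]
  utils::write.table(df, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(graphml_path)) {
    deg <- igraph::degree(g)
    igraph::V(g)$degree <- as.numeric(deg)
    igraph::V(g)$star <- as.character(deg >= 2)
    igraph::V(g)$hub <- as.character(deg >= 7)
    if (!is.null(drugs)) {
      tsm <- ts_matrix(drugs, n_levels)
      igraph::E(g)$ts <- tsm[igraph::as_edgelist(g)]
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(df)
}

#' Write a candidate ranking
#'
#' @param ranking A `candidate_ranking`.
#' @param path Output TSV path, mirroring the prediction-table layout:
#'   rank, the two drug ids, TS, the shared-neighbour counts and p-value,
#'   and the known-positive flag.
#' @export
write_ranking <- function(ranking, path) {
  df <- as.data.frame(ranking)
  df$known_positive <- tolower(as.character(df$known_positive))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a candidate ranking written by [write_ranking()]
#' @param path TSV path.
#' @return A `candidate_ranking` data frame.
#' @export
read_ranking <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  df$known_positive <- tolower(as.character(df$known_positive)) %in%
    c("true", "t", "1", "yes")
  class(df) <- c("candidate_ranking", "data.frame")
  df
}
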