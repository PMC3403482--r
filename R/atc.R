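# ATC codes and therapeutic similarity.

# Prefix length of each ATC hierarchy level (WHO standard): level 1 is the
# anatomical main group (1 char), level 5 the chemical substance (7 chars).
.atc_level_widths <- c(1L, 3L, 4L, 5L, 7L)

.atc_pattern <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"

#' Validate level-5 ATC codes
#'
#' Checks that each code is a syntactically valid 7-character level-5 ATC
#' code (letter, two digits, two letters, two digits).
#'
#' @param codes Character vector of candidate codes.
#' @return The validated character vector, invisibly unchanged.
#' @examples
#' validate_atc_codes(c("C03AA03", "N02BA01"))
#' @export
validate_atc_codes <- function(codes) {
  bad <- which(!grepl(.atc_pattern, codes))
  if (length(bad)) {
    stop("malformed ATC code(s) at position(s) ", paste(bad, collapse = ", "),
         ": ", paste(codes[bad], collapse = ", "), call. = FALSE)
  }
  invisible(codes)
}

#' Level-k prefix set of a drug's ATC codes
#'
#' A drug may carry several level-5 ATC codes; the level-`k` set is the set
#' of distinct `k`-level prefixes over all of them (prefix widths 1, 3, 4,
#' 5 and 7 characters for levels 1 to 5).
#'
#' @param codes Character vector of level-5 ATC codes for one drug.
#' @param level Integer hierarchy level, 1 to 5.
#' @return Character vector of distinct level-`k` prefixes.
#' @examples
#' atc_level_set(c("A01AB02", "C03AA03"), 1)
#' atc_level_set("C03AA03", 3)
#' @export
atc_level_set <- function(codes, level) {
  if (length(level) != 1L || is.na(level) || level < 1 || level > 5 ||
      level != as.integer(level)) {
    stop("'level' must be a single integer between 1 and 5", call. = FALSE)
  }
  unique(substr(codes, 1L, .atc_level_widths[[level]]))
}

#' Level-k therapeutic similarity between two drugs
#'
#' The Jaccard index of the two drugs' level-`k` ATC prefix sets:
#' \eqn{S_k = |A_k \cap B_k| / |A_k \cup B_k|}.
#'
#' @param codes1,codes2 Character vectors of level-5 ATC codes (non-empty).
#' @param level Hierarchy level, 1 to 5.
#' @return Similarity in \[0, 1\].
#' @examples
#' level_similarity("C03AA03", "C03AA01", 2)
#' @export
level_similarity <- function(codes1, codes2, level) {
  if (!length(codes1) || !length(codes2)) {
    stop("both drugs must have at least one ATC code", call. = FALSE)
  }
  a <- atc_level_set(codes1, level)
  b <- atc_level_set(codes2, level)
  length(intersect(a, b)) / length(union(a, b))
}

#' Therapeutic similarity (TS) between two drugs
#'
#' The mean of the level-wise Jaccard similarities over the first
#' `n_levels` ATC levels:
#' \eqn{TS = \frac{1}{n}\sum_{k=1}^{n} S_k}. The default `n_levels = 3`
#' averages the anatomical, therapeutic and pharmacological levels; level 5
#' is rarely informative because few drug pairs share a full code.
#'
#' @param codes1,codes2 Character vectors of level-5 ATC codes.
#' @param n_levels Number of levels to average over, 1 to 5.
#' @return TS in \[0, 1\]; symmetric in the two drugs.
#' @examples
#' therapeutic_similarity(c("A01AB02", "C03AA03"), "C03BB01")
#' @export
therapeutic_similarity <- function(codes1, codes2, n_levels = 3) {
  if (length(n_levels) != 1L || n_levels < 1 || n_levels > 5) {
    stop("'n_levels' must be between 1 and 5", call. = FALSE)
  }
  mean(vapply(seq_len(n_levels), function(k) {
    level_similarity(codes1, codes2, k)
  }, numeric(1)))
}

#' Pairwise therapeutic-similarity matrix
#'
#' Computes TS for every drug pair in a drug table at once. Per level, drugs
#' are expanded into a sparse drug-by-prefix incidence matrix; pairwise
#' intersection sizes come from its cross-product and union sizes from the
#' set-size sums, so the cost is far below looping over pairs.
#'
#' @param drugs A `drug_table` (see [drug_table()]).
#' @param n_levels Number of ATC levels to average over.
#' @return Symmetric numeric matrix with drug ids as dimnames; unit diagonal.
#' @export
ts_matrix <- function(drugs, n_levels = 3) {
  drugs <- as_drug_table(drugs)
  n <- nrow(drugs)
  acc <- matrix(0, n, n, dimnames = list(drugs$drug_id, drugs$drug_id))
  for (k in seq_len(n_levels)) {
    sets <- lapply(drugs$atc_codes, atc_level_set, level = k)
    prefixes <- unique(unlist(sets, use.names = FALSE))
    inc <- Matrix::sparseMatrix(
      i = rep.int(seq_len(n), lengths(sets)),
      j = match(unlist(sets, use.names = FALSE), prefixes),
      x = 1, dims = c(n, length(prefixes))
    )
    inter <- as.matrix(Matrix::tcrossprod(inc))
    sizes <- lengths(sets)
    uni <- outer(sizes, sizes, "+") - inter
    acc <- acc + inter / uni
  }
  acc / n_levels
}
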