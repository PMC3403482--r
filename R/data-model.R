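# Core tabular containers: drug annotations and combination records.

#' Construct a drug annotation table
#'
#' A `drug_table` is a data frame with one row per drug and columns
#' `drug_id`, `name`, `atc_codes` (list column of level-5 ATC code vectors)
#' and `targets` (list column of protein ids, possibly empty). Drugs without
#' any ATC code cannot be scored for therapeutic similarity and are rejected.
#'
#' @param drug_id Character vector of unique drug identifiers.
#' @param name Character vector of drug names (defaults to `drug_id`).
#' @param atc_codes List of character vectors, one non-empty vector of valid
#'   level-5 ATC codes per drug.
#' @param targets List of character vectors of target protein ids; may be
#'   empty vectors.
#' @return A data frame of class `drug_table`.
#' @examples
#' drug_table(c("d1", "d2"), atc_codes = list("C03AA03", c("C03AA01", "N02BA01")))
#' @export
drug_table <- function(drug_id, name = drug_id, atc_codes, targets = NULL) {
  drug_id <- as.character(drug_id)
  if (anyDuplicated(drug_id)) {
    stop("duplicated drug_id: ",
         paste(unique(drug_id[duplicated(drug_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.list(atc_codes) || length(atc_codes) != length(drug_id)) {
    stop("'atc_codes' must be a list with one entry per drug", call. = FALSE)
  }
  empty <- which(lengths(atc_codes) == 0L)
  if (length(empty)) {
    stop("drug(s) without ATC codes rejected: ",
         paste(drug_id[empty], collapse = ", "), call. = FALSE)
  }
  validate_atc_codes(unlist(atc_codes, use.names = FALSE))
  if (is.null(targets)) targets <- rep(list(character()), length(drug_id))
  df <- data.frame(drug_id = drug_id, name = as.character(name),
                   stringsAsFactors = FALSE)
  df$atc_codes <- lapply(atc_codes, as.character)
  df$targets <- lapply(targets, as.character)
  class(df) <- c("drug_table", "data.frame")
  df
}

#' Coerce to a drug table
#'
#' @param x A `drug_table`, or a data frame with the same columns.
#' @return A validated `drug_table`.
#' @export
as_drug_table <- function(x) {
  if (inherits(x, "drug_table")) return(x)
  stopifnot(is.data.frame(x), all(c("drug_id", "atc_codes") %in% names(x)))
  drug_table(x$drug_id,
             name = if ("name" %in% names(x)) x$name else x$drug_id,
             atc_codes = x$atc_codes,
             targets = if ("targets" %in% names(x)) x$targets else NULL)
}

# Named ATC code list keyed by drug id, the internal lookup most analyses use.
atc_lookup <- function(drugs) {
  drugs <- as_drug_table(drugs)
  stats::setNames(drugs$atc_codes, drugs$drug_id)
}

target_lookup <- function(drugs) {
  drugs <- as_drug_table(drugs)
  stats::setNames(drugs$targets, drugs$drug_id)
}

#' Construct a combination record table
#'
#' One row per drug combination: `combo_id`, `members` (list column of two
#' or more distinct drug ids), `status` (one of `approved`, `clinical`,
#' `preclinical`) and `effective` (logical). Loader front ends drop
#' non-effective records before network construction; the constructor only
#' enforces structural validity.
#'
#' @param combo_id Character vector of combination identifiers.
#' @param members List of character vectors of member drug ids (each of
#'   length at least 2, with distinct entries).
#' @param status Character vector of development statuses.
#' @param effective Logical vector, `TRUE` for effective combinations.
#' @return A data frame of class `combination_table`.
#' @export
combination_table <- function(combo_id, members,
                              status = "approved", effective = TRUE) {
  combo_id <- as.character(combo_id)
  if (anyDuplicated(combo_id)) stop("duplicated combo_id", call. = FALSE)
  members <- lapply(members, as.character)
  bad <- which(lengths(members) < 2L |
                 vapply(members, anyDuplicated, integer(1)) > 0L)
  if (length(bad)) {
    stop("combination(s) with fewer than 2 distinct members: ",
         paste(combo_id[bad], collapse = ", "), call. = FALSE)
  }
  status <- rep_len(as.character(status), length(combo_id))
  ok <- status %in% c("approved", "clinical", "preclinical")
  if (!all(ok)) {
    stop("unknown status value(s): ",
         paste(unique(status[!ok]), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(combo_id = combo_id, status = status,
                   effective = rep_len(as.logical(effective), length(combo_id)),
                   stringsAsFactors = FALSE)
  df$members <- members
  df <- df[, c("combo_id", "members", "status", "effective")]
  class(df) <- c("combination_table", "data.frame")
  df
}

#' @export
print.drug_table <- function(x, ...) {
  cat("<drug_table> ", nrow(x), " drugs, ",
      length(unique(unlist(x$atc_codes))), " distinct ATC codes, ",
      sum(lengths(x$targets) > 0), " drugs with targets\n", sep = "")
  print.data.frame(utils::head(transform(
    as.data.frame(x),
    atc_codes = vapply(atc_codes, paste, "", collapse = ";"),
    targets = vapply(targets, paste, "", collapse = ";")
  ), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("# ...", nrow(x) - 6, "more drugs\n")
  invisible(x)
}

#' @export
print.combination_table <- function(x, ...) {
  cat("<combination_table> ", nrow(x), " combinations (",
      sum(x$effective), " effective; ",
      sum(lengths(x$members) > 2L), " with >2 members)\n", sep = "")
  invisible(x)
}
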