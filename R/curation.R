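#' Prognosis keyword screen for literature annotations
#'
#' Tests free-text gene annotations (GeneRIF-style short descriptions) against
#' the boolean keyword pattern used to flag prognosis-related cancer studies:
#' the text must contain at least one prognosis term (*prognosis*,
#' *prognostic*) **and** at least one malignancy term (*cancer*, *tumour*,
#' *tumor*, *carcinoma*). Matching is case-insensitive and on whole words, so
#' derived forms such as "prognostically" or "carcinomas" do not count (see
#' [flag_substring_near_misses()] to surface them for manual review).
#'
#' Both British and American spellings of *tumour* are accepted: curated
#' literature databases mix the two.
#'
#' @param description Character vector of free-text descriptions. `NA` and
#'   empty strings return `FALSE`.
#'
#' @return Logical vector, one element per description.
#' @export
#' @examples
#' matches_prognosis_pattern(c(
#'   "High EZH2 predicts poor prognosis in ovarian cancer",
#'   "Gene regulates mitotic spindle assembly in yeast"
#' ))
matches_prognosis_pattern <- function(description) {
  if (length(description) == 0L) {
    return(logical(0))
  }
  stopifnot(is.character(description) || all(is.na(description)))
  x <- as.character(description)
  prog <- grepl("\\b(prognosis|prognostic)\\b", x, ignore.case = TRUE, perl = TRUE)
  canc <- grepl("\\b(cancer|tumour|tumor|carcinoma)\\b", x,
    ignore.case = TRUE, perl = TRUE
  )
  out <- prog & canc
  out[is.na(x)] <- FALSE
  out
}

#' Flag substring-only keyword near misses
#'
#' Identifies descriptions that fail the whole-word prognosis pattern but
#' would pass under substring matching (e.g. "prognostically ...
#' carcinomas"). In a live curation these go to manual review;
#' [curate_prognosis_genes()] counts them and reports the tally.
#'
#' @inheritParams matches_prognosis_pattern
#' @return Logical vector: `TRUE` for substring-only near misses.
#' @export
flag_substring_near_misses <- function(description) {
  x <- as.character(description)
  whole <- matches_prognosis_pattern(x)
  sub_prog <- grepl("(prognosis|prognostic)", x, ignore.case = TRUE)
  sub_canc <- grepl("(cancer|tumour|tumor|carcinoma)", x, ignore.case = TRUE)
  loose <- sub_prog & sub_canc
  loose[is.na(x)] <- FALSE
  !whole & loose
}

#' Tabulate prognosis-related genes from literature records
#'
#' Screens a table of literature annotation records with
#' [matches_prognosis_pattern()] and tabulates, per gene, the distinct PubMed
#' IDs of matching records. Duplicate (gene, PubMed ID) pairs collapse, so
#' `study_count` is the number of distinct supporting studies. Records that
#' match only under substring (not whole-word) matching are excluded but
#' counted and reported via a message and the `n_near_miss` attribute, because
#' in a real curation they would go to manual review.
#'
#' @param records Data frame with columns `gene_symbol`, `pubmed_id`,
#'   `description`. Rows with a missing/empty gene symbol or PubMed ID are
#'   skipped with a warning.
#'
#' @return A tibble with columns `gene_symbol`, `study_count`, `pubmed_ids`
#'   (comma-joined, sorted), one row per retained gene, sorted by descending
#'   `study_count` then symbol. Attributes `n_skipped` (malformed rows) and
#'   `n_near_miss` (substring-only matches) record screening side information.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   gene_symbol = c("EZH2", "EZH2", "YFG1"),
#'   pubmed_id = c("1", "2", "3"),
#'   description = c(
#'     "EZH2 predicts poor prognosis in ovarian cancer",
#'     "prognostic marker in colorectal tumour",
#'     "regulates spindle assembly"
#'   )
#' )
#' curate_prognosis_genes(recs)
curate_prognosis_genes <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("gene_symbol", "pubmed_id", "description")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0L) {
    stop("`records` lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  records <- tibble::as_tibble(records)

  bad <- is.na(records$gene_symbol) | records$gene_symbol == "" |
    is.na(records$pubmed_id) | records$pubmed_id == ""
  n_skipped <- sum(bad)
  if (n_skipped > 0L) {
    warning(n_skipped, " record(s) with missing gene symbol or PubMed ID skipped",
      call. = FALSE
    )
    records <- records[!bad, , drop = FALSE]
  }

  hit <- matches_prognosis_pattern(records$description)
  n_near_miss <- sum(flag_substring_near_misses(records$description))
  if (n_near_miss > 0L) {
    message(
      n_near_miss,
      " record(s) matched keywords only as substrings; excluded, flagged for review"
    )
  }

  out <- records[hit, c("gene_symbol", "pubmed_id")] |>
    dplyr::distinct() |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(
      study_count = dplyr::n(),
      pubmed_ids = paste(sort(.data$pubmed_id), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$study_count), .data$gene_symbol)

  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_near_miss") <- n_near_miss
  out
}
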