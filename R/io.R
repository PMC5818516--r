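#' Read literature annotation records
#'
#' Reads a tab-separated table of GeneRIF-style records with columns
#' `gene_symbol`, `pubmed_id`, `description`. Lines starting with `#` are
#' treated as comments.
#'
#' @param path Path to the TSV file.
#' @return A tibble of records.
#' @export
read_literature_tsv <- function(path) {
  x <- readr::read_tsv(path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  need <- c("gene_symbol", "pubmed_id", "description")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    stop("literature file lacks column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  x
}

#' Read a CNV call table (long or wide)
#'
#' Reads per-gene per-sample copy-number calls. Two dialects are
#' auto-detected from the header: the long format with columns `gene`,
#' `sample`, `call` (and optionally `cohort`), and the wide format with a
#' leading `gene` column and one column per sample holding the calls
#' (`GAIN`/`LOSS`/`NEUTRAL`). Wide input is pivoted to long; cohort labels
#' can then be supplied via `cohorts`, a named vector `sample -> cohort`.
#'
#' @param path Path to the TSV file (`#` comments ignored).
#' @param cohorts Optional named character vector mapping sample IDs to
#'   cohort labels, used (and required) only to attach cohorts to wide input.
#' @return A long-format tibble `gene`, `sample`, `call`[, `cohort`].
#' @export
read_cnv_calls <- function(path, cohorts = NULL) {
  x <- readr::read_tsv(path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (all(c("gene", "sample", "call") %in% names(x))) {
    return(validate_cnv_calls(x))
  }
  if (names(x)[1L] != "gene") {
    stop("CNV file is neither long (gene/sample/call columns) nor wide ",
      "(leading `gene` column)",
      call. = FALSE
    )
  }
  long <- tidyr::pivot_longer(x, -"gene",
    names_to = "sample", values_to = "call"
  )
  if (!is.null(cohorts)) {
    unmapped <- setdiff(unique(long$sample), names(cohorts))
    if (length(unmapped) > 0L) {
      stop("cohort map lacks ", length(unmapped), " sample(s)", call. = FALSE)
    }
    long$cohort <- unname(cohorts[long$sample])
  }
  validate_cnv_calls(long)
}

#' Read a wide expression matrix
#'
#' Reads a genes-by-samples expression table (leading `gene` column, one
#' column per sample, continuous values) and returns it in long format as
#' consumed by [expression_zscores()].
#'
#' @param path Path to the TSV file (`#` comments ignored).
#' @return A long tibble `gene`, `sample`, `expr`.
#' @export
read_expression_tsv <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (names(x)[1L] != "gene") {
    stop("expression file must have a leading `gene` column", call. = FALSE)
  }
  tidyr::pivot_longer(x, -"gene", names_to = "sample", values_to = "expr")
}

#' Read the reference-sample sidecar
#'
#' Reads the one-column table (`sample`) designating the reference sample
#' set used for Z-scoring.
#'
#' @param path Path to the TSV file.
#' @return Character vector of reference sample IDs.
#' @export
read_reference_samples <- function(path) {
  x <- readr::read_tsv(path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!"sample" %in% names(x)) {
    stop("reference-sample file lacks a `sample` column", call. = FALSE)
  }
  unique(x$sample)
}

#' Read a clinical endpoint table
#'
#' Reads survival endpoints: `sample`, `os_months` (overall survival in
#' months, > 0) and `os_event` (1 = death observed, 0 = censored).
#'
#' @param path Path to the TSV file.
#' @return A tibble of clinical records.
#' @export
read_clinical_tsv <- function(path) {
  x <- readr::read_tsv(path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      sample = readr::col_character(),
      os_months = readr::col_double(),
      os_event = readr::col_integer()
    )
  )
  need <- c("sample", "os_months", "os_event")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    stop("clinical file lacks column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  x
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields — set name,
#' description, then member gene symbols. Parsing is delegated to
#' [fgsea::gmtPathways()].
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (set name -> members).
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gene_sets, path) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "synthetic gene set", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction-network edge list
#'
#' Reads a tab-separated edge list with columns `gene_a`, `gene_b` and an
#' optional `weight` column.
#'
#' @param path Path to the TSV file (`#` comments ignored).
#' @return A tibble edge list.
#' @export
read_edge_list <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(x))) {
    stop("edge list lacks `gene_a`/`gene_b` columns", call. = FALSE)
  }
  x
}
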