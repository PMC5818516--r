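#' Hypergeometric gene-set over-representation analysis
#'
#' Tests a query gene list for over-representation in each set of a
#' collection using the upper-tail hypergeometric probability
#' `P(X >= k | N, K, n)`, where `N` is the universe size, `K` the set size,
#' `n` the query size and `k` the observed overlap — equivalently a one-sided
#' Fisher exact test on the 2x2 membership table. P-values are adjusted
#' across all tested sets with the Benjamini-Hochberg step-up procedure.
#'
#' Query genes outside the universe are dropped with a warning; set members
#' outside the universe are ignored, and sets left empty by that restriction
#' are not tested.
#'
#' @param query Character vector of gene symbols to test.
#' @param gene_sets Named list of character vectors (set name -> members),
#'   e.g. from [read_gmt()].
#' @param universe Character vector of all scorable genes. The query and
#'   every set are restricted to it.
#'
#' @return A tibble with one row per tested set, sorted by adjusted then raw
#'   p-value: `set`, `k` (overlap), `K` (set size), `n` (query size), `N`
#'   (universe size), `p`, `p_adj`, `overlap_genes` (comma-joined).
#' @export
#' @examples
#' sets <- list(planted = c("A", "B", "C"), decoy = c("D", "E"))
#' enrich_gene_sets(c("A", "B"), sets, universe = LETTERS[1:10])
enrich_gene_sets <- function(query, gene_sets, universe) {
  stopifnot(is.character(query), is.list(gene_sets), is.character(universe))
  if (is.null(names(gene_sets)) || any(names(gene_sets) == "")) {
    stop("`gene_sets` must be a named list", call. = FALSE)
  }
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the universe dropped",
      call. = FALSE
    )
    query <- intersect(query, universe)
  }
  if (length(query) == 0L) {
    stop("query is empty after restriction to the universe", call. = FALSE)
  }

  members <- purrr::map(gene_sets, ~ intersect(unique(.x), universe))
  members <- members[lengths(members) > 0L]
  if (length(members) == 0L) {
    stop("no gene set has members inside the universe", call. = FALSE)
  }

  N <- length(universe)
  n <- length(query)
  res <- purrr::imap(members, function(mem, nm) {
    K <- length(mem)
    hits <- intersect(query, mem)
    k <- length(hits)
    tibble::tibble(
      set = nm, k = k, K = K, n = n, N = N,
      p = hypergeom_upper_tail(k, N, K, n),
      overlap_genes = paste(sort(hits), collapse = ",")
    )
  }) |>
    purrr::list_rbind()

  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res |>
    dplyr::relocate("p_adj", .after = "p") |>
    dplyr::arrange(.data$p_adj, .data$p, .data$set)
}

# Upper-tail hypergeometric probability P(X >= k) for overlap k between a
# query of size n and a set of size K drawn from a universe of size N.
hypergeom_upper_tail <- function(k, N, K, n) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= K, N >= n, k <= min(K, n))
  if (k == 0L) {
    return(1)
  }
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}
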