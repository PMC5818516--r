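#' Seed-gene neighborhood of an interaction network
#'
#' Extracts from a gene-interaction network the subnetwork induced by a set
#' of seed genes plus their strongest linker genes: the non-seed neighbors
#' ranked by how many seed genes they connect to (ties broken
#' lexicographically by symbol, so results are deterministic). Edges are
#' treated as undirected and unweighted; self-loops are removed and duplicate
#' edges collapsed before any counting. A weight column, if present, is
#' carried through to the output edge list untouched.
#'
#' @param edges Data frame edge list with columns `gene_a`, `gene_b` and
#'   optionally `weight`. See [read_edge_list()].
#' @param seeds Character vector of seed gene symbols. Seeds absent from the
#'   network are dropped with a warning; if none is present, an error.
#' @param max_linkers Maximum number of linker genes to keep (default 20).
#'
#' @return An object of class `gene_neighborhood`: a list with `edges` (the
#'   induced subnetwork edge list tibble), `seeds` (those present), `linkers`
#'   (ranked character vector) and `linker_ranking` (tibble `gene`,
#'   `n_seed_connections`). Use [degree_table()] for within-subnetwork
#'   degrees.
#' @export
#' @examples
#' edges <- tibble::tibble(
#'   gene_a = c("A", "A", "C"),
#'   gene_b = c("B", "C", "D")
#' )
#' network_neighborhood(edges, seeds = "A", max_linkers = 2)
network_neighborhood <- function(edges, seeds, max_linkers = 20) {
  g <- clean_graph(edges)
  stopifnot(is.character(seeds), length(seeds) > 0L, max_linkers >= 0)

  present <- intersect(seeds, igraph::V(g)$name)
  absent <- setdiff(seeds, present)
  if (length(absent) > 0L) {
    warning(
      length(absent), " seed gene(s) absent from the network: ",
      paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  if (length(present) == 0L) {
    stop("no seed gene is present in the network", call. = FALSE)
  }

  # rank non-seed genes by their number of distinct seed neighbors, counted
  # on the simplified (undirected, de-duplicated) edge list
  edf <- igraph::as_data_frame(g, what = "edges")
  incident <- dplyr::bind_rows(
    tibble::tibble(gene = edf$to, seed = edf$from),
    tibble::tibble(gene = edf$from, seed = edf$to)
  ) |>
    dplyr::filter(.data$seed %in% .env$present, !.data$gene %in% .env$present)
  ranking <- incident |>
    dplyr::distinct() |>
    dplyr::count(.data$gene, name = "n_seed_connections") |>
    dplyr::arrange(dplyr::desc(.data$n_seed_connections), .data$gene)
  linkers <- utils::head(ranking$gene, as.integer(max_linkers))

  keep <- c(present, linkers)
  sub <- igraph::induced_subgraph(g, keep)
  sub_edges <- igraph::as_data_frame(sub, what = "edges")
  names(sub_edges)[1:2] <- c("gene_a", "gene_b")

  structure(
    list(
      edges = tibble::as_tibble(sub_edges),
      seeds = sort(present),
      linkers = linkers,
      linker_ranking = ranking
    ),
    class = "gene_neighborhood"
  )
}

#' @export
print.gene_neighborhood <- function(x, ...) {
  cat(
    "<gene_neighborhood> ", length(x$seeds), " seed(s), ",
    length(x$linkers), " linker(s), ", nrow(x$edges), " edge(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Within-subnetwork degree table
#'
#' Counts each gene's connections inside a neighborhood subnetwork (or any
#' edge list) and ranks genes by descending degree, ties broken by symbol.
#' Genes known to the subnetwork but without edges appear with degree 0.
#'
#' @param x A `gene_neighborhood` object or a data frame edge list with
#'   columns `gene_a`, `gene_b`.
#'
#' @return A tibble `gene`, `degree`, sorted by descending degree then
#'   symbol.
#' @export
degree_table <- function(x) {
  if (inherits(x, "gene_neighborhood")) {
    nodes <- union(c(x$seeds, x$linkers), c(x$edges$gene_a, x$edges$gene_b))
    edges <- x$edges
  } else {
    stopifnot(is.data.frame(x), all(c("gene_a", "gene_b") %in% names(x)))
    edges <- x
    nodes <- union(edges$gene_a, edges$gene_b)
  }
  g <- clean_graph(edges, nodes = nodes)
  deg <- igraph::degree(g)
  tibble::tibble(gene = names(deg), degree = as.integer(deg)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$gene)
}

# Undirected simple graph from an edge-list data frame; drops self-loops and
# collapses duplicate/reversed edges. Keeps the first weight seen, if any.
clean_graph <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("gene_a", "gene_b") %in% names(edges)))
  df <- as.data.frame(edges[c(
    "gene_a", "gene_b",
    intersect("weight", names(edges))
  )])
  g <- igraph::graph_from_data_frame(df, directed = FALSE, vertices = nodes)
  igraph::simplify(
    g,
    remove.multiple = TRUE, remove.loops = TRUE,
    edge.attr.comb = "first"
  )
}
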