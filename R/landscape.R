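#' Per-cohort alteration summaries (OncoPrint-style)
#'
#' Summarizes, for each cohort, how many samples carry at least one
#' copy-number alteration (GAIN or LOSS) in any gene of a given list — the
#' numeric counterpart of an OncoPrint's "altered in x%" header.
#'
#' @param cnv_calls Long-format CNV calls with columns `gene`, `sample`,
#'   `call`, `cohort`.
#' @param genes Character vector of genes defining "altered". `NULL` uses all
#'   genes in the matrix.
#' @param cohorts Optional character vector restricting the summary to these
#'   cohorts; unknown cohorts raise an error listing the known ones.
#'
#' @return A tibble `cohort`, `n_samples`, `n_altered_samples`,
#'   `altered_fraction`.
#' @export
cohort_alteration_summary <- function(cnv_calls, genes = NULL, cohorts = NULL) {
  cnv_calls <- validate_cnv_calls(cnv_calls)
  if (!"cohort" %in% names(cnv_calls)) {
    stop("CNV calls lack a `cohort` column", call. = FALSE)
  }
  known <- unique(cnv_calls$cohort)
  if (!is.null(cohorts)) {
    unknown <- setdiff(cohorts, known)
    if (length(unknown) > 0L) {
      stop(
        "unknown cohort(s): ", paste(unknown, collapse = ", "),
        "; known cohorts: ", paste(sort(known), collapse = ", "),
        call. = FALSE
      )
    }
    cnv_calls <- dplyr::filter(cnv_calls, .data$cohort %in% .env$cohorts)
  }
  listed <- if (is.null(genes)) unique(cnv_calls$gene) else genes

  cnv_calls |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(
      n_samples = dplyr::n_distinct(.data$sample),
      n_altered_samples = dplyr::n_distinct(
        .data$sample[.data$gene %in% .env$listed & .data$call != "NEUTRAL"]
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(altered_fraction = .data$n_altered_samples / .data$n_samples) |>
    dplyr::arrange(.data$cohort)
}

#' Per-gene gain/loss frequencies by cohort
#'
#' Tabulates, for each (cohort, gene) pair, the fraction of cohort samples
#' carrying a GAIN call (`gain_freq`, the amplification frequency) and a LOSS
#' call (`loss_freq`, the deletion frequency).
#'
#' @inheritParams cohort_alteration_summary
#' @return A tibble `cohort`, `gene`, `n_samples`, `gain_freq`, `loss_freq`.
#' @export
gene_alteration_freq <- function(cnv_calls, genes = NULL, cohorts = NULL) {
  cnv_calls <- validate_cnv_calls(cnv_calls)
  if (!"cohort" %in% names(cnv_calls)) {
    stop("CNV calls lack a `cohort` column", call. = FALSE)
  }
  if (!is.null(cohorts)) {
    unknown <- setdiff(cohorts, unique(cnv_calls$cohort))
    if (length(unknown) > 0L) {
      stop(
        "unknown cohort(s): ", paste(unknown, collapse = ", "),
        "; known cohorts: ",
        paste(sort(unique(cnv_calls$cohort)), collapse = ", "),
        call. = FALSE
      )
    }
    cnv_calls <- dplyr::filter(cnv_calls, .data$cohort %in% .env$cohorts)
  }
  if (!is.null(genes)) {
    cnv_calls <- dplyr::filter(cnv_calls, .data$gene %in% .env$genes)
  }

  cnv_calls |>
    dplyr::group_by(.data$cohort, .data$gene) |>
    dplyr::summarise(
      n_samples = dplyr::n_distinct(.data$sample),
      gain_freq = sum(.data$call == "GAIN") / dplyr::n_distinct(.data$sample),
      loss_freq = sum(.data$call == "LOSS") / dplyr::n_distinct(.data$sample),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cohort, .data$gene)
}

#' Top-k amplified genes per cohort
#'
#' Ranks genes within each cohort by descending gain (amplification)
#' frequency, breaking ties lexicographically by gene symbol so the ranking
#' is deterministic, and keeps the top `k`.
#'
#' @param freqs Output of [gene_alteration_freq()].
#' @param k Number of genes to keep per cohort (default 20). If a cohort has
#'   fewer genes, all are returned with a warning.
#'
#' @return A tibble `cohort`, `rank`, `gene`, `gain_freq`.
#' @export
top_amplified <- function(freqs, k = 20) {
  stopifnot(all(c("cohort", "gene", "gain_freq") %in% names(freqs)), k >= 1)
  short <- freqs |>
    dplyr::count(.data$cohort) |>
    dplyr::filter(.data$n < .env$k)
  if (nrow(short) > 0L) {
    warning(
      "cohort(s) with fewer than k = ", k, " genes return all genes: ",
      paste(short$cohort, collapse = ", "),
      call. = FALSE
    )
  }
  freqs |>
    dplyr::group_by(.data$cohort) |>
    dplyr::arrange(dplyr::desc(.data$gain_freq), .data$gene, .by_group = TRUE) |>
    dplyr::slice_head(n = as.integer(k)) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("cohort", "rank", "gene", "gain_freq")
}

#' Genes recurrent across all cohorts
#'
#' Intersects the per-cohort top-amplified gene sets: the genes that rank
#' among the most amplified in every cohort.
#'
#' @param top Output of [top_amplified()] covering at least two cohorts.
#' @return Sorted character vector of common genes (possibly empty).
#' @export
cross_cohort_common <- function(top) {
  stopifnot(all(c("cohort", "gene") %in% names(top)))
  sets <- split(top$gene, top$cohort)
  if (length(sets) < 2L) {
    stop("need top-amplified lists from at least two cohorts", call. = FALSE)
  }
  sort(purrr::reduce(sets, intersect))
}
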