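#' Expression Z-scores relative to a reference sample set
#'
#' Standardizes each gene's expression against a designated reference sample
#' population: `Z = (x - mu) / sigma`, where `mu` and `sigma` are the mean
#' and standard deviation of that gene's expression across the reference
#' samples. A tumour sample's Z-score is then its expression measured in
#' reference standard deviations away from the reference mean — the usual
#' cBioPortal-style convention for calling a gene over-expressed in a
#' particular sample.
#'
#' Genes whose reference standard deviation is zero (or not estimable) cannot
#' be scored; they are dropped with a warning. If `reference_samples` is
#' `NULL`, all samples act as their own reference population.
#'
#' @param expr Long-format expression data frame with columns `gene`,
#'   `sample`, `expr` (continuous values). See [read_expression_tsv()].
#' @param reference_samples Character vector of sample IDs forming the
#'   reference population (e.g. diploid/normal samples). Default `NULL`: all
#'   samples.
#'
#' @return A tibble `gene`, `sample`, `z` covering the non-reference (tumour)
#'   samples; reference samples define the scale and are not themselves
#'   scored. Missing expression values yield missing Z.
#' @export
expression_zscores <- function(expr, reference_samples = NULL) {
  stopifnot(is.data.frame(expr))
  need <- c("gene", "sample", "expr")
  missing_cols <- setdiff(need, names(expr))
  if (length(missing_cols) > 0L) {
    stop("expression table lacks column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  expr <- tibble::as_tibble(expr)
  if (is.null(reference_samples)) {
    reference_samples <- unique(expr$sample)
    tumour <- expr
  } else {
    if (!any(expr$sample %in% reference_samples)) {
      stop("none of the designated reference samples appear in the expression table",
        call. = FALSE
      )
    }
    tumour <- dplyr::filter(expr, !.data$sample %in% .env$reference_samples)
  }

  ref_stats <- expr |>
    dplyr::filter(.data$sample %in% .env$reference_samples) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      mu = mean(.data$expr, na.rm = TRUE),
      sigma = stats::sd(.data$expr, na.rm = TRUE),
      .groups = "drop"
    )

  unscorable <- ref_stats$gene[is.na(ref_stats$sigma) | ref_stats$sigma <= 0]
  if (length(unscorable) > 0L) {
    warning(
      length(unscorable),
      " gene(s) excluded: reference standard deviation is zero or not estimable",
      call. = FALSE
    )
    ref_stats <- dplyr::filter(ref_stats, !.data$gene %in% .env$unscorable)
  }

  tumour |>
    dplyr::inner_join(ref_stats, by = "gene") |>
    dplyr::mutate(z = (.data$expr - .data$mu) / .data$sigma) |>
    dplyr::select("gene", "sample", "z")
}

#' Call over- and under-expression from Z-scores
#'
#' Applies the strict Z-score rule: a sample is over-expressed for a gene when
#' `z > z_cutoff` and under-expressed when `z < -z_cutoff`. A Z-score exactly
#' at the cutoff is not a call.
#'
#' @param zscores Output of [expression_zscores()].
#' @param thresholds A [pipeline_thresholds()] object (or named list).
#'
#' @return The input tibble with logical columns `over` and `under` added
#'   (missing Z gives `FALSE` for both).
#' @export
call_expression <- function(zscores, thresholds = pipeline_thresholds()) {
  thresholds <- as_thresholds(thresholds)
  stopifnot(all(c("gene", "sample", "z") %in% names(zscores)))
  dplyr::mutate(
    tibble::as_tibble(zscores),
    over = !is.na(.data$z) & .data$z > thresholds$z_cutoff,
    under = !is.na(.data$z) & .data$z < -thresholds$z_cutoff
  )
}

#' Count matched-sample CNV/expression concordance
#'
#' For each gene, counts the tumour samples that simultaneously carry a
#' copy-number GAIN call and an over-expression call (`n_gain_over`), and
#' symmetrically the samples with a LOSS call and under-expression
#' (`n_loss_under`). Only samples present in both the CNV and the expression
#' data are counted; the size of the shared sample set is reported via a
#' message and the `n_shared_samples` attribute.
#'
#' @param cnv_calls Long-format CNV calls (`gene`, `sample`, `call`).
#' @param expr_calls Output of [call_expression()] (`gene`, `sample`, `over`,
#'   `under`).
#' @param genes Optional character vector restricting the count to these genes
#'   (typically the frequent-CNG set). `NULL` counts every gene present in
#'   both tables.
#'
#' @return A tibble `gene`, `n_gain`, `n_gain_over`, `n_loss`, `n_loss_under`
#'   over the shared samples.
#' @export
count_concordance <- function(cnv_calls, expr_calls, genes = NULL) {
  cnv_calls <- validate_cnv_calls(cnv_calls)
  stopifnot(all(c("gene", "sample", "over", "under") %in% names(expr_calls)))

  shared <- intersect(unique(cnv_calls$sample), unique(expr_calls$sample))
  if (length(shared) == 0L) {
    stop(
      "CNV and expression data share no sample IDs (",
      length(unique(cnv_calls$sample)), " CNV samples vs ",
      length(unique(expr_calls$sample)), " expression samples)",
      call. = FALSE
    )
  }
  message("counting concordance over ", length(shared), " shared sample(s)")

  cnv <- dplyr::filter(cnv_calls, .data$sample %in% .env$shared)
  ex <- dplyr::filter(tibble::as_tibble(expr_calls), .data$sample %in% .env$shared)
  if (!is.null(genes)) {
    cnv <- dplyr::filter(cnv, .data$gene %in% .env$genes)
    ex <- dplyr::filter(ex, .data$gene %in% .env$genes)
  }

  out <- cnv |>
    dplyr::inner_join(ex[c("gene", "sample", "over", "under")],
      by = c("gene", "sample")
    ) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_gain = sum(.data$call == "GAIN"),
      n_gain_over = sum(.data$call == "GAIN" & .data$over),
      n_loss = sum(.data$call == "LOSS"),
      n_loss_under = sum(.data$call == "LOSS" & .data$under),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene)
  attr(out, "n_shared_samples") <- length(shared)
  out
}

#' Select key genes by concordant-sample count
#'
#' Applies the final funnel gate: a gene is a key prognosis candidate when the
#' number of samples concordant for copy-number gain and over-expression
#' strictly exceeds `min_concordant_samples`. An alternative `mode = "ratio"`
#' instead gates on the literal ratio
#' `n_gain_over / n_loss_under > min_concordant_samples`; the count mode is
#' the default because the concordance tally is a sample count, not a ratio.
#'
#' @param concordance Output of [count_concordance()].
#' @param thresholds A [pipeline_thresholds()] object (or named list).
#' @param mode `"count"` (default) gates on `n_gain_over`; `"ratio"` gates on
#'   `n_gain_over / n_loss_under` (with a zero denominator and positive
#'   numerator treated as infinite, hence passing).
#'
#' @return The concordance tibble with a logical `passes_key_gene` column,
#'   filtered to the passing genes.
#' @export
select_key_genes <- function(concordance, thresholds = pipeline_thresholds(),
                             mode = c("count", "ratio")) {
  thresholds <- as_thresholds(thresholds)
  mode <- match.arg(mode)
  stopifnot(all(c("gene", "n_gain_over", "n_loss_under") %in% names(concordance)))
  cutoff <- thresholds$min_concordant_samples
  out <- dplyr::mutate(
    tibble::as_tibble(concordance),
    passes_key_gene = if (mode == "count") {
      .data$n_gain_over > cutoff
    } else {
      (.data$n_loss_under == 0L & .data$n_gain_over > 0L) |
        (.data$n_loss_under > 0L & .data$n_gain_over / .data$n_loss_under > cutoff)
    }
  )
  dplyr::filter(out, .data$passes_key_gene) |>
    dplyr::arrange(dplyr::desc(.data$n_gain_over), .data$gene)
}
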