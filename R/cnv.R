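#' Per-gene copy-number gain/loss profiling
#'
#' Counts, for each gene of interest, the tumour samples carrying a GAIN call
#' and those carrying a LOSS call (cohorts pooled), forms the gain/loss sample
#' ratio, and classifies each gene as copy-number gained (`CNG`), lost
#' (`CNL`), or `BALANCED` by the ratio rule: CNG when
#' `n_gain / n_loss > ratio_cutoff` and, symmetrically, CNL when
#' `n_loss / n_gain > ratio_cutoff`. A positive count over a zero count is
#' treated as an infinite ratio (hence CNG/CNL); a gene with no gains and no
#' losses is BALANCED.
#'
#' @param cnv_calls Data frame of long-format calls with columns `gene`,
#'   `sample`, `call` (values in `GAIN`, `LOSS`, `NEUTRAL`) and optionally
#'   `cohort`. See [read_cnv_calls()].
#' @param genes Optional character vector restricting profiling to these genes
#'   (e.g. the curated prognosis set). Genes absent from the call matrix are
#'   reported with a warning, not an error. `NULL` profiles every gene.
#' @param thresholds A [pipeline_thresholds()] object (or named list).
#'
#' @return A tibble with one row per profiled gene: `gene`, `n_gain`,
#'   `n_loss`, `gain_loss_ratio`, `cnv_class` and `passes_frequent_cng`
#'   (class CNG and strictly more than `min_cng_samples` gained samples).
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   gene = rep("A", 6), sample = paste0("s", 1:6),
#'   call = c("GAIN", "GAIN", "GAIN", "LOSS", "NEUTRAL", "NEUTRAL")
#' )
#' profile_cnv(calls)
profile_cnv <- function(cnv_calls, genes = NULL,
                        thresholds = pipeline_thresholds()) {
  thresholds <- as_thresholds(thresholds)
  cnv_calls <- validate_cnv_calls(cnv_calls)

  if (!is.null(genes)) {
    absent <- setdiff(genes, unique(cnv_calls$gene))
    if (length(absent) > 0L) {
      warning(
        length(absent), " gene(s) not present in the CNV call matrix: ",
        paste(utils::head(absent, 5L), collapse = ", "),
        if (length(absent) > 5L) ", ..." else "",
        call. = FALSE
      )
    }
    cnv_calls <- dplyr::filter(cnv_calls, .data$gene %in% .env$genes)
    if (nrow(cnv_calls) == 0L) {
      warning("no requested gene intersects the CNV call matrix", call. = FALSE)
      return(tibble::tibble(
        gene = character(), n_gain = integer(), n_loss = integer(),
        gain_loss_ratio = double(), cnv_class = character(),
        passes_frequent_cng = logical()
      ))
    }
  }

  prof <- cnv_calls |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_gain = sum(.data$call == "GAIN"),
      n_loss = sum(.data$call == "LOSS"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      gain_loss_ratio = dplyr::if_else(
        .data$n_gain == 0L & .data$n_loss == 0L,
        NA_real_,
        .data$n_gain / .data$n_loss
      ),
      cnv_class = classify_cnv(.data$n_gain, .data$n_loss,
        ratio_cutoff = thresholds$ratio_cutoff
      ),
      passes_frequent_cng = .data$cnv_class == "CNG" &
        .data$n_gain > thresholds$min_cng_samples
    ) |>
    dplyr::arrange(.data$gene)
  prof
}

#' Classify genes by the gain/loss sample-ratio rule
#'
#' Vectorized classification underlying [profile_cnv()]: `CNG` when the number
#' of gained samples is more than `ratio_cutoff` times the number of lost
#' samples, `CNL` symmetrically, else `BALANCED`. Zero denominators follow the
#' ratio's limit: gains with no losses is CNG (and vice versa); no gains and
#' no losses is BALANCED. For `ratio_cutoff >= 1` the CNG and CNL conditions
#' are mutually exclusive.
#'
#' @param n_gain,n_loss Integer vectors of gained / lost sample counts.
#' @param ratio_cutoff Ratio threshold (strict), default 2.
#'
#' @return Character vector in `c("CNG", "CNL", "BALANCED")`.
#' @export
#' @examples
#' classify_cnv(c(40, 10, 15, 5, 0), c(10, 40, 10, 0, 0))
classify_cnv <- function(n_gain, n_loss, ratio_cutoff = 2) {
  stopifnot(all(n_gain >= 0, na.rm = TRUE), all(n_loss >= 0, na.rm = TRUE))
  # n_gain/n_loss is Inf when n_loss == 0 and n_gain > 0, which correctly
  # exceeds any finite cutoff; only 0/0 needs special-casing.
  cng <- n_loss == 0 & n_gain > 0 | (n_loss > 0 & n_gain / n_loss > ratio_cutoff)
  cnl <- n_gain == 0 & n_loss > 0 | (n_gain > 0 & n_loss / n_gain > ratio_cutoff)
  dplyr::case_when(cng ~ "CNG", cnl ~ "CNL", .default = "BALANCED")
}

#' Frequent-CNG filter
#'
#' Retains the genes classified `CNG` whose gained-sample count strictly
#' exceeds `min_cng_samples` — the frequent copy-number-gain subset carried
#' forward to the expression-concordance stage.
#'
#' @param profiles Output of [profile_cnv()].
#' @param thresholds A [pipeline_thresholds()] object (or named list).
#'
#' @return The filtered profile tibble (possibly zero rows).
#' @export
filter_frequent_cng <- function(profiles, thresholds = pipeline_thresholds()) {
  thresholds <- as_thresholds(thresholds)
  stopifnot(all(c("cnv_class", "n_gain") %in% names(profiles)))
  dplyr::filter(
    profiles,
    .data$cnv_class == "CNG",
    .data$n_gain > thresholds$min_cng_samples
  )
}

validate_cnv_calls <- function(cnv_calls) {
  stopifnot(is.data.frame(cnv_calls))
  need <- c("gene", "sample", "call")
  missing_cols <- setdiff(need, names(cnv_calls))
  if (length(missing_cols) > 0L) {
    stop("CNV calls lack column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- setdiff(unique(cnv_calls$call), c("GAIN", "LOSS", "NEUTRAL"))
  if (length(bad) > 0L) {
    stop("unknown CNV call value(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(cnv_calls[c("gene", "sample")]) > 0L) {
    stop("duplicate (gene, sample) CNV calls", call. = FALSE)
  }
  tibble::as_tibble(cnv_calls)
}
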