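#' Kaplan-Meier survival plot
#'
#' Step plot of the product-limit curves per group, with tick marks at
#' censoring times.
#'
#' @param object A `km_curve` from [km_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tidy(object)
  # prepend S(0) = 1 for each group so the step starts at the origin
  origin <- df |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, n_risk = NA_integer_, n_event = 0L,
      n_censor = 0L, surv = 1)
  df <- dplyr::bind_rows(origin, df)
  censored <- dplyr::filter(df, .data$n_censor > 0L)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = censored, shape = 3, size = 1.5) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Months", y = "Overall survival probability", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Gene-prioritization funnel plot
#'
#' Bar chart of the per-stage gene counts of a pipeline run — the number of
#' genes surviving curation, CNV overlap, CNG classification, the
#' frequent-CNG filter and key-gene selection.
#'
#' @param pipeline A `prognosis_pipeline` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_funnel <- function(pipeline) {
  stopifnot(inherits(pipeline, "prognosis_pipeline"))
  df <- pipeline$manifest |>
    dplyr::mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$n_genes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_genes), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "Genes") +
    ggplot2::theme_minimal()
}

#' Cohort alteration-landscape plot
#'
#' OncoPrint-style numeric summary: per-gene amplification (gain) and
#' deletion (loss) frequencies, faceted by cohort, for the top amplified
#' genes.
#'
#' @param freqs Output of [gene_alteration_freq()].
#' @param genes Optional character vector restricting the plot; default all.
#' @return A ggplot object.
#' @export
plot_alteration_landscape <- function(freqs, genes = NULL) {
  stopifnot(all(c("cohort", "gene", "gain_freq", "loss_freq") %in% names(freqs)))
  if (!is.null(genes)) {
    freqs <- dplyr::filter(freqs, .data$gene %in% .env$genes)
  }
  long <- freqs |>
    tidyr::pivot_longer(c("gain_freq", "loss_freq"),
      names_to = "type", values_to = "freq"
    ) |>
    dplyr::mutate(type = dplyr::recode(.data$type,
      gain_freq = "Amplification", loss_freq = "Deletion"
    ))
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$gene, .data$freq, fill = .data$type)
  ) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(
      values = c(Amplification = "firebrick", Deletion = "steelblue")
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cohort)) +
    ggplot2::labs(x = NULL, y = "Alteration frequency", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Enrichment dot plot
#'
#' Top enriched gene sets by adjusted p-value, sized by overlap.
#'
#' @param results Output of [enrich_gene_sets()].
#' @param top_n Number of sets to display (default 10).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, top_n = 10) {
  stopifnot(all(c("set", "k", "p_adj") %in% names(results)))
  df <- utils::head(results, top_n) |>
    dplyr::mutate(set = stats::reorder(.data$set, -.data$p_adj))
  ggplot2::ggplot(
    df,
    ggplot2::aes(-log10(.data$p_adj), .data$set, size = .data$k)
  ) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::labs(
      x = expression(-log[10] ~ "adjusted p"), y = NULL, size = "Overlap"
    ) +
    ggplot2::theme_minimal()
}
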