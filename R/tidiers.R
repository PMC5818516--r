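#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Kaplan-Meier curve
#'
#' @param x A `km_curve` from [km_fit()].
#' @param ... Unused.
#' @return A tibble `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`.
#' @method tidy km_curve
#' @export
tidy.km_curve <- function(x, ...) {
  out <- x
  attributes(out)[c("medians", "n", "n_events")] <- NULL
  class(out) <- setdiff(class(out), "km_curve")
  tibble::as_tibble(out)
}

#' Per-group Kaplan-Meier summaries
#'
#' @param x A `km_curve` from [km_fit()].
#' @param ... Unused.
#' @return A tibble with one row per group: `group`, `n`, `events`,
#'   `median` (NA when the curve never reaches 0.5).
#' @method glance km_curve
#' @export
glance.km_curve <- function(x, ...) {
  med <- attr(x, "medians")
  tibble::tibble(
    group = names(med),
    n = as.integer(attr(x, "n")[names(med)]),
    events = as.integer(attr(x, "n_events")[names(med)]),
    median = as.numeric(med)
  )
}

#' Tidy a log-rank test
#'
#' @param x A `logrank_test` from [log_rank()].
#' @param ... Unused.
#' @return The per-group tibble (`group`, `n`, `events`, `median`).
#' @method tidy logrank_test
#' @export
tidy.logrank_test <- function(x, ...) {
  x$groups
}

#' One-row log-rank summary
#'
#' @param x A `logrank_test` from [log_rank()].
#' @param ... Unused.
#' @return A tibble `statistic`, `df`, `p.value`.
#' @method glance logrank_test
#' @export
glance.logrank_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p_value)
}

#' Tidy a pipeline run into its funnel manifest
#'
#' @param x A `prognosis_pipeline` from [run_pipeline()].
#' @param ... Unused.
#' @return The manifest tibble (`stage`, `n_genes`).
#' @method tidy prognosis_pipeline
#' @export
tidy.prognosis_pipeline <- function(x, ...) {
  x$manifest
}

#' One-row pipeline summary
#'
#' @param x A `prognosis_pipeline` from [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble with the funnel counts as columns plus
#'   `n_warnings`.
#' @method glance prognosis_pipeline
#' @export
glance.prognosis_pipeline <- function(x, ...) {
  wide <- stats::setNames(
    as.list(x$manifest$n_genes),
    paste0("n_", x$manifest$stage)
  )
  tibble::as_tibble(c(wide, list(n_warnings = length(x$warnings))))
}

#' Tidy a network neighborhood into its linker ranking
#'
#' @param x A `gene_neighborhood` from [network_neighborhood()].
#' @param ... Unused.
#' @return The linker ranking tibble (`gene`, `n_seed_connections`).
#' @method tidy gene_neighborhood
#' @export
tidy.gene_neighborhood <- function(x, ...) {
  x$linker_ranking
}
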