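#' Assign altered / unaltered survival groups
#'
#' Labels each clinical sample `ALTERED` when it carries a GAIN or LOSS call
#' in at least one gene of the given list, `UNALTERED` otherwise, and joins
#' the survival endpoint — the grouping used to compare overall survival
#' between samples with and without alterations in a gene list.
#'
#' @param cnv_calls Long-format CNV calls (`gene`, `sample`, `call`).
#' @param genes Character vector of genes defining "altered".
#' @param clinical Data frame with columns `sample`, `os_months` (> 0) and
#'   `os_event` (1 = death observed, 0 = censored). See
#'   [read_clinical_tsv()].
#'
#' @return A tibble `sample`, `time`, `event` (logical), `group` (factor
#'   `ALTERED`/`UNALTERED`), one row per clinical sample that also has CNV
#'   calls.
#' @export
assign_alteration_groups <- function(cnv_calls, genes, clinical) {
  cnv_calls <- validate_cnv_calls(cnv_calls)
  stopifnot(all(c("sample", "os_months", "os_event") %in% names(clinical)))
  clinical <- tibble::as_tibble(clinical)
  if (any(clinical$os_months <= 0, na.rm = TRUE)) {
    stop("`os_months` must be positive", call. = FALSE)
  }
  shared <- intersect(unique(cnv_calls$sample), clinical$sample)
  if (length(shared) == 0L) {
    stop("clinical table and CNV calls share no sample IDs", call. = FALSE)
  }

  altered <- cnv_calls |>
    dplyr::filter(
      .data$gene %in% .env$genes,
      .data$call != "NEUTRAL"
    ) |>
    dplyr::distinct(.data$sample) |>
    dplyr::pull()

  clinical |>
    dplyr::filter(.data$sample %in% .env$shared) |>
    dplyr::transmute(
      sample = .data$sample,
      time = as.numeric(.data$os_months),
      event = as.logical(.data$os_event),
      group = factor(
        dplyr::if_else(.data$sample %in% .env$altered, "ALTERED", "UNALTERED"),
        levels = c("ALTERED", "UNALTERED")
      )
    )
}

#' Kaplan-Meier product-limit estimator
#'
#' Fits the product-limit survival curve `S(t) = prod_{t_i <= t} (1 - d_i /
#' n_i)` over the distinct event times `t_i`, with `d_i` deaths and `n_i`
#' subjects at risk just before `t_i`. Subjects censored at an event time are
#' kept in that time's risk set (deaths are processed before censorings at
#' tied times, the standard convention). With a `group` column a separate
#' curve is fitted per group.
#'
#' The median survival is the smallest observed time at which the curve drops
#' to 0.5 or below; if the curve never reaches 0.5 the median is undefined
#' (`NA`), not infinite.
#'
#' @param records Data frame with columns `time` (> 0) and `event` (logical
#'   or 0/1), optionally `group`.
#'
#' @return An object of class `km_curve`: a tibble `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (one row per distinct observed time), with
#'   a `medians` attribute (named per group). Use [generics::tidy()] for the
#'   curve table and [generics::glance()] for per-group summaries.
#' @export
#' @examples
#' km_fit(data.frame(time = c(2, 3, 5, 7), event = c(TRUE, FALSE, TRUE, FALSE)))
km_fit <- function(records) {
  stopifnot(is.data.frame(records), all(c("time", "event") %in% names(records)))
  if (nrow(records) == 0L) {
    stop("no survival records", call. = FALSE)
  }
  if (any(records$time <= 0, na.rm = TRUE)) {
    stop("survival times must be positive", call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  if (!"group" %in% names(records)) {
    records$group <- factor("all")
  }
  records$event <- as.logical(records$event)

  curves <- records |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ km_one_group(.x$time, .x$event)) |>
    dplyr::ungroup()

  medians <- curves |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      median = if (any(.data$surv <= 0.5)) {
        min(.data$time[.data$surv <= 0.5])
      } else {
        NA_real_
      },
      .groups = "drop"
    )

  structure(
    curves,
    medians = stats::setNames(medians$median, as.character(medians$group)),
    n = table(records$group),
    n_events = tapply(records$event, records$group, sum),
    class = c("km_curve", class(curves))
  )
}

# Product-limit arithmetic for a single group; one row per distinct time.
km_one_group <- function(time, event) {
  ord <- order(time)
  time <- time[ord]
  event <- event[ord]
  times <- sort(unique(time))
  n_risk <- vapply(times, function(t) sum(time >= t), integer(1))
  n_event <- vapply(times, function(t) sum(time == t & event), integer(1))
  n_censor <- vapply(times, function(t) sum(time == t & !event), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  tibble::tibble(
    time = times, n_risk = n_risk, n_event = n_event,
    n_censor = n_censor, surv = surv
  )
}

#' @export
print.km_curve <- function(x, ...) {
  med <- attr(x, "medians")
  cat("<km_curve> ", length(med), " group(s)\n", sep = "")
  for (g in names(med)) {
    cat(
      "  ", g, ": n = ", attr(x, "n")[[g]],
      ", events = ", attr(x, "n_events")[[g]],
      ", median = ",
      if (is.na(med[[g]])) "undefined" else format(med[[g]]), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Two-group log-rank test
#'
#' Compares the survival distributions of two groups with the standard
#' log-rank (Mantel-Cox) test. At each distinct event time `t` with `d`
#' total deaths among `n` subjects at risk (`n1` of them in the first
#' group, `d1` dying), the first group contributes observed `d1`, expected
#' `E = d * n1 / n` and hypergeometric variance
#' `V = d * (n1/n) * (1 - n1/n) * (n - d) / (n - 1)`. The statistic
#' `(sum(d1 - E))^2 / sum(V)` is referred to a chi-square distribution with
#' one degree of freedom. Subjects censored at `t` remain in the risk set at
#' `t`.
#'
#' @param records Data frame with columns `time` (> 0), `event`
#'   (logical/0-1) and `group` with exactly two levels, e.g. from
#'   [assign_alteration_groups()].
#'
#' @return An object of class `logrank_test`: a list with `statistic`, `df`,
#'   `p_value` and a `groups` tibble (`group`, `n`, `events`, `median`).
#'   [generics::tidy()] and [generics::glance()] methods are provided.
#' @export
log_rank <- function(records) {
  stopifnot(
    is.data.frame(records),
    all(c("time", "event", "group") %in% names(records))
  )
  records <- tibble::as_tibble(records)
  records$event <- as.logical(records$event)
  records$group <- droplevels(factor(records$group))
  lev <- levels(records$group)
  if (length(lev) != 2L) {
    stop("log_rank needs exactly two non-empty groups, got ",
      length(lev),
      call. = FALSE
    )
  }
  if (any(table(records$group) == 0L)) {
    stop("both groups must contain records", call. = FALSE)
  }

  g1 <- records$group == lev[1L]
  event_times <- sort(unique(records$time[records$event]))
  o_minus_e <- 0
  v <- 0
  for (t in event_times) {
    at_risk <- records$time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(records$time == t & records$event)
    d1 <- sum(records$time == t & records$event & g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1L) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  statistic <- if (v > 0) o_minus_e^2 / v else 0
  p_value <- stats::pchisq(statistic, df = 1L, lower.tail = FALSE)

  km <- km_fit(records)
  medians <- attr(km, "medians")
  groups <- tibble::tibble(
    group = lev,
    n = as.integer(table(records$group)[lev]),
    events = as.integer(tapply(records$event, records$group, sum)[lev]),
    median = as.numeric(medians[lev])
  )

  structure(
    list(
      statistic = statistic, df = 1L, p_value = p_value,
      groups = groups, curve = km
    ),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("<logrank_test>\n")
  cat(
    "  chi-square = ", format(x$statistic, digits = 5),
    " (1 df), p = ", format(x$p_value, digits = 4), "\n",
    sep = ""
  )
  print(as.data.frame(x$groups), row.names = FALSE)
  invisible(x)
}
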