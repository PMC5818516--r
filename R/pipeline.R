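#' Run the full gene-prioritization pipeline
#'
#' Orchestrates the funnel end-to-end: literature curation -> CNV gain/loss
#' profiling (restricted to curated genes) -> frequent-CNG filter ->
#' expression Z-scoring and gain/over-expression concordance -> key-gene
#' selection; then the downstream summaries on the key genes: gene-set
#' enrichment, per-cohort alteration landscape, altered-vs-unaltered
#' survival comparison, and the interaction-network neighborhood.
#'
#' The input is either a `synthetic_bundle` from [generate_bundle()] or a
#' configuration (YAML path or named list) with a `files` block naming the
#' input paths (`literature`, `cnv`, `expression`, `reference_samples`,
#' `clinical`, `gene_sets`, `network`) and an optional `thresholds` block.
#' Downstream stages degrade gracefully: with no key genes, or with missing
#' optional inputs (clinical, gene sets, network), the corresponding
#' summaries are `NULL` and a warning is raised, but the funnel itself
#' completes. A hard failure inside a stage aborts with the stage named.
#'
#' @param input A `synthetic_bundle`, a named list, or the path to a YAML
#'   config file.
#' @param thresholds A [pipeline_thresholds()] object; overrides any
#'   thresholds in a config file.
#' @param key_gene_mode Passed to [select_key_genes()]: `"count"` (default)
#'   or `"ratio"`.
#' @param top_k Genes per cohort for the amplification ranking (default 20).
#' @param max_linkers Linker genes for the network neighborhood (default 20).
#'
#' @return An object of class `prognosis_pipeline`: a list with the stage
#'   outputs (`curated`, `profiles`, `frequent_cng`, `concordance`,
#'   `key_genes`, `enrichment`, `landscape`, `survival`, `network`), the
#'   funnel `manifest` tibble, the thresholds and warnings collected along
#'   the way. [generics::tidy()] returns the manifest.
#' @export
#' @examples
#' \donttest{
#' bundle <- generate_bundle(synth_config(
#'   n_genes = 60, n_samples = 80,
#'   planted_genes = c("DRV01", "DRV02"), n_gene_sets = 5,
#'   planted_set_overlap = 2, n_reference_samples = 20
#' ))
#' fit <- run_pipeline(bundle, thresholds = pipeline_thresholds(min_cng_samples = 5,
#'   min_concordant_samples = 3))
#' tidy(fit)
#' }
run_pipeline <- function(input,
                         thresholds = NULL,
                         key_gene_mode = c("count", "ratio"),
                         top_k = 20,
                         max_linkers = 20) {
  key_gene_mode <- match.arg(key_gene_mode)
  data <- load_pipeline_input(input)
  if (is.null(thresholds)) {
    thresholds <- data$thresholds %||% pipeline_thresholds()
  }
  thresholds <- as_thresholds(thresholds)

  warnings <- character()
  note <- function(msg) warnings <<- c(warnings, msg)
  stage <- function(name, expr) {
    tryCatch(
      withCallingHandlers(expr, warning = function(w) {
        note(paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
      }
    )
  }

  ## funnel ------------------------------------------------------------------
  curated <- stage("curation", curate_prognosis_genes(data$literature))
  cnv_genes <- unique(data$cnv$gene)
  overlap_genes <- intersect(curated$gene_symbol, cnv_genes)

  profiles <- stage(
    "cnv_profiling",
    profile_cnv(data$cnv, genes = curated$gene_symbol, thresholds = thresholds)
  )
  frequent <- filter_frequent_cng(profiles, thresholds)

  zcalls <- stage("expression", {
    z <- expression_zscores(data$expression, data$reference_samples)
    call_expression(z, thresholds)
  })
  concordance <- if (nrow(frequent) > 0L) {
    stage(
      "concordance",
      suppressMessages(
        count_concordance(data$cnv, zcalls, genes = frequent$gene)
      )
    )
  } else {
    note("concordance: no frequent-CNG gene to score")
    NULL
  }
  key_genes <- if (!is.null(concordance)) {
    select_key_genes(concordance, thresholds, mode = key_gene_mode)
  } else {
    NULL
  }
  key_symbols <- if (is.null(key_genes)) character() else key_genes$gene
  if (length(key_symbols) == 0L) {
    note("key_genes: selection is empty under the current thresholds")
  }

  ## downstream summaries ----------------------------------------------------
  enrichment <- NULL
  if (!is.null(data$gene_sets) && length(key_symbols) > 0L) {
    enrichment <- stage(
      "enrichment",
      enrich_gene_sets(key_symbols, data$gene_sets, universe = cnv_genes)
    )
  }

  landscape <- NULL
  if ("cohort" %in% names(data$cnv) && length(key_symbols) > 0L) {
    landscape <- stage("landscape", {
      freqs <- gene_alteration_freq(data$cnv, genes = key_symbols)
      top <- top_amplified(freqs, k = top_k)
      list(
        summary = cohort_alteration_summary(data$cnv, genes = key_symbols),
        freqs = freqs,
        top_amplified = top,
        common_genes = if (dplyr::n_distinct(top$cohort) >= 2L) {
          cross_cohort_common(top)
        } else {
          NULL
        }
      )
    })
  }

  survival <- NULL
  if (!is.null(data$clinical) && length(key_symbols) > 0L) {
    survival <- stage("survival", {
      groups <- assign_alteration_groups(data$cnv, key_symbols, data$clinical)
      if (dplyr::n_distinct(groups$group) == 2L) {
        log_rank(groups)
      } else {
        warning("only one alteration group present; log-rank skipped")
        NULL
      }
    })
  }

  network <- NULL
  if (!is.null(data$edges) && length(key_symbols) > 0L) {
    network_nodes <- union(data$edges$gene_a, data$edges$gene_b)
    if (any(key_symbols %in% network_nodes)) {
      network <- stage(
        "network",
        network_neighborhood(data$edges,
          seeds = intersect(key_symbols, network_nodes),
          max_linkers = max_linkers
        )
      )
    } else {
      note("network: no key gene present in the supplied network")
    }
  }

  manifest <- tibble::tibble(
    stage = c(
      "curated", "cnv_overlap", "cng", "cnl",
      "frequent_cng", "key_genes"
    ),
    n_genes = c(
      nrow(curated),
      length(overlap_genes),
      sum(profiles$cnv_class == "CNG"),
      sum(profiles$cnv_class == "CNL"),
      nrow(frequent),
      length(key_symbols)
    )
  )

  structure(
    list(
      manifest = manifest,
      thresholds = thresholds,
      curated = curated,
      profiles = profiles,
      frequent_cng = frequent,
      concordance = concordance,
      key_genes = key_genes,
      enrichment = enrichment,
      landscape = landscape,
      survival = survival,
      network = network,
      warnings = warnings
    ),
    class = "prognosis_pipeline"
  )
}

#' @export
print.prognosis_pipeline <- function(x, ...) {
  cat("<prognosis_pipeline>\n")
  funnel <- paste(
    sprintf("%s %d", x$manifest$stage, x$manifest$n_genes),
    collapse = " -> "
  )
  cat(" ", funnel, "\n")
  if (length(x$warnings) > 0L) {
    cat("  warnings:", length(x$warnings), "\n")
  }
  invisible(x)
}

# Normalizes the three accepted input forms (bundle / list / YAML path) to a
# common list of tables.
load_pipeline_input <- function(input) {
  if (inherits(input, "synthetic_bundle")) {
    return(list(
      literature = input$literature,
      cnv = input$cnv,
      expression = input$expression,
      reference_samples = input$reference_samples,
      clinical = input$clinical,
      gene_sets = input$gene_sets,
      edges = input$edges,
      thresholds = NULL
    ))
  }
  if (is.character(input) && length(input) == 1L) {
    if (!file.exists(input)) {
      stop("config file not found: ", input, call. = FALSE)
    }
    input <- yaml::read_yaml(input)
  }
  if (!is.list(input)) {
    stop("`input` must be a synthetic_bundle, a config list, or a YAML path",
      call. = FALSE
    )
  }
  files <- input$files %||% input
  for (req in c("literature", "cnv", "expression")) {
    if (is.null(files[[req]])) {
      stop("config lacks required input `", req, "`", call. = FALSE)
    }
    if (!file.exists(files[[req]])) {
      stop("input file for `", req, "` not found: ", files[[req]],
        call. = FALSE
      )
    }
  }
  opt <- function(key, reader) {
    if (is.null(files[[key]])) {
      return(NULL)
    }
    if (!file.exists(files[[key]])) {
      stop("input file for `", key, "` not found: ", files[[key]], call. = FALSE)
    }
    reader(files[[key]])
  }
  list(
    literature = read_literature_tsv(files$literature),
    cnv = read_cnv_calls(files$cnv),
    expression = read_expression_tsv(files$expression),
    reference_samples = opt("reference_samples", read_reference_samples),
    clinical = opt("clinical", read_clinical_tsv),
    gene_sets = opt("gene_sets", read_gmt),
    edges = opt("network", read_edge_list),
    thresholds = if (!is.null(input$thresholds)) {
      as_thresholds(input$thresholds)
    } else {
      NULL
    }
  )
}
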