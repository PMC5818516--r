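#' Configuration for the synthetic cohort generator
#'
#' Defines a fully reproducible synthetic study: a pan-cancer-style tumour
#' cohort with per-gene copy-number calls, a matched expression matrix with a
#' designated diploid-like reference sample set, literature annotations,
#' survival endpoints, gene sets and an interaction network — all with known
#' planted signal so that every pipeline stage can be validated against
#' ground truth.
#'
#' Planted driver genes receive GAIN calls in exactly
#' `round(planted_gain_fraction * n_samples)` tumour samples, and their
#' expression in those samples is shifted upward by `dosage_shift` reference
#' standard deviations — the copy-number-dosage effect the pipeline is built
#' to detect. All other (gene, sample) cells gain or lose copies
#' independently at the background rates. Samples carrying at least one
#' planted-gene gain ("altered") die at `hazard_ratio_altered` times the
#' baseline hazard, giving the survival stage a planted effect, and
#' `planted_set_overlap` planted genes are concentrated in the first gene
#' set, giving enrichment a known positive.
#'
#' @param n_genes Total genes in the universe (planted included).
#' @param n_samples Tumour samples.
#' @param n_cohorts Number of cancer-type cohorts the samples are split into.
#' @param n_reference_samples Reference (normal/diploid) samples used for
#'   Z-scoring; at least 3 so a standard deviation is estimable.
#' @param planted_genes Symbols of the planted driver genes.
#' @param planted_gain_fraction Fraction of tumour samples gained per planted
#'   gene.
#' @param dosage_shift Expression shift, in reference-SD units, applied to
#'   gained samples of planted genes. `0` gives a null cohort.
#' @param background_gain_rate,background_loss_rate Per-gene per-sample
#'   background call probabilities (their sum must be at most 1).
#' @param hazard_ratio_altered Multiplicative hazard for samples carrying at
#'   least one planted-gene gain.
#' @param median_survival_months Baseline (unaltered) median overall
#'   survival, months.
#' @param censor_horizon_months Administrative censoring horizon, months.
#' @param n_gene_sets Number of gene sets emitted (the first carries the
#'   planted overlap).
#' @param planted_set_overlap How many planted genes are placed in the first
#'   gene set.
#' @param prognosis_fraction Fraction of background genes whose literature
#'   records carry the prognosis keyword pattern; planted genes always do.
#' @param seed Integer seed; fully determines every emitted value.
#'
#' @return An object of class `synth_config` (a named list).
#' @export
#' @examples
#' cfg <- synth_config(n_genes = 50, n_samples = 40, planted_genes = c("DRV01", "DRV02"))
#' cfg$planted_genes
synth_config <- function(n_genes = 500,
                         n_samples = 600,
                         n_cohorts = 3,
                         n_reference_samples = 60,
                         planted_genes = sprintf("DRV%02d", 1:12),
                         planted_gain_fraction = 0.1,
                         dosage_shift = 3,
                         background_gain_rate = 0.02,
                         background_loss_rate = 0.02,
                         hazard_ratio_altered = 3,
                         median_survival_months = 40,
                         censor_horizon_months = 120,
                         n_gene_sets = 25,
                         planted_set_overlap = 10,
                         prognosis_fraction = 0.8,
                         seed = 1L) {
  cfg <- as.list(environment())

  chk_count <- function(field, min = 1) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < min ||
      v != round(v)) {
      stop("invalid `", field, "`: must be an integer >= ", min, call. = FALSE)
    }
  }
  chk_rate <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("invalid `", field, "`: must be in [0, 1]", call. = FALSE)
    }
  }
  chk_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop("invalid `", field, "`: must be positive", call. = FALSE)
    }
  }
  chk_count("n_genes")
  chk_count("n_samples")
  chk_count("n_cohorts")
  chk_count("n_reference_samples", min = 3)
  chk_count("n_gene_sets")
  chk_count("planted_set_overlap", min = 0)
  chk_count("seed", min = -.Machine$integer.max)
  chk_rate("planted_gain_fraction")
  chk_rate("background_gain_rate")
  chk_rate("background_loss_rate")
  chk_rate("prognosis_fraction")
  chk_pos("hazard_ratio_altered")
  chk_pos("median_survival_months")
  chk_pos("censor_horizon_months")
  if (!is.numeric(cfg$dosage_shift) || length(cfg$dosage_shift) != 1L ||
    is.na(cfg$dosage_shift)) {
    stop("invalid `dosage_shift`: must be a single number", call. = FALSE)
  }
  if (cfg$background_gain_rate + cfg$background_loss_rate > 1) {
    stop("invalid `background_gain_rate`: gain and loss rates must sum to <= 1",
      call. = FALSE
    )
  }
  if (!is.character(cfg$planted_genes) ||
    anyDuplicated(cfg$planted_genes) > 0L ||
    any(cfg$planted_genes == "")) {
    stop("invalid `planted_genes`: must be distinct non-empty symbols",
      call. = FALSE
    )
  }
  if (length(cfg$planted_genes) > cfg$n_genes) {
    stop("invalid `planted_genes`: more planted genes than `n_genes`",
      call. = FALSE
    )
  }
  if (cfg$planted_set_overlap > length(cfg$planted_genes)) {
    stop("invalid `planted_set_overlap`: exceeds the number of planted genes",
      call. = FALSE
    )
  }
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> ", x$n_genes, " genes x ", x$n_samples, " samples, ",
    length(x$planted_genes), " planted driver(s), seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' Generate a complete synthetic study bundle
#'
#' Draws every input the prioritization pipeline consumes — literature
#' records, CNV call matrix with cohort labels, expression matrix with
#' reference samples, clinical endpoints, gene sets and an interaction
#' network — together with the ground truth of the planted signal. The seed
#' in the configuration fully determines the output: the same configuration
#' generates byte-identical files via [write_bundle()].
#'
#' Ground truth (`$truth`) records, per planted gene, the realized gained
#' samples and the concordant gain+over-expression sample count obtained by
#' direct counting on the emitted matrices (reference mean/SD from the
#' emitted reference columns, Z > 2), so pipeline results can be compared
#' against it exactly.
#'
#' @param config A [synth_config()] object.
#'
#' @return An object of class `synthetic_bundle`: a list with tibbles
#'   `literature`, `cnv`, `expression` (long), `clinical`, `edges`, a named
#'   list `gene_sets`, character vectors `genes` and `reference_samples`, the
#'   `truth` tibble and the `config`.
#' @export
#' @examples
#' bundle <- generate_bundle(synth_config(
#'   n_genes = 40, n_samples = 50,
#'   planted_genes = "DRV01", n_gene_sets = 5, planted_set_overlap = 1
#' ))
#' bundle$truth
generate_bundle <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)

  planted <- config$planted_genes
  n_bg <- config$n_genes - length(planted)
  background <- setdiff(sprintf("G%04d", seq_len(n_bg + length(planted))), planted)[seq_len(n_bg)]
  genes <- c(planted, background)
  samples <- sprintf("S%04d", seq_len(config$n_samples))
  ref_samples <- sprintf("REF%03d", seq_len(config$n_reference_samples))
  cohorts <- sprintf("COHORT%d", rep_len(seq_len(config$n_cohorts), config$n_samples))
  names(cohorts) <- samples

  ## --- CNV calls -----------------------------------------------------------
  call_mat <- matrix("NEUTRAL",
    nrow = length(genes), ncol = length(samples),
    dimnames = list(genes, samples)
  )
  n_gain_planted <- round(config$planted_gain_fraction * config$n_samples)
  gain_sets <- list()
  for (g in planted) {
    gained <- sort(sample(samples, n_gain_planted))
    gain_sets[[g]] <- gained
    call_mat[g, gained] <- "GAIN"
    rest <- setdiff(samples, gained)
    lost <- rest[stats::runif(length(rest)) < config$background_loss_rate]
    call_mat[g, lost] <- "LOSS"
  }
  if (length(background) > 0L) {
    u <- matrix(stats::runif(length(background) * length(samples)),
      nrow = length(background)
    )
    bg_calls <- matrix("NEUTRAL", nrow = length(background), ncol = length(samples))
    bg_calls[u < config$background_gain_rate] <- "GAIN"
    bg_calls[u >= config$background_gain_rate &
      u < config$background_gain_rate + config$background_loss_rate] <- "LOSS"
    call_mat[background, ] <- bg_calls
  }
  cnv <- tibble::tibble(
    gene = rep(genes, times = length(samples)),
    sample = rep(samples, each = length(genes)),
    call = as.vector(call_mat),
    cohort = cohorts[rep(samples, each = length(genes))]
  )

  ## --- Expression ----------------------------------------------------------
  # gene-specific background distribution, drawn once
  gene_mean <- stats::runif(length(genes), 5, 12)
  gene_sd <- stats::runif(length(genes), 0.5, 2)
  names(gene_mean) <- names(gene_sd) <- genes
  all_cols <- c(samples, ref_samples)
  expr_mat <- matrix(
    stats::rnorm(length(genes) * length(all_cols),
      mean = rep(gene_mean, times = length(all_cols)),
      sd = rep(gene_sd, times = length(all_cols))
    ),
    nrow = length(genes), dimnames = list(genes, all_cols)
  )
  for (g in planted) {
    expr_mat[g, gain_sets[[g]]] <-
      expr_mat[g, gain_sets[[g]]] + config$dosage_shift * gene_sd[[g]]
  }
  expression <- tibble::tibble(
    gene = rep(genes, times = length(all_cols)),
    sample = rep(all_cols, each = length(genes)),
    expr = as.vector(expr_mat)
  )

  ## --- Clinical ------------------------------------------------------------
  altered <- samples[colSums(call_mat[planted, , drop = FALSE] == "GAIN") > 0L]
  base_rate <- log(2) / config$median_survival_months
  rate <- ifelse(samples %in% altered,
    base_rate * config$hazard_ratio_altered, base_rate
  )
  t_raw <- stats::rexp(length(samples), rate = rate)
  clinical <- tibble::tibble(
    sample = samples,
    os_months = round(pmin(t_raw, config$censor_horizon_months), 4),
    os_event = as.integer(t_raw <= config$censor_horizon_months)
  )
  # rounding could in principle produce 0; survival times must stay positive
  clinical$os_months[clinical$os_months <= 0] <- 0.0001

  ## --- Literature ----------------------------------------------------------
  positive_genes <- c(
    planted,
    background[stats::runif(length(background)) < config$prognosis_fraction]
  )
  tissues <- c(
    "breast", "ovarian", "lung", "gastric", "colorectal",
    "pancreatic", "bladder", "renal"
  )
  pos_templates <- c(
    "High %s expression predicts poor prognosis in %s cancer",
    "%s is a prognostic marker in %s carcinoma",
    "Overexpression of %s correlates with prognosis in %s tumour patients",
    "Low %s levels indicate favourable prognosis in %s tumor cohorts"
  )
  neg_templates <- c(
    "%s regulates mitotic spindle assembly in %s cell lines",
    "%s encodes a membrane transporter expressed in %s tissue",
    "%s phosphorylation modulates cytoskeletal dynamics in %s cells",
    "%s is prognostically relevant across %s carcinomas" # substring-only near miss
  )
  n_rec <- sample(1:3, length(genes), replace = TRUE)
  lit <- purrr::map2(genes, n_rec, function(g, k) {
    pos <- g %in% positive_genes
    tmpl <- if (pos) {
      sample(pos_templates, k, replace = TRUE)
    } else {
      sample(neg_templates, k, replace = TRUE)
    }
    tibble::tibble(
      gene_symbol = g,
      description = sprintf(tmpl, g, sample(tissues, k, replace = TRUE))
    )
  }) |> purrr::list_rbind()
  lit$pubmed_id <- as.character(10000000L + seq_len(nrow(lit)))
  literature <- lit[c("gene_symbol", "pubmed_id", "description")]

  ## --- Gene sets -----------------------------------------------------------
  set_names <- sprintf("GS%03d", seq_len(config$n_gene_sets))
  gene_sets <- list()
  planted_members <- planted[seq_len(config$planted_set_overlap)]
  filler <- sample(background, min(30L - length(planted_members), length(background)))
  gene_sets[[set_names[1L]]] <- sort(c(planted_members, filler))
  if (config$n_gene_sets > 1L) {
    for (nm in set_names[-1L]) {
      size <- sample(20:50, 1L)
      gene_sets[[nm]] <- sort(sample(genes, min(size, length(genes))))
    }
  }

  ## --- Interaction network -------------------------------------------------
  n_linkers <- min(30L, length(background))
  linker_genes <- sample(background, n_linkers)
  edges_list <- list()
  for (lg in linker_genes) {
    k <- sample(1:min(8L, length(planted)), 1L)
    edges_list[[lg]] <- tibble::tibble(
      gene_a = sort(sample(planted, k)), gene_b = lg
    )
  }
  # sparse background edges among a random slice of the universe
  pool <- sample(genes, min(80L, length(genes)))
  n_rand <- 60L
  rand_edges <- tibble::tibble(
    gene_a = sample(pool, n_rand, replace = TRUE),
    gene_b = sample(pool, n_rand, replace = TRUE)
  )
  edges <- dplyr::bind_rows(purrr::list_rbind(edges_list), rand_edges) |>
    dplyr::filter(.data$gene_a != .data$gene_b) |>
    dplyr::mutate(weight = round(stats::runif(dplyr::n(), 0.1, 1), 3)) |>
    dplyr::distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE)

  ## --- Ground truth (direct counting on the emitted matrices) --------------
  ref_mu <- rowMeans(expr_mat[, ref_samples, drop = FALSE])
  ref_sd <- apply(expr_mat[, ref_samples, drop = FALSE], 1L, stats::sd)
  truth <- purrr::map(planted, function(g) {
    gained <- gain_sets[[g]]
    z <- (expr_mat[g, gained] - ref_mu[[g]]) / ref_sd[[g]]
    tibble::tibble(
      gene = g,
      n_gain = length(gained),
      n_gain_over = sum(z > 2),
      gain_samples = paste(gained, collapse = ",")
    )
  }) |> purrr::list_rbind()

  structure(
    list(
      literature = literature,
      cnv = cnv,
      expression = expression,
      clinical = clinical,
      gene_sets = gene_sets,
      edges = edges,
      genes = genes,
      reference_samples = ref_samples,
      altered_samples = sort(altered),
      planted_set = set_names[1L],
      truth = truth,
      config = config
    ),
    class = "synthetic_bundle"
  )
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle> ", length(x$genes), " genes x ",
    x$config$n_samples, " tumour samples (+",
    length(x$reference_samples), " reference), seed ", x$config$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Emits the bundle as the plain-text formats the package readers consume:
#' tab-separated tables with a header row (`literature.tsv`,
#' `cnv_calls.tsv`, `expression.tsv` wide genes-by-samples,
#' `reference_samples.tsv`, `clinical.tsv`, `network.tsv`, `truth.tsv`) and a
#' standard GMT file (`gene_sets.gmt`). Output is deterministic: the same
#' bundle writes byte-identical files.
#'
#' @param bundle A `synthetic_bundle` from [generate_bundle()].
#' @param dir Output directory (created if needed).
#'
#' @return Invisibly, a named character vector of the written file paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  paths <- c(
    literature = file.path(dir, "literature.tsv"),
    cnv = file.path(dir, "cnv_calls.tsv"),
    expression = file.path(dir, "expression.tsv"),
    reference_samples = file.path(dir, "reference_samples.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    network = file.path(dir, "network.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(bundle$literature, paths[["literature"]])
  readr::write_tsv(bundle$cnv, paths[["cnv"]])
  expr_wide <- bundle$expression |>
    tidyr::pivot_wider(names_from = "sample", values_from = "expr") |>
    dplyr::arrange(match(.data$gene, bundle$genes))
  readr::write_tsv(expr_wide, paths[["expression"]])
  readr::write_tsv(
    tibble::tibble(sample = bundle$reference_samples),
    paths[["reference_samples"]]
  )
  readr::write_tsv(bundle$clinical, paths[["clinical"]])
  write_gmt(bundle$gene_sets, paths[["gene_sets"]])
  readr::write_tsv(bundle$edges, paths[["network"]])
  readr::write_tsv(bundle$truth, paths[["truth"]])
  invisible(paths)
}
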