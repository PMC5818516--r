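# Independent brute-force oracles. Each recomputes a pipeline quantity with
# plain loops over the raw records, deliberately avoiding the package's own
# code paths.

# gain/loss tallies per gene from a long call table
oracle_tally <- function(cnv) {
  genes <- sort(unique(cnv$gene))
  out <- data.frame(gene = genes, n_gain = 0L, n_loss = 0L)
  for (i in seq_len(nrow(cnv))) {
    j <- match(cnv$gene[i], genes)
    if (cnv$call[i] == "GAIN") out$n_gain[j] <- out$n_gain[j] + 1L
    if (cnv$call[i] == "LOSS") out$n_loss[j] <- out$n_loss[j] + 1L
  }
  out
}

# classification by literal transcription of the ratio rule
oracle_class <- function(n_gain, n_loss, cutoff = 2) {
  if (n_gain == 0 && n_loss == 0) return("BALANCED")
  if (n_loss == 0 || n_gain / n_loss > cutoff) {
    if (n_gain > 0) return("CNG")
  }
  if (n_gain == 0 || n_loss / n_gain > cutoff) {
    if (n_loss > 0) return("CNL")
  }
  "BALANCED"
}

# per-cell Z recomputation from a long expression table
oracle_z <- function(expr, ref_samples) {
  is_ref <- expr$sample %in% ref_samples
  out <- expr[!is_ref, , drop = FALSE]
  out$z <- NA_real_
  for (i in seq_len(nrow(out))) {
    ref_vals <- expr$expr[is_ref & expr$gene == out$gene[i]]
    out$z[i] <- (out$expr[i] - mean(ref_vals)) / sd(ref_vals)
  }
  out[c("gene", "sample", "z")]
}

# concordant counts by explicit set intersection per gene
oracle_concordance <- function(cnv, expr_calls, z_cutoff = 2) {
  shared <- intersect(unique(cnv$sample), unique(expr_calls$sample))
  genes <- sort(intersect(unique(cnv$gene), unique(expr_calls$gene)))
  res <- data.frame(
    gene = genes, n_gain = 0L, n_gain_over = 0L,
    n_loss = 0L, n_loss_under = 0L
  )
  for (j in seq_along(genes)) {
    g <- genes[j]
    gain_s <- cnv$sample[cnv$gene == g & cnv$call == "GAIN"]
    loss_s <- cnv$sample[cnv$gene == g & cnv$call == "LOSS"]
    over_s <- expr_calls$sample[expr_calls$gene == g & expr_calls$over]
    under_s <- expr_calls$sample[expr_calls$gene == g & expr_calls$under]
    res$n_gain[j] <- length(intersect(gain_s, shared))
    res$n_loss[j] <- length(intersect(loss_s, shared))
    res$n_gain_over[j] <- length(intersect(intersect(gain_s, over_s), shared))
    res$n_loss_under[j] <- length(intersect(intersect(loss_s, under_s), shared))
  }
  res
}

# per-cohort altered fraction by double loop over (sample, gene)
oracle_altered_fraction <- function(cnv, genes, cohort) {
  rows <- cnv[cnv$cohort == cohort, , drop = FALSE]
  samples <- unique(rows$sample)
  altered <- 0L
  for (s in samples) {
    hit <- FALSE
    for (g in genes) {
      calls <- rows$call[rows$sample == s & rows$gene == g]
      if (length(calls) > 0L && any(calls != "NEUTRAL")) hit <- TRUE
    }
    if (hit) altered <- altered + 1L
  }
  altered / length(samples)
}

# per-gene gain frequency in one cohort by direct counting
oracle_gain_freq <- function(cnv, gene, cohort) {
  rows <- cnv[cnv$cohort == cohort & cnv$gene == gene, , drop = FALSE]
  sum(rows$call == "GAIN") / length(unique(rows$sample))
}

# node degrees by scanning a de-duplicated undirected edge list
oracle_degree <- function(edges) {
  seen <- character()
  a <- character()
  b <- character()
  for (i in seq_len(nrow(edges))) {
    u <- edges$gene_a[i]
    v <- edges$gene_b[i]
    if (u == v) next
    key <- paste(sort(c(u, v)), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    a <- c(a, u)
    b <- c(b, v)
  }
  nodes <- sort(unique(c(a, b)))
  deg <- vapply(nodes, function(n) sum(a == n) + sum(b == n), integer(1))
  data.frame(gene = nodes, degree = as.integer(deg))
}

# second, independent product-limit implementation: walks subjects ordered by
# time, updating the risk set one subject at a time
oracle_km <- function(time, event) {
  ord <- order(time, !event) # deaths before censorings at ties
  time <- time[ord]
  event <- as.logical(event)[ord]
  s <- 1
  at_risk <- length(time)
  res_t <- numeric()
  res_s <- numeric()
  for (t in sort(unique(time))) {
    d <- sum(time == t & event)
    if (d > 0) s <- s * (1 - d / at_risk)
    res_t <- c(res_t, t)
    res_s <- c(res_s, s)
    at_risk <- at_risk - sum(time == t)
  }
  data.frame(time = res_t, surv = res_s)
}

# small, cheap generator configuration for property loops
tiny_config <- function(seed, ...) {
  args <- list(
    n_genes = 40, n_samples = 60, n_cohorts = 2,
    n_reference_samples = 10,
    planted_genes = c("DRV01", "DRV02", "DRV03"),
    planted_gain_fraction = 0.2, dosage_shift = 3,
    background_gain_rate = 0.05, background_loss_rate = 0.05,
    n_gene_sets = 5, planted_set_overlap = 3, seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synth_config, args)
}

# survival records with a given hazard ratio, exponential baseline
sim_survival <- function(n_per_group, hr, censor = 80, median0 = 40) {
  rate0 <- log(2) / median0
  t1 <- rexp(n_per_group, rate0 * hr)
  t0 <- rexp(n_per_group, rate0)
  data.frame(
    time = pmax(pmin(c(t1, t0), censor), 1e-6),
    event = c(t1, t0) <= censor,
    group = rep(c("ALTERED", "UNALTERED"), each = n_per_group)
  )
}
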