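test_that("Z-scores follow the (x - mu) / sigma arithmetic", {
  # three reference samples with mean 4, sd 3; one tumour sample at 10
  expr <- tibble::tibble(
    gene = "A",
    sample = c("r1", "r2", "r3", "t1"),
    expr = c(1, 4, 7, 10)
  )
  z <- expression_zscores(expr, reference_samples = c("r1", "r2", "r3"))
  expect_equal(z$z, (10 - 4) / 3)
  expr$expr[4] <- 4 # tumour at the reference mean
  z0 <- expression_zscores(expr, reference_samples = c("r1", "r2", "r3"))
  expect_equal(z0$z, 0)
})

test_that("Z-scores on random matrices match direct re-computation to 1e-12", {
  for (seed in 1:3) {
    set.seed(seed)
    genes <- sprintf("g%02d", 1:20)
    samples <- sprintf("s%02d", 1:30)
    refs <- samples[1:8]
    expr <- expand.grid(gene = genes, sample = samples, stringsAsFactors = FALSE)
    expr$expr <- rnorm(nrow(expr), mean = 10, sd = 2)
    got <- expression_zscores(expr, reference_samples = refs)
    want <- oracle_z(expr, refs)
    merged <- merge(got, want, by = c("gene", "sample"))
    expect_equal(merged$z.x, merged$z.y, tolerance = 1e-12)
  }
})

test_that("zero-variance genes are excluded with a warning", {
  expr <- tibble::tibble(
    gene = rep(c("flat", "ok"), each = 4),
    sample = rep(c("r1", "r2", "r3", "t1"), 2),
    expr = c(5, 5, 5, 9, 1, 2, 3, 4)
  )
  expect_warning(
    z <- expression_zscores(expr, reference_samples = c("r1", "r2", "r3")),
    "standard deviation"
  )
  expect_identical(unique(z$gene), "ok")
})

test_that("over/under-expression calls are strict at the cutoff", {
  z <- tibble::tibble(
    gene = "A", sample = paste0("s", 1:4),
    z = c(2.1, 2.0, -2.5, NA)
  )
  calls <- call_expression(z)
  expect_identical(calls$over, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(calls$under, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("concordance is the per-gene intersection of gained and over-expressed samples", {
  cnv <- tibble::tibble(
    gene = "A",
    sample = paste0("s", 1:5),
    call = c("GAIN", "GAIN", "GAIN", "NEUTRAL", "LOSS")
  )
  ex <- tibble::tibble(
    gene = "A", sample = paste0("s", 1:5),
    over = c(FALSE, TRUE, TRUE, TRUE, FALSE),
    under = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  rec <- suppressMessages(count_concordance(cnv, ex))
  expect_identical(rec$n_gain_over, 2L) # s2, s3
  expect_identical(rec$n_loss_under, 1L) # s5

  disjoint <- ex
  disjoint$over <- c(FALSE, FALSE, FALSE, TRUE, FALSE) # only the neutral sample
  expect_identical(
    suppressMessages(count_concordance(cnv, disjoint))$n_gain_over, 0L
  )
})

test_that("zero shared samples is an error naming both sample sets", {
  cnv <- tibble::tibble(gene = "A", sample = "x1", call = "GAIN")
  ex <- tibble::tibble(gene = "A", sample = "y1", over = TRUE, under = FALSE)
  expect_error(count_concordance(cnv, ex), "share no sample")
})

test_that("pipeline concordance reproduces the generator's ground truth exactly", {
  for (seed in c(3, 17)) {
    bundle <- generate_bundle(tiny_config(seed))
    z <- expression_zscores(bundle$expression, bundle$reference_samples)
    calls <- call_expression(z)
    rec <- suppressMessages(
      count_concordance(bundle$cnv, calls, genes = bundle$truth$gene)
    )
    merged <- merge(bundle$truth, rec, by = "gene")
    expect_identical(merged$n_gain.x, merged$n_gain.y)
    expect_identical(merged$n_gain_over.x, merged$n_gain_over.y)
    # and the brute-force intersection oracle agrees as well
    oracle <- oracle_concordance(bundle$cnv, calls)
    merged2 <- merge(rec, oracle, by = "gene")
    expect_identical(merged2$n_gain_over.x, merged2$n_gain_over.y)
    expect_identical(merged2$n_loss_under.x, merged2$n_loss_under.y)
  }
})

test_that("Z-scores and downstream calls are invariant to affine rescaling", {
  bundle <- generate_bundle(tiny_config(5))
  expr2 <- bundle$expression
  # rescale one gene: x -> a*x + b with a > 0
  g <- bundle$truth$gene[1]
  sel <- expr2$gene == g
  expr2$expr[sel] <- 3.7 * expr2$expr[sel] - 11
  z1 <- expression_zscores(bundle$expression, bundle$reference_samples)
  z2 <- expression_zscores(expr2, bundle$reference_samples)
  expect_equal(z1$z[z1$gene == g], z2$z[z2$gene == g], tolerance = 1e-10)
})

test_that("n_gain_over is non-increasing in the z cutoff", {
  bundle <- generate_bundle(tiny_config(9))
  z <- expression_zscores(bundle$expression, bundle$reference_samples)
  counts <- vapply(c(1, 1.5, 2, 2.5, 3), function(zc) {
    calls <- call_expression(z, pipeline_thresholds(z_cutoff = zc))
    rec <- suppressMessages(
      count_concordance(bundle$cnv, calls, genes = bundle$truth$gene)
    )
    sum(rec$n_gain_over)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("key-gene selection is strict in count mode and supports ratio mode", {
  rec <- tibble::tibble(
    gene = c("keep", "boundary", "ratio_pass"),
    n_gain = c(40L, 40L, 40L),
    n_gain_over = c(21L, 20L, 5L),
    n_loss = c(0L, 0L, 0L),
    n_loss_under = c(0L, 0L, 0L)
  )
  count_sel <- select_key_genes(rec)
  expect_identical(count_sel$gene, "keep")
  # ratio mode: 5 / 0 is treated as infinite, hence passes the > 20 gate
  ratio_sel <- select_key_genes(rec, mode = "ratio")
  expect_setequal(ratio_sel$gene, c("keep", "boundary", "ratio_pass"))
})

test_that("planted drivers are recovered exactly at strong dosage shift", {
  cfg <- tiny_config(21,
    n_samples = 200, planted_gain_fraction = 0.25,
    background_gain_rate = 0.02, background_loss_rate = 0.02
  )
  bundle <- generate_bundle(cfg)
  th <- pipeline_thresholds(min_cng_samples = 20, min_concordant_samples = 15)
  prof <- profile_cnv(bundle$cnv, thresholds = th)
  freq <- filter_frequent_cng(prof, th)
  z <- expression_zscores(bundle$expression, bundle$reference_samples)
  calls <- call_expression(z, th)
  rec <- suppressMessages(count_concordance(bundle$cnv, calls, genes = freq$gene))
  key <- select_key_genes(rec, th)
  expect_setequal(key$gene, cfg$planted_genes)
})
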