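test_that("the same configuration and seed reproduce byte-identical files", {
  cfg <- tiny_config(99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_bundle(generate_bundle(cfg), d1)
  p2 <- write_bundle(generate_bundle(cfg), d2)
  expect_identical(names(p1), names(p2))
  for (nm in names(p1)) {
    expect_identical(
      unname(tools::md5sum(p1[[nm]])),
      unname(tools::md5sum(p2[[nm]])),
      info = nm
    )
  }
  # and a different seed changes the data
  p3 <- write_bundle(generate_bundle(tiny_config(100)), withr::local_tempdir())
  expect_false(identical(
    unname(tools::md5sum(p1[["cnv"]])),
    unname(tools::md5sum(p3[["cnv"]]))
  ))
})

test_that("planted genes receive exactly round(fraction * n) GAIN calls", {
  cfg <- tiny_config(3, n_samples = 60, planted_gain_fraction = 0.1)
  bundle <- generate_bundle(cfg)
  gains <- table(bundle$cnv$gene[bundle$cnv$call == "GAIN"])
  for (g in cfg$planted_genes) {
    expect_identical(unname(gains[g]), 6L)
  }
  # at the headline scale: fraction 0.1 of 600 samples is exactly 60
  big <- generate_bundle(synth_config(seed = 5))
  big_gains <- table(big$cnv$gene[big$cnv$call == "GAIN"])
  expect_true(all(big_gains[synth_config()$planted_genes] == 60L))
})

test_that("counting GAIN calls in the emitted matrix reproduces the truth table", {
  bundle <- generate_bundle(tiny_config(23))
  for (i in seq_len(nrow(bundle$truth))) {
    g <- bundle$truth$gene[i]
    emitted <- sort(bundle$cnv$sample[bundle$cnv$gene == g & bundle$cnv$call == "GAIN"])
    expect_identical(paste(emitted, collapse = ","), bundle$truth$gain_samples[i])
    expect_identical(length(emitted), bundle$truth$n_gain[i])
  }
})

test_that("reference samples carry no CNV calls and no dosage shift", {
  cfg <- tiny_config(8, dosage_shift = 5)
  bundle <- generate_bundle(cfg)
  expect_length(intersect(bundle$reference_samples, bundle$cnv$sample), 0L)
  # reference expression of planted genes stays near the background mean:
  # a 5-SD shift applied to references would push their mean far off
  ref_expr <- bundle$expression[bundle$expression$sample %in% bundle$reference_samples, ]
  tum_expr <- bundle$expression[!bundle$expression$sample %in% bundle$reference_samples, ]
  g <- cfg$planted_genes[1]
  gained <- strsplit(bundle$truth$gain_samples[bundle$truth$gene == g], ",")[[1]]
  ref_mean <- mean(ref_expr$expr[ref_expr$gene == g])
  gain_mean <- mean(tum_expr$expr[tum_expr$gene == g & tum_expr$sample %in% gained])
  expect_gt(gain_mean - ref_mean, 2) # shifted tumours sit far above reference
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(synth_config(n_reference_samples = 2), "n_reference_samples")
  expect_error(synth_config(planted_gain_fraction = 1.5), "planted_gain_fraction")
  expect_error(synth_config(background_gain_rate = 0.9, background_loss_rate = 0.9),
    "background_gain_rate"
  )
  expect_error(synth_config(planted_genes = c("A", "A")), "planted_genes")
  expect_error(
    synth_config(n_genes = 5, planted_genes = sprintf("D%d", 1:9)),
    "planted_genes"
  )
  expect_error(synth_config(hazard_ratio_altered = -1), "hazard_ratio_altered")
  expect_error(
    synth_config(planted_set_overlap = 99),
    "planted_set_overlap"
  )
})

test_that("emitted files round-trip through the module readers", {
  bundle <- generate_bundle(tiny_config(44))
  dir <- withr::local_tempdir()
  paths <- write_bundle(bundle, dir)

  lit <- read_literature_tsv(paths[["literature"]])
  expect_identical(nrow(lit), nrow(bundle$literature))

  cnv <- read_cnv_calls(paths[["cnv"]])
  expect_identical(nrow(cnv), nrow(bundle$cnv))
  expect_setequal(unique(cnv$cohort), unique(bundle$cnv$cohort))

  expr <- read_expression_tsv(paths[["expression"]])
  expect_identical(nrow(expr), nrow(bundle$expression))
  merged <- merge(expr, bundle$expression, by = c("gene", "sample"))
  expect_equal(merged$expr.x, merged$expr.y, tolerance = 1e-9)

  refs <- read_reference_samples(paths[["reference_samples"]])
  expect_identical(refs, bundle$reference_samples)

  clin <- read_clinical_tsv(paths[["clinical"]])
  expect_identical(clin$sample, bundle$clinical$sample)
  expect_true(all(clin$os_months > 0))

  sets <- read_gmt(paths[["gene_sets"]])
  expect_identical(names(sets), names(bundle$gene_sets))
  expect_identical(sets[[1]], bundle$gene_sets[[1]])

  edges <- read_edge_list(paths[["network"]])
  expect_identical(nrow(edges), nrow(bundle$edges))
})

test_that("literature for planted genes always carries the keyword pattern", {
  bundle <- generate_bundle(tiny_config(71))
  planted_lit <- bundle$literature[
    bundle$literature$gene_symbol %in% bundle$config$planted_genes,
  ]
  expect_true(all(matches_prognosis_pattern(planted_lit$description)))
})

test_that("a zero dosage shift leaves concordance at the null exceedance rate", {
  # Monte-Carlo null calibration at a size where binomial error is tight:
  # with Z called against an estimated reference mean/SD, the exceedance
  # probability is known analytically only up to estimation noise, so a large
  # reference set is used and the band is 3 binomial SDs around n * P(Z > 2).
  cfg <- synth_config(
    n_genes = 30, n_samples = 5000, n_reference_samples = 500,
    planted_genes = sprintf("DRV%02d", 1:12), planted_gain_fraction = 0.1,
    dosage_shift = 0, background_gain_rate = 0.01,
    background_loss_rate = 0.01, n_gene_sets = 3, planted_set_overlap = 3,
    seed = 424
  )
  bundle <- generate_bundle(cfg)
  p_null <- stats::pnorm(2, lower.tail = FALSE)
  n_gain <- bundle$truth$n_gain[1]
  expected <- n_gain * p_null
  band <- 3 * sqrt(n_gain * p_null * (1 - p_null) / nrow(bundle$truth))
  expect_lt(abs(mean(bundle$truth$n_gain_over) - expected), band)
})
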