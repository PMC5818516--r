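test_that("product-limit arithmetic: one death among four at risk gives S = 0.75", {
  km <- km_fit(data.frame(
    time = c(2, 3, 5, 7),
    event = c(TRUE, FALSE, FALSE, FALSE)
  ))
  expect_equal(km$surv[km$time == 2], 0.75)
  expect_true(all(diff(km$surv) <= 0))
})

test_that("with no events the curve stays at 1 and the median is undefined", {
  km <- km_fit(data.frame(time = c(1, 2, 3), event = FALSE))
  expect_true(all(km$surv == 1))
  expect_true(is.na(attr(km, "medians")[["all"]]))
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(9)
  time <- rexp(60, 0.02)
  km <- km_fit(data.frame(time = time, event = TRUE))
  ecdf_surv <- vapply(km$time, function(t) mean(time > t), numeric(1))
  expect_equal(km$surv, ecdf_surv, tolerance = 1e-12)
})

test_that("KM matches an independent product-limit implementation to 1e-12", {
  set.seed(31)
  for (i in 1:5) {
    time <- round(rexp(50, 0.03), 1) + 0.1 # rounding forces ties
    event <- runif(50) < 0.7
    km <- km_fit(data.frame(time = time, event = event))
    oracle <- oracle_km(time, event)
    expect_equal(km$time, oracle$time)
    expect_equal(km$surv, oracle$surv, tolerance = 1e-12)
  }
})

test_that("KM also agrees with survival::survfit, censoring included", {
  set.seed(77)
  time <- round(rexp(80, 0.02), 1) + 0.1
  event <- runif(80) < 0.6
  km <- km_fit(data.frame(time = time, event = event))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  sf_s <- summary(sf, times = km$time)
  expect_equal(km$surv, sf_s$surv, tolerance = 1e-12)
})

test_that("median survival is the first time S drops to 0.5 or below", {
  # 4 subjects, deaths at 1, 2, 3 -> S = .75, .5, .25: median at time 2
  km <- km_fit(data.frame(time = 1:4, event = c(TRUE, TRUE, TRUE, FALSE)))
  expect_equal(attr(km, "medians")[["all"]], 2)
})

test_that("identical groups give a zero log-rank statistic and p = 1", {
  df <- data.frame(
    time = rep(c(3, 5, 8, 13), 2),
    event = rep(c(TRUE, TRUE, FALSE, TRUE), 2),
    group = rep(c("ALTERED", "UNALTERED"), each = 4)
  )
  lr <- log_rank(df)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)
})

test_that("complete group separation at large n gives a significant log-rank", {
  df <- data.frame(
    time = c(1:40, 101:140),
    event = TRUE,
    group = rep(c("ALTERED", "UNALTERED"), each = 40)
  )
  lr <- log_rank(df)
  expect_gt(lr$statistic, 10)
  expect_lt(lr$p_value, 0.05)
})

test_that("log-rank matches survival::survdiff to 1e-8 on random fixtures", {
  set.seed(2024)
  for (i in 1:20) {
    df <- sim_survival(30, hr = 3)
    df$time <- round(df$time, 1) + 0.05 # ties
    lr <- log_rank(df)
    sd_fit <- survival::survdiff(
      survival::Surv(time, event) ~ group,
      data = df
    )
    expect_equal(lr$statistic, sd_fit$chisq, tolerance = 1e-8)
    expect_equal(lr$p_value,
      stats::pchisq(sd_fit$chisq, 1, lower.tail = FALSE),
      tolerance = 1e-8
    )
  }
})

test_that("the log-rank statistic is invariant to swapping group labels", {
  set.seed(4)
  df <- sim_survival(25, hr = 2)
  swapped <- df
  swapped$group <- ifelse(df$group == "ALTERED", "UNALTERED", "ALTERED")
  expect_equal(log_rank(df)$statistic, log_rank(swapped)$statistic,
    tolerance = 1e-12
  )
})

test_that("group assignment follows gain/loss calls in the listed genes", {
  cnv <- tibble::tibble(
    gene = rep(c("A", "B"), each = 3),
    sample = rep(c("s1", "s2", "s3"), 2),
    call = c("GAIN", "NEUTRAL", "NEUTRAL", "NEUTRAL", "LOSS", "NEUTRAL")
  )
  clinical <- tibble::tibble(
    sample = c("s1", "s2", "s3"),
    os_months = c(10, 20, 30),
    os_event = c(1L, 0L, 1L)
  )
  grp <- assign_alteration_groups(cnv, c("A", "B"), clinical)
  expect_identical(
    as.character(grp$group[match(c("s1", "s2", "s3"), grp$sample)]),
    c("ALTERED", "ALTERED", "UNALTERED")
  )
  # restricting the list to gene A leaves only s1 altered
  grp_a <- assign_alteration_groups(cnv, "A", clinical)
  expect_identical(sum(grp_a$group == "ALTERED"), 1L)
  expect_error(
    assign_alteration_groups(cnv, "A", dplyr::mutate(clinical, sample = paste0("x", sample))),
    "share no sample"
  )
})

test_that("synthetic bundle groups equal the generator's altered-sample truth", {
  bundle <- generate_bundle(tiny_config(12))
  grp <- assign_alteration_groups(
    # altered is defined by planted-gene GAINs in the generator, so restrict
    # the call table to gains for the comparison
    bundle$cnv[bundle$cnv$call != "LOSS", ],
    bundle$config$planted_genes, bundle$clinical
  )
  expect_setequal(grp$sample[grp$group == "ALTERED"], bundle$altered_samples)
})

test_that("a single-group input errors in log_rank", {
  df <- data.frame(time = 1:5, event = TRUE, group = "ALTERED")
  expect_error(log_rank(df), "two non-empty groups")
})
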