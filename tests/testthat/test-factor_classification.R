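test_that("single-gene calls reproduce the worked drug-target examples", {
  th <- factor_thresholds()
  kcnj6 <- classify_gene(list(symbol = "KCNJ6", proximity = 9, a_plus_t = 60), th)
  expect_equal(as.character(kcnj6$category), "BOTH")
  kcnk4 <- classify_gene(list(symbol = "KCNK4", proximity = 71, a_plus_t = 34), th)
  expect_equal(as.character(kcnk4$category), "NONE")
  cacna2d1 <- classify_gene(list(symbol = "CACNA2D1", proximity = 76,
                                 a_plus_t = 64), th)
  expect_equal(as.character(cacna2d1$category), "FII_ONLY")
})

test_that("boundary genes fail both factors under strict defaults", {
  rec <- make_records("EDGE", proximity = 50, a_plus_t = 59)
  strict <- classify_genes(rec)
  expect_equal(as.character(strict$category), "NONE")
  relaxed <- classify_genes(rec, factor_thresholds(strict_fi = FALSE,
                                                   strict_fii = FALSE))
  expect_equal(as.character(relaxed$category), "BOTH")
})

test_that("missing inputs and bad thresholds raise informative errors", {
  rec <- make_records(c("OKG", "BADG"), proximity = c(10, NA),
                      a_plus_t = c(60, 55))
  expect_error(classify_genes(rec), "BADG")
  expect_error(factor_thresholds(proximity_cutoff = 0), "positive")
  expect_error(summarize_cohort(classify_genes(rec[1, ])[0, ]), "empty")
})

test_that("cohort summaries match the published drug-target counts", {
  t1 <- summarize_cohort(classify_genes(drug_target_table("ion_channels")))
  expect_equal(t1$n, 11)
  expect_equal(t1$either_count, 9)
  expect_equal(t1$matching_pct, 82)

  t2 <- summarize_cohort(classify_genes(drug_target_table("gpcrs")))
  expect_equal(t2$either_count, 15)
  expect_equal(t2$counts[["NONE"]], 5)

  all_none <- summarize_cohort(
    classify_genes(make_records(c("N1", "N2"), c(90, 80), c(40, 41))))
  expect_equal(all_none$matching_rate, 0)
})

test_that("summaries equal a brute-force recount on small random cohorts", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(1:25, 1)
    calls <- classify_genes(random_cohort(n))
    s <- summarize_cohort(calls)
    oracle <- brute_force_summary(calls)
    expect_equal(s$counts, oracle$counts)
    expect_equal(s$either_count, oracle$either_count)
    expect_equal(s$matching_rate, oracle$matching_rate)
    expect_equal(sum(s$counts), n)  # partition property
  }
})

test_that("factor counts are monotone in the thresholds", {
  set.seed(41)
  cohort <- random_cohort(60)
  at_cuts <- c(70, 59, 55, 45, 35)
  fii <- vapply(at_cuts, function(cut) {
    sum(classify_genes(cohort, factor_thresholds(at_cutoff = cut))$meets_fii)
  }, integer(1))
  expect_true(all(diff(fii) >= 0))  # lowering the A+T cutoff never loses genes
  prox_cuts <- c(10, 30, 50, 100, 160)
  fi <- vapply(prox_cuts, function(cut) {
    sum(classify_genes(cohort,
                       factor_thresholds(proximity_cutoff = cut))$meets_fi)
  }, integer(1))
  expect_true(all(diff(fi) >= 0))  # raising the proximity cutoff never loses genes
})

test_that("prioritization ranks within the Both and None groups", {
  t1 <- drug_target_table("ion_channels")
  calls <- classify_genes(t1)
  expect_setequal(prioritize(t1, calls, "NONE", 5), c("KCNK4", "GABRB3"))
  expect_equal(prioritize(t1, calls, "NONE", 0), character(0))

  # constructed 5-gene cohort, ranking checked by hand:
  # BOTH group sorted by A+T desc then proximity asc; the single BOTH gene
  # with the top A+T leads
  cohort <- make_records(
    symbol = c("B1", "B2", "N1", "N2", "F1"),
    proximity = c(10, 5, 90, 70, 20),
    a_plus_t = c(66, 63, 40, 40, 45))
  calls <- classify_genes(cohort)
  expect_equal(prioritize(cohort, calls, "BOTH", 5), c("B1", "B2"))
  expect_equal(prioritize(cohort, calls, "BOTH", 1), "B1")
  # NONE group: A+T asc, proximity desc breaks the tie -> N1 before N2
  expect_equal(prioritize(cohort, calls, "NONE", 5), c("N1", "N2"))
})
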