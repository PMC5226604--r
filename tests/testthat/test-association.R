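test_that("pearson matches hand-expanded sums and handles exact linearity", {
  # manual arithmetic for {(0,0),(1,1),(2,0),(3,1)}:
  # dx = (-1.5,-0.5,0.5,1.5), dy = (-0.5,0.5,-0.5,0.5)
  # sum dx dy = 1, ssx = 5, ssy = 1 -> r = 1/sqrt(5)
  res <- pearson(c(0, 1, 2, 3), c(0, 1, 0, 1))
  expect_equal(res$statistic, 1 / sqrt(5), tolerance = 1e-12)
  expect_identical(res$df, 2)

  lin <- pearson(1:10, 2 * (1:10) + 1)
  expect_equal(lin$statistic, 1)
  expect_equal(lin$p_value, 0)

  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)),
               class = "rasmct_validation_error")
  expect_error(pearson(1:4, 1:5), class = "rasmct_contract_error")
  expect_error(pearson(1:2, 2:3), class = "rasmct_contract_error")
})

test_that("welch matches the closed formula on a hand case and is symmetric", {
  a <- c(0, 0, 1, 1); b <- c(10, 10, 11, 11)
  # means 0.5 / 10.5, var 1/3 each: t = -10 / sqrt(1/6), df = 6
  res <- welch_t_test(a, b)
  expect_equal(res$statistic, -10 / sqrt(1 / 6), tolerance = 1e-12)
  expect_equal(res$df, 6, tolerance = 1e-12)

  ident <- welch_t_test(c(1, 2, 3), c(3, 2, 1))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  set.seed(61)
  x <- rnorm(9); y <- rnorm(14, 1)
  expect_equal(welch_t_test(x, y)$p_value, welch_t_test(y, x)$p_value,
               tolerance = 1e-14)
  expect_error(welch_t_test(1, c(1, 2)), class = "rasmct_contract_error")
})

test_that("hand-rolled statistics agree with stats:: references on random data", {
  set.seed(71)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n, sd = runif(1, 0.5, 2))
    ours <- pearson(x, y)
    ref <- cor.test(x, y)
    expect_equal(ours$statistic, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)

    a <- rnorm(sample(2:20, 1)); b <- rnorm(sample(2:20, 1), mean = runif(1))
    ourw <- welch_t_test(a, b)
    refw <- t.test(a, b)
    expect_equal(ourw$statistic, unname(refw$statistic), tolerance = 1e-10)
    expect_equal(ourw$df, unname(refw$parameter), tolerance = 1e-10)
    expect_equal(ourw$p_value, refw$p.value, tolerance = 1e-10)
  }
})

test_that("pearson is affine-invariant and flips sign under negation", {
  set.seed(81)
  x <- rnorm(15); y <- rnorm(15)
  r0 <- pearson(x, y)$statistic
  expect_equal(pearson(2.5 * x + 3, 0.1 * y - 7)$statistic, r0,
               tolerance = 1e-12)
  expect_equal(pearson(-x, y)$statistic, -r0, tolerance = 1e-12)
})

test_that("stratified association reproduces the genotype subgroup structure", {
  tbl <- load_cetuximab_mct()
  res <- stratified_association(tbl)
  expect_identical(res$subgroup, c("all", "WT", "mutant"))
  expect_identical(res$n, c(25L, 15L, 10L))
  expect_identical(res$df, c(23, 13, 8))

  one <- stratified_association(tbl, strata = "none")
  expect_equal(one$statistic, res$statistic[res$subgroup == "all"])

  fine <- stratified_association(tbl, strata = "kras_fine")
  expect_identical(fine$n[fine$subgroup == "G12x"], 4L)
  expect_identical(fine$n[fine$subgroup == "G13D"], 6L)

  tiny <- model_table(data.frame(
    model_id = c("A", "B", "C"), ras_score = c(1, 2, 3),
    delta_t_over_delta_c = c(0.1, 0.2, 0.3),
    kras_allele = c("WT", "WT", "G12D")))
  w <- capture_warnings(res2 <- stratified_association(tiny))
  expect_match(w, "skipped", all = TRUE)
  expect_length(w, 2L)  # WT (n = 2) and mutant (n = 1) both too small
  expect_identical(res2$subgroup, "all")
})

test_that("sign contingency counts are exhaustive and threshold-monotone", {
  tbl <- load_cetuximab_mct()
  sc <- sign_contingency(tbl)
  for (nm in names(sc$tables)) {
    n_expected <- c(all = 25L, WT = 15L, mutant = 10L)[[nm]]
    expect_identical(sum(sc$tables[[nm]]), n_expected)
  }
  expect_identical(sc$tables$WT["score_positive", "poor"], 6L)
  # 4 of 10 mutants with strictly negative scores
  mut <- tbl[tbl$kras_class != "WT", ]
  expect_identical(sum(mut$ras_score < 0), 4L)
  expect_identical(sum(sc$tables$mutant["score_non_positive", ]), 4L)

  # strict boundary: a model at exactly 0 lands in the non-positive margin
  zero <- model_table(data.frame(
    model_id = c("A", "B", "C"), ras_score = c(0, 0, 0),
    delta_t_over_delta_c = c(0, 1, -1), kras_allele = "WT"))
  scz <- sign_contingency(zero, strata = "none")
  expect_identical(sum(scz$tables$all["score_non_positive", ]), 3L)
  expect_identical(scz$tables$all["score_non_positive", "poor"], 1L)

  # raising the response threshold can only shrink the poor margin
  poor_at <- function(th) sum(sign_contingency(tbl, response_threshold = th,
                                               strata = "none")$tables$all[, "poor"])
  ths <- c(-1, 0, 0.2, 0.5, 1, 2)
  expect_true(all(diff(vapply(ths, poor_at, numeric(1))) <= 0))
})

test_that("covariate screen reports raw and BH-adjusted p-values", {
  set.seed(91)
  tbl <- load_cetuximab_mct()
  tbl$EGFR <- rnorm(25, 2.5, 0.4)
  tbl$EREG <- rnorm(25, 2.0, 0.4)
  tbl$AREG <- rnorm(25, 1.8, 0.4)
  res <- covariate_screen(tbl, c("EGFR", "EREG", "AREG"))
  expect_identical(nrow(res), 3L)
  expect_true(all(res$p_bh >= res$p_value))

  tbl$SELF <- tbl$delta_t_over_delta_c
  expect_equal(covariate_screen(tbl, "SELF")$r, 1)

  tbl$FLAT <- 1
  expect_warning(res2 <- covariate_screen(tbl, c("EGFR", "FLAT")), "skipped")
  expect_identical(res2$covariate, "EGFR")

  # null covariates: BH keeps the family-wise false-positive count near zero
  set.seed(92)
  hits <- replicate(40, {
    for (j in 1:20) tbl[[paste0("NULLCOV", j)]] <- rnorm(25)
    sum(covariate_screen(tbl, paste0("NULLCOV", 1:20))$p_bh < 0.05)
  })
  expect_lt(mean(hits), 1)
})
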