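test_that("signature mapping reports requested/mapped counts and fails when empty", {
  set.seed(11)
  m <- random_matrix(150, 4)
  sig <- gene_signature("RAS",
                        up = c(rownames(m)[1:97], sprintf("MISSU%02d", 1:8)),
                        down = c(rownames(m)[98:129],
                                 sprintf("MISSD%02d", 1:10)))
  mapped <- map_signature(sig, m)
  rep <- mapped$report
  expect_identical(c(rep$n_up_requested, rep$n_up_mapped,
                     rep$n_down_requested, rep$n_down_mapped),
                   c(105L, 97L, 42L, 32L))
  expect_length(rep$unmapped_up, 105 - 97)
  expect_length(rep$unmapped_down, 42 - 32)

  full <- gene_signature("FULL", rownames(m)[1:5], rownames(m)[6:8])
  rep2 <- map_signature(full, m)$report
  expect_identical(rep2$n_up_mapped, rep2$n_up_requested)
  expect_length(rep2$unmapped_down, 0)

  none <- gene_signature("NONE", rownames(m)[1:3], c("ZZZ1", "ZZZ2"))
  expect_error(map_signature(none, m), "scoring impossible",
               class = "rasmct_validation_error")
})

test_that("z-normalization yields exact per-gene mean 0 / sd 1 and drops flat genes", {
  v <- matrix(c(1, 2, 3), 1, 3, dimnames = list("A", c("s1", "s2", "s3")))
  z <- zscore_normalize(expression_matrix(v, "log2"))
  expect_equal(unname(unclass(z)[1, ]), c(-1, 0, 1))

  set.seed(21)
  m <- random_matrix(50, 20)
  z2 <- zscore_normalize(m)
  expect_true(all(abs(rowMeans(unclass(z2))) < 1e-10))
  expect_true(all(abs(apply(unclass(z2), 1, sd) - 1) < 1e-10))
  expect_identical(scale_tag(z2), "zscored")

  flat <- unclass(m)
  flat[3, ] <- 7
  expect_warning(z3 <- zscore_normalize(expression_matrix(flat, "log10")),
                 "zero-variance")
  expect_identical(nrow(z3), 49L)
  expect_false("G003" %in% rownames(z3))
  expect_true(all(is.finite(unclass(z3))))

  single <- unclass(m)[, 1, drop = FALSE]
  expect_error(zscore_normalize(expression_matrix(single, "log10")),
               class = "rasmct_validation_error")
})

test_that("score_samples implements mean(up z) - mean(down z) with provenance", {
  v <- matrix(c(1, 2, 4,
                0, 1, 5,
                3, 2, 1), 3, 3, byrow = TRUE,
              dimnames = list(c("U1", "U2", "D1"), c("s1", "s2", "s3")))
  sig <- gene_signature("TOY", c("U1", "U2"), "D1")
  res <- score_pipeline(expression_matrix(v, "log10"), sig)
  manual <- brute_force_scores(v, c("U1", "U2"), "D1")
  expect_equal(res$scores$score, unname(manual), tolerance = 1e-12)
  prov <- attr(res$scores, "provenance")
  expect_identical(prov$n_up_used, 2L)
  expect_identical(prov$n_down_used, 1L)

  # identical up and down rows cancel exactly
  v2 <- matrix(c(1, 2, 3, 1, 2, 3), 2, 3, byrow = TRUE,
               dimnames = list(c("U", "D"), c("a", "b", "c")))
  res2 <- score_pipeline(expression_matrix(v2, "log10"),
                         gene_signature("T", "U", "D"))
  expect_equal(res2$scores$score, rep(0, 3), tolerance = 1e-12)

  # un-normalized matrix is a contract violation
  mapped <- map_signature(sig, expression_matrix(v, "log10"))
  expect_error(score_samples(expression_matrix(v, "log10"), mapped),
               class = "rasmct_contract_error")
})

test_that("cohort scores are centered and equivariant under sample permutation", {
  set.seed(31)
  m <- random_matrix(40, 12)
  sig <- gene_signature("S", rownames(m)[1:10], rownames(m)[11:16])
  scores <- score_pipeline(m, sig)$scores
  expect_lt(abs(mean(scores$score)), 1e-10)

  perm <- sample(ncol(m))
  mp <- expression_matrix(unclass(m)[, perm], scale_tag = scale_tag(m))
  sp <- score_pipeline(mp, sig)$scores
  expect_equal(sp$score[match(scores$sample_id, sp$sample_id)],
               scores$score, tolerance = 1e-12)
})

test_that("scores are invariant under per-gene positive affine rescaling", {
  set.seed(41)
  m <- random_matrix(30, 8)
  sig <- gene_signature("S", rownames(m)[1:8], rownames(m)[9:12])
  base <- score_pipeline(m, sig)$scores$score
  v <- unclass(m)
  v[5, ] <- 3.7 * v[5, ] + 11      # single up gene
  v[10, ] <- 0.2 * v[10, ] - 4     # another signature gene
  rescaled <- score_pipeline(expression_matrix(v, "log10"), sig)$scores$score
  expect_equal(rescaled, base, tolerance = 1e-10)
})

test_that("raising one up-gene z-value raises only that sample's score by dz/n_up", {
  set.seed(51)
  m <- random_matrix(12, 6)
  sig <- gene_signature("S", rownames(m)[1:4], rownames(m)[5:7])
  z <- zscore_normalize(expression_matrix(
    unclass(m)[c(sig$up, sig$down), ], "log10"))
  mapped <- map_signature(sig, m)
  base <- score_samples(z, mapped)
  bumped <- unclass(z)
  dz <- 0.35
  bumped[2, 4] <- bumped[2, 4] + dz
  bump_scores <- score_samples(
    structure(bumped, scale_tag = "zscored",
              class = class(z)), mapped)
  diff <- bump_scores$score - base$score
  expect_equal(diff[4], dz / 4, tolerance = 1e-12)
  expect_equal(diff[-4], rep(0, 5), tolerance = 1e-15)
})

test_that("pipeline scores track the generator's latent activation", {
  cohort <- generate_cohort(cohort_spec(seed = 97))
  scores <- score_pipeline(cohort$expression, cohort$signature)$scores
  s <- scores$score[match(cohort$truth$model_id, scores$sample_id)]
  expect_gt(cor(s, cohort$truth$activation, method = "spearman"), 0.8)
  expect_warning(
    score_pipeline(expression_matrix(10^unclass(cohort$expression), "linear"),
                   cohort$signature),
    "linear")
})
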