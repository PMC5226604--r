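test_that("signature constructor enforces its invariants", {
  sig <- gene_signature("RAS", up = c("a", "B "), down = "c")
  expect_identical(sig$up, c("A", "B"))
  expect_identical(sig$down, "C")
  expect_warning(s2 <- gene_signature("RAS", c("A", "a", "B"), "C"),
                 "duplicate")
  expect_identical(s2$up, c("A", "B"))
  expect_error(gene_signature("RAS", c("KRAS", "A"), c("KRAS", "B")),
               "KRAS", class = "rasmct_validation_error")
  expect_error(gene_signature("RAS", character(0), "A"),
               class = "rasmct_validation_error")
})

test_that("GMT and two-column signature files round-trip", {
  up <- sprintf("UP%03d", 1:105)
  dn <- sprintf("DN%03d", 1:42)
  sig <- gene_signature("RAS", up, dn)
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_signature(sig, gmt, "gmt")
  got <- read_signature(gmt, "gmt")
  expect_length(got$up, 105)
  expect_length(got$down, 42)
  expect_identical(got$up, up)

  two <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,direction", "TP53,up", "MYC,down"), two)
  got2 <- read_signature(two, "two_column")
  expect_identical(got2$up, "TP53")
  expect_identical(got2$down, "MYC")

  # missing direction record in GMT
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("RAS_UP\tdesc\tA\tB", bad)
  expect_error(read_signature(bad, "gmt"), class = "rasmct_format_error")

  # gene in both directions
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,direction", "KRAS,up", "KRAS,down"), dup)
  expect_error(read_signature(dup, "two_column"), "KRAS",
               class = "rasmct_validation_error")
})

test_that("expression matrices read from TSV, CSV and GCT, and round-trip", {
  m <- random_matrix(3, 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, tsv)
  got <- read_expression(tsv)
  expect_identical(dim(got), c(3L, 2L))
  expect_identical(unclass(got)[, ], unclass(m)[, ])  # exact round trip

  gct <- withr::local_tempfile(fileext = ".gct")
  body <- apply(unclass(m), 1, function(r) paste(r, collapse = "\t"))
  writeLines(c("#1.2", "3\t2",
               paste(c("Name", "Description", colnames(m)), collapse = "\t"),
               paste(rownames(m), "na", body, sep = "\t")), gct)
  got_gct <- read_expression(gct)
  expect_equal(unclass(got_gct)[, ], unclass(m)[, ], tolerance = 1e-12)

  # declared dimensions mismatching the body
  bad <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "4\t2",
               paste(c("Name", "Description", colnames(m)), collapse = "\t"),
               paste(rownames(m), "na", body, sep = "\t")), bad)
  expect_error(read_expression(bad), "declares",
               class = "rasmct_format_error")
})

test_that("expression reader rejects or repairs pathological inputs loudly", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,S1,S2", "A,1,2", "B,oops,4"), bad)
  expect_error(read_expression(bad), "non-numeric value 'oops'",
               class = "rasmct_format_error")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,S1,S2", "A,1,2", "A,5,6", "B,0,1"), dup)
  expect_warning(m <- read_expression(dup), "duplicate")
  expect_identical(nrow(m), 2L)
  expect_equal(unname(unclass(m)["A", ]), c(5, 6))  # highest-mean row kept

  na_file <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,S1,S2", "A,1,", "B,3,4"), na_file)
  expect_error(read_expression(na_file), class = "rasmct_format_error")
  expect_warning(kept <- read_expression(na_file, drop_incomplete = TRUE),
                 "dropped")
  expect_identical(rownames(kept), "B")
})

test_that("volume series validation enforces the trial-design invariants", {
  v <- toy_volumes()
  expect_s3_class(v, "volume_series")
  expect_identical(nrow(v), 36L)

  two_arms <- as.data.frame(v)
  two_arms$arm[two_arms$animal == "MA_control_1"][1] <- "treated"
  expect_error(volume_series(two_arms), "more than one arm",
               class = "rasmct_validation_error")

  no_base <- as.data.frame(v)
  no_base <- no_base[!(no_base$animal == "MB_treated_2" & no_base$day == 0), ]
  expect_error(volume_series(no_base), "MB_treated_2",
               class = "rasmct_validation_error")

  neg <- as.data.frame(v)
  neg$volume[1] <- -5
  expect_error(volume_series(neg), class = "rasmct_validation_error")

  csv <- withr::local_tempfile(fileext = ".csv")
  write_volumes(v, csv)
  expect_identical(nrow(read_volumes(csv)), 36L)
})

test_that("bundled MCT table matches the published 25-model summary", {
  tbl <- load_cetuximab_mct()
  expect_identical(nrow(tbl), 25L)
  expect_identical(sum(tbl$kras_class == "WT"), 15L)
  expect_identical(sum(tbl$kras_class != "WT"), 10L)
  cr0047 <- tbl[tbl$model_id == "CR0047", ]
  expect_identical(cr0047$ras_score, 0.105)
  expect_identical(cr0047$delta_t_over_delta_c, 0.27)
  expect_identical(cr0047$kras_class, "G12x")
  cr2110 <- tbl[tbl$model_id == "CR2110", ]
  expect_identical(cr2110$ras_score, -0.424)
  expect_identical(cr2110$delta_t_over_delta_c, -0.48)
  expect_identical(max(tbl$delta_t_over_delta_c), 1.58)
  expect_identical(tbl$model_id[which.max(tbl$delta_t_over_delta_c)],
                   "CR0010")
  # transcription guard: direct sum of the printed score column
  expect_gt(sum(tbl$ras_score), -0.36)
  expect_lt(sum(tbl$ras_score), -0.33)
})

test_that("KRAS vocabulary collapses codon-12 alleles and rejects strangers", {
  expect_identical(kras_class(c("WT", "G12D", "G12V", "G12C", "G13D")),
                   c("WT", "G12x", "G12x", "G12x", "G13D"))
  expect_error(kras_class("Q61H"), class = "rasmct_validation_error")
})
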