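test_that("packaged drug-target tables parse with every printed cell intact", {
  t1 <- drug_target_table("ion_channels")
  expect_equal(nrow(t1), 11)
  expect_equal(t1$symbol[1], "CACNA1C")
  expect_equal(t1$proximity[1], 1.9)
  expect_equal(t1$a_plus_t[1], 48)
  expect_equal(t1$fl_size[1], 13744)
  # spot checks across the parsing quirks: alias resolution, thousands
  # separators, the comma-joined A,T pair
  kcnh2 <- t1[t1$symbol == "KCNH2", ]
  expect_equal(kcnh2$gene_name, "HERG (KCNH2)")
  expect_equal(kcnh2$proximity, 8)
  kcnj6 <- t1[t1$symbol == "KCNJ6", ]
  expect_equal(c(kcnj6$a_pct, kcnj6$t_pct, kcnj6$a_plus_t), c(29, 31, 60))
  expect_equal(kcnj6$fl_size, 19659)
  expect_equal(t1[t1$symbol == "GABRB3", "a_plus_t"], 59)
  expect_true(all(t1$protein_class == "ion_channel"))

  t2 <- drug_target_table("gpcrs")
  expect_equal(nrow(t2), 20)
  expect_setequal(
    t2$symbol[t2$drug %in% c("Varubi", "Belsomra", "Zontivity")],
    c("TACR1", "HCRTR2", "NR1I2"))
  expect_equal(sum(t2$symbol == "GLP1R"), 2)  # Trulicity and Adlyxin rows
  expect_true(all(t2$protein_class == "gpcr"))
})

test_that("generic dialect reads minimal and header-only tables", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(
    "gene\tchr\tproximity_mb\tat_pct\tfl_size_bp",
    "AAA\t1\t10\t62\t1500",
    "BBB\tchrX\t80\t45\t7000", sep = "\n"), path)
  rec <- read_gene_table(path, dialect = "generic")
  expect_equal(rec$symbol, c("AAA", "BBB"))
  expect_equal(rec$chromosome, c(1L, 23L))
  expect_equal(rec$chrom_name, c("1", "X"))
  expect_true(all(is.na(rec$gene_locus)))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\tchr\tproximity_mb\tat_pct\tfl_size_bp", empty)
  expect_equal(nrow(read_gene_table(empty, dialect = "generic")), 0)
})

test_that("schema and cell errors name the offending column and row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\tproximity_mb\nAAA\t10", path)
  expect_error(read_gene_table(path, dialect = "generic"), "chr")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(
    "gene\tchr\tproximity_mb\tat_pct\tfl_size_bp",
    "AAA\t1\t10\t62\t1500",
    "BBB\t2\toops\t45\t7000", sep = "\n"), bad)
  err <- expect_error(read_gene_table(bad, dialect = "generic"), "oops")
  expect_match(conditionMessage(err), "row 2")
})

test_that("record invariants reject out-of-range fields", {
  rec <- make_records("A1", proximity = 10, a_plus_t = 60)
  expect_silent(validate_gene_records(rec))
  bad <- rec; bad$a_plus_t <- 130
  expect_error(validate_gene_records(bad), "a_plus_t")
  bad <- rec; bad$proximity <- -1
  expect_error(validate_gene_records(bad), "proximity.*A1|A1")
  bad <- rec; bad$a_pct <- 20; bad$t_pct <- 20; bad$a_plus_t <- 60
  expect_error(validate_gene_records(bad), "more than 1 point")
})

test_that("chrom.sizes reader converts bp to Mb and normalizes names", {
  path <- withr::local_tempfile(fileext = ".sizes")
  writeLines(c(sprintf("chr%d\t%.0f", 1:22, seq(249e6, 50e6, length.out = 22)),
               "chrX\t156040895"), path)
  map <- read_chrom_sizes(path)
  expect_length(map, 23)
  expect_equal(unname(map[["X"]]), 156.040895)

  one <- withr::local_tempfile()
  writeLines("chr7\t159345973", one)
  expect_equal(unname(read_chrom_sizes(one)[["7"]]), 159.345973)

  zero <- withr::local_tempfile()
  writeLines("chr7\t0", zero)
  expect_error(read_chrom_sizes(zero), "non-positive")

  dup <- withr::local_tempfile()
  writeLines(c("chr7\t100", "7\t200"), dup)
  expect_error(read_chrom_sizes(dup), "duplicate")
})

test_that("telomere BED reader validates intervals", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10000", "chr1\t248946422\t248956422"), path)
  bed <- read_telomere_bed(path)
  expect_equal(bed$chrom, c("1", "1"))
  expect_equal(bed$end[1], 0.01)
  badf <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t500\t100", badf)
  expect_error(read_telomere_bed(badf), "malformed")
})

test_that("classified results round-trip through write and read", {
  t1 <- drug_target_table("ion_channels")
  calls <- classify_genes(t1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(t1, calls, path)
  back <- read_gene_table(path, dialect = "generic")
  expect_equal(back$symbol, t1$symbol)
  expect_equal(back$proximity, t1$proximity)
  expect_equal(back$a_plus_t, t1$a_plus_t)
  expect_equal(back$fl_size, t1$fl_size)
  expect_equal(back$category, as.character(calls$category))
  expect_setequal(back$symbol[back$category == "NONE"], c("KCNK4", "GABRB3"))

  # empty in, header-only out
  empty_path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(t1[0, ], calls[0, ], empty_path)
  expect_length(readLines(empty_path), 1)
})
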