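# Evidence I/O: mutation tables, VCF trios, and result reports.

test_that("mutation tables round-trip through write/read at full precision", {
  ev <- generate_fixture_trio(10, 4, 3, c(dbsnp = 2), seed = 31)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_table(ev, path)
  back <- read_mutation_table(path)
  expect_identical(as.data.frame(ev), as.data.frame(back))
})

test_that("a small table reads cell-for-cell and an empty one is fine", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("chrom", "pos", "ref", "alt", "g_depth", "g_alt",
                 "g_hq_depth", "a_depth", "a_alt", "a_called",
                 "b_depth", "b_alt", "b_called", "in_dbsnp"),
               collapse = "\t")
  writeLines(c(hdr,
               "chr1\t100\tA\tT\t30\t0\t30\t60\t20\tTRUE\t80\t30\tTRUE\tFALSE",
               "chr2\t5\tG\tC\t20\t1\t20\t50\t15\tTRUE\t45\t0\tFALSE\tFALSE",
               "chrX\t77\tT\tA\t40\t0\t40\t90\t40\tFALSE\t90\t40\tTRUE\tTRUE"),
             path)
  ev <- read_mutation_table(path)
  expect_identical(nrow(ev), 3L)
  expect_identical(ev$pos, c(100L, 5L, 77L))
  expect_identical(ev$b_called, c(TRUE, FALSE, TRUE))
  expect_identical(ev$key[2], "chr2:5:G>C")

  writeLines(hdr, path)
  expect_identical(nrow(read_mutation_table(path)), 0L)
})

test_that("invalid tables are rejected with a named reason", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt",
               "chr1\t100\tA\tT"), path)
  expect_error(read_mutation_table(path), "g_depth")
  writeLines(c(paste(c("chrom", "pos", "ref", "alt", "g_depth", "g_alt",
                       "g_hq_depth", "a_depth", "a_alt", "a_called",
                       "b_depth", "b_alt", "b_called", "in_dbsnp"),
                     collapse = "\t"),
               "chr1\t0\tA\tT\t30\t0\t30\t60\t20\tTRUE\t80\t30\tTRUE\tFALSE"),
             path)
  expect_error(read_mutation_table(path), "1-based")
  expect_error(read_mutation_table("/nonexistent/x.tsv"), "not found")
})

test_that("a call absent from one tumor is encoded as not-called", {
  d <- withr::local_tempdir()
  g <- write_minimal_vcf(file.path(d, "g.vcf"),
                         "chr1\t100\t.\tA\t.\t.\tPASS\t.\tGT:DP:AD\t0/0:30:30,0")
  a <- write_minimal_vcf(file.path(d, "a.vcf"),
                         "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:DP:AD\t0/1:100:60,40")
  b <- write_minimal_vcf(file.path(d, "b.vcf"), character(0))
  ev <- suppressMessages(read_trio_vcfs(g, a, b))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$key, "chr1:100:A>T")
  expect_true(ev$a_called); expect_identical(ev$a_alt, 40L)
  expect_false(ev$b_called); expect_identical(ev$b_depth, 0L)
  # absent germline would be rejected downstream; here germline exists
  expect_identical(ev$g_depth, 30L)
})

test_that("multiallelic records split into one evidence row per allele", {
  d <- withr::local_tempdir()
  g <- write_minimal_vcf(file.path(d, "g.vcf"),
                         "chr1\t100\t.\tA\t.\t.\tPASS\t.\tGT:DP:AD\t0/0:30:30,0")
  a <- write_minimal_vcf(file.path(d, "a.vcf"),
                         "chr1\t100\t.\tA\tT,C\t.\tPASS\t.\tGT:DP:AD\t1/2:100:50,30,20")
  b <- write_minimal_vcf(file.path(d, "b.vcf"), character(0))
  ev <- suppressMessages(read_trio_vcfs(g, a, b))
  expect_identical(nrow(ev), 2L)
  expect_setequal(ev$alt, c("T", "C"))
  expect_setequal(ev$a_alt, c(30L, 20L))
  expect_true(all(ev$a_depth == 100L))
})

test_that("indels are skipped and depth-less VCFs are format errors", {
  d <- withr::local_tempdir()
  g <- write_minimal_vcf(file.path(d, "g.vcf"),
                         "chr1\t100\t.\tA\t.\t.\tPASS\t.\tGT:DP:AD\t0/0:30:30,0")
  a <- write_minimal_vcf(file.path(d, "a.vcf"), c(
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:DP:AD\t0/1:100:60,40",
    "chr1\t200\t.\tAT\tA\t.\tPASS\t.\tGT:DP:AD\t0/1:90:60,30"))
  b <- write_minimal_vcf(file.path(d, "b.vcf"), character(0))
  expect_message(ev <- read_trio_vcfs(g, a, b), "non-SNV")
  expect_identical(ev$key, "chr1:100:A>T")

  bad <- write_minimal_vcf(file.path(d, "bad.vcf"),
                           "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1",
                           format_def = FALSE)
  expect_error(suppressWarnings(read_trio_vcfs(g, bad, b)), "depth")
  expect_error(read_trio_vcfs(g, "/missing.vcf", b), "not found")
})

test_that("a 100-locus fixture trio round-trips identically through VCF", {
  ev <- generate_fixture_trio(40, 30, 30, seed = 1)
  d <- withr::local_tempdir()
  paths <- file.path(d, c("g.vcf", "a.vcf", "b.vcf"))
  write_trio_vcfs(ev, paths[1], paths[2], paths[3])
  back <- read_trio_vcfs(paths[1], paths[2], paths[3])
  expect_identical(nrow(back), 100L)
  srt <- function(x) {
    x <- as.data.frame(x)[order(x$key), ]
    rownames(x) <- NULL
    x
  }
  expect_identical(srt(ev), srt(back))
  # and twice more: parsing is deterministic
  again <- read_trio_vcfs(paths[1], paths[2], paths[3])
  expect_identical(srt(back), srt(again))
})

test_that("VCF and mutation-table paths agree on equivalent content", {
  ev <- generate_fixture_trio(12, 5, 7,
                              c(dbsnp = 3, germline_coverage = 2,
                                tumor_coverage = 2), seed = 37)
  d <- withr::local_tempdir()
  tab <- file.path(d, "muts.tsv")
  write_mutation_table(ev, tab)
  paths <- file.path(d, c("g.vcf", "a.vcf", "b.vcf"))
  write_trio_vcfs(ev, paths[1], paths[2], paths[3])
  from_tab <- read_mutation_table(tab)
  from_vcf <- read_trio_vcfs(paths[1], paths[2], paths[3])
  srt <- function(x) {
    x <- as.data.frame(x)[order(x$key), ]
    rownames(x) <- NULL
    x
  }
  expect_identical(srt(from_tab), srt(from_vcf))
  p1 <- build_profile(from_tab); p2 <- build_profile(from_vcf)
  expect_identical(p1$X, p2$X); expect_identical(p1$n, p2$n)
  expect_identical(p1$filter_log, p2$filter_log)
})

test_that("the dbSNP flag can come from a lookup file instead of the ID column", {
  ev <- generate_fixture_trio(5, 2, 2, seed = 41)
  d <- withr::local_tempdir()
  paths <- file.path(d, c("g.vcf", "a.vcf", "b.vcf"))
  write_trio_vcfs(ev, paths[1], paths[2], paths[3])
  lookup <- file.path(d, "dbsnp.tsv")
  flagged <- as.data.frame(ev)[1:2, c("chrom", "pos", "ref", "alt")]
  utils::write.table(flagged, lookup, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- read_trio_vcfs(paths[1], paths[2], paths[3],
                         dbsnp_flag_source = lookup)
  expect_identical(sum(back$in_dbsnp), 2L)
  expect_setequal(back$key[back$in_dbsnp], ev$key[1:2])
})

test_that("reports serialize every test field and round-trip numerically", {
  fit <- cls_test(50, 62)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(fit, path, format = "json")
  rep <- jsonlite::fromJSON(path)
  expect_identical(rep$cls_display, "81")
  expect_identical(rep$ci_display, "69% to 90%")
  expect_identical(rep$decision, "clonal")
  expect_identical(rep$p_value_display, "<1e-15")
  expect_identical(rep$x, 50L)
  expect_equal(rep$cls, fit$cls)          # full precision
  expect_equal(rep$ci_low, fit$ci_low)
  expect_equal(rep$p_value, fit$p_value)
  expect_identical(rep$p0, 0.04)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(fit, tsv, format = "tsv")
  lines <- readLines(tsv)
  expect_length(lines, 2L)  # header plus exactly one data row

  # filter parameters travel with profile-fitted results
  prof <- build_profile(generate_fixture_trio(50, 0, 12, seed = 1))
  write_report(cls_test(prof), path, format = "json")
  rep2 <- jsonlite::fromJSON(path)
  expect_identical(rep2$filter_params$tumor_min_depth, 40L)
  suppressWarnings(
    expect_error(write_report(fit, "/nonexistent/dir/x.json")))
})
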