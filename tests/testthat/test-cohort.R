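# Counterfactual cross-patient pairing and cohort calibration of p0.

key_seq <- function(n, chrom = "chr1", offset = 0L) {
  if (n == 0) return(character(0))
  locus_key(chrom, offset + seq_len(n) * 10L, "A", "T")
}

mini_cohort <- function() {
  # t1/t2 share exactly one key; t3 is disjoint from both
  tumor_cohort(list(
    tumor_mutation_list("t1", "p1", key_seq(50)),
    tumor_mutation_list("t2", "p2", c(key_seq(1), key_seq(49, "chr9"))),
    tumor_mutation_list("t3", "p3", key_seq(50, "chr2"))))
}

test_that("cross-group pairing gives the full product of the two strata", {
  tumors <- c(
    lapply(1:357, function(i) tumor_mutation_list(
      paste0("er", i), paste0("erp", i), group_label = "ER+")),
    lapply(1:46, function(i) tumor_mutation_list(
      paste0("tn", i), paste0("tnp", i), group_label = "TN")))
  cohort <- tumor_cohort(tumors)
  pairs <- counterfactual_pairs(cohort, "cross_group")
  expect_identical(nrow(pairs), 357L * 46L)  # 16,422
  expect_false(any(pairs$tumor_a == pairs$tumor_b))
})

test_that("pairs never join two tumors of one patient", {
  cohort <- tumor_cohort(list(
    tumor_mutation_list("t1", "same"),
    tumor_mutation_list("t2", "same")))
  expect_identical(nrow(counterfactual_pairs(cohort, "all_cross_patient")),
                   0L)
})

test_that("all_cross_patient enumerates distinct-patient combinations", {
  cohort <- tumor_cohort(lapply(1:5, function(i)
    tumor_mutation_list(paste0("t", i), paste0("p", i))))
  pairs <- counterfactual_pairs(cohort, "all_cross_patient")
  expect_identical(nrow(pairs), 10L)  # choose(5, 2)
  expect_identical(nrow(unique(pairs)), 10L)
  sub <- counterfactual_pairs(cohort, "random_cross_patient", k = 4,
                              seed = 9)
  expect_identical(nrow(sub), 4L)
  expect_identical(sub, counterfactual_pairs(cohort,
                                             "random_cross_patient",
                                             k = 4, seed = 9))
})

test_that("cross_group pairing demands exactly two labelled groups", {
  cohort <- tumor_cohort(list(
    tumor_mutation_list("t1", "p1", group_label = "ER+"),
    tumor_mutation_list("t2", "p2")))
  expect_error(counterfactual_pairs(cohort, "cross_group"),
               "two group labels")
})

test_that("pair counts are plain set arithmetic and symmetric", {
  a <- tumor_mutation_list("a", "pa", key_seq(10))
  b <- tumor_mutation_list("b", "pb", key_seq(15, "chr2"))
  expect_identical(pair_cls(a, b)[c("x", "n")], list(x = 0L, n = 25L))

  ident <- tumor_mutation_list("c", "pc", key_seq(7))
  ident2 <- tumor_mutation_list("d", "pd", key_seq(7))
  expect_identical(pair_cls(ident, ident2)[c("x", "n")],
                   list(x = 7L, n = 7L))

  k <- key_seq(5)
  l1 <- tumor_mutation_list("e", "pe", k[1:3])
  l2 <- tumor_mutation_list("f", "pf", k[2:5])
  pc <- pair_cls(l1, l2)
  expect_identical(pc$x, 2L); expect_identical(pc$n, 5L)
  expect_setequal(pc$shared, k[2:3])
  rev <- pair_cls(l2, l1)
  expect_identical(rev$x, pc$x); expect_identical(rev$n, pc$n)
})

test_that("an all-disjoint cohort suggests the floor p0 of 3%", {
  cohort <- tumor_cohort(lapply(1:4, function(i)
    tumor_mutation_list(paste0("t", i), paste0("p", i),
                        key_seq(30, paste0("chr", i)))))
  s <- summarize_cohort(cohort)
  expect_identical(s$num_pairs, 6L)
  expect_identical(s$frac_zero_cls, 1)
  expect_identical(s$max_cls, 0)
  expect_identical(s$suggested_p0, 0.03)
})

test_that("the histogram matches a hand enumeration", {
  s <- summarize_cohort(mini_cohort())
  # pairwise shared counts 1, 0, 0 with unions of 99/100/100 loci
  expect_identical(s$num_pairs, 3L)
  expect_identical(unname(s$cls_histogram[c("0", "1")]), c(2L, 1L))
  expect_identical(sum(s$cls_histogram), s$num_pairs)
  expect_equal(s$frac_zero_cls, 2 / 3)
})

test_that("max CLS agrees with an independent per-pair recomputation", {
  cohort <- tumor_cohort(list(
    tumor_mutation_list("t1", "p1", key_seq(40)),
    tumor_mutation_list("t2", "p2", c(key_seq(35), key_seq(5, "chr8"))),
    tumor_mutation_list("t3", "p3", c(key_seq(2), key_seq(58, "chr7")))))
  s <- summarize_cohort(cohort)
  pairs <- counterfactual_pairs(cohort, "all_cross_patient")
  by_hand <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- cohort[[pairs$tumor_a[i]]]$mutations
    b <- cohort[[pairs$tumor_b[i]]]$mutations
    100 * length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  expect_equal(s$max_cls, max(by_hand))
})

test_that("a planted recurrent driver tops the shared tally", {
  driver <- locus_key("chr3", 500L, "G", "A")
  set.seed(7)
  tumors <- lapply(1:6, function(i) tumor_mutation_list(
    paste0("t", i), paste0("p", i),
    c(driver, key_seq(40, paste0("chr", i)))))
  gene_map <- stats::setNames("PIK3CA", driver)
  s <- summarize_cohort(tumor_cohort(tumors), gene_map = gene_map)
  expect_identical(names(s$shared_locus_tally)[1], "PIK3CA")
  expect_identical(unname(s$shared_locus_tally[1]), 15L)  # all C(6,2) pairs
  expect_gt(s$suggested_p0, 0)
})

test_that("cohorts read from disk preserve lists and gene annotations", {
  d <- withr::local_tempdir()
  write_list <- function(name, keys, genes = NULL) {
    parts <- do.call(rbind, strsplit(keys, "[:>]"))
    df <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                     ref = parts[, 3], alt = parts[, 4])
    if (!is.null(genes)) df$gene <- genes
    utils::write.table(df, file.path(d, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_list("a.tsv", key_seq(5), genes = c(rep("TP53", 3), "OTHER", "OTHER"))
  write_list("b.tsv", key_seq(3))
  utils::write.table(
    data.frame(tumor_id = c("ta", "tb"), patient_id = c("pa", "pb"),
               group_label = c("ER+", "TN"), file = c("a.tsv", "b.tsv")),
    file.path(d, "manifest.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  cohort <- read_cohort(file.path(d, "manifest.tsv"))
  expect_length(cohort, 2)
  expect_identical(as.character(cohort[["ta"]]$mutations), key_seq(5))
  expect_identical(unname(attr(cohort[["ta"]]$mutations, "genes")[1]),
                   "TP53")
  s <- summarize_cohort(cohort, pairing_rule = "cross_group")
  expect_identical(names(s$shared_locus_tally)[1], "TP53")
})

test_that("degenerate cohorts are refused", {
  expect_error(summarize_cohort(tumor_cohort(list(
    tumor_mutation_list("t1", "p1")))), "degenerate")
  expect_error(summarize_cohort(tumor_cohort(list(
    tumor_mutation_list("t1", "same"),
    tumor_mutation_list("t2", "same")))), "degenerate")
  expect_error(tumor_cohort(list(
    tumor_mutation_list("dup", "p1"),
    tumor_mutation_list("dup", "p2"))), "unique")
})
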