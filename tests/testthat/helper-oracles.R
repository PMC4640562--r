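# Independent oracles used across the suite. These deliberately avoid
# the code paths they check: the binomial tail oracle sums terms in
# log space instead of using the incomplete-beta tail, and the filter
# oracle is a straight-line per-row transcription of the HC rules.

# Upper binomial tail P(B >= x) by log-space (logsumexp) summation.
oracle_upper_tail <- function(x, n, p) {
  if (x <= 0) return(1)
  if (x > n) return(0)
  k <- x:n
  lg <- lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
  m <- max(lg)
  exp(m + log(sum(exp(lg - m))))
}

# Lower tail P(B <= x) by the same route (for conservation checks).
oracle_lower_tail <- function(x, n, p) {
  if (x < 0) return(0)
  if (x >= n) return(1)
  k <- 0:x
  lg <- lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
  m <- max(lg)
  exp(m + log(sum(exp(lg - m))))
}

# Straight-line re-statement of the four HC filtering rules, applied
# to a single evidence row in spec order.
oracle_classify_row <- function(row, params = hc_params()) {
  if (params$exclude_dbsnp && row$in_dbsnp) return("rejected:dbsnp")
  if (row$g_hq_depth < params$germline_min_hq_depth)
    return("rejected:germline_coverage")
  if (row$g_alt > params$germline_max_alt_reads)
    return("rejected:germline_alt_reads")
  frac <- if (row$g_depth > 0) row$g_alt / row$g_depth else 0
  if (frac >= params$germline_max_alt_fraction)
    return("rejected:germline_alt_fraction")
  if (row$a_depth < params$tumor_min_depth ||
      row$b_depth < params$tumor_min_depth)
    return("rejected:tumor_coverage")
  if (!row$a_called && !row$b_called) return("rejected:no_tumor_call")
  if (row$a_called && row$b_called) return("shared")
  if (row$a_called) "private_a" else "private_b"
}

# Random but invariant-respecting evidence tables for property tests.
random_evidence <- function(n_loci, seed) {
  set.seed(seed)
  g_depth <- sample(0:60, n_loci, replace = TRUE)
  g_alt <- pmin(g_depth, sample(0:3, n_loci, replace = TRUE))
  a_depth <- sample(20:120, n_loci, replace = TRUE)
  b_depth <- sample(20:120, n_loci, replace = TRUE)
  a_called <- sample(c(TRUE, FALSE), n_loci, replace = TRUE, prob = c(.6, .4))
  b_called <- sample(c(TRUE, FALSE), n_loci, replace = TRUE, prob = c(.6, .4))
  ref <- sample(c("A", "C", "G", "T"), n_loci, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  locus_evidence(data.frame(
    chrom = "chr1", pos = seq_len(n_loci) * 10L, ref = ref, alt = unname(alt),
    g_depth = g_depth, g_alt = g_alt,
    g_hq_depth = pmin(g_depth, sample(0:60, n_loci, replace = TRUE)),
    a_depth = a_depth,
    a_alt = ifelse(a_called, pmin(a_depth, sample(5:40, n_loci, TRUE)), 0L),
    a_called = a_called,
    b_depth = b_depth,
    b_alt = ifelse(b_called, pmin(b_depth, sample(5:40, n_loci, TRUE)), 0L),
    b_called = b_called,
    in_dbsnp = sample(c(TRUE, FALSE), n_loci, replace = TRUE,
                      prob = c(.1, .9)),
    stringsAsFactors = FALSE))
}

# Minimal hand-written VCF text for reader edge cases.
write_minimal_vcf <- function(path, records, sample = "S1",
                              format_def = TRUE) {
  header <- c("##fileformat=VCFv4.2")
  if (format_def) header <- c(
    header,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">")
  writeLines(c(header,
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", sample, sep = "\t"),
               records), path)
  path
}
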