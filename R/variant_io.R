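# Reading and writing locus evidence: the per-locus read support across
# germline and two tumors that the HC filter consumes. The canonical
# exchange format is a tab-delimited mutation table; single-sample VCFs
# for the germline/tumorA/tumorB trio are supported via vcfR.

EVIDENCE_COLS <- c(
  "chrom", "pos", "ref", "alt",
  "g_depth", "g_alt", "g_hq_depth",
  "a_depth", "a_alt", "a_called",
  "b_depth", "b_alt", "b_called",
  "in_dbsnp"
)

#' Construct a locus evidence table
#'
#' One row per genomic locus key (chromosome, position, ref, alt) carrying
#' read evidence for the germline sample and both tumors of a pair.
#' Column meanings: `g_depth`/`g_alt`/`g_hq_depth` are germline total
#' depth, alternate-read count and count of high-quality (Q>20) reads;
#' `a_depth`/`a_alt` (`b_*`) are tumor total depth and alternate reads;
#' `a_called`/`b_called` flag whether the variant caller emitted a
#' variant at this key in that tumor; `in_dbsnp` is a precomputed dbSNP
#' membership annotation (never computed here).
#'
#' @param df data.frame with (at least) the columns named above.
#' @return validated `locus_evidence` data.frame.
#' @export
locus_evidence <- function(df) {
  missing_cols <- setdiff(EVIDENCE_COLS, names(df))
  if (length(missing_cols) > 0)
    stop("evidence table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$pos <- as.integer(df$pos)
  validate_locus_key(df$chrom, df$pos, df$ref, df$alt)
  num <- c("g_depth", "g_alt", "g_hq_depth", "a_depth", "a_alt",
           "b_depth", "b_alt")
  for (col in num) {
    df[[col]] <- as.integer(df[[col]])
    if (any(is.na(df[[col]])) || any(df[[col]] < 0L))
      stop("column '", col, "' must contain non-negative counts")
  }
  df$a_called <- as.logical(df$a_called)
  df$b_called <- as.logical(df$b_called)
  df$in_dbsnp <- as.logical(df$in_dbsnp)
  if (any(df$g_alt > df$g_depth) || any(df$g_hq_depth > df$g_depth) ||
      any(df$a_alt > df$a_depth) || any(df$b_alt > df$b_depth))
    stop("alt_count and hq_depth cannot exceed total depth")
  key <- locus_key(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(key))
    stop("duplicated locus key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  rownames(df) <- NULL
  df$key <- key
  class(df) <- c("locus_evidence", "data.frame")
  df
}

#' Read a tab-delimited mutation table
#'
#' The canonical fixture/exchange format: a UTF-8, tab-separated file
#' whose header names the columns documented in [locus_evidence()].
#' Extra columns are preserved.
#'
#' @param path file path.
#' @return `locus_evidence` data.frame (zero rows for a header-only file).
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character", ref = "character",
                                         alt = "character"))
  locus_evidence(df)
}

#' Write a mutation table
#'
#' @param evidence `locus_evidence` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(evidence, path) {
  df <- as.data.frame(evidence)
  df$key <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# ---- VCF trio path -------------------------------------------------------

# Parse one single-sample VCF into a per-allele data.frame:
# key fields, DP, per-allele AD, HQ (high-quality depth), called flag
# (ALT present and non-ref), dbSNP id. Multiallelic records are split
# into one row per alternate allele; non-SNV alleles are dropped.
parse_sample_vcf <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx)))  # single record drops to a named vector
    fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  n <- nrow(fix)
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      depth = integer(), alt_count = integer(),
                      hq_depth = integer(), called = logical(),
                      id = character(), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2)
    stop("VCF has no sample genotype columns: ", path)
  fmt_has <- function(tag) {
    any(vapply(strsplit(gt[, 1], ":", fixed = TRUE),
               function(f) tag %in% f, logical(1)))
  }
  if (!fmt_has("DP") && !fmt_has("AD"))
    stop("VCF without depth fields (need FORMAT DP or AD); first record: ",
         fix$CHROM[1], ":", fix$POS[1], " in ", path)
  get_fmt <- function(tag) {
    if (!fmt_has(tag)) return(rep(NA_character_, n))
    as.vector(vcfR::extract.gt(v, element = tag))
  }
  dp <- suppressWarnings(as.integer(get_fmt("DP")))
  ad <- get_fmt("AD")
  hq <- suppressWarnings(as.integer(get_fmt("HQ")))

  out <- vector("list", n)
  n_skipped <- 0L
  for (i in seq_len(n)) {
    ref <- fix$REF[i]
    alt_field <- fix$ALT[i]
    if (is.na(alt_field)) alt_field <- "."
    id_field <- fix$ID[i]
    if (is.na(id_field)) id_field <- "."
    alts <- strsplit(alt_field, ",", fixed = TRUE)[[1]]
    ad_i <- if (is.na(ad[i])) integer(0) else
      suppressWarnings(as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1]]))
    depth_i <- if (!is.na(dp[i])) dp[i] else sum(ad_i, na.rm = TRUE)
    if (is.na(depth_i)) {
      stop("VCF record lacks depth (DP/AD): ",
           fix$CHROM[i], ":", fix$POS[i], " in ", path)
    }
    # ALT "." marks a coverage-only (no-call) record at a key supplied
    # for cross-sample depth lookup.
    if (identical(alts, ".")) {
      # AD still carries (ref, alt) read counts for a no-call record,
      # e.g. stray alternate reads in the germline sample
      alt0 <- if (length(ad_i) >= 2 && !is.na(ad_i[2])) ad_i[2] else 0L
      out[[i]] <- data.frame(chrom = fix$CHROM[i],
                             pos = as.integer(fix$POS[i]),
                             ref = ref, alt = NA_character_,
                             depth = depth_i, alt_count = alt0,
                             hq_depth = if (is.na(hq[i])) depth_i else hq[i],
                             called = FALSE, id = id_field,
                             stringsAsFactors = FALSE)
      next
    }
    keep <- nchar(ref) == 1L & nchar(alts) == 1L &
      ref %in% BASES & alts %in% BASES
    n_skipped <- n_skipped + sum(!keep)
    if (!any(keep)) { out[[i]] <- NULL; next }
    alts_k <- alts[keep]
    # AD is ref count followed by one count per ALT allele.
    alt_counts <- if (length(ad_i) >= 1L + length(alts)) {
      ad_i[1L + which(keep)]
    } else rep(NA_integer_, length(alts_k))
    alt_counts[is.na(alt_counts)] <- 0L
    out[[i]] <- data.frame(chrom = fix$CHROM[i],
                           pos = as.integer(fix$POS[i]),
                           ref = ref, alt = alts_k,
                           depth = depth_i, alt_count = alt_counts,
                           hq_depth = if (is.na(hq[i])) depth_i else hq[i],
                           called = TRUE, id = id_field,
                           stringsAsFactors = FALSE)
  }
  if (n_skipped > 0)
    message("skipped ", n_skipped,
            " non-SNV allele(s) (indels/MNVs are out of scope): ", path)
  if (any(is.na(hq)))
    message("VCF lacks FORMAT HQ (high-quality depth); ",
            "defaulting hq_depth to total depth: ", path)
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) empty else res
}

#' Read a germline/tumorA/tumorB VCF trio
#'
#' Builds one evidence row per locus key called in either tumor. Depths
#' come from the standard `DP`/`AD` genotype fields; the optional `HQ`
#' FORMAT field carries the count of high-quality (Q>20) reads and
#' defaults to total depth (with a message) when absent. Records with
#' `ALT=.` are treated as coverage-only no-call records, which lets a
#' tumor VCF report depth at loci called only in the other tumor.
#' Loci with no matching germline record get germline evidence marked
#' absent (`g_hq_depth = 0`), which the HC filter rejects.
#'
#' @param germline_path,tumor_a_path,tumor_b_path single-sample VCF paths.
#' @param dbsnp_flag_source `"id"` (default) flags a locus as a dbSNP
#'   member when either tumor record has a non-missing ID column;
#'   alternatively the path of a lookup file with columns
#'   chrom, pos, ref, alt listing known dbSNP keys.
#' @return `locus_evidence` data.frame.
#' @export
read_trio_vcfs <- function(germline_path, tumor_a_path, tumor_b_path,
                           dbsnp_flag_source = "id") {
  g <- parse_sample_vcf(germline_path)
  a <- parse_sample_vcf(tumor_a_path)
  b <- parse_sample_vcf(tumor_b_path)

  called_keys <- function(s) {
    s <- s[s$called, , drop = FALSE]
    if (nrow(s) == 0) character(0) else
      locus_key(s$chrom, s$pos, s$ref, s$alt)
  }
  keys <- union(called_keys(a), called_keys(b))
  if (length(keys) == 0) {
    return(locus_evidence(utils::read.table(text = paste(EVIDENCE_COLS,
                                                         collapse = "\t"),
                                            header = TRUE, sep = "\t")))
  }
  parts <- do.call(rbind, strsplit(keys, "[:>]"))
  chrom <- parts[, 1]; pos <- as.integer(parts[, 2])
  ref <- parts[, 3]; alt <- parts[, 4]

  # Germline and coverage-only records match on position (the locus),
  # allele-level records on the full key.
  site <- paste(chrom, pos, ref, sep = ":")
  match_evidence <- function(s) {
    depth <- integer(length(keys)); alt_n <- integer(length(keys))
    hq <- integer(length(keys)); called <- logical(length(keys))
    id <- rep(".", length(keys))
    if (nrow(s) > 0) {
      # allele-level match first (called records) ...
      s_key <- ifelse(s$called & !is.na(s$alt),
                      sprintf("%s:%d:%s>%s", s$chrom, s$pos, s$ref, s$alt),
                      NA_character_)
      m_allele <- match(keys, s_key)
      # ... then site-level (coverage-only and germline records)
      m_site <- match(site, paste(s$chrom, s$pos, s$ref, sep = ":"))
      m <- ifelse(is.na(m_allele), m_site, m_allele)
      idx <- which(!is.na(m))
      depth[idx] <- s$depth[m[idx]]
      hq[idx] <- s$hq_depth[m[idx]]
      called[idx] <- !is.na(m_allele[idx]) & s$called[m[idx]]
      alt_n[idx] <- s$alt_count[m[idx]]
      # a site-level match to a record CALLED for a different allele
      # contributes depth only: its alt reads belong to that allele
      alt_n[idx[!called[idx] & s$called[m[idx]]]] <- 0L
      id[idx] <- s$id[m[idx]]
    }
    list(depth = depth, alt = alt_n, hq = hq, called = called, id = id)
  }
  ga <- match_evidence(g); ta <- match_evidence(a); tb <- match_evidence(b)

  in_dbsnp <- if (identical(dbsnp_flag_source, "id")) {
    (ta$id != "." & ta$id != "") | (tb$id != "." & tb$id != "")
  } else {
    db <- utils::read.delim(dbsnp_flag_source, stringsAsFactors = FALSE,
                            colClasses = c(chrom = "character", ref = "character",
                                         alt = "character"))
    keys %in% locus_key(db$chrom, db$pos, db$ref, db$alt)
  }

  locus_evidence(data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    g_depth = ga$depth, g_alt = ga$alt, g_hq_depth = ga$hq,
    a_depth = ta$depth, a_alt = ta$alt, a_called = ta$called,
    b_depth = tb$depth, b_alt = tb$alt, b_called = tb$called,
    in_dbsnp = in_dbsnp, stringsAsFactors = FALSE))
}

#' Write a locus evidence table as a germline/tumorA/tumorB VCF trio
#'
#' Inverse of [read_trio_vcfs()] on the evidence representation: each
#' tumor VCF contains a called record per key that tumor called, plus a
#' coverage-only (`ALT=.`) record at keys called only in the other
#' tumor; the germline VCF carries coverage-only records at every key.
#' High-quality depth travels in the custom FORMAT field `HQ`; dbSNP
#' membership is encoded in the tumor ID columns.
#'
#' @param evidence `locus_evidence` data.frame.
#' @param germline_path,tumor_a_path,tumor_b_path output VCF paths.
#' @return invisibly, the three paths.
#' @export
write_trio_vcfs <- function(evidence, germline_path, tumor_a_path,
                            tumor_b_path) {
  ev <- locus_evidence(evidence)
  ord <- order(ev$chrom, ev$pos, ev$ref, ev$alt)
  ev <- ev[ord, , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("##FORMAT=<ID=HQ,Number=1,Type=Integer,Description=",
           "\"Reads with base quality above Q20\">"))
  write_one <- function(path, sample, depth, alt_count, hq, called,
                        dbsnp = NULL) {
    body <- vapply(seq_len(nrow(ev)), function(i) {
      is_call <- called[i]
      alt_field <- if (is_call) ev$alt[i] else "."
      id <- if (!is.null(dbsnp) && dbsnp[i]) {
        sprintf("rs%d%03d", ev$pos[i], i %% 1000L)
      } else "."
      gt <- if (is_call) "0/1" else "0/0"
      ad <- sprintf("%d,%d", depth[i] - alt_count[i], alt_count[i])
      paste(ev$chrom[i], ev$pos[i], id, ev$ref[i], alt_field, ".",
            "PASS", ".", "GT:DP:AD:HQ",
            sprintf("%s:%d:%s:%d", gt, depth[i], ad, hq[i]),
            sep = "\t")
    }, character(1))
    col_line <- paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", sample, sep = "\t")
    writeLines(c(header, col_line, body), path)
  }
  write_one(germline_path, "GERMLINE", ev$g_depth, ev$g_alt,
            ev$g_hq_depth, rep(FALSE, nrow(ev)))
  write_one(tumor_a_path, "TUMOR_A", ev$a_depth, ev$a_alt,
            ev$a_depth, ev$a_called, dbsnp = ev$in_dbsnp)
  write_one(tumor_b_path, "TUMOR_B", ev$b_depth, ev$b_alt,
            ev$b_depth, ev$b_called, dbsnp = ev$in_dbsnp)
  invisible(c(germline_path, tumor_a_path, tumor_b_path))
}

#' Write a CLS test report
#'
#' Serializes a fitted [cls_test()] object to JSON (full precision) or
#' a one-row TSV. The report carries X, n, the CLS and its display
#' form, the null rate p0, alpha, the p-value, exact CI bounds, the
#' decision, and the HC filter parameters used (when the result was
#' fitted from an evidence profile).
#'
#' @param result a `cls_test` object.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "cls_test"))
  rep <- list(
    tool = "clstest",
    version = as.character(utils::packageVersion("clstest")),
    x = result$x, n = result$n,
    cls = result$cls, cls_display = format_percent(result$cls),
    p0 = result$params$p0, alpha = result$params$alpha,
    pa = result$params$pa, conf_level = result$params$conf_level,
    p_value = result$p_value,
    p_value_display = format_p_value(result$p_value),
    ci_low = result$ci_low, ci_high = result$ci_high,
    ci_display = sprintf("%s%% to %s%%", format_percent(result$ci_low),
                         format_percent(result$ci_high)),
    critical_value = result$critical_value,
    n_min_power = result$n_min_power,
    underpowered = result$underpowered,
    test_outcome = result$test_outcome,
    decision = result$decision)
  if (!is.null(result$filter_params))
    rep$filter_params <- result$filter_params
  if (format == "json") {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    flat <- rep
    flat$filter_params <- NULL
    df <- as.data.frame(flat, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
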