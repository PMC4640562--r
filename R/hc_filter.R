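# High-confidence (HC) mutation filtering for a tumor pair.
#
# An HC mutation is a somatic SNV called in at least one tumor, with a
# high-confidence homozygous-reference germline call (>= 15 high-quality
# reads, at most one alternate read, < 5% alternate fraction), not a
# dbSNP member, and with adequate coverage (40x) in BOTH tumors. The
# surviving loci partition into shared / private-to-A / private-to-B.

#' HC filter parameters
#'
#' Defaults encode the stringent filtering used to retain high-confidence
#' somatic SNVs: the germline sample must look homozygous reference
#' (at least `germline_min_hq_depth` reads of quality above
#' `germline_hq_quality_threshold`, at most `germline_max_alt_reads`
#' alternate reads, alternate fraction strictly below
#' `germline_max_alt_fraction`), dbSNP members are excluded as likely
#' germline variants, and both tumors must reach `tumor_min_depth`
#' total coverage at the locus.
#'
#' @param germline_min_hq_depth minimum high-quality germline reads (15).
#' @param germline_hq_quality_threshold phred cutoff defining a
#'   high-quality read (20); applied upstream when `g_hq_depth` is
#'   computed, recorded here for report provenance.
#' @param germline_max_alt_reads maximum germline alternate reads (1).
#' @param germline_max_alt_fraction germline alternate-fraction bound,
#'   rejection at >= this value (0.05).
#' @param tumor_min_depth minimum total depth in each tumor (40).
#' @param exclude_dbsnp drop dbSNP members (TRUE).
#' @return list of class `hc_params`.
#' @export
hc_params <- function(germline_min_hq_depth = 15L,
                      germline_hq_quality_threshold = 20,
                      germline_max_alt_reads = 1L,
                      germline_max_alt_fraction = 0.05,
                      tumor_min_depth = 40L,
                      exclude_dbsnp = TRUE) {
  p <- list(germline_min_hq_depth = as.integer(germline_min_hq_depth),
            germline_hq_quality_threshold = germline_hq_quality_threshold,
            germline_max_alt_reads = as.integer(germline_max_alt_reads),
            germline_max_alt_fraction = germline_max_alt_fraction,
            tumor_min_depth = as.integer(tumor_min_depth),
            exclude_dbsnp = isTRUE(exclude_dbsnp))
  if (p$germline_min_hq_depth < 0 || p$germline_max_alt_reads < 0 ||
      p$tumor_min_depth < 0 || p$germline_hq_quality_threshold < 0)
    stop("HC filter thresholds must be non-negative")
  if (p$germline_max_alt_fraction < 0 || p$germline_max_alt_fraction > 1)
    stop("germline_max_alt_fraction must lie in [0,1]")
  class(p) <- "hc_params"
  p
}

REJECT_REASONS <- c("dbsnp", "germline_coverage", "germline_alt_reads",
                    "germline_alt_fraction", "tumor_coverage",
                    "no_tumor_call")

#' Classify locus evidence rows
#'
#' Applies the HC rules to each row and returns one outcome per locus:
#' `shared`, `private_a`, `private_b`, or `rejected:<reason>`. Rules are
#' checked in a fixed precedence so rejection tallies are deterministic:
#' dbSNP membership, then the germline homozygous-reference criteria
#' (coverage, alternate reads, alternate fraction), then tumor coverage,
#' then absence of a call in both tumors. Precedence affects only the
#' reported reason, never which loci survive.
#'
#' @param evidence `locus_evidence` data.frame (or one row of it).
#' @param params [hc_params()].
#' @return character vector of outcomes, one per row.
#' @export
classify_loci <- function(evidence, params = hc_params()) {
  ev <- if (inherits(evidence, "locus_evidence")) evidence else
    locus_evidence(evidence)
  stopifnot(inherits(params, "hc_params"))
  out <- rep(NA_character_, nrow(ev))
  g_frac <- ifelse(ev$g_depth > 0, ev$g_alt / ev$g_depth, 0)
  reject <- function(cond, reason) {
    hit <- is.na(out) & cond
    out[hit] <<- paste0("rejected:", reason)
  }
  if (params$exclude_dbsnp) reject(ev$in_dbsnp, "dbsnp")
  reject(ev$g_hq_depth < params$germline_min_hq_depth, "germline_coverage")
  reject(ev$g_alt > params$germline_max_alt_reads, "germline_alt_reads")
  reject(g_frac >= params$germline_max_alt_fraction, "germline_alt_fraction")
  reject(ev$a_depth < params$tumor_min_depth |
           ev$b_depth < params$tumor_min_depth, "tumor_coverage")
  reject(!ev$a_called & !ev$b_called, "no_tumor_call")
  out[is.na(out)] <- ifelse(ev$a_called[is.na(out)] & ev$b_called[is.na(out)],
                            "shared",
                            ifelse(ev$a_called[is.na(out)], "private_a",
                                   "private_b"))
  out
}

#' @rdname classify_loci
#' @export
classify_locus <- function(evidence, params = hc_params()) {
  res <- classify_loci(evidence, params)
  if (length(res) != 1L) stop("classify_locus expects a single row")
  res
}

#' Build the HC mutation profile of a tumor pair
#'
#' Partitions all surviving loci into shared and private sets and
#' tallies every rejection reason. `X` is the number of shared HC
#' mutations and `n` the total number of distinct HC loci called in
#' either tumor — the two counts the CLS test consumes.
#'
#' @param evidence `locus_evidence` data.frame, one row per locus key.
#' @param params [hc_params()].
#' @return object of class `hc_profile` with elements `shared`,
#'   `private_a`, `private_b` (locus-key character vectors), `X`, `n`,
#'   `filter_log` (named rejection tallies) and `params`.
#' @export
build_profile <- function(evidence, params = hc_params()) {
  ev <- if (inherits(evidence, "locus_evidence")) evidence else
    locus_evidence(evidence)
  outcome <- classify_loci(ev, params)
  shared <- ev$key[outcome == "shared"]
  private_a <- ev$key[outcome == "private_a"]
  private_b <- ev$key[outcome == "private_b"]
  reasons <- sub("^rejected:", "", outcome[startsWith(outcome, "rejected:")])
  filter_log <- vapply(REJECT_REASONS,
                       function(r) sum(reasons == r), integer(1))
  structure(list(shared = shared, private_a = private_a,
                 private_b = private_b,
                 X = length(shared),
                 n = length(shared) + length(private_a) + length(private_b),
                 filter_log = filter_log, params = params),
            class = "hc_profile")
}

#' @export
print.hc_profile <- function(x, ...) {
  cat("HC mutation profile of a tumor pair\n")
  cat(sprintf("  shared: %d   private A: %d   private B: %d\n",
              x$X, length(x$private_a), length(x$private_b)))
  cat(sprintf("  X = %d shared of n = %d total HC mutations\n", x$X, x$n))
  rej <- x$filter_log[x$filter_log > 0]
  if (length(rej))
    cat("  rejected:", paste(sprintf("%s=%d", names(rej), rej),
                             collapse = ", "), "\n")
  invisible(x)
}
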