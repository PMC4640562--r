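# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' Build canonical locus keys
#'
#' A mutation is identified by the full (chromosome, position, ref, alt)
#' tuple, so two different alternate alleles at one position are two
#' distinct mutations. Coordinates are 1-based VCF-style.
#'
#' @param chrom character chromosome labels.
#' @param pos integer 1-based positions.
#' @param ref,alt single-base reference/alternate alleles (A/C/G/T).
#' @return character vector of keys, `"chrom:pos:ref>alt"`.
#' @examples
#' locus_key("chr1", 100, "A", "T")
#' @export
locus_key <- function(chrom, pos, ref, alt) {
  validate_locus_key(chrom, pos, ref, alt)
  sprintf("%s:%d:%s>%s", as.character(chrom), as.integer(pos),
          as.character(ref), as.character(alt))
}

validate_locus_key <- function(chrom, pos, ref, alt) {
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L))
    stop("locus positions must be integers >= 1 (1-based convention)")
  if (!all(ref %in% BASES) || !all(alt %in% BASES))
    stop("ref and alt alleles must be single bases in {A,C,G,T} (SNVs only)")
  if (any(ref == alt))
    stop("ref and alt alleles must differ")
  invisible(TRUE)
}

# Round half away from zero (round() is half-even, which would turn a
# displayed 68.5% into 68%).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a percentage the way CLS reports print it
#'
#' Values at or above 2 percent are shown to the nearest integer percent,
#' values below 2 percent to one decimal, so small scores such as 1.1%
#' or a CI bound of 0.1% keep a significant figure while 80.6% prints
#' as 81% and 3.87% as 4%. Underlying values are never rounded; this is
#' display only.
#'
#' @param x numeric vector of percentages (0-100 scale).
#' @return character vector like `"81"` or `"1.1"` (no percent sign).
#' @export
format_percent <- function(x) {
  ifelse(x >= 2,
         sprintf("%.0f", round_half_up(x, 0)),
         sprintf("%.1f", round_half_up(x, 1)))
}

# Clip tiny p-values for display, mirroring "p < 1e-15" report style.
format_p_value <- function(p) {
  if (p < 1e-15) "<1e-15" else sprintf("%.4g", p)
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state.
# Single named generator, no lasting global side effects.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
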