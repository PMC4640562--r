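# Cohort-based calibration of the null shared-call rate p0.
#
# Tumors from DIFFERENT patients are paired computationally
# ("counterfactual pairs"): any sharing between them reflects chance
# recurrence of driver mutations plus technical artifacts, so the
# empirical CLS distribution over many such pairs bounds the background
# rate p0 used by the test.

#' A tumor's mutation list
#'
#' @param tumor_id unique tumor identifier.
#' @param patient_id patient the tumor came from (pairs never join two
#'   tumors of one patient).
#' @param mutations character vector of locus keys (see [locus_key()]);
#'   deduplicated on construction.
#' @param group_label optional stratum label (e.g. a subtype) for
#'   cross-group pairing.
#' @return list of class `tumor_mutation_list`.
#' @export
tumor_mutation_list <- function(tumor_id, patient_id, mutations = character(),
                                group_label = NA_character_) {
  stopifnot(is.character(tumor_id), length(tumor_id) == 1,
            is.character(patient_id), length(patient_id) == 1)
  structure(list(tumor_id = tumor_id, patient_id = patient_id,
                 mutations = unique(as.character(mutations)),
                 group_label = as.character(group_label)),
            class = "tumor_mutation_list")
}

#' Assemble a cohort of tumor mutation lists
#'
#' @param tumors list of [tumor_mutation_list()] objects with unique
#'   tumor ids.
#' @return list of class `tumor_cohort`, indexable by tumor id.
#' @export
tumor_cohort <- function(tumors) {
  stopifnot(all(vapply(tumors, inherits, logical(1),
                       "tumor_mutation_list")))
  ids <- vapply(tumors, `[[`, character(1), "tumor_id")
  if (anyDuplicated(ids))
    stop("tumor_id must be unique within a cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(tumors) <- ids
  structure(tumors, class = "tumor_cohort")
}

#' Read a cohort from a manifest and a directory of mutation lists
#'
#' The manifest is tab-delimited with columns `tumor_id`, `patient_id`,
#' optional `group_label`, and `file` naming a per-tumor mutation list
#' in `dir`: tab-delimited with columns `chrom`, `pos`, `ref`, `alt`
#' and optionally `gene`.
#'
#' @param manifest_path manifest file path.
#' @param dir directory holding the per-tumor files.
#' @return a [tumor_cohort()]; per-key gene symbols, when present, are
#'   attached as a named `genes` attribute on each mutation vector.
#' @export
read_cohort <- function(manifest_path, dir = dirname(manifest_path)) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("tumor_id", "patient_id", "file")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols))
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tumors <- lapply(seq_len(nrow(man)), function(i) {
    path <- file.path(dir, man$file[i])
    if (!file.exists(path)) stop("mutation list not found: ", path)
    mut <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(chrom = "character", ref = "character",
                                         alt = "character"))
    keys <- if (nrow(mut) == 0) character(0) else
      locus_key(mut$chrom, mut$pos, mut$ref, mut$alt)
    keys_u <- unique(keys)
    tl <- tumor_mutation_list(man$tumor_id[i], man$patient_id[i],
                              keys_u,
                              group_label = man$group_label[i] %||%
                                NA_character_)
    if ("gene" %in% names(mut) && length(keys))
      attr(tl$mutations, "genes") <-
        stats::setNames(mut$gene[match(keys_u, keys)], keys_u)
    tl
  })
  tumor_cohort(tumors)
}

#' Enumerate counterfactual tumor pairs
#'
#' Never pairs two tumors of the same patient. Rules:
#' `cross_group` forms all A x B pairs across the two levels of
#' `group_label` (a ER+ group of 357 and a TN group of 46 give
#' 357 x 46 = 16,422 pairs); `all_cross_patient` forms every unordered
#' pair with distinct `patient_id`; `random_cross_patient` samples `k`
#' of those without replacement, reproducibly from `seed`.
#'
#' @param cohort a [tumor_cohort()].
#' @param pairing_rule one of `"cross_group"`, `"all_cross_patient"`,
#'   `"random_cross_patient"`.
#' @param k,seed for `random_cross_patient`.
#' @return data.frame with columns `tumor_a`, `tumor_b` (tumor ids),
#'   deterministic order given inputs (and seed).
#' @export
counterfactual_pairs <- function(cohort,
                                 pairing_rule = c("all_cross_patient",
                                                  "cross_group",
                                                  "random_cross_patient"),
                                 k = NULL, seed = NULL) {
  pairing_rule <- match.arg(pairing_rule)
  ids <- vapply(cohort, `[[`, character(1), "tumor_id")
  pat <- vapply(cohort, `[[`, character(1), "patient_id")
  grp <- vapply(cohort, `[[`, character(1), "group_label")
  if (pairing_rule == "cross_group") {
    levels <- unique(grp[!is.na(grp)])
    if (length(levels) != 2)
      stop("cross_group pairing needs exactly two group labels; found ",
           length(levels))
    ia <- which(grp == levels[1]); ib <- which(grp == levels[2])
    pairs <- expand.grid(a = ia, b = ib, KEEP.OUT.ATTRS = FALSE)
    pairs <- pairs[pat[pairs$a] != pat[pairs$b], , drop = FALSE]
  } else {
    idx <- utils::combn(length(ids), 2)
    keep <- pat[idx[1, ]] != pat[idx[2, ]]
    pairs <- data.frame(a = idx[1, keep], b = idx[2, keep])
    if (pairing_rule == "random_cross_patient") {
      if (is.null(k)) stop("random_cross_patient needs k")
      k <- min(k, nrow(pairs))
      pairs <- with_seed(seed,
                         pairs[sample.int(nrow(pairs), k), , drop = FALSE])
    }
  }
  out <- data.frame(tumor_a = ids[pairs$a], tumor_b = ids[pairs$b],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Shared and total mutation counts of one pair
#'
#' @param list_a,list_b [tumor_mutation_list()] objects.
#' @return list with `x` (= size of the key intersection), `n` (= size
#'   of the union) and `shared` (the shared keys). Symmetric in its
#'   arguments.
#' @export
pair_cls <- function(list_a, list_b) {
  shared <- intersect(list_a$mutations, list_b$mutations)
  n <- length(list_a$mutations) + length(list_b$mutations) -
    length(shared)
  list(x = length(shared), n = n, shared = shared)
}

#' Summarize the counterfactual CLS distribution of a cohort
#'
#' Streams over all pairs from [counterfactual_pairs()] one at a time
#' (memory does not grow with the number of pairs) and aggregates the
#' empirical CLS distribution. `suggested_p0` is the smallest rate on
#' the percent grid 3%, 4%, 5%, ... strictly above the empirical 99.9th
#' percentile of pair CLS, floored at 3% — a reproducible version of
#' choosing p0 with headroom above the observed background maximum, to
#' allow for the higher artifact sharing expected between two samples
#' of one patient sequenced in one batch.
#'
#' @param cohort a [tumor_cohort()] with >= 2 tumors from >= 2 patients.
#' @param pairing_rule,k,seed passed to [counterfactual_pairs()].
#' @param gene_map optional named character vector, locus key -> gene
#'   symbol, used for the shared-mutation tally; per-tumor gene
#'   annotations from [read_cohort()] are used when present.
#' @return list of class `cohort_summary`: `num_pairs`,
#'   `frac_zero_cls`, `max_cls` (percent), `cls_histogram` (named
#'   vector, shared count -> number of pairs), `shared_locus_tally`
#'   (times each locus/gene was shared, decreasing), `suggested_p0`.
#' @export
summarize_cohort <- function(cohort,
                             pairing_rule = "all_cross_patient",
                             k = NULL, seed = NULL, gene_map = NULL) {
  pats <- unique(vapply(cohort, `[[`, character(1), "patient_id"))
  if (length(cohort) < 2 || length(pats) < 2)
    stop("degenerate cohort: need >= 2 tumors from >= 2 patients")
  pairs <- counterfactual_pairs(cohort, pairing_rule, k = k, seed = seed)
  if (nrow(pairs) == 0)
    stop("degenerate cohort: the pairing rule produced no pairs")
  if (is.null(gene_map)) {
    gl <- do.call(c, unname(lapply(cohort,
                                   function(t) attr(t$mutations, "genes"))))
    if (!is.null(gl)) gene_map <- gl[!duplicated(names(gl))]
  }
  hist_counts <- integer()      # names: shared count X
  tally <- integer()            # names: locus key or gene
  cls_values <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pc <- pair_cls(cohort[[pairs$tumor_a[i]]], cohort[[pairs$tumor_b[i]]])
    cls_values[i] <- if (pc$n > 0) pc$x / pc$n else 0
    xc <- as.character(pc$x)
    hist_counts[xc] <- (if (xc %in% names(hist_counts))
      hist_counts[[xc]] else 0L) + 1L
    if (pc$x > 0) {
      lab <- pc$shared
      if (!is.null(gene_map)) {
        mapped <- gene_map[lab]
        lab <- ifelse(is.na(mapped), lab, mapped)
      }
      for (l in lab)
        tally[l] <- (if (l %in% names(tally)) tally[[l]] else 0L) + 1L
    }
  }
  q999 <- stats::quantile(cls_values, 0.999, type = 1, names = FALSE)
  grid <- seq(0.03, 1, by = 0.01)
  suggested_p0 <- grid[grid > q999][1]
  hist_counts <- hist_counts[order(as.integer(names(hist_counts)))]
  structure(list(
    num_pairs = nrow(pairs),
    frac_zero_cls = mean(cls_values == 0),
    max_cls = 100 * max(cls_values),
    cls_histogram = hist_counts,
    shared_locus_tally = sort(tally, decreasing = TRUE),
    suggested_p0 = suggested_p0), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Counterfactual cohort calibration\n")
  cat(sprintf("  %d cross-patient pairs; %.1f%% with CLS = 0; max CLS %.2f%%\n",
              x$num_pairs, 100 * x$frac_zero_cls, x$max_cls))
  cat(sprintf("  suggested p0: %g\n", x$suggested_p0))
  if (length(x$shared_locus_tally)) {
    top <- utils::head(x$shared_locus_tally, 5)
    cat("  most-shared loci:",
        paste(sprintf("%s (%d)", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}
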