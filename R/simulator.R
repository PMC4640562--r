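# Monte-Carlo machinery: synthetic tumor-pair profiles with controlled
# clonal structure, and empirical type-I error / power of the CLS
# decision rule. Three knobs map one-to-one onto the quantities the
# test calibrates: the true sharing rate (the clonal pa), per-tumor
# detection sensitivities (low-cellularity dropout that miscalls shared
# mutations as private), and a false-positive sharing rate (the
# technical-artifact component of p0).

#' Simulation parameters
#'
#' @param n_total_range integer interval (length-2 vector, or a single
#'   value for fixed n) for the total mutation count per pair.
#' @param true_shared_rate probability a locus is truly shared between
#'   the tumors (0 for independent pairs; pa-like for clonal pairs).
#' @param fp_shared_rate probability an unshared locus is miscalled as
#'   shared (technical artifacts, recurrent drivers).
#' @param detection_sensitivity_a,detection_sensitivity_b probability a
#'   truly shared mutation is detected in that tumor; a shared mutation
#'   detected in only one tumor degrades to a private call, the main
#'   false-negative mode for low-cellularity samples.
#' @param reps number of simulated pairs.
#' @param seed RNG seed; every simulation is reproducible from it.
#'   `NULL` draws from the current RNG stream instead.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_total_range = c(44L, 44L),
                       true_shared_rate = 0,
                       fp_shared_rate = 0,
                       detection_sensitivity_a = 1,
                       detection_sensitivity_b = 1,
                       reps = 10000L, seed = 1L) {
  if (length(n_total_range) == 1) n_total_range <- rep(n_total_range, 2)
  n_total_range <- as.integer(n_total_range)
  fr <- c(true_shared_rate, fp_shared_rate,
          detection_sensitivity_a, detection_sensitivity_b)
  if (any(fr < 0) || any(fr > 1)) stop("rates must lie in [0, 1]")
  if (n_total_range[1] > n_total_range[2] || n_total_range[1] < 1)
    stop("n_total_range must be a non-empty interval of n >= 1")
  if (reps < 1) stop("reps must be >= 1")
  structure(list(n_total_range = n_total_range,
                 true_shared_rate = true_shared_rate,
                 fp_shared_rate = fp_shared_rate,
                 detection_sensitivity_a = detection_sensitivity_a,
                 detection_sensitivity_b = detection_sensitivity_b,
                 reps = as.integer(reps),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_params")
}

# One pair draw using the CURRENT RNG stream. n is drawn uniformly from
# the range; each of the n loci is truly shared w.p. true_shared_rate;
# a truly shared locus is observed shared only if detected in both
# tumors (independent sensitivities), otherwise it remains in n as a
# private call; an unshared locus is observed shared w.p.
# fp_shared_rate. Returns observed counts.
draw_pair <- function(params) {
  n <- if (params$n_total_range[1] == params$n_total_range[2])
    params$n_total_range[1]
  else sample(params$n_total_range[1]:params$n_total_range[2], 1L)
  s_true <- stats::rbinom(1L, n, params$true_shared_rate)
  s_seen <- stats::rbinom(1L, s_true,
                          params$detection_sensitivity_a *
                            params$detection_sensitivity_b)
  fp <- stats::rbinom(1L, n - s_true, params$fp_shared_rate)
  list(x = s_seen + fp, n = n)
}

#' Simulate one tumor-pair mutation profile
#'
#' @param params [sim_params()]; its `seed` controls the draw.
#' @param fixture if `TRUE`, also return a full locus-evidence table
#'   realizing the drawn counts (clean germline, both tumors covered at
#'   depth passing the default HC filter), for end-to-end pipeline
#'   tests.
#' @return list with observed `x`, `n`, and optionally `evidence`.
#' @export
simulate_pair <- function(params, fixture = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  draw <- with_seed(params$seed, draw_pair(params))
  if (fixture) {
    # split the private remainder between the tumors arbitrarily but
    # reproducibly (the test statistic only sees x and n)
    n_priv <- draw$n - draw$x
    n_a <- n_priv %/% 2L
    draw$evidence <- generate_fixture_trio(
      n_shared = draw$x, n_private_a = n_a,
      n_private_b = n_priv - n_a, seed = params$seed + 1L)
  }
  draw
}

#' Empirical operating characteristics of the CLS test
#'
#' Simulates `reps` tumor pairs under `sim` and applies the CLS
#' decision rule (reject independence when X reaches the exact critical
#' value for the drawn n): with `true_shared_rate = 0` the rejection
#' fraction estimates the type-I error; with a clonal
#' `true_shared_rate` it estimates power.
#'
#' @param sim [sim_params()].
#' @param test [cls_params()]; only `p0` and `alpha` enter the rule.
#' @return list of class `cls_oc`: `rejection_fraction`, `mc_stderr`
#'   (= sqrt(f(1-f)/reps)), `reps`, `params_echo`, `test_params_echo`.
#' @examples
#' estimate_operating_characteristics(
#'   sim_params(44, true_shared_rate = 0.15, reps = 2000, seed = 7))
#' @export
estimate_operating_characteristics <- function(sim,
                                               test = cls_params()) {
  stopifnot(inherits(sim, "sim_params"), inherits(test, "cls_params"))
  lo <- sim$n_total_range[1]; hi <- sim$n_total_range[2]
  crit <- vapply(lo:hi, critical_value, integer(1),
                 p0 = test$p0, alpha = test$alpha)
  rejected <- with_seed(sim$seed, {
    vapply(seq_len(sim$reps), function(i) {
      d <- draw_pair(sim)
      d$x >= crit[d$n - lo + 1L]
    }, logical(1))
  })
  f <- mean(rejected)
  structure(list(rejection_fraction = f,
                 mc_stderr = sqrt(f * (1 - f) / sim$reps),
                 reps = sim$reps,
                 params_echo = sim, test_params_echo = test),
            class = "cls_oc")
}

#' @export
print.cls_oc <- function(x, ...) {
  cat(sprintf("CLS test rejection fraction: %.4f (MC stderr %.4f, %d reps)\n",
              x$rejection_fraction, x$mc_stderr, x$reps))
  cat(sprintf("  sim: n in [%d,%d], true shared %.3g, fp shared %.3g, sensitivities %.2f/%.2f\n",
              x$params_echo$n_total_range[1], x$params_echo$n_total_range[2],
              x$params_echo$true_shared_rate, x$params_echo$fp_shared_rate,
              x$params_echo$detection_sensitivity_a,
              x$params_echo$detection_sensitivity_b))
  cat(sprintf("  test: p0 = %g, alpha = %g\n",
              x$test_params_echo$p0, x$test_params_echo$alpha))
  invisible(x)
}

# ---- deterministic fixture generation -----------------------------------

rand_alleles <- function(k) {
  ref <- sample(BASES, k, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L),
                character(1))
  list(ref = ref, alt = unname(alt))
}

#' Generate a locus-evidence fixture with a known HC profile
#'
#' Emits an evidence table that, under the default HC filter
#' parameters, yields exactly the requested shared/private counts, plus
#' loci engineered to fail exactly one named rule each. The profile is
#' verified internally with [build_profile()] before returning.
#'
#' @param n_shared,n_private_a,n_private_b surviving locus counts.
#' @param n_rejected_by_reason named integer vector/list over the
#'   rejection reasons (`dbsnp`, `germline_coverage`,
#'   `germline_alt_reads`, `germline_alt_fraction`, `tumor_coverage`,
#'   `no_tumor_call`), e.g. `c(dbsnp = 5)`.
#' @param seed RNG seed (depths and alleles are drawn reproducibly).
#' @param params [hc_params()] the fixture must satisfy.
#' @return `locus_evidence` data.frame.
#' @examples
#' ev <- generate_fixture_trio(50, 0, 12, seed = 1)
#' build_profile(ev)  # X = 50, n = 62
#' @export
generate_fixture_trio <- function(n_shared, n_private_a, n_private_b,
                                  n_rejected_by_reason = integer(),
                                  seed = 1L, params = hc_params()) {
  stopifnot(n_shared >= 0, n_private_a >= 0, n_private_b >= 0)
  rej <- as.list(n_rejected_by_reason)
  bad <- setdiff(names(rej), REJECT_REASONS)
  if (length(bad))
    stop("unknown rejection reason(s): ", paste(bad, collapse = ", "))
  get_rej <- function(r) as.integer(rej[[r]] %||% 0L)
  if (!params$exclude_dbsnp && get_rej("dbsnp") > 0)
    stop("cannot generate dbsnp rejections with exclude_dbsnp = FALSE")

  total <- n_shared + n_private_a + n_private_b +
    sum(vapply(REJECT_REASONS, get_rej, integer(1)))
  ev <- with_seed(seed, {
    al <- rand_alleles(max(total, 1L))
    t_depth <- function(k) sample(params$tumor_min_depth:(params$tumor_min_depth + 160L),
                                  k, replace = TRUE)
    g_depth <- function(k) sample(max(params$germline_min_hq_depth, 15L):60L,
                                  k, replace = TRUE)
    rows <- function(k, kind) {
      if (k == 0) return(NULL)
      gd <- g_depth(k); ad <- t_depth(k); bd <- t_depth(k)
      df <- data.frame(
        g_depth = gd, g_alt = 0L, g_hq_depth = gd,
        a_depth = ad, a_alt = as.integer(round(ad * 0.35)),
        a_called = TRUE,
        b_depth = bd, b_alt = as.integer(round(bd * 0.35)),
        b_called = TRUE, in_dbsnp = FALSE)
      switch(kind,
        shared = df,
        private_a = { df$b_called <- FALSE; df$b_alt <- 0L; df },
        private_b = { df$a_called <- FALSE; df$a_alt <- 0L; df },
        dbsnp = { df$in_dbsnp <- TRUE; df },
        germline_coverage = {
          df$g_hq_depth <- pmax(params$germline_min_hq_depth - 1L, 0L)
          df
        },
        germline_alt_reads = {
          df$g_alt <- params$germline_max_alt_reads + 1L; df
        },
        germline_alt_fraction = {
          # alt count within the read limit but a depth low enough that
          # the alternate fraction reaches the bound
          need_alt <- min(params$germline_max_alt_reads, 1L)
          if (need_alt == 0)
            stop("germline_alt_fraction unreachable with max_alt_reads 0 ",
                 "(alt-read rule fires first)")
          depth <- max(params$germline_min_hq_depth,
                       floor(need_alt / params$germline_max_alt_fraction))
          df$g_depth <- as.integer(depth)
          df$g_hq_depth <- as.integer(depth)
          df$g_alt <- need_alt
          df
        },
        tumor_coverage = {
          df$b_depth <- params$tumor_min_depth - 1L
          df$b_called <- FALSE
          df$b_alt <- 0L
          df
        },
        no_tumor_call = {
          df$a_called <- FALSE; df$a_alt <- 0L
          df$b_called <- FALSE; df$b_alt <- 0L
          df
        })
    }
    kinds <- c(shared = n_shared, private_a = n_private_a,
               private_b = n_private_b,
               stats::setNames(vapply(REJECT_REASONS, get_rej, integer(1)),
                               REJECT_REASONS))
    parts <- Filter(Negate(is.null),
                    lapply(names(kinds),
                           function(k) rows(kinds[[k]], k)))
    if (length(parts) == 0) {
      df <- data.frame(g_depth = integer(), g_alt = integer(),
                       g_hq_depth = integer(), a_depth = integer(),
                       a_alt = integer(), a_called = logical(),
                       b_depth = integer(), b_alt = integer(),
                       b_called = logical(), in_dbsnp = logical())
    } else df <- do.call(rbind, parts)
    k <- nrow(df)
    df <- cbind(data.frame(chrom = rep("chr1", k),
                           pos = seq_len(max(k, 0L)) * 100L,
                           ref = al$ref[seq_len(k)],
                           alt = al$alt[seq_len(k)],
                           stringsAsFactors = FALSE), df)
    locus_evidence(df)
  })
  # verify the contract before handing the fixture out
  prof <- build_profile(ev, params)
  want_rej <- vapply(REJECT_REASONS, get_rej, integer(1))
  if (prof$X != n_shared ||
      length(prof$private_a) != n_private_a ||
      length(prof$private_b) != n_private_b ||
      !all(prof$filter_log == want_rej))
    stop("fixture generation failed to realize the requested profile")
  ev
}
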