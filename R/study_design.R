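# Study design for the CLS test: exact critical values, exact power,
# and the minimum number of total HC mutations needed for target power.

#' Exact critical value of the one-sided binomial test
#'
#' The smallest integer `c` with `P(X >= c | n, p0) <= alpha` under
#' `X ~ Binomial(n, p0)`. Observing `X >= c` rejects independence. The
#' boundary uses `<= alpha` (the standard exact-test convention).
#' `c = n + 1` means no achievable rejection region at this `n`.
#'
#' @param n number of trials (total HC mutations), `n >= 1`.
#' @param p0 null success rate.
#' @param alpha significance level.
#' @return integer critical value in `0..n+1`.
#' @examples
#' critical_value(44, 0.04, 0.05)  # 5
#' critical_value(21, 0.03, 0.05)  # 3
#' @export
critical_value <- function(n, p0, alpha = 0.05) {
  stopifnot(n >= 1, p0 > 0, p0 < 1, alpha > 0, alpha < 1)
  # qbinom gives a near-miss starting point; adjust to the exact
  # smallest c with upper tail <= alpha
  c <- stats::qbinom(1 - alpha, n, p0)
  while (c <= n && binomial_upper_p(c, n, p0) > alpha) c <- c + 1L
  while (c >= 1 && binomial_upper_p(c - 1L, n, p0) <= alpha) c <- c - 1L
  as.integer(c)
}

#' Exact power of the CLS rejection rule
#'
#' `P(X >= c | n, pa)`: the probability of rejecting independence for a
#' truly clonal pair whose shared-mutation rate is `pa`.
#'
#' @param n number of trials.
#' @param c critical value, `0 <= c <= n + 1`.
#' @param pa alternative success rate.
#' @return exact rejection probability.
#' @examples
#' exact_power(44, 5, 0.15)  # 0.8097...
#' @export
exact_power <- function(n, c, pa) {
  stopifnot(c >= 0, c <= n + 1, pa > 0, pa < 1)
  if (c == 0) return(1)
  if (c == n + 1) return(0)
  binomial_upper_p(c, n, pa)
}

#' Minimum total mutations for target power
#'
#' Scans n upward and returns the FIRST n whose exact test (with its
#' own recomputed critical value) reaches the target power. Power as a
#' function of n is a sawtooth — it dips each time the critical value
#' steps up — so the first-passing n is not the n beyond which power
#' stays above target; the first-passing convention is the one used
#' for the published design table.
#'
#' @param p0 null shared-call rate.
#' @param pa alternative (clonal) shared rate, `pa > p0`.
#' @param alpha significance level.
#' @param target_power required power (0.80).
#' @param n_max search ceiling.
#' @return a one-row `data.frame` (class `cls_design_row`) with columns
#'   `p0, pa, alpha, target_power, n_required, critical_value,
#'   achieved_alpha, achieved_power`.
#' @examples
#' min_n_for_power(0.04, 0.15, 0.05, 0.80)  # n = 44, c = 5
#' @export
min_n_for_power <- function(p0, pa, alpha = 0.05, target_power = 0.80,
                            n_max = 1e6) {
  stopifnot(p0 > 0, p0 < pa, pa < 1, alpha > 0, alpha < 1,
            target_power > 0, target_power < 1)
  for (n in seq_len(n_max)) {
    c <- critical_value(n, p0, alpha)
    if (c > n) next  # no rejection region at this n
    pow <- exact_power(n, c, pa)
    if (pow >= target_power) {
      row <- data.frame(p0 = p0, pa = pa, alpha = alpha,
                        target_power = target_power,
                        n_required = as.integer(n),
                        critical_value = c,
                        achieved_alpha = binomial_upper_p(c, n, p0),
                        achieved_power = pow)
      class(row) <- c("cls_design_row", "data.frame")
      return(row)
    }
  }
  stop("target power ", target_power, " not reachable with n <= ", n_max)
}

#' Design table over a grid of rates
#'
#' Cartesian product of `p0_list` x `pa_list` in input order, one
#' design row per cell. With the default operating points
#' (`p0` 3-4%, `pa` 10/15/20%, alpha 5%, power 80%) this reproduces the
#' recommended (n, c) table: at p0 = 4% and pa = 15%, at least 44 total
#' HC mutations are needed, with rejection at X >= 5.
#'
#' @param p0_list,pa_list numeric vectors of rates.
#' @param alpha significance level.
#' @param target_power required power.
#' @return `data.frame` (class `cls_design`) of design rows.
#' @examples
#' design_table(c(0.03, 0.04), c(0.10, 0.15, 0.20))
#' @export
design_table <- function(p0_list = c(0.03, 0.04),
                         pa_list = c(0.10, 0.15, 0.20),
                         alpha = 0.05, target_power = 0.80) {
  stopifnot(length(p0_list) >= 1, length(pa_list) >= 1)
  rows <- list()
  for (p0 in p0_list) for (pa in pa_list)
    rows[[length(rows) + 1L]] <- min_n_for_power(p0, pa, alpha,
                                                 target_power)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("cls_design", "data.frame")
  tab
}

#' @export
print.cls_design <- function(x, ...) {
  cat("CLS test design: exact critical values and minimum n for",
      sprintf("%g%% power\n", 100 * x$target_power[1]))
  df <- data.frame(p0 = sprintf("%g%%", 100 * x$p0),
                   pa = sprintf("%g%%", 100 * x$pa),
                   n = x$n_required, c = x$critical_value,
                   achieved_alpha = sprintf("%.4f", x$achieved_alpha),
                   achieved_power = sprintf("%.4f", x$achieved_power))
  print(df, row.names = FALSE)
  invisible(x)
}
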