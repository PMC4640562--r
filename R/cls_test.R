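# The Clonal Likelihood Score test.
#
# For a tumor pair, let n be the total number of distinct genomic loci
# with a high-confidence mutation called in either tumor and X the
# number shared by both. Under the null hypothesis of independent
# origin, X ~ Binomial(n, p0) where p0 is the maximum shared-call rate
# expected between unrelated tumors (chance drivers plus technical
# artifacts; 4% by default). A high CLS = 100*X/n is evidence of clonal
# origin; the test is the one-sided exact binomial test rejecting
# independence when X reaches the critical value c(n, p0, alpha).

#' Clonal Likelihood Score
#'
#' `CLS = 100 * X / n`: the percentage of high-confidence mutations
#' shared by both tumors out of all distinct HC mutations in the pair.
#' Returned at full precision; display rounding is the report's job
#' (see [format_percent()]).
#'
#' @param x shared HC mutation count.
#' @param n total HC mutation count, `n >= 1`.
#' @return the score as a percentage in `[0, 100]`.
#' @examples
#' cls_score(50, 62)   # 80.645..., displayed "81"
#' cls_score(2, 184)   # 1.087...,  displayed "1.1"
#' @export
cls_score <- function(x, n) {
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("CLS is undefined for n = 0: no HC mutations, report no-test")
  if (x < 0 || x > n) stop("x must satisfy 0 <= x <= n")
  100 * x / n
}

#' Upper-tail exact binomial probability
#'
#' `P(B >= x)` for `B ~ Binomial(n, p0)`, the p-value of the one-sided
#' CLS test. Computed through the regularized incomplete beta function
#' (the numerically stable route used by R's binomial tail), accurate in
#' the far tail where naive summation underflows.
#'
#' @param x observed count, `0 <= x <= n` (vectorized).
#' @param n number of trials.
#' @param p0 null success probability in (0, 1).
#' @return `P(B >= x)`.
#' @examples
#' binomial_upper_p(50, 62, 0.04)  # < 1e-15
#' binomial_upper_p(2, 184, 0.04)  # > 0.99
#' @export
binomial_upper_p <- function(x, n, p0) {
  if (any(p0 <= 0) || any(p0 >= 1)) stop("p0 must lie strictly in (0, 1)")
  if (any(x < 0) || any(x > n)) stop("x must satisfy 0 <= x <= n")
  stats::pbinom(x - 1, n, p0, lower.tail = FALSE)
}

#' Exact Clopper-Pearson confidence interval
#'
#' Two-sided exact binomial interval for the success probability,
#' obtained by inverting binomial tail probabilities (beta quantile
#' form). The lower bound is exactly 0 when `x = 0` and the upper bound
#' exactly 1 when `x = n`.
#'
#' @param x success count, `0 <= x <= n`.
#' @param n number of trials, `n >= 1`.
#' @param confidence two-sided confidence level (0.95).
#' @return named numeric `c(low, high)` as fractions.
#' @examples
#' clopper_pearson(50, 62)  # (0.686, 0.896): displayed 69% to 90%
#' @export
clopper_pearson <- function(x, n, confidence = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n, confidence > 0, confidence < 1)
  a <- 1 - confidence
  low <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  high <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(low = low, high = high)
}

#' Test parameters for the CLS test
#'
#' @param p0 null shared-call rate among independent pairs (0.04).
#' @param alpha significance level (0.05).
#' @param pa design alternative: the lowest shared-mutation rate
#'   expected in clonal pairs (0.15); used only to flag underpowered
#'   inputs via the 80%-power minimum n.
#' @param conf_level Clopper-Pearson confidence level (0.95).
#' @return list of class `cls_params`.
#' @export
cls_params <- function(p0 = 0.04, alpha = 0.05, pa = 0.15,
                       conf_level = 0.95) {
  if (!(p0 > 0 && p0 < pa && pa < 1))
    stop("need 0 < p0 < pa < 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (!(conf_level > 0 && conf_level < 1))
    stop("conf_level must lie in (0, 1)")
  structure(list(p0 = p0, alpha = alpha, pa = pa,
                 conf_level = conf_level), class = "cls_params")
}

#' Fit the CLS clonality test to a tumor pair
#'
#' The main entry point: given the shared count `x` and total count `n`
#' of high-confidence mutations (or an [build_profile()] result),
#' computes the CLS, the one-sided exact binomial p-value against
#' `H0: p <= p0`, the exact Clopper-Pearson interval, and the decision.
#' Independence is rejected in favor of clonal origin when `x` reaches
#' the exact critical value `c(n, p0, alpha)` (equivalently, when the
#' p-value does not exceed the achieved alpha of that critical value).
#' Pairs with fewer total mutations than the 80%-power minimum for
#' `(p0, pa, alpha)` are flagged `underpowered`; the raw test outcome is
#' still reported alongside.
#'
#' @param x shared HC mutation count, or an `hc_profile`.
#' @param n total HC mutation count (`n >= 1`).
#' @param p0,alpha,pa,conf_level see [cls_params()].
#' @param ... passed between methods.
#' @return object of class `cls_test`: a list with `x`, `n`, `cls`
#'   (percent), `p_value`, `ci_low`/`ci_high` (percent),
#'   `critical_value`, `n_min_power`, `underpowered`, `test_outcome`
#'   (`"clonal"` or `"independence_not_rejected"`), `decision`
#'   (`"underpowered"` when flagged, else the test outcome) and
#'   `params`.
#' @examples
#' cls_test(50, 62)   # clonal
#' cls_test(2, 184)   # independence not rejected
#' @export
cls_test <- function(x, ...) UseMethod("cls_test")

#' @rdname cls_test
#' @export
cls_test.default <- function(x, n, p0 = 0.04, alpha = 0.05, pa = 0.15,
                             conf_level = 0.95, ...) {
  params <- cls_params(p0 = p0, alpha = alpha, pa = pa,
                       conf_level = conf_level)
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("no test possible: n = 0 HC mutations in the pair ",
         "(the CLS is undefined; report no-test)")
  if (x < 0 || x > n) stop("x must satisfy 0 <= x <= n")
  cls <- cls_score(x, n)
  p_value <- binomial_upper_p(x, n, params$p0)
  ci <- clopper_pearson(x, n, confidence = params$conf_level)
  cv <- critical_value(n, params$p0, params$alpha)
  design <- min_n_for_power(params$p0, params$pa, params$alpha, 0.80)
  outcome <- if (x >= cv) "clonal" else "independence_not_rejected"
  under <- n < design$n_required
  structure(list(
    x = as.integer(x), n = as.integer(n), cls = cls,
    p_value = p_value,
    ci_low = 100 * ci[["low"]], ci_high = 100 * ci[["high"]],
    critical_value = cv,
    n_min_power = design$n_required,
    underpowered = under,
    test_outcome = outcome,
    decision = if (under) "underpowered" else outcome,
    params = params, filter_params = NULL, profile = NULL),
    class = "cls_test")
}

#' @rdname cls_test
#' @export
cls_test.hc_profile <- function(x, ...) {
  fit <- cls_test.default(x$X, x$n, ...)
  fit$profile <- x
  fit$filter_params <- unclass(x$params)
  fit
}

#' @export
print.cls_test <- function(x, ...) {
  cat("\n\tClonal Likelihood Score test\n\n")
  cat(sprintf("CLS = %s%% (%d shared of %d total HC mutations)\n",
              format_percent(x$cls), x$x, x$n))
  cat(sprintf("one-sided exact binomial test, H0: p <= %g, p-value %s\n",
              x$params$p0, format_p_value(x$p_value)))
  cat(sprintf("%g%% Clopper-Pearson CI: %s%% to %s%%\n",
              100 * x$params$conf_level,
              format_percent(x$ci_low), format_percent(x$ci_high)))
  cat("decision:", x$decision)
  if (x$underpowered)
    cat(sprintf(" (n = %d < %d needed for 80%% power at pa = %g; raw outcome: %s)",
                x$n, x$n_min_power, x$params$pa, x$test_outcome))
  cat("\n\n")
  invisible(x)
}

#' @export
summary.cls_test <- function(object, ...) {
  print(object)
  cat(sprintf("critical value: reject independence when X >= %d (n = %d, p0 = %g, alpha = %g)\n",
              object$critical_value, object$n, object$params$p0,
              object$params$alpha))
  cat(sprintf("achieved alpha at c = %d: %.4g\n", object$critical_value,
              binomial_upper_p(object$critical_value, object$n,
                               object$params$p0)))
  if (!is.null(object$profile)) {
    cat("\n"); print(object$profile)
  }
  invisible(object)
}

#' @export
coef.cls_test <- function(object, ...) {
  c(cls = object$cls)
}

#' @export
confint.cls_test <- function(object, parm = "cls", level = NULL, ...) {
  if (!is.null(level) && level != object$params$conf_level) {
    ci <- 100 * clopper_pearson(object$x, object$n, confidence = level)
  } else {
    ci <- c(low = object$ci_low, high = object$ci_high)
    level <- object$params$conf_level
  }
  m <- matrix(ci, nrow = 1,
              dimnames = list("cls", sprintf("%g %%", 100 * c((1 - level) / 2,
                                                              1 - (1 - level) / 2))))
  m
}
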