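---
title: "The CLS clonality test: model, design and simulation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CLS clonality test: model, design and simulation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clstest)
```

## The problem and the model

Synchronous tumors — for example bilateral breast cancers diagnosed at
the same time — can be two independent primaries or a clonal
primary–metastasis pair, and the distinction matters for prognosis,
familial-risk counselling and therapy. Clonally related tumors descend
from one founding clone and therefore share a large fraction of their
somatic mutations; independent tumors share essentially none beyond
recurrent driver mutations and technical artifacts.

The package quantifies this with the Clonal Likelihood Score. Let $n$
be the total number of distinct genomic loci carrying a high-confidence
(HC) somatic SNV in either tumor of a pair, and $X$ the number of those
loci where the identical mutation is called in both tumors. Then

$$\mathrm{CLS} = 100 \cdot X / n ,$$

and, treating $n$ as fixed, $X \sim \mathrm{Binomial}(n, p)$ with $p$
the per-locus probability of a shared call. Under the null hypothesis
of independent origin $p \le p_0$, where $p_0$ is the largest
shared-call rate plausibly produced between unrelated tumors; under
clonality $p \ge p_a$, the smallest sharing rate expected in clonal
pairs. `cls_test()` performs the one-sided exact binomial test of
$H_0\!: p \le p_0$, rejecting independence when $X$ reaches the exact
critical value $c(n, p_0, \alpha)$ — the smallest integer with
$P(X \ge c) \le \alpha$ — and reports the exact two-sided
Clopper–Pearson interval for the CLS alongside the p-value.

```{r basic}
cls_test(50, 62)   # strong sharing: clonal
cls_test(2, 184)   # background-level sharing: independence stands
```

Key modelling assumptions: loci are exchangeable and shared-call events
independent given $n$ (reasonable for exome-scale SNV sets after
stringent filtering, questionable for small panels with hotspot
enrichment); $n$ is ancillary, so conditioning on it is harmless; and
mutation identity is allele-level — the full (chromosome, position,
reference, alternate) tuple — so two different alternate alleles at one
position are two different mutations. The allele-level convention is
stricter than counting positions and can only reduce spurious sharing.

## Tunable parameters

* `p0` (fraction, default **0.04**). The null shared-call rate.
  Empirical background sharing between unrelated breast tumor exomes is
  at most ~3%, but two samples from one patient sequenced in one batch
  share artifacts at a higher rate, so the default keeps headroom above
  the observed background. Raising `p0` trades type-I error for a
  larger required $n$.
* `pa` (fraction, default **0.15**). The design alternative: a
  conservative lower bound on sharing in truly clonal pairs (observed
  clonal pairs overwhelmingly sit well above 15%). `pa` never changes
  the decision for given data; it only sets the power calculation
  behind the `underpowered` flag.
* `alpha` (default **0.05**) and `conf_level` (default **0.95**): the
  usual exact-test operating point.
* HC filter thresholds (`hc_params()`): germline requires at least 15
  reads with base quality above Q20, at most 1 alternate read, and an
  alternate fraction strictly below 5%; dbSNP members are excluded as
  probable germline variants; both tumors must reach 40x total depth at
  the locus; the locus must be called in at least one tumor. These
  defaults encode the stringent specificity-first filtering the test's
  calibration assumes; loosening them invalidates the default `p0`.

A pair is flagged `underpowered` when $n$ falls below
`min_n_for_power(p0, pa, alpha, 0.80)$n_required` (44 at the default
operating point). The flag is reported *alongside* the raw test
outcome rather than replacing it: a rejection at small $n$ is still a
rejection, but a non-rejection at small $n$ is uninformative.

## Exact design calculations

`critical_value()` uses the $\le \alpha$ boundary convention, the
standard one for exact tests; `exact_power(n, c, pa)` is
$P(X \ge c \mid n, p_a)$. `min_n_for_power()` scans $n$ upward and
returns the **first** $n$ whose own recomputed critical value reaches
the target power. Power as a function of $n$ is a sawtooth — it drops
each time $c$ steps up — so "first $n$ passing" and "smallest $n$
beyond which power never dips" can differ; the first-passing convention
is the one the published design grid uses, and the design row's
contract (achieved $\alpha \le \alpha$, achieved power $\ge$ target,
all smaller $n$ failing) is asserted in the test suite.

```{r design}
design_table(c(0.03, 0.04), c(0.10, 0.15, 0.20))
```

The rejection rule is stated operationally as $X \ge c$. A literal
strict-inequality reading ("CLS > c/n") does not reproduce the
published $(n, c)$ grid — e.g. at $n = 21$, $p_0 = 0.04$ the tail at
$c = 3$ is exactly $0.0497 \le 0.05$ and is meant to be a rejection —
so the $X \ge c$ convention is adopted throughout, and the decision is
dual to comparing the p-value with the achieved alpha of $c$.

## Cohort calibration of `p0`

`summarize_cohort()` implements counterfactual pairing: tumors from
different patients are paired computationally (all cross-patient pairs,
all pairs across two strata, or a random subset), and the CLS of each
pair is aggregated streamingly, so cohorts of $10^4$–$10^5$ pairs run
in constant memory. Because the choice of `p0` from such a summary
should be reproducible rather than judgment-based, the package uses a
fixed rule: `suggested_p0` is the smallest value on the 1%-grid
{3%, 4%, 5%, ...} strictly above the empirical 99.9th percentile
(inverse-ECDF quantile) of pair CLS, floored at 3%. The floor and the
grid step encode the same headroom-above-background reasoning as the
default `p0`; the rule is overridable and the full histogram is
returned for inspection.

## The simulator

`simulate_pair()` draws $n$ from `n_total_range`, marks each locus
truly shared with probability `true_shared_rate`, observes a truly
shared locus as shared only when it is detected in both tumors
(independent Bernoulli `detection_sensitivity_a/_b`), and miscalls an
unshared locus as shared with probability `fp_shared_rate`. A shared
mutation missed in one tumor degrades to a *private* call — it stays in
$n$ — which is the dominant false-negative mode in practice: low tumor
cellularity pushes allelic fractions below the caller's sensitivity in
one sample. The three knobs map one-to-one onto $p_a$, the
cellularity-driven detection loss, and the artifact component of $p_0$.

`estimate_operating_characteristics()` applies the decision rule to
`reps` simulated pairs and returns the rejection fraction with its
binomial Monte-Carlo standard error. All randomness flows from the
single `seed` in `sim_params()`; runs are bit-reproducible.

What the generator deliberately does **not** emulate: read-level noise
(no FASTQ/BAM synthesis), locus-specific mutation rates and hotspot
recurrence, copy-number/LOH structure, subclonal phylogenies, and
correlated artifact structure between samples of one batch. Passing
operating-characteristic tests therefore verifies the *statistical*
machinery under the binomial model the test itself assumes — it does
not validate the HC filter against real sequencing error profiles.

## Numerical choices

* Binomial tails go through `stats::pbinom(..., lower.tail = FALSE)`,
  i.e. the regularized incomplete beta function, stable to far below
  $10^{-15}$; the test suite pins them against an independent log-space
  summation oracle for all $X \le n \le 200$ and against exact-rational
  reference values at selected points.
* Clopper–Pearson bounds use the beta-quantile form, with the exact
  conventions low $= 0$ at $X = 0$ and high $= 1$ at $X = n$.
* Display rounding (reports only; stored values are full precision):
  percentages at or above 2% print to the nearest integer (half away
  from zero), below 2% to one decimal. This reproduces the printed
  forms 81%, 1.1%, "69% to 90%" and "0.1% to 4%" exactly; a 10%
  threshold would print the 3.87% CI bound as "3.9%" rather than the
  conventional "4%".
* p-values below $10^{-15}$ display as `<1e-15`.
* Degenerate inputs: $n = 0$ is a refuse-to-test error (the CLS is
  undefined), surfaced by the CLI as exit code 1; a critical value of
  $n + 1$ marks an unattainable rejection region and yields power 0.

## Problem sizes in the test suite

The suite exercises the oracle sweep at $n \le 200$, the HC-filter
oracle on 1,000 random evidence rows, Clopper–Pearson coverage and the
two operating-characteristic checks at 10,000 replicates each, and
smaller property loops elsewhere; the whole suite runs in well under a
minute. These sizes give Monte-Carlo standard errors of about 0.2–0.4
percentage points on the estimated error rates, small enough to verify
the 5%/80% operating points through three-standard-error bounds.

## Known limitations

* The binomial model ignores inter-locus dependence; recurrent hotspot
  drivers shared by chance are partially absorbed into `p0` but a
  small panel dominated by hotspots would need a recalibrated, larger
  `p0`.
* Calibration transfers only across comparable assays and pipelines: a
  caller with a higher shared-artifact rate than ~4% breaks the
  default null.
* The test is specified for SNVs only; indels and MNVs are excluded on
  input.
* `read_trio_vcfs()` expects single-sample VCFs with `DP`/`AD`
  genotype fields; high-quality depth travels in a custom `HQ` FORMAT
  field and falls back to total depth (with a message) when absent,
  which weakens the germline-coverage filter accordingly.
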