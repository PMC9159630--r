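---
title: "Methods behind fragtools: fragility of binary-outcome clinical results"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind fragtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragtools)
```

## The fragility index and quotient

A two-group trial with a binary outcome is a 2x2 table: event counts
$e_0, e_1$ and sample sizes $n_0, n_1$.  An *event-status modification*
$(f_0, f_1)$ turns $f_k$ non-events into events in group $k$ (negative
values turn events back), leaving $n_k$ fixed, with
$-e_k \le f_k \le n_k - e_k$.  Writing $p(f_0, f_1)$ for the p-value of
the modified table, the fragility index at significance level $\alpha$ is

$$\mathrm{FI} = \min_{p(f_0,f_1) \ge \alpha} \{|f_0| + |f_1|\}$$

when the original result is significant ($p(0,0) < \alpha$), and the
analogous minimum over $p(f_0,f_1) < \alpha$ otherwise.  Significance is
strict: $p = \alpha$ counts as non-significant.  Restricting the search to
one group gives $\mathrm{FI}_0$ and $\mathrm{FI}_1$, and
$1 \le \mathrm{FI} \le \min\{\mathrm{FI}_0, \mathrm{FI}_1\}$ whenever all
are defined.  If no legal modification alters significance the FI is `NA`
— common for small tables, whose most extreme attainable p-value may still
exceed $\alpha$.  The fragility quotient
$\mathrm{FQ} = \mathrm{FI}/(n_0+n_1) \times 100\%$ makes studies of
different size comparable.

Five association methods are supported: Fisher's exact test (two-sided
conditional p by the probability-mass rule, i.e. the sum of hypergeometric
probabilities of all tables no more probable than the observed one — the
convention of `stats::fisher.test`), the Pearson chi-squared test, and
Wald tests of the log odds ratio, log relative risk and risk difference
with their standard large-sample standard errors.  When an OR/RR/RD table
contains a zero cell, 0.5 is added to **all four cells** of that table
(only), re-evaluated after every modification; Fisher and chi-squared
tests never use the correction.  Users should pre-specify one method; the
package computes several only to show how the choice affects the FI.

Two deliberately open choices are fixed as follows:

* **Yates correction.** The chi-squared test applies the Yates continuity
  correction by default, matching the 2x2 default of
  `stats::chisq.test`; `yates = FALSE` disables it.
* **One-sided Wald p.** The one-sided p is $\Phi(-|y - \theta_0|/s)$,
  always the tail on the side of the observed deviation, hence exactly
  half the two-sided p.  It is *not* a directional test with a
  pre-specified sign; the documentation flags this.

## Search strategies for a single study

`frag_study(all = FALSE)` walks "shells" of constant total modification
$m = |f_0| + |f_1| = 1, 2, \dots$ and stops at the first shell containing
a significance flip; this returns the exact FI and *all* minimal
modification sets (enumerated in deterministic order: $f_0$ ascending,
then $f_1$) without touching the rest of the landscape.
`all = TRUE` evaluates every legal cell — up to
$(n_0 + 1)(n_1 + 1)$ of them — retains the p-value grid for plotting, and
refuses grids above `cell_cap` ($10^6$ cells by default; a study with
1000 participants per arm reaches that order).  The full Fisher landscape
is computed margin-total by margin-total with a sort/cumsum pass, so the
exhaustive grid costs $O((n_0+n_1)\, \min(n_0,n_1) \log n)$ rather than
one hypergeometric enumeration per cell.

Both routes are tested against each other on hundreds of random tables,
and against a brute-force enumeration oracle built on
`stats::fisher.test` / `chisq.test`.

### Significance-level sweeps

FI$(\alpha)$ is a step function; `frag_study_alpha` evaluates it on an
equally spaced grid (defaults $[0.005, 0.05]$, $B = 100$ levels) and
reports the arithmetic mean of the defined values, a discrete
approximation of the normalised area under FI$(\alpha)$.  The sweep
reuses work across levels: each shell is evaluated once, and only its
minimum and maximum p decide, for every level simultaneously, whether the
shell flips significance.  Levels whose FI is `NA` are excluded from the
average and counted separately (`n.NA`); the grid averages only what is
defined rather than imputing a value the data cannot produce.  The
direction label is re-derived at every level from $p(0,0)$ versus
$\alpha_b$, so a sweep that straddles the original p-value changes
colour, not meaning.

## Pairwise meta-analysis

Study effects $y_i$ (log OR by default) with within-study variances
$s_i^2$ are pooled by inverse-variance weights
$w_i = 1/(s_i^2 + \hat\tau^2)$:
$\hat\theta = \sum w_i y_i / \sum w_i$.  The between-study variance is
estimated by DerSimonian–Laird (default), REML (fixed-point iteration,
tolerance $10^{-8}$, at most 100 steps, falling back to DL with a warning
on non-convergence), or forced to zero for a fixed-effect fit; the
truncation of negative moment estimates at zero is explicit.  Confidence
intervals are the conventional normal interval
$\hat\theta \pm z_{1-\alpha/2}\,(\sum w_i)^{-1/2}$ or the
Hartung–Knapp–Sidik–Jonkman interval with the $t_{N-1}$ quantile and the
weighted residual scale, used exactly as written, without the truncation
variant some software applies.  The engine reproduces
`metafor::rma.uni` (methods `DL`/`REML`, tests `z`/`knha`) to $10^{-6}$
on randomized datasets in the test suite.

Per-study continuity correction (0.5 to all four cells of studies with a
zero cell only) mirrors standard meta-analytic practice; double-zero
studies are retained with correction in pairwise MAs.

### The greedy CI-driven search

Exhaustive search over modification sequences is exponential
($(2N)^{\mathrm{FI}}$ fits), so the FI of an MA is derived by the greedy
iterative algorithm: at each step, every feasible single-event change
(one event removed from group 1 or added to group 0 of one study, for a
leftward target; at most $2N$ candidates) is applied, the whole MA is
refitted — $\hat\tau^2$ re-estimated every time, since each candidate is
a genuinely different meta-analysis — and the candidate moving the
relevant CI bound furthest in the target direction is kept (target left:
smallest lower bound; target right: largest upper bound).  Iteration
stops when the CI's significance state flips, so at most
$2N \times \mathrm{FI}$ fits are performed per direction; the suite
asserts this bound on every run.  Significance is judged by the CI
covering the null, which for the normal interval is equivalent to the
Wald p-value test.

For an originally non-significant MA the CI can leave the null on either
side; `mod.dir` selects left, right, the side of the point estimate
(`"one"`, defaulting to the right with a warning when the estimate equals
the null exactly), or both (`"both"`, the default), in which case the two
directional searches run independently from the original data and the
smaller FI is reported.

Details the algorithm definition leaves open are fixed
deterministically: ties between candidates with equal bounds are broken
by lowest study id, then the group-1 move before the group-0 move; and a
per-direction iteration cap equal to the total sample size guarantees
termination (`FI = NA` with a diagnostic when reached).  The greedy
search is a heuristic upper bound on the true minimum; on tiny instances
($N \le 3$, arms of at most 6) the suite compares it against a
brute-force search over all modification vectors and asserts
greedy $\ge$ optimum.

## Network meta-analysis

The frequentist contrast-based model is solved by the graph-theoretical
route: each study contributes its within-study contrasts, whose
information matrix in arm space is a Laplacian; summing study Laplacians
over the treatment graph and taking the Moore–Penrose inverse yields all
$K(K-1)/2$ comparisons and their variances at once, independent of any
reference-treatment choice.  For a $p$-arm study the contrast covariance
is built from additive per-arm variance components (for log OR:
$u_a = 1/e_a + 1/(n_a - e_a)$, with the shared-arm component as
covariance); inverting it and expanding to arm space *is* the multi-arm
variance adjustment — the adjusted per-contrast variances reported by
`arms_to_contrasts` inflate the naive ones exactly so that weighted least
squares over the redundant contrasts carries the information of the joint
model.  A single shared $\tau^2$ is estimated by the generalised
method-of-moments (DerSimonian–Laird-type) estimator
$\hat\tau^2 = \max\{0, (Q - \mathrm{df})/\mathrm{tr}(P\Delta)\}$ on the
stacked baseline contrasts, where $\Delta$ encodes the heterogeneity
structure (variance $\tau^2$ per contrast, covariance $\tau^2/2$ for
contrasts sharing the baseline arm); in a two-treatment network this
reduces algebraically to the pairwise DL estimator, and the tests assert
the reduction to $10^{-8}$.  The engine is validated against an
independently coded per-study GLS fit (explicit block covariance
matrices, reference-treatment parameterisation) on the packaged COPD
network and on random networks.

Zero-cell handling mirrors arm-level conventions: by default 0.5 is
added to the cells of every arm of a study containing a zero cell;
`allincr` extends the correction to all studies as soon as one needs it,
`addincr` applies it unconditionally, and studies carrying no
information for a ratio measure (all arms zero, or all arms full) are
dropped unless `allstudies = TRUE`.

### Per-comparison fragility

The FI of a network is defined per comparison.  For treatments $t_1$ vs
$t_2$, candidate modifications are restricted to arms of those two
treatments in any study containing them — modifications elsewhere could
in principle flip the comparison too, but the two-arm restriction keeps
the search tractable and interpretable, and an `NA` FI must be read
against it.  After each candidate single-event change the *entire
network* is refitted ($\hat\tau^2$ included).  Tie-breaking follows the
pairwise rule: lowest study id, then the arm of the first-named
treatment.  Two fragility quotients are reported: dividing by $n_{AB}$
(the sample size of the two compared arms across studies) keeps the
quotient in $(0, 100]$ and comparable across pairs, while dividing by the
network total $n_{\mathrm{NMA}}$ is bounded above by
$n_{AB}/n_{\mathrm{NMA}}$ and differs structurally between pairs.
Because every level of a significance sweep repeats the whole greedy
search for every comparison, `frag_nma_alpha` defaults to a coarse grid
of 10 levels.

## Synthetic data

The generators emulate the three dataset schemas under the
binomial-normal model the analyses assume: per-study true log odds
ratios $\theta_i \sim N(\theta, \tau^2)$, uniform baseline risks, and
binomial arm events.  Network data draw independent $N(0, \tau^2/2)$
arm-level log-odds perturbations, giving each within-study contrast
heterogeneity variance $\tau^2$ with the shared-arm covariance
$\tau^2/2$ the model posits.  Defaults (arm sizes 20–200, baseline risks
0.1–0.4, $\tau^2$ around 0.05–0.1) reflect typical trial collections in
the applied literature.  The generators match the analysis model by
construction, so passing recovery tests demonstrates internal
correctness, not robustness to the misspecifications of real data:
non-normal heterogeneity, correlated or overlapping studies,
publication bias and outcome misclassification are all absent.

## Numerical conventions and test scales

* P-values are never rounded internally; printing rounds to 3 decimals.
* Fisher's probability-mass rule uses the same $1 + 10^{-7}$ relative
  tolerance as `stats::fisher.test`, and sums are clamped at 1.
* Degenerate margins: Fisher p is 1; the chi-squared p is 1 with a
  warning.
* All reported minimal modification sets are sorted ($f_0$, then $f_1$);
  all search and tie-break orders are deterministic, so identical inputs
  give byte-identical results.
* Landscape plots truncate p-values below $10^{-10}$ (plus signs) and map
  colour opacity linearly in $-\log_{10} p$ between the significance
  level and the truncation point; red marks significant, green
  non-significant results, with an orange/blue colour-vision-safe
  palette behind `palette = "colorblind"`.

The test suite sizes randomized checks to run comfortably on one CPU:
300 tables (arms up to 30) for search-vs-exhaustive equivalence, 50
tables for sweep monotonicity, 50 synthetic MAs for the greedy work
bound and replay, 30 tiny MAs against the brute-force optimum, 20
two-treatment networks for the pairwise reduction, 50 datasets against
`metafor`, and 500 replicates at $N = 30$ for parameter recovery.

## Known limitations

* The greedy MA/NMA search can overestimate the true minimal FI; the
  exhaustive optimum is only computed as a test oracle at toy scale.
* Only binary outcomes are covered — no survival, continuous or
  regression-adjusted fragility.
* The NMA layer is frequentist only, with a single shared $\tau^2$;
  Bayesian refits inside the iterative search would be impractically
  slow.
* The full-scale clinical datasets behind the packaged printed excerpts
  are not redistributed; `scripts/fetch-external-data.R` documents how to
  obtain them, and the corresponding reproduction test runs only when
  they are present.
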