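# fragtools

Statistical significance in clinical research can hinge on astonishingly
few patients: if reclassifying a single participant's outcome (event to
non-event or back) flips a trial from "significant" to "not", the finding
is fragile no matter how small its p-value looks.  **fragtools**
quantifies this for binary-outcome results with the **fragility index
(FI)** — the minimal number of event-status modifications that alters
statistical significance — and the **fragility quotient (FQ)**, the FI as
a percentage of the sample size.  It is aimed at clinicians,
methodologists and systematic reviewers who want to report fragility
alongside p-values and confidence intervals.

Three layers are covered:

* **Individual 2x2 trials** — for a table with events/sizes
  $e_0/n_0, e_1/n_1$ and modifications $(f_0, f_1)$,
  $\mathrm{FI} = \min_{p(f_0,f_1) \ge \alpha}\{|f_0|+|f_1|\}$ for an
  originally significant result (the mirrored minimum over
  $p < \alpha$ otherwise), under Fisher's exact test, the chi-squared
  test, or Wald tests of the OR, RR or RD.  Group-restricted indices
  FI0/FI1, all minimal modification sets, exhaustive p-value landscapes,
  significance-level sweeps with the average FI, and batch summaries are
  included.
* **Pairwise meta-analyses** — inverse-variance pooling with
  DerSimonian–Laird or REML heterogeneity and normal or
  Hartung–Knapp–Sidik–Jonkman intervals; the FI is found by the greedy
  CI-driven algorithm that tries every single-event modification (at most
  $2N$ per step), keeps the one moving the interval furthest toward the
  flip, and refits the whole MA — at most $2N \times \mathrm{FI}$ fits.
* **Network meta-analyses** — frequentist contrast-based NMA solved on
  the treatment graph (Laplacian pseudo-inverse, multi-arm variance
  adjustment, generalised method-of-moments $\tau^2$); fragility is
  assessed per comparison with modifications restricted to the two
  compared treatments' arms.

Plot methods draw the significance landscape of a study, FI versus
significance level (step plots), the modification trajectory of a
meta-analysis search, and FI/FQ distributions across many datasets, using
the red (significant) / green (non-significant) convention with opacity
proportional to $-\log_{10} p$.

## Worked example

The package ships small plain-text datasets (`frag_example()`), including
the printed six-trial excerpt of a large antidepressant-acceptability
collection and a complete 3-study, 4-treatment COPD network.

```r
library(fragtools)
ad <- read_trials(frag_example("dat_ad_head.csv"))
frag_study(data = ad[1, ])
#> Fragility of an individual study
#>   group 0: 7/107 events; group 1: 12/105 events
#>   modification ranges: f0 in [-7, 100], f1 in [-12, 93]
#>   significance level: 0.05
#>
#>   p-values:
#> Fisher  chisq     OR     RR     RD
#>  0.238  0.315  0.218  0.220  0.212
#>
#>   fragility index (direction):
#>     Fisher FI = 3    FQ = 1.415%  [nonsig2sig]
#>     chisq  FI = 4    FQ = 1.887%  [nonsig2sig]
#>     OR     FI = 3    FQ = 1.415%  [nonsig2sig]
#>     RR     FI = 3    FQ = 1.415%  [nonsig2sig]
#>     RD     FI = 3    FQ = 1.415%  [nonsig2sig]
```

This trial (7/107 vs 12/105 events) is non-significant under all five
methods at $\alpha = 0.05$; reclassifying just 3 participants (4 under
the chi-squared test) would make it *significant* — about 1.4% of the 212
participants, so the non-significance itself is fragile.

The same assessment for every comparison of the COPD network:

```r
copd <- read_nma(frag_example("dat_copd.csv"))
frag_nma(data = copd, random = TRUE)
#> Fragility of a network meta-analysis: 4 treatments, 3 studies (OR, random effects)
#>   alpha = 0.05, tau^2 = 0
#>
#>   fragility index (row vs column):
#>    1  2  3  4
#> 1 NA  5  3  4
#> 2  5 NA  7  7
#> 3  3  7 NA  9
#> 4  4  7  9 NA
```

Salmeterol vs placebo (3 vs 1) needs only 3 modifications to become
significant, the most fragile comparison in this sparse network.  The
per-comparison trajectories (`plot(out, tid1 = 3, tid2 = 1)`) show which
studies and arms drive each flip.

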