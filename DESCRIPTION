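Package: fragtools
Title: Fragility of Clinical Results with Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses and visualizes the fragility of statistical significance
    in clinical results with binary outcomes. Computes the fragility index
    (the minimal number of event-status modifications that alters statistical
    significance) and fragility quotient for individual 2x2 trials, for
    pairwise meta-analyses via a greedy confidence-interval-driven search, and
    for frequentist network meta-analyses with modifications restricted to the
    two compared treatments. Supports Fisher's exact test, the chi-squared
    test, and Wald tests on the odds ratio, relative risk and risk difference;
    DerSimonian-Laird and REML heterogeneity estimation with normal or
    Hartung-Knapp-Sidik-Jonkman intervals; significance-level sweeps with
    averaged fragility; batch assessment of many studies or meta-analyses; and
    plots of the modification landscape, search trajectories and fragility
    distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, grDevices, utils
Suggests: testthat (>= 3.0.0), metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
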