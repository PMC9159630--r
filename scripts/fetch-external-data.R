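#!/usr/bin/env Rscript

## The full datasets behind the published worked examples -- 347
## antidepressant trials, 564 nutrition-support meta-analyses, and the
## 24-study smoking-cessation network -- are distributed with the CRAN
## package "fragility" and are not redistributed here.  Run this script on
## a machine with network access to extract them as CSV; copy the three
## files into inst/extdata/external/ (or <installed pkg>/extdata/external/)
## to enable the full-scale reproduction test in
## tests/testthat/test-acceptance.R.

dest <- file.path("inst", "extdata", "external")
dir.create(dest, recursive = TRUE, showWarnings = FALSE)

if (!requireNamespace("fragility", quietly = TRUE))
  install.packages("fragility")

data("dat.ad", "dat.ns", "dat.sc", package = "fragility",
     envir = environment())
write.csv(dat.ad, file.path(dest, "dat_ad.csv"), row.names = FALSE)
write.csv(dat.ns, file.path(dest, "dat_ns.csv"), row.names = FALSE)
names(dat.sc) <- c("sid", "tid", "e", "n")[seq_along(names(dat.sc))]
write.csv(dat.sc, file.path(dest, "dat_sc.csv"), row.names = FALSE)
cat("wrote dat_ad.csv, dat_ns.csv, dat_sc.csv to", dest, "\n")
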