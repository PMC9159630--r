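test_that("small-table fragility matches full enumeration", {
  ## (0,3,3,3): the most extreme table has two-sided Fisher p = 0.1, so at
  ## alpha = 0.05 no modification can reach significance
  x <- frag_study(0, 3, 3, 3, methods = "fisher", alpha = 0.05)
  expect_equal(unname(x$p0), 0.1)
  expect_true(is.na(x$FI))
  expect_true(is.na(x$FQ))
  ## at alpha = 0.11 the original is significant and one change loses it
  x2 <- frag_study(0, 3, 3, 3, methods = "fisher", alpha = 0.11)
  expect_equal(unname(x2$FI), 1)
  expect_equal(unname(x2$dir), "sig2nonsig")
  orc <- oracle_fi_enum(0, 3, 3, 3, "fisher", 0.11)
  expect_equal(unname(x2$FI), orc$FI)
})

test_that("shell search and exhaustive landscape agree on random tables", {
  set.seed(101)
  for (i in 1:25) {
    tb <- rand_table(15)
    alpha <- sample(c(0.01, 0.05, 0.2), 1)
    xs <- frag_study(tb$e0, tb$n0, tb$e1, tb$n1, alpha = alpha)
    xe <- frag_study(tb$e0, tb$n0, tb$e1, tb$n1, alpha = alpha, all = TRUE)
    expect_equal(xs$FI, xe$FI)
    expect_equal(xs$dir, xe$dir)
    for (m in names(xs$FI)) {
      expect_equal(xs$mods[[m]], xe$mods[[m]])
      ## bound 1 <= FI <= min(FI0, FI1) whenever defined
      if (!is.na(xe$FI[m])) {
        expect_gte(xe$FI[m], 1)
        if (!is.na(xe$FI0[m]) && !is.na(xe$FI1[m]))
          expect_lte(xe$FI[m], min(xe$FI0[m], xe$FI1[m]))
      }
    }
  }
})

test_that("every minimal modification flips significance and none smaller does",
{
  set.seed(202)
  for (i in 1:10) {
    tb <- rand_table(12)
    x <- frag_study(tb$e0, tb$n0, tb$e1, tb$n1, methods = "fisher",
                    alpha = 0.05, all = TRUE)
    m <- "Fisher"
    if (is.na(x$FI[m])) next
    sig0 <- x$p0[m] < x$alpha
    for (r in seq_len(nrow(x$mods[[m]]))) {
      expect_equal(sum(abs(x$mods[[m]][r, ])), unname(x$FI[m]))
      p <- p_value(apply_modification(x$table, x$mods[[m]][r, 1],
                                      x$mods[[m]][r, 2]), "fisher")
      expect_true(if (sig0) p >= x$alpha else p < x$alpha)
    }
    ## enumeration cross-check against the independent oracle
    orc <- oracle_fi_enum(tb$e0, tb$n0, tb$e1, tb$n1, "fisher", 0.05)
    expect_equal(unname(x$FI[m]), orc$FI)
  }
})

test_that("modification constraints restrict the search space", {
  x <- frag_study(7, 107, 12, 105, methods = "fisher",
                  modify0 = "none", modify1 = "none")
  expect_true(is.na(x$FI))
  x2 <- frag_study(7, 107, 12, 105, methods = "fisher",
                   modify0 = "increase", modify1 = "none", all = TRUE)
  if (!is.na(x2$FI)) expect_true(all(x2$mods[["Fisher"]][, 1] >= 0))
  expect_equal(x2$f0.range[1], 0)
  expect_equal(x2$f1.range, c(0, 0))
  ## decrease-only range is clipped at -e
  x3 <- frag_study(2, 30, 5, 30, methods = "fisher", modify0 = "decrease")
  expect_equal(x3$f0.range, c(-2, 0))
})

test_that("restricted indices agree with 1-D scans of the landscape", {
  set.seed(303)
  for (i in 1:8) {
    tb <- rand_table(15)
    x <- frag_study(tb$e0, tb$n0, tb$e1, tb$n1, methods = "fisher",
                    all = TRUE)
    grid <- x$p_grid[["Fisher"]]
    sig0 <- x$p0[["Fisher"]] < x$alpha
    row0 <- grid[, colnames(grid) == "0"]
    f0 <- as.integer(rownames(grid))
    flip <- if (sig0) row0 >= x$alpha else row0 < x$alpha
    flip <- flip & f0 != 0
    expct <- if (any(flip)) min(abs(f0[flip])) else NA_integer_
    expect_equal(unname(x$FI0[["Fisher"]]), expct)
    tab <- frag_table(tb$e0, tb$n0, tb$e1, tb$n1)
    expect_equal(fi_restricted(tab, 0), unname(x$FI0[["Fisher"]]))
    expect_equal(fi_restricted(tab, 1), unname(x$FI1[["Fisher"]]))
  }
})

test_that("fragility quotient scales the FI by the total sample size", {
  expect_equal(fq(5, 500), 1)
  expect_true(is.na(fq(NA, 100)))
  expect_equal(fq(14, 14000), 0.1)
  x <- frag_study(1, 20, 12, 20, methods = "fisher")
  if (!is.na(x$FI[1]))
    expect_equal(unname(x$FQ[1]), unname(x$FI[1]) / 40 * 100)
})

test_that("batch assessment reproduces per-study results and summaries", {
  d <- read_trials(frag_example("dat_ad_head.csv"))
  b <- frag_studies(data = d, methods = c("fisher", "OR"))
  expect_equal(nrow(b$FI), 6)
  for (i in 1:6) {
    xi <- frag_study(d$e0[i], d$n0[i], d$e1[i], d$n1[i],
                     methods = c("fisher", "OR"))
    expect_equal(b$FI[i, ], xi$FI)
    expect_equal(b$dir[i, ], xi$dir)
  }
  ## a batch of one study summarises to that study
  b1 <- frag_studies(e0 = d$e0[1], n0 = d$n0[1], e1 = d$e1[1],
                     n1 = d$n1[1], methods = "fisher")
  s <- b1$summary[["Fisher"]][[b1$dir[1, 1]]]
  expect_equal(s$n, 1)
  expect_equal(s$FI.median, unname(b1$FI[1, 1]))
  ## FQ values lie in (0, 100] wherever the FI is defined
  ok <- !is.na(b$FQ)
  expect_true(all(b$FQ[ok] > 0 & b$FQ[ok] <= 100))
})
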