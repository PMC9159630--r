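test_that("event-status modifications respect table bounds", {
  t1 <- frag_table(7, 107, 12, 105)
  expect_identical(apply_modification(t1, 0, 0), t1)
  t2 <- apply_modification(t1, 6, 0)
  expect_equal(c(t2$e0, t2$n0, t2$e1, t2$n1), c(13, 107, 12, 105))
  expect_error(apply_modification(frag_table(0, 10, 5, 10), -1, 0),
               "group 0")
  expect_error(apply_modification(frag_table(0, 10, 5, 10), 0, 6),
               "group 1")
  expect_error(frag_table(5, 4, 0, 3))
  expect_error(frag_table(-1, 4, 0, 3))
})

test_that("continuity correction fires only on zero cells and hits all four",
{
  cc <- continuity_correct(frag_table(0, 10, 5, 10))
  expect_true(cc$corrected)
  expect_equal(c(cc$e0, cc$n0 - cc$e0, cc$e1, cc$n1 - cc$e1),
               c(0.5, 10.5, 5.5, 5.5))
  cc2 <- continuity_correct(frag_table(3, 24, 4, 20))
  expect_false(cc2$corrected)
  expect_equal(c(cc2$e0, cc2$n0, cc2$e1, cc2$n1), c(3, 24, 4, 20))
  cc3 <- continuity_correct(frag_table(0, 3, 3, 3))
  expect_equal(c(cc3$e0, cc3$n0 - cc3$e0, cc3$e1, cc3$n1 - cc3$e1),
               c(0.5, 3.5, 3.5, 0.5))
})

test_that("Fisher exact p matches enumeration and stats::fisher.test", {
  expect_equal(fisher_p(frag_table(5, 10, 5, 10)), 1)
  expect_equal(fisher_p(frag_table(0, 3, 3, 3)), 0.1)
  expect_equal(fisher_p(frag_table(7, 107, 12, 105)),
               oracle_fisher_p(7, 107, 12, 105), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:60) {
    tb <- rand_table(25)
    p <- fisher_p(frag_table(tb$e0, tb$n0, tb$e1, tb$n1))
    expect_gt(p, 0); expect_lte(p, 1)
    expect_equal(p, oracle_fisher_p(tb$e0, tb$n0, tb$e1, tb$n1),
                 tolerance = 1e-12)
    expect_equal(p, oracle_p(tb$e0, tb$n0, tb$e1, tb$n1, "fisher"),
                 tolerance = 1e-12)
    ## swap invariance
    expect_equal(p, fisher_p(frag_table(tb$e1, tb$n1, tb$e0, tb$n0)),
                 tolerance = 1e-12)
  }
})

test_that("the full Fisher p landscape matrix agrees with the scalar route",
{
  M <- fragtools:::.fisher_p_matrix(12, 9)
  for (a0 in c(0, 3, 7, 12)) for (a1 in c(0, 2, 9))
    expect_equal(M[a0 + 1, a1 + 1],
                 fisher_p(frag_table(a0, 12, a1, 9)), tolerance = 1e-12)
})

test_that("chi-squared p mirrors stats::chisq.test with and without Yates",
{
  expect_equal(chisq_p(frag_table(5, 10, 5, 10)), 1)
  expect_equal(chisq_p(frag_table(30, 252, 49, 263), yates = FALSE),
               oracle_p(30, 252, 49, 263, "chisq", yates = FALSE),
               tolerance = 1e-10)
  expect_gt(chisq_p(frag_table(30, 252, 49, 263), yates = TRUE),
            chisq_p(frag_table(30, 252, 49, 263), yates = FALSE))
  expect_warning(p <- chisq_p(frag_table(0, 5, 0, 7)), "degenerate")
  expect_equal(p, 1)
  set.seed(22)
  for (i in 1:40) {
    tb <- rand_table(40)
    if (tb$e0 + tb$e1 == 0 || tb$e0 + tb$e1 == tb$n0 + tb$n1) next
    for (yates in c(TRUE, FALSE))
      expect_equal(chisq_p(frag_table(tb$e0, tb$n0, tb$e1, tb$n1), yates),
                   oracle_p(tb$e0, tb$n0, tb$e1, tb$n1, "chisq", yates),
                   tolerance = 1e-10)
  }
})

test_that("effect estimates follow the printed formulas", {
  est <- effect_estimate(frag_table(5, 10, 5, 10), "OR")
  expect_equal(est$y, 0)
  expect_equal(est$se, sqrt(0.8))
  est2 <- effect_estimate(frag_table(7, 107, 12, 105), "OR")
  expect_equal(est2$y, 0.6115672, tolerance = 1e-6)
  expect_equal(est2$se, 0.4969338, tolerance = 1e-6)
  est3 <- effect_estimate(frag_table(7, 107, 12, 105), "RD")
  expect_equal(est3$y, 0.04886515, tolerance = 1e-6)
  expect_equal(est3$se, 0.03918483, tolerance = 1e-6)
  ## zero cells never yield infinite estimates
  for (tb in list(c(0, 10, 5, 10), c(0, 3, 3, 3), c(2, 2, 0, 5)))
    for (ms in c("OR", "RR", "RD")) {
      e <- effect_estimate(frag_table(tb[1], tb[2], tb[3], tb[4]), ms)
      expect_true(is.finite(e$y) && is.finite(e$se) && e$se > 0)
      expect_true(e$corrected)
    }
})

test_that("Wald p-values behave as 2*Phi(-|z|) and its one-sided half", {
  est <- effect_estimate(frag_table(5, 10, 5, 10), "OR")
  expect_equal(wald_p(est, 0, "two.sided"), 1)
  est2 <- effect_estimate(frag_table(7, 107, 12, 105), "OR")
  expect_equal(wald_p(est2, 0, "two.sided"), 0.218442, tolerance = 1e-5)
  set.seed(33)
  for (i in 1:20) {
    tb <- rand_table(30)
    for (ms in c("OR", "RR", "RD")) {
      e <- effect_estimate(frag_table(tb$e0, tb$n0, tb$e1, tb$n1), ms)
      expect_equal(wald_p(e, 0, "two.sided"), 2 * wald_p(e, 0, "one.sided"))
    }
  }
})

test_that("p_value dispatches to the right engine and rejects unknowns", {
  t1 <- frag_table(5, 10, 5, 10)
  expect_equal(p_value(t1, "fisher"), 1)
  expect_equal(p_value(t1, "OR"), 1)
  expect_error(p_value(t1, "barnard"), "unknown method")
  ## RD on a zero-cell table uses the corrected cells
  p <- p_value(frag_table(0, 10, 5, 10), "RD")
  y <- 5.5 / 11 - 0.5 / 11
  s <- sqrt(0.5 * 10.5 / 11^3 + 5.5 * 5.5 / 11^3)
  expect_equal(p, 2 * pnorm(-y / s), tolerance = 1e-12)
  ## two-sided Wald p is invariant to swapping the groups
  p_ab <- p_value(frag_table(3, 20, 9, 25), "OR")
  p_ba <- p_value(frag_table(9, 25, 3, 20), "OR")
  expect_equal(p_ab, p_ba, tolerance = 1e-12)
})
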