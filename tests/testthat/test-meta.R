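test_that("pooling closed forms hold for equal studies", {
  f <- ma_pool(c(0.5, 0.5), c(0.2, 0.2), tau2 = 0, alpha = 0.05, "z")
  expect_equal(f$theta, 0.5)
  expect_equal(f$ci.lb, 0.5 - qnorm(0.975) * 0.2 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(f$ci.ub, 0.5 + qnorm(0.975) * 0.2 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(round(c(f$ci.lb, f$ci.ub), 4), c(0.2228, 0.7772))
  ## homogeneous effects give a zero-width HKSJ interval
  h <- ma_pool(rep(0.3, 4), c(0.1, 0.2, 0.3, 0.4), tau2 = 0,
               ci_method = "hksj")
  expect_equal(h$ci.lb, h$ci.ub)
  expect_equal(h$theta, 0.3)
  expect_error(ma_pool(0.5, 0.2, ci_method = "hksj"), "two studies")
})

test_that("DerSimonian-Laird estimator follows the moment formula", {
  expect_equal(tau2_dl(c(0.5, 0.5), c(0.2, 0.2)), 0)
  ## hand evaluation: w = 4, Q = 8, C = 8 - 32/8 = 4, tau2 = (8 - 1)/4
  expect_equal(tau2_dl(c(0, 2), c(0.5, 0.5)), 1.75)
  expect_equal(tau2_dl(0.3, 0.1), 0)
  expect_gte(tau2_dl(rnorm(5), runif(5, 0.1, 1)), 0)
})

test_that("REML estimator recovers heterogeneity and stays non-negative", {
  expect_equal(tau2_reml(rep(0.2, 5), rep(0.3, 5)), 0)
  set.seed(606)
  ## parameter recovery at scale: mean REML estimate near the truth
  est <- replicate(120, {
    y <- rnorm(30, 0, sqrt(0.25 + 0.1^2))
    tau2_reml(y, rep(0.1, 30))
  })
  expect_equal(mean(est), 0.25, tolerance = 0.05)
  expect_true(all(est >= 0))
})

test_that("the engine reproduces the reference implementation", {
  skip_if_not_installed("metafor")
  set.seed(707)
  for (i in 1:12) {
    d <- gen_ma(N = sample(3:12, 1), theta = runif(1, -1, 1),
                tau2 = runif(1, 0, 0.3), seed = NULL)
    es <- metafor::escalc(measure = "OR", ai = d$e1, n1i = d$n1,
                          ci = d$e0, n2i = d$n0)
    f <- ma_fit(d$e0, d$n0, d$e1, d$n1, tau2_method = "DL")
    r <- metafor::rma(yi, vi, data = es, method = "DL", test = "z")
    expect_equal(f$theta, as.numeric(r$b), tolerance = 1e-8)
    expect_equal(f$ci.lb, r$ci.lb, tolerance = 1e-8)
    expect_equal(f$ci.ub, r$ci.ub, tolerance = 1e-8)
    expect_equal(f$tau2, r$tau2, tolerance = 1e-8)
    fh <- ma_fit(d$e0, d$n0, d$e1, d$n1, tau2_method = "DL",
                 ci_method = "hksj")
    rh <- metafor::rma(yi, vi, data = es, method = "DL", test = "knha")
    expect_equal(fh$ci.lb, rh$ci.lb, tolerance = 1e-8)
    expect_equal(fh$ci.ub, rh$ci.ub, tolerance = 1e-8)
    fr <- ma_fit(d$e0, d$n0, d$e1, d$n1, tau2_method = "REML")
    rr <- metafor::rma(yi, vi, data = es, method = "REML")
    expect_equal(fr$tau2, rr$tau2, tolerance = 1e-4)
  }
})

test_that("per-study effects apply the correction study by study", {
  d <- read_ma(frag_example("dat_ns_head.csv"))
  eff <- study_effects(d$e0, d$n0, d$e1, d$n1, "OR")
  expect_false(any(eff$corrected[-3]))
  expect_true(eff$corrected[3])   # (2, 28, 0, 22) has a zero cell
  expect_equal(eff$y[3], log((0.5 / 22.5) / (2.5 / 26.5)),
               tolerance = 1e-12)
  expect_equal(eff$s[3], sqrt(1 / 2.5 + 1 / 26.5 + 1 / 0.5 + 1 / 22.5),
               tolerance = 1e-12)
  expect_equal(eff$y[1], log((4 / 16) / (3 / 21)), tolerance = 1e-12)
})

test_that("composite fit honours the model settings", {
  d <- gen_ma(N = 6, theta = 0.5, tau2 = 0.3, seed = 8)
  fe <- ma_fit(d$e0, d$n0, d$e1, d$n1, tau2_method = "FE")
  re <- ma_fit(d$e0, d$n0, d$e1, d$n1, tau2_method = "DL")
  expect_equal(fe$tau2, 0)
  if (re$tau2 > 0)
    expect_lt(fe$ci.ub - fe$ci.lb, re$ci.ub - re$ci.lb)
  ## single study: pooled estimate is the study estimate
  f1 <- ma_fit(d$e0[1], d$n0[1], d$e1[1], d$n1[1])
  eff <- study_effects(d$e0[1], d$n0[1], d$e1[1], d$n1[1], "OR")
  expect_equal(f1$theta, eff$y)
  expect_equal(f1$ci.lb, eff$y - qnorm(0.975) * eff$s)
  ## the pooled estimate is a convex combination of study effects
  eff_all <- study_effects(d$e0, d$n0, d$e1, d$n1, "OR")
  expect_gte(re$theta, min(eff_all$y))
  expect_lte(re$theta, max(eff_all$y))
  expect_equal(sum(re$weights), 1)
})
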