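test_that("long-format validation catches malformed networks", {
  expect_error(nma_fit(sid = c(1, 1), tid = c(1, 1), e = c(1, 2),
                       n = c(10, 10)), "duplicated")
  expect_error(nma_fit(sid = c(1, 1, 2), tid = c(1, 2, 3), e = c(1, 1, 1),
                       n = c(10, 10, 10)), "fewer than two arms")
  expect_error(nma_fit(sid = c(1, 1, 2, 2), tid = c(1, 2, 3, 4),
                       e = rep(1, 4), n = rep(10, 4)), "disconnected")
  expect_error(nma_fit(sid = c(1, 1), tid = c(1, 2), e = c(11, 1),
                       n = c(10, 10)), "invalid event count")
})

test_that("a two-treatment network equals the pairwise meta-analysis", {
  set.seed(121)
  for (i in 1:8) {
    d <- rand_nma(K = 2, n_studies = sample(3:6, 1))
    ## pairwise layout: treatment 1 is group 0, treatment 2 is group 1
    wide <- do.call(rbind, lapply(split(d, d$sid), function(s)
      data.frame(e0 = s$e[s$tid == 1], n0 = s$n[s$tid == 1],
                 e1 = s$e[s$tid == 2], n1 = s$n[s$tid == 2])))
    for (random in c(FALSE, TRUE)) {
      f <- nma_fit(data = d, random = random)
      m <- ma_fit(wide$e0, wide$n0, wide$e1, wide$n1,
                  tau2_method = if (random) "DL" else "FE")
      expect_equal(f$est["2", "1"], m$theta, tolerance = 1e-8)
      expect_equal(f$ci.lb["2", "1"], m$ci.lb, tolerance = 1e-8)
      expect_equal(f$ci.ub["2", "1"], m$ci.ub, tolerance = 1e-8)
      if (random) expect_equal(f$tau2, m$tau2, tolerance = 1e-8)
    }
  }
})

test_that("fitted estimates are antisymmetric and triple-consistent", {
  set.seed(232)
  for (i in 1:6) {
    d <- rand_nma(K = sample(3:5, 1), n_studies = 8)
    f <- nma_fit(data = d, random = i %% 2 == 0)
    expect_equal(f$est, -t(f$est), tolerance = 1e-10)
    expect_equal(f$se, t(f$se), tolerance = 1e-10)
    for (a in 1:(f$K - 2)) for (b in (a + 1):(f$K - 1))
      for (cc in (b + 1):f$K)
        expect_equal(f$est[a, b] + f$est[b, cc] + f$est[cc, a], 0,
                     tolerance = 1e-10)
    expect_gte(f$tau2, 0)
  }
})

test_that("tree networks force exact consistency along paths", {
  ## star network 1-2, 1-3: indirect 2 vs 3 is the difference of directs
  d <- data.frame(sid = c(1, 1, 2, 2), tid = c(1, 2, 1, 3),
                  e = c(10, 20, 8, 15), n = c(100, 100, 90, 95))
  f <- nma_fit(data = d, random = FALSE)
  direct21 <- log((20 / 80) / (10 / 90))
  direct31 <- log((15 / 80) / (8 / 82))
  expect_equal(f$est["2", "1"], direct21, tolerance = 1e-10)
  expect_equal(f$est["3", "1"], direct31, tolerance = 1e-10)
  expect_equal(f$est["2", "3"], direct21 - direct31, tolerance = 1e-10)
})

test_that("perfectly homogeneous networks have zero heterogeneity", {
  d <- data.frame(sid = rep(1:4, each = 2), tid = c(1, 2, 1, 2, 2, 3, 1, 3),
                  e = rep(c(10, 20), 4), n = rep(80, 8))
  f <- nma_fit(data = d, random = TRUE)
  expect_equal(f$tau2, 0)
})

test_that("the engine matches the independent GLS route", {
  d <- read_nma(frag_example("dat_copd.csv"))
  f <- nma_fit(data = d, random = FALSE)
  g <- oracle_nma_gls(d, tau2 = 0)
  expect_equal(unclass(f$est), g$est, tolerance = 1e-6)
  expect_equal(unclass(f$se), g$se, tolerance = 1e-6)
  fr <- nma_fit(data = d, random = TRUE)
  gr <- oracle_nma_gls(d, tau2 = fr$tau2)
  expect_equal(unclass(fr$est), gr$est, tolerance = 1e-6)
  expect_equal(unclass(fr$se), gr$se, tolerance = 1e-6)
  set.seed(343)
  for (i in 1:5) {
    dr <- rand_nma(K = 4, n_studies = 7)
    fi <- nma_fit(data = dr, random = TRUE)
    gi <- oracle_nma_gls(dr, tau2 = fi$tau2)
    expect_equal(unclass(fi$est), gi$est, tolerance = 1e-8)
    expect_equal(unclass(fi$se), gi$se, tolerance = 1e-8)
  }
})

test_that("multi-arm adjustment inflates redundant contrast variances", {
  d <- read_nma(frag_example("dat_copd.csv"))
  ct <- arms_to_contrasts(data = d)
  multi <- ct[ct$sid == 2, ]
  expect_equal(nrow(multi), 6)          # 4 arms -> 6 contrasts
  expect_true(all(multi$v >= multi$v_naive - 1e-12))
  expect_true(any(multi$v > multi$v_naive + 1e-12))
  two_arm <- ct[ct$sid != 2, ]
  expect_equal(two_arm$v, two_arm$v_naive, tolerance = 1e-12)
})

test_that("continuity-correction flags behave like the arm-level rules", {
  d <- data.frame(sid = c(1, 1, 2, 2), tid = c(1, 2, 1, 2),
                  e = c(0, 3, 4, 6), n = c(20, 20, 30, 30))
  ct <- arms_to_contrasts(data = d)
  ## contrasts are first-listed vs second-listed treatment:
  ## study 1 corrected (zero cell), study 2 untouched
  expect_equal(ct$y[ct$sid == 1], log((0.5 / 20.5) / (3.5 / 17.5)),
               tolerance = 1e-12)
  expect_equal(ct$y[ct$sid == 2], log((4 / 26) / (6 / 24)),
               tolerance = 1e-12)
  ct_all <- arms_to_contrasts(data = d, allincr = TRUE)
  expect_equal(ct_all$y[ct_all$sid == 2], log((4.5 / 26.5) / (6.5 / 24.5)),
               tolerance = 1e-12)
  ## double-zero studies are dropped for OR unless allstudies = TRUE
  d2 <- rbind(d, data.frame(sid = 3, tid = c(1, 2), e = c(0, 0),
                            n = c(15, 15)))
  expect_false(3 %in% arms_to_contrasts(data = d2)$sid)
  expect_true(3 %in% arms_to_contrasts(data = d2, allstudies = TRUE)$sid)
})
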