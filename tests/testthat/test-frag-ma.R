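test_that("candidate sets honour the bounds and the 2N count", {
  cand <- fragtools:::.ma_candidates(c(3, 5, 2), c(10, 10, 10),
                                     c(4, 6, 1), c(12, 12, 12), "left")
  expect_equal(nrow(cand), 6)
  ## group-1 candidate precedes group-0 within each study
  expect_equal(cand[, "group"], rep(c(1L, 0L), 3), ignore_attr = TRUE)
  ## a study with no events in group 1 only offers its group-0 move
  cand2 <- fragtools:::.ma_candidates(c(3), c(10), c(0), c(12), "left")
  expect_equal(nrow(cand2), 1)
  expect_equal(unname(cand2[1, ]), c(1L, 0L, 1L))
  ## fully saturated states offer nothing
  expect_null(fragtools:::.ma_candidates(c(10), c(10), c(0), c(12), "left"))
})

test_that("the first greedy step picks the argmin over brute-force refits",
{
  set.seed(808)
  for (i in 1:5) {
    d <- gen_ma(N = 2, theta = 1.2, tau2 = 0, n_range = c(15, 30),
                p0_range = c(0.2, 0.4), seed = NULL)
    r <- frag_ma(data = d, max_iter = 1)
    run <- r$runs[[1]]
    if (!nrow(run$trajectory)) next
    target <- names(r$runs)[1]
    cand <- fragtools:::.ma_candidates(d$e0, d$n0, d$e1, d$n1, target)
    scores <- apply(cand, 1, function(cc) {
      e0 <- d$e0; e1 <- d$e1
      if (cc["group"] == 0) e0[cc["study"]] <- e0[cc["study"]] + cc["delta"]
      else e1[cc["study"]] <- e1[cc["study"]] + cc["delta"]
      ci <- oracle_ma_ci(e0, d$n0, e1, d$n1)
      if (target == "left") ci[2] else ci[3]
    })
    best <- if (target == "left") which.min(scores) else which.max(scores)
    step <- run$trajectory[1, ]
    expect_equal(unname(c(step$study, step$group, step$delta)),
                 unname(cand[best, ]))
  }
})

test_that("greedy search obeys the work bound and replays exactly", {
  set.seed(909)
  checked <- 0
  for (i in 1:12) {
    N <- sample(3:8, 1)
    d <- gen_ma(N, theta = runif(1, -1.2, 1.2), tau2 = runif(1, 0, 0.15),
                n_range = c(25, 90), seed = NULL)
    r <- frag_ma(data = d)
    if (is.na(r$FI)) next
    checked <- checked + 1
    ## the complexity bound: at most 2N fits per step
    win <- r$runs[[which(vapply(r$runs, function(x)
      !is.na(x$FI) && x$FI == r$FI, logical(1)))[1]]]
    expect_lte(win$fits, 2 * N * r$FI)
    expect_equal(nrow(r$trajectory), r$FI)
    ## replaying the trajectory reproduces the final dataset
    e0 <- d$e0; e1 <- d$e1
    for (k in seq_len(nrow(r$trajectory))) {
      s <- r$trajectory$study[k]
      if (r$trajectory$group[k] == 0) e0[s] <- e0[s] + r$trajectory$delta[k]
      else e1[s] <- e1[s] + r$trajectory$delta[k]
    }
    expect_equal(e0, r$final_data$e0)
    expect_equal(e1, r$final_data$e1)
    expect_true(all(e0 >= 0 & e0 <= d$n0 & e1 >= 0 & e1 <= d$n1))
    ## significance flips exactly at the last step
    null <- 0
    sig_at <- function(k) {
      lb <- r$trajectory$ci.lb[k]; ub <- r$trajectory$ci.ub[k]
      lb > null || ub < null
    }
    sig0 <- r$fit0$ci.lb > null || r$fit0$ci.ub < null
    expect_false(sig_at(r$FI) == sig0)
    if (r$FI > 1) expect_true(sig_at(r$FI - 1) == sig0)
  }
  expect_gte(checked, 5)
})

test_that("group totals move monotonically along a directional run", {
  d <- gen_ma(N = 5, theta = 1.1, tau2 = 0, n_range = c(30, 60), seed = 31)
  r <- frag_ma(data = d)
  expect_false(is.na(r$FI))
  expect_equal(r$dir, "sig2nonsig")
  ## target left: group-0 events never decrease, group-1 never increase
  tr <- r$trajectory
  expect_true(all(tr$delta[tr$group == 0] == 1))
  expect_true(all(tr$delta[tr$group == 1] == -1))
})

test_that("non-significant MAs take the minimum over both directions", {
  set.seed(111)
  found <- 0
  for (i in 1:10) {
    d <- gen_ma(N = 4, theta = 0.1, tau2 = 0.02, n_range = c(30, 80),
                seed = NULL)
    r <- frag_ma(data = d, mod.dir = "both")
    if (r$dir != "nonsig2sig") next
    found <- found + 1
    rl <- frag_ma(data = d, mod.dir = "left")
    rr <- frag_ma(data = d, mod.dir = "right")
    expect_equal(r$FI, min(c(rl$FI, rr$FI), na.rm = TRUE))
    ## directions share no state: both sub-runs start from the originals
    expect_equal(r$runs[["left"]]$FI, rl$FI)
    expect_equal(r$runs[["right"]]$FI, rr$FI)
  }
  expect_gte(found, 3)
})

test_that("a single-study MA reduces to the Wald-restricted study FI", {
  set.seed(222)
  found <- 0
  for (i in 1:15) {
    tb <- list(e0 = sample(2:8, 1), n0 = 40, e1 = sample(12:25, 1), n1 = 40)
    f <- ma_fit(tb$e0, tb$n0, tb$e1, tb$n1)
    sig0 <- f$ci.lb > 0 || f$ci.ub < 0
    if (!sig0 || f$theta < 0) next
    found <- found + 1
    r <- frag_ma(e0 = tb$e0, n0 = tb$n0, e1 = tb$e1, n1 = tb$n1)
    ## the study-level search with matching constraints: events may only
    ## increase in group 0 and decrease in group 1
    x <- frag_study(tb$e0, tb$n0, tb$e1, tb$n1, methods = "OR",
                    modify0 = "increase", modify1 = "decrease")
    expect_equal(as.numeric(r$FI), unname(as.numeric(x$FI)))
  }
  expect_gte(found, 3)
})

test_that("impossible flips are reported as NA", {
  ## two tiny studies at an extreme level: no sequence can reach
  ## significance
  r <- frag_ma(e0 = c(1, 1), n0 = c(3, 3), e1 = c(1, 1), n1 = c(3, 3),
               alpha = 1e-12)
  expect_true(is.na(r$FI))
  expect_true(is.na(r$FQ))
})

test_that("alpha sweep and batch wrappers agree with direct calls", {
  d <- gen_ma(N = 3, theta = 0.9, tau2 = 0, n_range = c(25, 45), seed = 77)
  sw <- frag_ma_alpha(data = d, alpha.from = 0.02, alpha.to = 0.1,
                      alpha.breaks = 5)
  for (b in seq_along(sw$alphas)) {
    rb <- frag_ma(data = d, alpha = sw$alphas[b])
    expect_equal(sw$FI[b], as.numeric(rb$FI))
    expect_equal(sw$dir[b], rb$dir)
  }
  if (!anyNA(sw$FI)) expect_equal(sw$FI.avg, mean(sw$FI))

  md <- gen_mas(4, N_range = c(3, 5), theta = 0.5, tau2 = 0.05, seed = 55)
  b <- frag_mas(data = md)
  expect_equal(length(b$FI), 4)
  for (k in 1:4) {
    sel <- md$ma.id == k
    fk <- ma_fit(md$e0[sel], md$n0[sel], md$e1[sel], md$n1[sel])
    sig <- fk$ci.lb > 0 || fk$ci.ub < 0
    expect_equal(b$dir[k], if (sig) "sig2nonsig" else "nonsig2sig")
  }
  expect_equal(b$summary$sig2nonsig$n + b$summary$nonsig2sig$n, 4)
})
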