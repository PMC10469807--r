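test_that("funnel centering subtracts each comparison's pooled effect", {
  net <- load_fixture("pfs")
  fun <- comparison_adjusted_funnel(net)
  expect_identical(nrow(fun$points), 12L)
  expect_false(any(fun$points$imputed))
  # single-comparison subset: centering equals subtracting its pooled value
  d <- net$contrast[net$contrast$treat_alt == "alectinib" &
                    net$contrast$treat_ref == "crizotinib", ]
  pooled <- pool_fixed(d)$pooled_log_effect
  pts <- fun$points[fun$points$treat_alt == "alectinib" &
                    fun$points$treat_ref == "crizotinib", ]
  expect_equal(pts$centered_effect, d$log_effect - pooled, tolerance = 1e-10)
  # per-comparison centered effects have weighted mean zero
  expect_equal(sum(pts$centered_effect / d$se^2), 0, tolerance = 1e-8)
  expect_equal(fun$contours$z, qnorm(1 - c(0.10, 0.05, 0.01) / 2))
})

test_that("the Egger intercept vanishes for mirror-symmetric effect sets", {
  eff <- data.frame(log_effect = c(-0.4, 0.4, -0.2, 0.2, 0),
                    se = c(0.1, 0.1, 0.3, 0.3, 0.2))
  r <- egger_test(eff)
  expect_equal(r$intercept, 0, tolerance = 1e-10)
  expect_equal(r$p, 1, tolerance = 1e-8)
  expect_false(egger_test(eff[1:2, ])$computable)
})

test_that("Egger agrees with the weighted-regression cross-check", {
  set.seed(11)
  for (i in 1:10) {
    k <- sample(5:15, 1)
    eff <- data.frame(log_effect = rnorm(k), se = runif(k, 0.1, 0.6))
    mine <- egger_test(eff)
    ref <- metafor::regtest(x = eff$log_effect, sei = eff$se,
                            model = "lm", predictor = "sei")
    expect_equal(mine$p, ref$pval, tolerance = 1e-8)
    expect_equal(mine$t, as.numeric(ref$zval), tolerance = 1e-8)
  }
})

test_that("Egger flags the published small-study effects in the fixture", {
  pfs <- egger_test(alknma:::.study_effects(load_fixture("pfs")))
  expect_lt(pfs$p, 0.05)
  bm <- egger_test(alknma:::.study_effects(load_fixture("pfs_bm")))
  expect_lt(abs(bm$p - 0.006), 0.002)
})

test_that("Begg's tau equals exhaustive concordance counting", {
  set.seed(5)
  for (i in 1:10) {
    k <- sample(c(3, 5, 10, 30), 1)
    eff <- data.frame(log_effect = rnorm(k), se = runif(k, 0.1, 0.5))
    mine <- begg_test(eff)
    # independent oracle: Kendall correlation of the standardized deviates
    w <- 1 / eff$se^2
    pooled <- sum(w * eff$log_effect) / sum(w)
    u <- (eff$log_effect - pooled) / sqrt(eff$se^2 - 1 / sum(w))
    tau <- suppressWarnings(cor(u, eff$se^2, method = "kendall"))
    expect_equal(mine$kendall_tau, tau, tolerance = 1e-10)
  }
  # perfect concordance: effects strictly increasing with variance
  eff <- data.frame(log_effect = 1:6, se = sqrt(1:6))
  expect_equal(begg_test(eff)$kendall_tau, 1)
  expect_false(begg_test(eff[1:2, ])$computable)
})

test_that("Begg p-values are roughly uniform under the null", {
  set.seed(77)
  rej <- 0
  for (i in 1:40) {
    eff <- data.frame(log_effect = rnorm(20), se = runif(20, 0.1, 0.5))
    rej <- rej + (begg_test(eff)$p < 0.05)
  }
  expect_lte(rej, 6)  # ~5% nominal; generous binomial band
})

test_that("trim-and-fill is the identity on symmetric sets", {
  eff <- data.frame(log_effect = c(-0.4, 0.4, -0.2, 0.2, 0),
                    se = c(0.1, 0.1, 0.3, 0.3, 0.2))
  tf <- trim_and_fill(eff)
  expect_identical(tf$k0, 0L)
  expect_equal(tf$adjusted_pooled, tf$original_pooled)
  expect_error(trim_and_fill(eff[1:2, ]), "at least 3")
})

test_that("trim-and-fill agrees with the metafor cross-check on the fixture", {
  for (oid in c("pfs", "pfs_bm")) {
    eff <- alknma:::.study_effects(load_fixture(oid))
    mine <- trim_and_fill(eff)
    ref <- metafor::trimfill(metafor::rma.uni(yi = eff$log_effect,
                                              sei = eff$se, method = "FE"))
    expect_identical(mine$k0, as.integer(ref$k0))
    expect_identical(mine$side, ref$side)
  }
})

test_that("trim-and-fill imputes missing small studies planted by construction", {
  set.seed(123)
  # symmetric funnel, then delete the k most negative small-study effects
  y <- rnorm(20, 0, 0.05) + c(rep(0, 10), rep(c(-0.6, 0.6), 5))
  s <- c(runif(10, 0.05, 0.1), rep(0.35, 10))
  eff <- data.frame(log_effect = y, se = s)
  keep <- order(eff$log_effect)[-(1:3)]  # censor 3 leftmost studies
  tf <- trim_and_fill(eff[keep, ])
  expect_gte(tf$k0, 2L)
  expect_identical(tf$side, "left")
  expect_identical(nrow(tf$filled), tf$k0)
  # imputation pulls the pooled estimate back down
  expect_lt(tf$adjusted_pooled["estimate"], tf$original_pooled["estimate"])
})
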