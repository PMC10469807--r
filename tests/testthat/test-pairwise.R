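# brute-force oracle: the pooling formulas evaluated symbol by symbol
oracle_fixed <- function(y, s) {
  w <- 1 / s^2
  est <- sum(w * y) / sum(w)
  list(est = est, se = sum(w)^-0.5, Q = sum(w * (y - est)^2))
}
oracle_dl <- function(y, s) {
  w <- 1 / s^2
  f <- oracle_fixed(y, s)
  df <- length(y) - 1
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (f$Q - df) / C)
  w2 <- 1 / (s^2 + tau2)
  list(est = sum(w2 * y) / sum(w2), se = sum(w2)^-0.5, tau2 = tau2, Q = f$Q)
}

test_that("per-trial odds ratios follow the 2x2 formula with continuity correction", {
  r <- trial_log_or(10, 20, 5, 20)
  expect_equal(r$log_or, log(3), tolerance = 1e-12)
  expect_equal(r$se, sqrt(1 / 10 + 1 / 10 + 1 / 5 + 1 / 15), tolerance = 1e-12)
  r <- trial_log_or(5, 10, 5, 10)
  expect_equal(r$log_or, 0)
  expect_equal(r$se, sqrt(0.8), tolerance = 1e-12)
  # single zero cell: 0.5 added everywhere
  r <- trial_log_or(0, 10, 5, 10)
  expect_equal(r$log_or, log((0.5 * 5.5) / (10.5 * 5.5)), tolerance = 1e-12)
  expect_warning(expect_null(trial_log_or(0, 10, 0, 10)), "uninformative")
  expect_warning(expect_null(trial_log_or(10, 10, 10, 10)), "uninformative")
})

test_that("fixed-effect pooling matches identity and closed-form cases", {
  one <- pool_fixed(data.frame(log_effect = -0.5, se = 0.2))
  expect_equal(one$pooled_log_effect, -0.5)
  expect_equal(one$pooled_se, 0.2)
  expect_equal(one$Q, 0)
  expect_false(one$heterogeneity_estimable)

  two <- pool_fixed(data.frame(log_effect = c(-1, -1), se = c(0.3, 0.3)))
  expect_equal(two$pooled_log_effect, -1)
  expect_equal(two$pooled_se, 0.3 / sqrt(2), tolerance = 1e-10)
  expect_equal(two$Q, 0)
  expect_error(pool_fixed(data.frame(log_effect = numeric(0), se = numeric(0))))
})

test_that("FE and DL pooling agree with the brute-force oracle on small sets", {
  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    y <- rnorm(k); s <- runif(k, 0.1, 0.5)
    eff <- data.frame(log_effect = y, se = s)
    fe <- pool_fixed(eff); of <- oracle_fixed(y, s)
    expect_equal(fe$pooled_log_effect, of$est, tolerance = 1e-8)
    expect_equal(fe$pooled_se, of$se, tolerance = 1e-8)
    expect_equal(fe$Q, of$Q, tolerance = 1e-8)
    dl <- pool_dersimonian_laird(eff); od <- oracle_dl(y, s)
    expect_equal(dl$pooled_log_effect, od$est, tolerance = 1e-8)
    expect_equal(dl$pooled_se, od$se, tolerance = 1e-8)
    expect_equal(dl$tau_squared, od$tau2, tolerance = 1e-8)
    # random-effects interval is never tighter than fixed
    expect_gte(dl$pooled_se, fe$pooled_se - 1e-12)
    # pooled estimate is a convex combination of the study effects
    expect_gte(dl$pooled_log_effect, min(y) - 1e-12)
    expect_lte(dl$pooled_log_effect, max(y) + 1e-12)
    # Q invariant under study relabeling
    perm <- sample(k)
    expect_equal(pool_fixed(eff[perm, ])$Q, fe$Q, tolerance = 1e-10)
  }
})

test_that("two discordant studies produce positive tau2 and a wider CI", {
  eff <- data.frame(log_effect = c(-2, 0), se = c(0.1, 0.1))
  dl <- pool_dersimonian_laird(eff)
  od <- oracle_dl(eff$log_effect, eff$se)
  expect_gt(dl$tau_squared, 0)
  expect_equal(dl$tau_squared, od$tau2, tolerance = 1e-8)
  expect_gt(dl$pooled_se, pool_fixed(eff)$pooled_se)
})

test_that("DL reduces to the fixed-effect result for homogeneous studies", {
  eff <- data.frame(log_effect = rep(-0.7, 3), se = c(0.2, 0.3, 0.25))
  fe <- pool_fixed(eff); dl <- pool_dersimonian_laird(eff)
  expect_equal(dl$pooled_log_effect, fe$pooled_log_effect, tolerance = 1e-10)
  expect_equal(dl$pooled_se, fe$pooled_se, tolerance = 1e-10)
  expect_equal(dl$tau_squared, 0)
})

test_that("I-squared follows the truncated Higgins formula", {
  expect_equal(i_squared(20, 2), 90)
  expect_equal(i_squared(1.5, 2), 0)
  expect_equal(i_squared(0, 0), 0)
  expect_equal(i_squared(5, 0), 0)
  expect_error(i_squared(-1, 2))
})

test_that("pairwise tables cover every direct comparison of a network", {
  net <- load_fixture("pfs")
  tab <- pairwise_all(net)
  expect_identical(nrow(tab), 2L * nrow(net$edges))
  expect_setequal(unique(tab$model), c("fixed", "random"))
  # three-trial crizotinib-vs-chemotherapy comparison against the oracle
  d <- net$contrast[net$contrast$treat_ref == "chemotherapy" &
                    net$contrast$treat_alt == "crizotinib", ]
  of <- oracle_fixed(-d$log_effect, d$se)  # oriented chemo vs crizotinib
  row <- tab[tab$treat_alt == "chemotherapy" & tab$treat_ref == "crizotinib" &
             tab$model == "fixed", ]
  expect_equal(log(row$estimate), of$est, tolerance = 1e-8)
  expect_false(tab$het_estimable[tab$treat_alt == "brigatinib"][1])
})

test_that("forest data carries study weights and both pooled rows", {
  fd <- forest_data(load_fixture("pfs"), "alectinib", "crizotinib")
  expect_identical(sum(fd$type == "study"), 3L)
  expect_equal(sum(fd$weight_pct[fd$type == "study"]), 100)
  expect_setequal(fd$type, c("study", "pooled_fixed", "pooled_random"))
})
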