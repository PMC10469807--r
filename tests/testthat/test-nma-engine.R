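test_that("a single-trial fixed-effect fit reproduces the conjugate limit", {
  net <- toy_network(log_effect = -0.5, se = 0.1)
  fit <- fit_nma(net, nma_model_spec(effect_model = "fixed", chains = 2,
                                     burn_in = 1000, kept_iterations = 5000,
                                     thin = 1, seed = 3))
  # vague prior: posterior of d_B ~ Normal(y, se^2)
  expect_equal(mean(fit$draws[, "d.B"]), -0.5, tolerance = 0.01)
  expect_equal(sd(fit$draws[, "d.B"]), 0.1, tolerance = 0.01)
  # one effective parameter
  expect_equal(compute_dic(fit)$pD, 1, tolerance = 0.1)
})

test_that("identical seed and spec give bit-identical draws", {
  net <- load_fixture("pfs")
  s <- quick_spec(seed = 42)
  f1 <- suppressWarnings(fit_nma(net, s))
  f2 <- suppressWarnings(fit_nma(net, s))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$chain, f2$chain)
  f3 <- suppressWarnings(fit_nma(net, quick_spec(seed = 43)))
  expect_false(identical(f1$draws, f3$draws))
  # draw-count contract: chains * kept / thin
  expect_identical(nrow(f1$draws), 2L * 4000L)
})

test_that("fixed-effect network posteriors match the closed-form GLS oracle", {
  net <- load_fixture("pfs")
  fit <- fit_nma(net, nma_model_spec(effect_model = "fixed", chains = 2,
                                     burn_in = 2000, kept_iterations = 20000,
                                     thin = 1, seed = 11))
  X <- alknma:::.basic_design(net, NULL)$X
  w <- 1 / net$contrast$se^2
  gls <- solve(t(X) %*% (w * X), t(X) %*% (w * net$contrast$log_effect))
  post <- colMeans(fit$draws[, paste0("d.", rownames(gls))])
  expect_equal(post, setNames(gls[, 1], names(post)), tolerance = 0.01)
})

test_that("random-effects draws respect the model's support constraints", {
  fit <- suppressWarnings(fit_nma(load_fixture("pfs"), quick_spec(seed = 2)))
  expect_true(all(fit$draws[, "tau"] > 0))
  expect_true(all(fit$draws[, "tau"] < fit$tau_upper))
  expect_true(all(fit$draws[, "deviance"] >= 0))
  # consistency holds per draw by construction: d_AB + d_BC = d_AC
  d <- alknma:::.d_draws(fit)
  lhs <- (d[, "alectinib"] - d[, "crizotinib"]) +
         (d[, "chemotherapy"] - d[, "alectinib"])
  expect_equal(lhs, d[, "chemotherapy"] - d[, "crizotinib"], tolerance = 1e-12)
})

test_that("league tables are reciprocal with unit diagonal", {
  fit <- cached_fixture_fit("pfs")
  lt <- league_table(fit)
  K <- length(lt$treatments)
  expect_equal(diag(lt$median), rep(1, K), ignore_attr = TRUE)
  for (a in 1:(K - 1)) for (b in (a + 1):K) {
    expect_equal(lt$median[a, b], 1 / lt$median[b, a], tolerance = 1e-10)
    expect_equal(lt$low[a, b], 1 / lt$high[b, a], tolerance = 1e-10)
    expect_equal(lt$bayes_p[a, b], lt$bayes_p[b, a], tolerance = 1e-12)
  }
  re <- relative_effect(fit, "alectinib", "crizotinib")
  expect_equal(unname(re["median"]), lt$median["crizotinib", "alectinib"])
})

test_that("a fixed-effect fit on one comparison reproduces inverse-variance pooling", {
  net <- load_fixture("pfs")
  d <- net$contrast[net$contrast$treat_alt == "alectinib" &
                    net$contrast$treat_ref == "crizotinib", ]
  sub <- build_network(d, net$outcome, treatment_order = c("crizotinib", "alectinib"))
  fit <- fit_nma(sub, nma_model_spec(effect_model = "fixed", chains = 2,
                                     burn_in = 1000, kept_iterations = 10000,
                                     thin = 1, seed = 9))
  fe <- pool_fixed(d)
  expect_equal(mean(fit$draws[, "d.alectinib"]), fe$pooled_log_effect,
               tolerance = 0.01)
  expect_equal(sd(fit$draws[, "d.alectinib"]), fe$pooled_se, tolerance = 0.01)
})

test_that("split-chain PSRF separates mixed from disjoint chains", {
  # well-mixed: same distribution in both chains
  set.seed(1)
  fake <- list(draws = cbind(d.B = rnorm(4000), deviance = rnorm(4000)),
               chain = rep(1:2, each = 2000))
  class(fake) <- "nma_fit"
  gr <- gelman_rubin(fake)
  expect_lt(gr$psrf["d.B"], 1.05)
  expect_true(gr$pass)
  # disjoint supports: brute-force PSRF formula expects a large value
  fake$draws[, "d.B"] <- c(rnorm(2000, 0, 1), rnorm(2000, 10, 1))
  gr <- gelman_rubin(fake)
  expect_gt(gr$psrf["d.B"], 1.5)
  expect_false(gr$pass)
  fake$chain <- rep(1L, 4000)
  expect_error(gelman_rubin(fake), "2 chains")
})

test_that("near-noiseless data drive the residual deviance to the data size", {
  cfg <- synthetic_config(n_treatments = 3, topology = "star",
                          true_basic_effects = c(-0.5, 0.3),
                          heterogeneity_sd = 0, trials_per_edge = 3,
                          contrast_se = 1e-4, seed = 5)
  net <- generate_contrast_network(cfg)
  fit <- fit_nma(net, nma_model_spec(effect_model = "fixed", chains = 2,
                                     burn_in = 2000, kept_iterations = 5000,
                                     thin = 1, seed = 5))
  dic <- compute_dic(fit)
  # Dbar ~ N - p + p = N in the normal fixed-effect case; loose band
  expect_lt(abs(dic$Dbar - nrow(net$trials)), 4)
})

test_that("the UME model frees one parameter per observed comparison", {
  net <- load_fixture("pfs")
  fit <- suppressWarnings(
    fit_nma(net, quick_spec(consistency = "ume_inconsistent", seed = 8)))
  dcols <- grep("^d\\.", colnames(fit$draws), value = TRUE)
  expect_length(dcols, nrow(net$edges))
  # a UME edge estimate equals the direct Bayesian estimate of that edge:
  # single-trial edge lorlatinib-crizotinib should match its own datum
  row <- net$contrast[net$contrast$treat_alt == "lorlatinib", ]
  expect_equal(median(fit$draws[, "d.lorlatinib.crizotinib"]),
               row$log_effect, tolerance = 0.05)
})

test_that("binary fits recover large-sample odds ratios", {
  # one huge trial: posterior log OR concentrates near the empirical one
  obs <- data.frame(trial = "T1", treatment = c("B", "A"),
                    n = 20000, events = c(12000, 10000))
  net <- build_network(obs, outcome_spec("bin", "arm_binary", "higher"),
                       treatment_order = c("A", "B"))
  fit <- fit_nma(net, nma_model_spec(effect_model = "fixed", chains = 2,
                                     burn_in = 2000, kept_iterations = 10000,
                                     thin = 1, seed = 13))
  emp <- trial_log_or(12000, 20000, 10000, 20000)
  expect_equal(median(fit$draws[, "d.B"]), emp$log_or, tolerance = 0.02)
})
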