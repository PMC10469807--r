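# shared builders and memoised fits -------------------------------------------

# default-settings fits of the bundled networks are expensive enough to share
.fit_cache <- new.env(parent = emptyenv())

cached_fixture_fit <- function(outcome_id) {
  if (!exists(outcome_id, envir = .fit_cache)) {
    assign(outcome_id, fit_nma(load_fixture(outcome_id)), envir = .fit_cache)
  }
  get(outcome_id, envir = .fit_cache)
}

# reduced sampler settings for property-style tests
quick_spec <- function(..., seed = 20230619) {
  nma_model_spec(chains = 2, burn_in = 1000, kept_iterations = 4000,
                 thin = 1, seed = seed, ...)
}

# minimal two-treatment contrast network
toy_network <- function(log_effect = -0.5, se = 0.1) {
  obs <- data.frame(trial = "T1", treat_ref = "A", treat_alt = "B",
                    log_effect = log_effect, se = se)
  build_network(obs, outcome_spec("toy", "contrast_loghr", "lower"),
                treatment_order = c("A", "B"))
}

# triangle network with direct evidence on every edge
triangle_network <- function(seed = 1, tau = 0.05, shift_t1t2 = 0) {
  cfg <- synthetic_config(n_treatments = 3, topology = "loop",
                          true_basic_effects = c(-0.5, -0.2),
                          heterogeneity_sd = tau, trials_per_edge = 2,
                          contrast_se = 0.15, seed = seed)
  net <- generate_contrast_network(cfg)
  if (shift_t1t2 != 0) {
    idx <- with(net$contrast, treat_ref == "t1" & treat_alt == "t2")
    net$contrast$log_effect[idx] <- net$contrast$log_effect[idx] + shift_t1t2
  }
  net
}

# fake minimal nma_fit around given basic-parameter draws, for ranking tests
fake_fit <- function(d_draws, reference, treatments) {
  free <- setdiff(treatments, reference)
  colnames(d_draws) <- paste0("d.", free)
  structure(list(draws = d_draws, treatments = treatments,
                 reference = reference, consistency = "consistent",
                 outcome = outcome_spec("fake", "contrast_loghr", "lower")),
            class = "nma_fit")
}
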