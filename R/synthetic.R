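# Synthetic evidence networks with known ground truth -------------------------

#' Configuration for a synthetic two-arm trial network
#'
#' Describes a network simulated from the same data-generating model the
#' NMA engine assumes: trial-level effects
#' `delta ~ Normal(d_alt - d_ref, tau^2)` observed either as contrasts with
#' known standard error or as binomial arm counts on a logit baseline.
#' The same config (including `seed`) always yields the identical dataset:
#' a single seeded RNG stream is used, drawing per trial in edge order --
#' contrast networks: delta, then se (if a range), then y; binary
#' networks: delta, baseline jitter, control events, experimental events.
#'
#' @param n_treatments K >= 2; treatments are labelled `t1 ... tK` with
#'   `t1` the reference.
#' @param topology `"star"` (all edges t1-tk), `"loop"` (ring), or
#'   `"paper_like"` (the bundled 12-trial ALK network's shape: 7 treatments,
#'   7 edges, 12 trials; `n_treatments` and `trials_per_edge` are implied).
#' @param true_basic_effects numeric `d_k` for k = 2..K (log scale);
#'   `d_1 = 0`.
#' @param heterogeneity_sd between-trial SD `tau >= 0`.
#' @param trials_per_edge trials on each edge.
#' @param arm_size arm size (single value or range) for binary networks.
#' @param baseline_event_prob control-arm event probability (binary).
#' @param contrast_se contrast standard error (single value or range).
#' @param seed integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_treatments = 3,
                             topology = c("star", "loop", "paper_like"),
                             true_basic_effects = NULL,
                             heterogeneity_sd = 0.1,
                             trials_per_edge = 2,
                             arm_size = c(100, 200),
                             baseline_event_prob = 0.4,
                             contrast_se = c(0.1, 0.3),
                             seed = 1L) {
  topology <- match.arg(topology)
  if (topology == "paper_like") n_treatments <- 7
  stopifnot(n_treatments >= 2, heterogeneity_sd >= 0, trials_per_edge >= 1,
            all(arm_size >= 2), baseline_event_prob > 0,
            baseline_event_prob < 1, all(contrast_se > 0))
  if (is.null(true_basic_effects))
    true_basic_effects <- seq(-0.5, 0.5, length.out = n_treatments - 1)
  stopifnot(length(true_basic_effects) == n_treatments - 1)
  structure(list(n_treatments = as.integer(n_treatments), topology = topology,
                 true_basic_effects = true_basic_effects,
                 heterogeneity_sd = heterogeneity_sd,
                 trials_per_edge = as.integer(trials_per_edge),
                 arm_size = arm_size,
                 baseline_event_prob = baseline_event_prob,
                 contrast_se = contrast_se, seed = as.integer(seed)),
            class = "synthetic_config")
}

# edge list (ref, alt index pairs) for a topology, one row per trial
.synthetic_trials <- function(config) {
  K <- config$n_treatments
  if (config$topology == "star") {
    edges <- cbind(ref = rep(1L, K - 1), alt = 2:K)
  } else if (config$topology == "loop") {
    edges <- cbind(ref = 1:K, alt = c(2:K, 1L))
  } else {  # the bundled PFS network's shape (t1 = crizotinib-like hub,
            # t7 = chemotherapy-like second hub)
    edges <- cbind(ref = c(1L, 1L, 1L, 1L, 7L, 7L, 7L),
                   alt = c(2L, 4L, 5L, 6L, 1L, 2L, 3L))
    reps <- c(3L, 1L, 1L, 1L, 3L, 1L, 2L)
    return(edges[rep(seq_len(nrow(edges)), reps), , drop = FALSE])
  }
  edges[rep(seq_len(nrow(edges)), each = config$trials_per_edge), ,
        drop = FALSE]
}

.draw_range <- function(range) {
  if (length(range) == 1) range else runif(1, range[1], range[2])
}

#' Simulate a contrast-level evidence network
#'
#' Per trial on edge (a, b): `delta ~ Normal(d_b - d_a, tau^2)` and
#' `y ~ Normal(delta, se^2)` with `se` drawn from `contrast_se`.
#'
#' @param config a [synthetic_config()].
#' @param outcome_id label for the generated outcome.
#' @return an `evidence_network` with attribute `truth` (list of `d`,
#'   `tau`, per-trial `delta`).
#' @export
generate_contrast_network <- function(config, outcome_id = "synthetic") {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  trials <- .synthetic_trials(config)
  d <- c(0, config$true_basic_effects)
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    a <- trials[i, "ref"]; b <- trials[i, "alt"]
    delta <- rnorm(1, d[b] - d[a], config$heterogeneity_sd)
    se <- .draw_range(config$contrast_se)
    y <- rnorm(1, delta, se)
    data.frame(trial = sprintf("S%02d", i),
               treat_ref = paste0("t", a), treat_alt = paste0("t", b),
               log_effect = y, se = se, delta = delta,
               stringsAsFactors = FALSE)
  })
  obs <- do.call(rbind, rows)
  net <- build_network(obs[, 1:5],
                       outcome_spec(outcome_id, "contrast_loghr", "lower"),
                       treatment_order = paste0("t", 1:config$n_treatments))
  attr(net, "truth") <- list(d = setNames(d, paste0("t", 1:config$n_treatments)),
                             tau = config$heterogeneity_sd, delta = obs$delta)
  net
}

#' Simulate an arm-level binary evidence network
#'
#' Per trial on edge (a, b): baseline
#' `mu = qlogis(baseline_event_prob) + Normal(0, 0.1)`, trial effect
#' `delta ~ Normal(d_b - d_a, tau^2)`, then
#' `r_ref ~ Binomial(n, plogis(mu))` and
#' `r_alt ~ Binomial(n, plogis(mu + delta))`.
#'
#' @inheritParams generate_contrast_network
#' @param better_direction passed to the generated [outcome_spec()].
#' @return an `evidence_network` with attribute `truth`.
#' @export
generate_binary_network <- function(config, outcome_id = "synthetic_bin",
                                    better_direction = "lower") {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  trials <- .synthetic_trials(config)
  d <- c(0, config$true_basic_effects)
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    a <- trials[i, "ref"]; b <- trials[i, "alt"]
    delta <- rnorm(1, d[b] - d[a], config$heterogeneity_sd)
    mu <- qlogis(config$baseline_event_prob) + rnorm(1, 0, 0.1)
    n <- round(.draw_range(config$arm_size))
    r_ref <- rbinom(1, n, plogis(mu))
    r_alt <- rbinom(1, n, plogis(mu + delta))
    # experimental arm first, control second (the arm-order convention)
    data.frame(trial = sprintf("S%02d", i),
               treatment = paste0("t", c(b, a)), n = n,
               events = c(r_alt, r_ref), delta = delta,
               stringsAsFactors = FALSE)
  })
  obs <- do.call(rbind, rows)
  net <- build_network(obs[, 1:4],
                       outcome_spec(outcome_id, "arm_binary", better_direction),
                       treatment_order = paste0("t", 1:config$n_treatments))
  attr(net, "truth") <- list(d = setNames(d, paste0("t", 1:config$n_treatments)),
                             tau = config$heterogeneity_sd,
                             delta = obs$delta[!duplicated(obs$trial)])
  net
}
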