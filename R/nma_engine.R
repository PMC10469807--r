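# Bayesian NMA engine ---------------------------------------------------------

#' Model and sampler settings for a network meta-analysis
#'
#' Defaults follow common practice for Bayesian NMA of two-arm trial
#' networks: vague Normal(0, 10^2) priors on basic effects and trial
#' baselines, Uniform(0, U) prior on the between-trial SD `tau` (U = 2 for
#' contrast outcomes, 5 for binary ones), four chains with overdispersed
#' starting values, 10,000 burn-in iterations, 50,000 sampling iterations
#' with thinning 2 (so 100,000 retained draws in total).
#'
#' @param effect_model `"random"` (between-trial heterogeneity) or `"fixed"`.
#' @param consistency `"consistent"` (all contrasts expressed through basic
#'   parameters versus the reference) or `"ume_inconsistent"` (one free
#'   parameter per observed comparison; the global-inconsistency benchmark).
#' @param reference treatment id used as the reference (default: the
#'   network's first treatment).
#' @param prior_sd_effect,prior_sd_baseline prior SDs of effect and baseline
#'   parameters (log scale).
#' @param tau_upper upper bound of the uniform prior on `tau`; `NULL` picks
#'   2 (contrast) or 5 (binary) from the network.
#' @param chains number of chains (>= 2).
#' @param burn_in,kept_iterations,thin sampler schedule; `kept_iterations`
#'   must be divisible by `thin`.
#' @param seed integer seed; identical spec + seed gives bit-identical draws.
#' @return An object of class `nma_model_spec`.
#' @export
nma_model_spec <- function(effect_model = c("random", "fixed"),
                           consistency = c("consistent", "ume_inconsistent"),
                           reference = NULL,
                           prior_sd_effect = 10, prior_sd_baseline = 10,
                           tau_upper = NULL,
                           chains = 4, burn_in = 10000,
                           kept_iterations = 50000, thin = 2,
                           seed = 20230619) {
  effect_model <- match.arg(effect_model)
  consistency <- match.arg(consistency)
  stopifnot(chains >= 2, burn_in > 0, kept_iterations > 0, thin >= 1,
            kept_iterations %% thin == 0,
            prior_sd_effect > 0, prior_sd_baseline > 0)
  structure(list(effect_model = effect_model, consistency = consistency,
                 reference = reference, prior_sd_effect = prior_sd_effect,
                 prior_sd_baseline = prior_sd_baseline,
                 tau_upper = tau_upper, chains = as.integer(chains),
                 burn_in = as.integer(burn_in),
                 kept_iterations = as.integer(kept_iterations),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "nma_model_spec")
}

# Assemble sampler inputs shared by consistency / UME / node-split fits.
# X maps free effect parameters onto each trial's contrast mean.
.sampler_data <- function(network) {
  kind <- if (network$outcome$data_kind == "arm_binary") 1L else 0L
  tr <- network$trials
  if (kind == 0L) {
    d <- network$contrast
    list(kind = kind, trials = tr, y = d$log_effect, s = d$se,
         r_ref = integer(0), n_ref = integer(0),
         r_alt = integer(0), n_alt = integer(0))
  } else {
    arms <- network$arms
    key <- paste(arms$trial, arms$treatment)
    ia <- match(paste(tr$trial, tr$treat_alt), key)
    ir <- match(paste(tr$trial, tr$treat_ref), key)
    list(kind = kind, trials = tr, y = numeric(0), s = numeric(0),
         r_ref = as.integer(arms$events[ir]), n_ref = as.integer(arms$n[ir]),
         r_alt = as.integer(arms$events[ia]), n_alt = as.integer(arms$n[ia]))
  }
}

.run_sampler <- function(network, spec, X, param_names) {
  dat <- .sampler_data(network)
  random <- spec$effect_model == "random"
  tau_upper <- spec$tau_upper
  if (is.null(tau_upper)) tau_upper <- if (dat$kind == 1L) 5 else 2
  binary <- dat$kind == 1L
  mu_init <- if (binary)
    qlogis((dat$r_ref + 0.5) / (dat$n_ref + 1)) else numeric(nrow(X))
  offsets <- c(-2, -0.5, 0.5, 2)
  set.seed(spec$seed)
  out <- nma_mcmc_cpp(dat$kind, X, dat$y, dat$s,
                      dat$r_ref, dat$n_ref, dat$r_alt, dat$n_alt,
                      random, spec$prior_sd_effect, spec$prior_sd_baseline,
                      tau_upper, spec$chains, spec$burn_in,
                      spec$kept_iterations, spec$thin, offsets, mu_init)
  cn <- c(param_names,
          if (random) "tau",
          if (random) paste0("delta.", dat$trials$trial),
          if (binary) paste0("mu.", dat$trials$trial),
          "deviance")
  colnames(out$draws) <- cn
  out$tau_upper <- tau_upper
  out$data <- dat
  out$X <- X
  out
}

# consistency design: column per non-reference treatment, +1 alt / -1 ref
.basic_design <- function(network, reference) {
  trts <- network$treatments
  if (is.null(reference)) reference <- trts[1]
  if (!reference %in% trts) stop("reference treatment not in network")
  free <- setdiff(trts, reference)
  tr <- network$trials
  X <- matrix(0, nrow(tr), length(free), dimnames = list(tr$trial, free))
  for (i in seq_len(nrow(tr))) {
    if (tr$treat_alt[i] != reference) X[i, tr$treat_alt[i]] <- 1
    if (tr$treat_ref[i] != reference) X[i, tr$treat_ref[i]] <- -1
  }
  list(X = X, reference = reference, free = free)
}

#' Fit a Bayesian network meta-analysis
#'
#' Random- or fixed-effect model on a connected two-arm evidence network.
#' Contrast networks use a normal likelihood on the observed log hazard
#' ratios with their derived standard errors; binary networks use a
#' binomial-logit likelihood on arm-level counts with trial-specific
#' baselines.  Under the consistency model every contrast is a difference of
#' basic parameters `d_k` (log HR or log OR of treatment k versus the
#' reference, `d_ref = 0`); under `consistency = "ume_inconsistent"` every
#' observed comparison gets its own unrelated mean effect.  Sampling is
#' Metropolis-within-Gibbs (see the package vignette); convergence is
#' assessed by split-chain potential scale reduction factors and flagged,
#' never silently accepted.
#'
#' @param network an `evidence_network`.
#' @param spec an [nma_model_spec()].
#' @return An object of class `nma_fit`: posterior `draws` (matrix with
#'   named columns `d.<treatment>` or `d.<alt>.<ref>` for UME fits, `tau`,
#'   `delta.<trial>`, `mu.<trial>`, `deviance`), `chain` index,
#'   `convergence` report, acceptance rates, and the model metadata.
#' @examples
#' \donttest{
#' net <- load_fixture("pfs")
#' fit <- fit_nma(net, nma_model_spec(chains = 2, burn_in = 500,
#'                                    kept_iterations = 2000, thin = 1))
#' league_table(fit)
#' }
#' @export
fit_nma <- function(network, spec = nma_model_spec()) {
  stopifnot(inherits(network, "evidence_network"),
            inherits(spec, "nma_model_spec"))
  if (spec$consistency == "ume_inconsistent") {
    des <- .ume_design(network)
  } else {
    des <- .basic_design(network, spec$reference)
  }
  out <- .run_sampler(network, spec, des$X, des$names %||% paste0("d.", des$free))
  fit <- structure(list(
    draws = out$draws, chain = out$chain, accept = out$accept,
    treatments = network$treatments, reference = des$reference,
    consistency = spec$consistency, effect_model = spec$effect_model,
    outcome = network$outcome, network = network, spec = spec,
    tau_upper = out$tau_upper, X = out$X, data = out$data),
    class = "nma_fit")
  fit$convergence <- gelman_rubin(fit)
  fit$flagged <- !fit$convergence$pass
  if (fit$flagged)
    warning("MCMC convergence flagged: max PSRF = ",
            round(max(fit$convergence$psrf), 3))
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# UME design: one parameter per observed edge, oriented treat2-vs-treat1
.ume_design <- function(network) {
  tr <- network$trials; ed <- network$edges
  nm <- paste0("d.", ed$treat2, ".", ed$treat1)
  X <- matrix(0, nrow(tr), nrow(ed), dimnames = list(tr$trial, nm))
  for (i in seq_len(nrow(tr))) {
    j <- which((ed$treat1 == tr$treat_ref[i] & ed$treat2 == tr$treat_alt[i]) |
               (ed$treat2 == tr$treat_ref[i] & ed$treat1 == tr$treat_alt[i]))
    X[i, j] <- if (ed$treat2[j] == tr$treat_alt[i]) 1 else -1
  }
  list(X = X, reference = NULL, names = nm)
}

#' @export
print.nma_fit <- function(x, ...) {
  cat(sprintf("Bayesian NMA fit: %s, %s %s model, reference = %s\n",
              x$outcome$outcome_id, x$effect_model,
              if (x$consistency == "consistent") "consistency" else "UME",
              x$reference %||% "(none)"))
  cat(sprintf("  %d draws (%d chains), max PSRF %.3f (%s)\n",
              nrow(x$draws), x$spec$chains, max(x$convergence$psrf),
              if (x$convergence$pass) "converged" else "FLAGGED"))
  invisible(x)
}

# draws of d_k for every treatment (reference column is exactly 0)
.d_draws <- function(fit) {
  if (fit$consistency != "consistent")
    stop("treatment-level draws need a consistency fit")
  free <- setdiff(fit$treatments, fit$reference)
  d <- fit$draws[, paste0("d.", free), drop = FALSE]
  full <- cbind(matrix(0, nrow(d), 1), d)
  colnames(full) <- c(fit$reference, free)
  full[, fit$treatments, drop = FALSE]
}

#' League table of all pairwise relative effects
#'
#' For every ordered treatment pair summarises the posterior of
#' `exp(d_col - d_row)`: the relative effect (HR or OR) of the column
#' treatment versus the row treatment, as posterior median, 2.5% / 97.5%
#' percentiles, and a two-sided Bayesian p-value
#' `2 * min(Pr(diff > 0), Pr(diff < 0))`.
#'
#' @param fit a consistency `nma_fit`.
#' @param scale `"hr"` or `"or"`; only affects labelling (default follows
#'   the outcome's data kind).
#' @return An object of class `league_table`: list of matrices `median`,
#'   `low`, `high`, `bayes_p` (treatments x treatments, columns vs rows);
#'   the diagonal is 1 and `median[a,b] = 1/median[b,a]`.
#' @export
league_table <- function(fit, scale = NULL) {
  d <- .d_draws(fit)
  K <- ncol(d); trts <- colnames(d)
  if (is.null(scale))
    scale <- if (fit$outcome$data_kind == "arm_binary") "or" else "hr"
  med <- lo <- hi <- bp <- matrix(1, K, K, dimnames = list(trts, trts))
  for (a in seq_len(K)) for (b in seq_len(K)) {
    if (a == b) { bp[a, b] <- 1; next }
    diff <- d[, b] - d[, a]        # column b vs row a
    q <- quantile(diff, c(0.5, 0.025, 0.975), names = FALSE)
    med[a, b] <- exp(q[1]); lo[a, b] <- exp(q[2]); hi[a, b] <- exp(q[3])
    pg <- mean(diff > 0); pl <- mean(diff < 0)
    bp[a, b] <- 2 * min(pg, pl)
  }
  structure(list(median = med, low = lo, high = hi, bayes_p = bp,
                 scale = scale, treatments = trts,
                 outcome_id = fit$outcome$outcome_id),
            class = "league_table")
}

#' @export
print.league_table <- function(x, digits = 2, ...) {
  K <- length(x$treatments)
  out <- matrix("", K, K, dimnames = list(x$treatments, x$treatments))
  for (a in seq_len(K)) for (b in seq_len(K)) {
    out[a, b] <- if (a == b) x$treatments[a] else
      sprintf("%.*f (%.*f, %.*f)%s", digits, x$median[a, b], digits,
              x$low[a, b], digits, x$high[a, b],
              if (x$bayes_p[a, b] < 0.05) "*" else "")
  }
  cat(sprintf("League table (%s scale, column vs row), outcome %s\n",
              toupper(x$scale), x$outcome_id))
  print(out, quote = FALSE)
  cat("* Bayesian p < 0.05\n")
  invisible(x)
}

#' Extract one pairwise posterior summary from a fit
#'
#' @param fit a consistency `nma_fit`.
#' @param treat_alt,treat_ref the comparison: effect of `treat_alt` versus
#'   `treat_ref` on the ratio scale.
#' @return named vector `median`, `low`, `high`, `bayes_p`.
#' @export
relative_effect <- function(fit, treat_alt, treat_ref) {
  d <- .d_draws(fit)
  diff <- d[, treat_alt] - d[, treat_ref]
  q <- quantile(diff, c(0.5, 0.025, 0.975), names = FALSE)
  pg <- mean(diff > 0); pl <- mean(diff < 0)
  c(median = exp(q[1]), low = exp(q[2]), high = exp(q[3]),
    bayes_p = 2 * min(pg, pl))
}

#' Brooks--Gelman--Rubin convergence diagnostics
#'
#' Split-chain potential scale reduction factor (PSRF) for every effect
#' parameter (and `tau`), plus a crude effective sample size from the
#' pooled autocorrelation (Geyer initial positive sequence).  The fit
#' passes when all PSRFs are below 1.05.
#'
#' @param fit an `nma_fit` (>= 2 chains).
#' @return list with `psrf` (named), `ess` (named), `pass`.
#' @export
gelman_rubin <- function(fit) {
  draws <- fit$draws; chain <- fit$chain
  if (length(unique(chain)) < 2) stop("PSRF needs at least 2 chains")
  pars <- setdiff(colnames(draws), "deviance")
  pars <- pars[!startsWith(pars, "delta.") & !startsWith(pars, "mu.")]
  psrf <- vapply(pars, function(p) .split_psrf(draws[, p], chain), 0)
  ess <- vapply(pars, function(p) .ess(draws[, p], chain), 0)
  list(psrf = psrf, ess = ess, pass = all(psrf < 1.05))
}

.split_psrf <- function(x, chain) {
  seqs <- list()
  for (c in unique(chain)) {
    v <- x[chain == c]; n2 <- floor(length(v) / 2)
    seqs <- c(seqs, list(v[seq_len(n2)], v[n2 + seq_len(n2)]))
  }
  n <- min(lengths(seqs)); m <- length(seqs)
  seqs <- lapply(seqs, function(v) v[seq_len(n)])
  means <- vapply(seqs, mean, 0); vars <- vapply(seqs, var, 0)
  W <- mean(vars); B_n <- var(means)      # B/n
  if (W == 0) return(1)
  sqrt((n - 1) / n + B_n / W)
}

.ess <- function(x, chain, max_lag = 200) {
  chains <- split(x, chain)
  n <- min(lengths(chains)); m <- length(chains)
  if (var(x) == 0) return(m * n)
  rho_sum <- 0
  for (lag in seq(1, max_lag, by = 2)) {
    r1 <- mean(vapply(chains, function(v) .acf1(v[seq_len(n)], lag), 0))
    r2 <- mean(vapply(chains, function(v) .acf1(v[seq_len(n)], lag + 1), 0))
    if (r1 + r2 < 0) break
    rho_sum <- rho_sum + r1 + r2
  }
  m * n / (1 + 2 * rho_sum)
}

.acf1 <- function(v, lag) {
  n <- length(v)
  if (lag >= n) return(0)
  v <- v - mean(v)
  sum(v[seq_len(n - lag)] * v[lag + seq_len(n - lag)]) / sum(v * v)
}

#' Deviance information criterion
#'
#' `Dbar` is the posterior mean of the total residual deviance, `pD = Dbar -
#' D(posterior means)` the effective number of parameters, and `DIC = Dbar +
#' pD`.  The plug-in deviance uses posterior means of the trial-level
#' effects (and baselines for binary models).
#'
#' @param fit an `nma_fit`.
#' @return list with `Dbar`, `pD`, `DIC`.
#' @export
compute_dic <- function(fit) {
  draws <- fit$draws; dat <- fit$data
  Dbar <- mean(draws[, "deviance"])
  random <- fit$effect_model == "random"
  N <- nrow(dat$trials)
  if (random) {
    delta_hat <- colMeans(draws[, paste0("delta.", dat$trials$trial),
                                drop = FALSE])
  } else {
    b_hat <- colMeans(draws[, seq_len(ncol(fit$X)), drop = FALSE])
    delta_hat <- as.vector(fit$X %*% b_hat)
  }
  if (dat$kind == 0L) {
    Dhat <- sum(((dat$y - delta_hat) / dat$s)^2)
  } else {
    mu_hat <- colMeans(draws[, paste0("mu.", dat$trials$trial), drop = FALSE])
    p0 <- plogis(mu_hat); p1 <- plogis(mu_hat + delta_hat)
    dev1 <- .binom_dev(dat$r_ref, dat$n_ref, p0)
    dev2 <- .binom_dev(dat$r_alt, dat$n_alt, p1)
    Dhat <- sum(dev1) + sum(dev2)
  }
  pD <- Dbar - Dhat
  list(Dbar = Dbar, pD = pD, DIC = Dbar + pD)
}

.binom_dev <- function(r, n, p) {
  t1 <- ifelse(r > 0, r * log(r / (n * p)), 0)
  t2 <- ifelse(n - r > 0, (n - r) * log((n - r) / (n - n * p)), 0)
  2 * (t1 + t2)
}

#' Global inconsistency assessment by DIC comparison
#'
#' Fits the consistency model and the unrelated-mean-effects (UME) model
#' with identical likelihood and sampler settings and compares their DICs.
#' A consistency DIC well above the UME DIC signals global inconsistency.
#'
#' @param network an `evidence_network`.
#' @param spec an [nma_model_spec()]; the UME fit derives its seed from
#'   `spec$seed + 1`.
#' @return list with `consistency` and `ume` DIC lists and `dic_difference`
#'   (consistency minus UME).
#' @export
compare_consistency_dic <- function(network, spec = nma_model_spec()) {
  fit_c <- fit_nma(network, spec)
  spec_u <- spec
  spec_u$consistency <- "ume_inconsistent"
  spec_u$seed <- spec$seed + 1L
  fit_u <- fit_nma(network, spec_u)
  dic_c <- compute_dic(fit_c); dic_u <- compute_dic(fit_u)
  list(consistency = dic_c, ume = dic_u,
       dic_difference = dic_c$DIC - dic_u$DIC)
}
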