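# Frequentist pairwise meta-analysis of direct comparisons -------------------

.pairwise_result <- function(comparison, model, fit, k) {
  Q <- as.numeric(fit$QE); df <- max(k - 1L, 0L)
  structure(list(
    comparison = comparison, model = model, k = k,
    pooled_log_effect = as.numeric(fit$beta),
    pooled_se = as.numeric(fit$se),
    ci95 = c(as.numeric(fit$beta) - Z95 * as.numeric(fit$se),
             as.numeric(fit$beta) + Z95 * as.numeric(fit$se)),
    Q = Q, df = df,
    i_squared = i_squared(Q, df),
    tau_squared = as.numeric(fit$tau2),
    heterogeneity_estimable = k >= 2),
    class = "pairwise_result")
}

#' Inverse-variance fixed-effect pooling
#'
#' Pools study-level log effects with weights `1/se^2`.  Cochran's Q is the
#' weighted sum of squared deviations from the pooled mean.
#'
#' @param effects data frame (or list) with components `log_effect` and `se`.
#' @param comparison optional label (e.g. `c("alectinib", "crizotinib")`).
#' @return A `pairwise_result` with the pooled estimate, its SE, 95% CI,
#'   `Q`, `df`, `i_squared` (percent) and `tau_squared` (0 for fixed).
#' @export
pool_fixed <- function(effects, comparison = NULL) {
  y <- effects$log_effect; s <- effects$se
  if (length(y) < 1) stop("at least one study required")
  stopifnot(length(y) == length(s), all(s > 0))
  fit <- metafor::rma.uni(yi = y, sei = s, method = "FE")
  .pairwise_result(comparison, "fixed", fit, length(y))
}

#' DerSimonian--Laird random-effects pooling
#'
#' Method-of-moments between-trial variance
#' `tau^2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with fixed-effect
#' weights `w = 1/se^2`, then inverse-variance pooling with weights
#' `1/(se^2 + tau^2)`.  With a single study the fixed-effect result is
#' returned (`tau^2 = 0`, heterogeneity flagged not estimable).
#'
#' @inheritParams pool_fixed
#' @return A `pairwise_result`; `pooled_se` is never smaller than the
#'   fixed-effect one.
#' @export
pool_dersimonian_laird <- function(effects, comparison = NULL) {
  y <- effects$log_effect; s <- effects$se
  if (length(y) < 1) stop("at least one study required")
  if (length(y) == 1) {
    res <- pool_fixed(effects, comparison)
    res$model <- "random"
    return(res)
  }
  fit <- metafor::rma.uni(yi = y, sei = s, method = "DL")
  .pairwise_result(comparison, "random", fit, length(y))
}

#' Higgins I-squared heterogeneity statistic
#'
#' `I^2 = 100 * max(0, (Q - df) / Q)` percent; 0 when `Q = 0` or `df = 0`.
#'
#' @param Q Cochran's Q.
#' @param df degrees of freedom (number of studies minus 1).
#' @return percent in \[0, 100\].
#' @export
i_squared <- function(Q, df) {
  stopifnot(Q >= 0, df >= 0)
  if (Q == 0 || df == 0) return(0)
  100 * max(0, (Q - df) / Q)
}

# study-level effects (log scale) for every trial of a network, oriented
# experimental (treat_alt) vs control (treat_ref)
.study_effects <- function(network) {
  if (network$outcome$data_kind == "contrast_loghr") {
    d <- network$contrast
    return(data.frame(trial = d$trial, treat_ref = d$treat_ref,
                      treat_alt = d$treat_alt, log_effect = d$log_effect,
                      se = d$se, stringsAsFactors = FALSE))
  }
  tr <- network$trials; arms <- network$arms
  key <- paste(arms$trial, arms$treatment)
  res <- lapply(seq_len(nrow(tr)), function(i) {
    a <- arms[key == paste(tr$trial[i], tr$treat_alt[i]), ]
    r <- arms[key == paste(tr$trial[i], tr$treat_ref[i]), ]
    lo <- trial_log_or(a$events, a$n, r$events, r$n)
    if (is.null(lo)) return(NULL)
    data.frame(trial = tr$trial[i], treat_ref = tr$treat_ref[i],
               treat_alt = tr$treat_alt[i], log_effect = lo$log_or,
               se = lo$se, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Pairwise meta-analysis of every direct comparison in a network
#'
#' For each edge with direct evidence, pools the trial-level log effects
#' (log HR for contrast networks, log OR via [trial_log_or()] for binary
#' networks) under both the fixed-effect and DerSimonian--Laird
#' random-effects models.
#'
#' @param network an `evidence_network`.
#' @return data frame with one row per edge x model: pooled estimate, 95%
#'   CI (all on the exponentiated ratio scale), `Q`, `df`, `i_squared`,
#'   `tau_squared`, and a `het_estimable` flag (FALSE for single-study
#'   comparisons).
#' @export
pairwise_all <- function(network) {
  eff <- .study_effects(network)
  out <- list()
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    # orientation: treat2 (experimental side) vs treat1 as observed
    rows <- eff[(eff$treat_ref == e$treat1 & eff$treat_alt == e$treat2) |
                (eff$treat_ref == e$treat2 & eff$treat_alt == e$treat1), ]
    flip <- rows$treat_alt == e$treat1
    rows$log_effect[flip] <- -rows$log_effect[flip]
    for (fn in list(pool_fixed, pool_dersimonian_laird)) {
      p <- fn(rows, comparison = c(e$treat2, e$treat1))
      out[[length(out) + 1L]] <- data.frame(
        treat_alt = e$treat2, treat_ref = e$treat1, model = p$model,
        k = p$k, estimate = exp(p$pooled_log_effect),
        ci_low = exp(p$ci95[1]), ci_high = exp(p$ci95[2]),
        Q = p$Q, df = p$df, i_squared = p$i_squared,
        tau_squared = p$tau_squared, het_estimable = p$heterogeneity_estimable,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Forest-plot data for one direct comparison
#'
#' Study rows (effect, CI, inverse-variance weight in percent) followed by
#' the pooled fixed-effect and random-effects rows, ready for plotting or
#' CSV export.
#'
#' @param network an `evidence_network`.
#' @param treat_alt,treat_ref the comparison, experimental vs control.
#' @return data frame with columns `study`, `estimate`, `ci_low`,
#'   `ci_high`, `weight_pct`, `type`.
#' @export
forest_data <- function(network, treat_alt, treat_ref) {
  eff <- .study_effects(network)
  rows <- eff[(eff$treat_ref == treat_ref & eff$treat_alt == treat_alt) |
              (eff$treat_ref == treat_alt & eff$treat_alt == treat_ref), ]
  if (nrow(rows) == 0) stop("no direct evidence for this comparison")
  flip <- rows$treat_alt == treat_ref
  rows$log_effect[flip] <- -rows$log_effect[flip]
  w <- 1 / rows$se^2
  fe <- pool_fixed(rows); re <- pool_dersimonian_laird(rows)
  rbind(
    data.frame(study = rows$trial, estimate = exp(rows$log_effect),
               ci_low = exp(rows$log_effect - Z95 * rows$se),
               ci_high = exp(rows$log_effect + Z95 * rows$se),
               weight_pct = 100 * w / sum(w), type = "study"),
    data.frame(study = "FE pooled", estimate = exp(fe$pooled_log_effect),
               ci_low = exp(fe$ci95[1]), ci_high = exp(fe$ci95[2]),
               weight_pct = 100, type = "pooled_fixed"),
    data.frame(study = "RE pooled", estimate = exp(re$pooled_log_effect),
               ci_low = exp(re$ci95[1]), ci_high = exp(re$ci95[2]),
               weight_pct = 100, type = "pooled_random"))
}
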