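# Publication bias and small-study effects ------------------------------------

#' Comparison-adjusted funnel data for a network
#'
#' In a network the studies estimate different contrasts, so each study's
#' effect is centered on the fixed-effect pooled estimate of its own direct
#' comparison before plotting against its standard error.  Contour
#' boundaries for two-sided p = 0.10, 0.05 and 0.01 are emitted as
#' `+/- z * se` rays.
#'
#' @param network an `evidence_network`.
#' @return list with `points` (study, treat_alt, treat_ref, centered_effect,
#'   se, imputed = FALSE) and `contours` (p, z).
#' @export
comparison_adjusted_funnel <- function(network) {
  eff <- .study_effects(network)
  eff$centered_effect <- NA_real_
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    idx <- (eff$treat_ref == e$treat1 & eff$treat_alt == e$treat2) |
           (eff$treat_ref == e$treat2 & eff$treat_alt == e$treat1)
    rows <- eff[idx, ]
    flip <- rows$treat_alt == e$treat1
    rows$log_effect[flip] <- -rows$log_effect[flip]
    pooled <- pool_fixed(rows)$pooled_log_effect
    centered <- rows$log_effect - pooled
    centered[flip] <- -centered[flip]       # back to the study's orientation
    eff$centered_effect[idx] <- centered
  }
  pts <- data.frame(study = eff$trial, treat_alt = eff$treat_alt,
                    treat_ref = eff$treat_ref,
                    centered_effect = eff$centered_effect, se = eff$se,
                    imputed = FALSE, stringsAsFactors = FALSE)
  contours <- data.frame(p = c(0.10, 0.05, 0.01),
                         z = qnorm(1 - c(0.10, 0.05, 0.01) / 2))
  list(points = pts, contours = contours)
}

#' Egger regression test for funnel asymmetry
#'
#' Classic Egger test: ordinary least-squares regression of the
#' standardized effects `y/se` on precision `1/se`; the intercept estimates
#' the small-study bias and is tested against zero with a t-test on `n - 2`
#' degrees of freedom.
#'
#' @param effects data frame with `log_effect` and `se` (>= 3 studies).
#' @return list with `intercept`, `intercept_se`, `t`, `df`, `p`; or a
#'   result with `computable = FALSE` for fewer than 3 studies.
#' @export
egger_test <- function(effects) {
  y <- effects$log_effect; s <- effects$se
  if (length(y) < 3)
    return(list(computable = FALSE, intercept = NA_real_,
                intercept_se = NA_real_, t = NA_real_,
                df = length(y) - 2, p = NA_real_))
  fit <- stats::lm(I(y / s) ~ I(1 / s))
  ct <- summary(fit)$coefficients
  list(computable = TRUE, intercept = ct[1, 1], intercept_se = ct[1, 2],
       t = ct[1, 3], df = length(y) - 2L, p = ct[1, 4])
}

#' Begg--Mazumdar rank correlation test
#'
#' Kendall's tau between the standardized deviates
#' `(y_i - pooled) / sqrt(se_i^2 - pooled_var)` and the sampling variances
#' `se_i^2`, where `pooled` is the fixed-effect estimate and `pooled_var`
#' its variance.  The p-value uses the normal approximation with the
#' standard tie correction.
#'
#' @param effects data frame with `log_effect` and `se` (>= 3 studies).
#' @return list with `kendall_tau`, `z`, `p` (and `computable`).
#' @export
begg_test <- function(effects) {
  y <- effects$log_effect; s <- effects$se
  n <- length(y)
  if (n < 3)
    return(list(computable = FALSE, kendall_tau = NA_real_, z = NA_real_,
                p = NA_real_))
  w <- 1 / s^2
  pooled <- sum(w * y) / sum(w)
  vstar <- s^2 - 1 / sum(w)
  u <- (y - pooled) / sqrt(pmax(vstar, .Machine$double.eps))
  v <- s^2
  # concordant / discordant pairs
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pr <- (u[j] - u[i]) * (v[j] - v[i])
    if (pr > 0) conc <- conc + 1 else if (pr < 0) disc <- disc + 1
  }
  npairs <- n * (n - 1) / 2
  tau <- (conc - disc) / npairs
  tie_term <- function(x) {
    t <- table(x); sum(t * (t - 1) * (2 * t + 5))
  }
  var_s <- (n * (n - 1) * (2 * n + 5) - tie_term(u) - tie_term(v)) / 18
  S <- conc - disc
  z <- if (var_s > 0) (S - sign(S) * 1) / sqrt(var_s) else 0  # continuity corr.
  if (S == 0) z <- 0
  list(computable = TRUE, kendall_tau = tau, z = z,
       p = 2 * pnorm(-abs(z)))
}

#' Duval--Tweedie trim-and-fill adjustment
#'
#' Iteratively estimates the number `k0` of studies missing from one side
#' of the funnel with the rank-based `L0` (default) or `R0` estimator:
#' the `k0` most extreme studies on the over-represented side are trimmed,
#' the fixed-effect center is re-estimated from the trimmed set, and the
#' estimator is re-evaluated until `k0` stabilises.  The trimmed studies
#' are then mirror-imputed about the final center on the deficient side,
#' which is chosen automatically from the sign of the rank-sum asymmetry
#' statistic unless given.  Reported pooled estimates (original and
#' adjusted, observed + imputed) use DerSimonian--Laird random-effects
#' pooling.
#'
#' @param effects data frame with `log_effect` and `se` (>= 3 studies).
#' @param estimator `"L0"` (default) or `"R0"`.
#' @param side `"left"`, `"right"` or `NULL` (automatic): the side where
#'   missing studies are presumed and imputed.
#' @return An object of class `trim_fill_result`: `k0`, `side`,
#'   `original_pooled` and `adjusted_pooled` (estimate + 95% CI on the
#'   ratio scale), and `filled` (the imputed studies' effects and SEs).
#' @export
trim_and_fill <- function(effects, estimator = c("L0", "R0"), side = NULL) {
  estimator <- match.arg(estimator)
  y <- effects$log_effect; s <- effects$se
  n <- length(y)
  if (n < 3) stop("trim-and-fill needs at least 3 studies")
  fe_est <- function(yy, ss) {
    w <- 1 / ss^2
    sum(w * yy) / sum(w)
  }
  if (is.null(side)) {
    # rank-sum asymmetry around the overall fixed-effect center: excess
    # mass on the right means the missing studies sit on the left
    dev <- y - fe_est(y, s)
    Tr <- sum(rank(abs(dev))[dev > 0])
    side <- if (Tr > n * (n + 1) / 4) "left" else "right"
  }
  side <- match.arg(side, c("left", "right"))
  # canonical form trims the largest effects and imputes on the left;
  # imputing on the right is the mirror image
  z <- if (side == "left") y else -y
  k0 <- 0L
  for (iter in seq_len(50)) {
    keep <- if (k0 > 0) order(z, decreasing = TRUE)[-seq_len(k0)] else
      seq_len(n)
    center <- fe_est(z[keep], s[keep])
    dev <- z - center
    r <- rank(abs(dev))
    Tn <- sum(r[dev > 0])
    k_new <- if (estimator == "L0") {
      max(0, round((4 * Tn - n * (n + 1)) / (2 * n - 1)))
    } else {
      # R0: length of the run of top |dev| ranks on the positive side
      ord <- order(r, decreasing = TRUE)
      run <- 0L
      for (i in ord) {
        if (dev[i] > 0) run <- run + 1L else break
      }
      max(0L, run - 1L)
    }
    if (k_new == k0) break
    if (iter == 50) stop("trim-and-fill failed to converge after 50 ",
                         "iterations (k0 oscillating at ", k0, " vs ", k_new, ")")
    k0 <- as.integer(k_new)
  }
  if (k0 > 0) {
    trim_idx <- order(z, decreasing = TRUE)[seq_len(k0)]
    center <- fe_est(z[-trim_idx], s[-trim_idx])
    fill_z <- 2 * center - z[trim_idx]
    fill_y <- if (side == "left") fill_z else -fill_z
    filled <- data.frame(log_effect = fill_y, se = s[trim_idx])
  } else {
    filled <- data.frame(log_effect = numeric(0), se = numeric(0))
  }
  orig <- metafor::rma.uni(yi = y, sei = s, method = "DL")
  adj <- if (k0 > 0)
    metafor::rma.uni(yi = c(y, filled$log_effect), sei = c(s, filled$se),
                     method = "DL")
  else orig
  pack <- function(f) c(estimate = exp(as.numeric(f$beta)),
                        low = exp(f$ci.lb), high = exp(f$ci.ub))
  structure(list(k0 = k0, side = side,
                 original_pooled = pack(orig), adjusted_pooled = pack(adj),
                 filled = filled),
            class = "trim_fill_result")
}

#' @export
print.trim_fill_result <- function(x, ...) {
  f <- function(v) sprintf("%.3f (%.3f, %.3f)", v[1], v[2], v[3])
  cat(sprintf("Trim-and-fill: k0 = %d imputed on the %s side\n", x$k0, x$side))
  cat("  original: ", f(x$original_pooled), "\n  adjusted: ",
      f(x$adjusted_pooled), "\n")
  invisible(x)
}

#' Publication-bias summary for one outcome network
#'
#' Egger, Begg and trim-and-fill applied to the network's study-level
#' effects, all oriented experimental versus control.
#'
#' @param network an `evidence_network`.
#' @return list with `egger`, `begg`, `trim_fill`, `funnel`.
#' @export
publication_bias <- function(network) {
  eff <- .study_effects(network)
  list(egger = egger_test(eff), begg = begg_test(eff),
       trim_fill = trim_and_fill(eff),
       funnel = comparison_adjusted_funnel(network))
}
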