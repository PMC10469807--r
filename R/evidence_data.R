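#' Outcome specification
#'
#' Describes one endpoint of an evidence network: how its trial data are
#' encoded and which direction of effect is clinically better.  Survival
#' endpoints (PFS, OS, PFS with brain metastases) arrive as log hazard-ratio
#' contrasts, response/safety endpoints as arm-level binomial counts.
#'
#' @param outcome_id short outcome label, e.g. `"pfs"`.
#' @param data_kind `"contrast_loghr"` or `"arm_binary"`.
#' @param better_direction `"lower"` when a smaller relative effect (HR or OR
#'   below 1) is preferable (survival, adverse events), `"higher"` when a
#'   larger effect is preferable (response).
#' @return An object of class `outcome_spec`.
#' @export
outcome_spec <- function(outcome_id,
                         data_kind = c("contrast_loghr", "arm_binary"),
                         better_direction = c("lower", "higher")) {
  stopifnot(is.character(outcome_id), length(outcome_id) == 1L)
  structure(list(outcome_id = outcome_id,
                 data_kind = match.arg(data_kind),
                 better_direction = match.arg(better_direction)),
            class = "outcome_spec")
}

#' Log hazard ratio and its standard error from a printed HR and 95% CI
#'
#' Published time-to-event comparisons report a hazard ratio with a 95%
#' confidence interval.  On the log scale the interval is (asymptotically)
#' symmetric, so the standard error is recovered from the interval width:
#' `se = (log(ci_high) - log(ci_low)) / (2 * qnorm(0.975))`.
#'
#' @param hr hazard ratio (positive).
#' @param ci_low,ci_high 95% confidence limits, `0 < ci_low <= hr <= ci_high`.
#' @return list with `log_effect` and `se`.
#' @examples
#' derive_log_hr(0.37, 0.26, 0.52)
#' @export
derive_log_hr <- function(hr, ci_low, ci_high) {
  if (any(!is.finite(c(hr, ci_low, ci_high))) || any(c(hr, ci_low, ci_high) <= 0))
    stop("hr, ci_low and ci_high must all be positive")
  if (ci_low > ci_high) stop("ci_low exceeds ci_high")
  if (ci_low == ci_high)
    stop("zero-width confidence interval: standard error undefined")
  if (hr < ci_low || hr > ci_high)
    stop("hr must lie inside [ci_low, ci_high]")
  list(log_effect = log(hr), se = (log(ci_high) - log(ci_low)) / (2 * Z95))
}

#' Reconstruct an event count from a printed percentage
#'
#' Arm-level outcomes are printed as percentages; the underlying count is
#' recovered as `round(percent * n / 100)` (round half to even).
#'
#' @param percent event percentage in \[0, 100\].
#' @param n arm size (positive integer).
#' @return integer event count in \[0, n\].
#' @examples
#' reconstruct_events(92.23, 103)  # 95 responders
#' @export
reconstruct_events <- function(percent, n) {
  stopifnot(is.numeric(percent), is.numeric(n), n >= 1)
  if (any(percent < 0 | percent > 100))
    stop("percent must lie in [0, 100]")
  ev <- as.integer(round(percent * n / 100))
  pmin(pmax(ev, 0L), as.integer(n))
}

#' Per-trial log odds ratio with Woolf standard error
#'
#' Computes `log((r1 (n0 - r0)) / (r0 (n1 - r1)))` with standard error
#' `sqrt(1/r1 + 1/(n1-r1) + 1/r0 + 1/(n0-r0))`.  When any of the four cells
#' is zero, 0.5 is added to all cells (Haldane--Anscombe correction).
#' Double-zero or double-full tables carry no information about the odds
#' ratio and are rejected.
#'
#' @param r1,n1 events and size of the experimental arm.
#' @param r0,n0 events and size of the control arm.
#' @return list with `log_or` and `se`, or `NULL` (with a warning) for
#'   uninformative tables.
#' @export
trial_log_or <- function(r1, n1, r0, n0) {
  stopifnot(r1 >= 0, r1 <= n1, r0 >= 0, r0 <= n0)
  if ((r1 == 0 && r0 == 0) || (r1 == n1 && r0 == n0)) {
    warning("uninformative 2x2 table (double-zero or double-full); excluded")
    return(NULL)
  }
  a <- r1; b <- n1 - r1; c <- r0; d <- n0 - r0
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  list(log_or = log(a * d / (b * c)), se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

# connected components over a treatment set given trial edges
.components <- function(treatments, edges) {
  comp <- setNames(seq_along(treatments), treatments)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      a <- edges$treat1[i]; b <- edges$treat2[i]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(names(comp), comp)
}

#' Assemble an evidence network from trial-level observations
#'
#' Observations are supplied as a data frame in one of two layouts:
#' * contrast (`data_kind = "contrast_loghr"`): columns `trial`,
#'   `treat_ref`, `treat_alt`, `log_effect`, `se` -- one row per two-arm
#'   trial, effect oriented experimental (`treat_alt`) versus control
#'   (`treat_ref`);
#' * arm-level binary (`data_kind = "arm_binary"`): columns `trial`,
#'   `treatment`, `n`, `events` -- exactly two rows per trial, the
#'   experimental arm listed first and the control arm second.
#'
#' The network records the deduplicated treatment set (in order of first
#' appearance unless `treatment_order` is given), per-edge trial counts, and
#' is checked for connectivity: every treatment must be reachable from every
#' other through head-to-head comparisons, otherwise no common ranking
#' exists and an error names the isolated component.
#'
#' @param observations data frame as described above.
#' @param outcome an [outcome_spec()].
#' @param treatment_order optional character vector fixing the node order
#'   (the first treatment is the default NMA reference).
#' @param display_names optional named character vector of display labels.
#' @return An object of class `evidence_network` with elements `treatments`,
#'   `outcome`, `trials` (per-trial ref/alt orientation), `contrast` or
#'   `arms`, and `edges`.
#' @export
build_network <- function(observations, outcome, treatment_order = NULL,
                          display_names = NULL) {
  stopifnot(inherits(outcome, "outcome_spec"), is.data.frame(observations),
            nrow(observations) > 0)
  kind <- outcome$data_kind
  if (kind == "contrast_loghr") {
    need <- c("trial", "treat_ref", "treat_alt", "log_effect", "se")
    if (!all(need %in% names(observations)))
      stop("contrast observations need columns: ", paste(need, collapse = ", "))
    obs <- observations[, need]
    if (any(obs$se <= 0)) stop("standard errors must be positive")
    if (any(obs$treat_ref == obs$treat_alt))
      stop("treat_ref and treat_alt must differ")
    if (anyDuplicated(obs$trial)) stop("duplicate trial ids")
    trials <- obs[, c("trial", "treat_ref", "treat_alt")]
    seen <- unique(c(rbind(obs$treat_alt, obs$treat_ref)))
    arms <- NULL
    contrast <- obs
  } else {
    need <- c("trial", "treatment", "n", "events")
    if (!all(need %in% names(observations)))
      stop("arm observations need columns: ", paste(need, collapse = ", "))
    obs <- observations[, need]
    if (any(obs$n < 1) || any(obs$events < 0) || any(obs$events > obs$n))
      stop("need 0 <= events <= n and n >= 1 in every arm")
    if (anyDuplicated(obs[, c("trial", "treatment")]))
      stop("more than one record per (trial, treatment)")
    tab <- table(obs$trial)
    if (any(tab != 2))
      stop("every trial needs exactly two arms; offending: ",
           paste(names(tab)[tab != 2], collapse = ", "))
    obs <- obs[order(match(obs$trial, unique(obs$trial))), ]  # stable: keeps arm order
    alt <- obs[!duplicated(obs$trial), ]                 # first-listed arm
    ref <- obs[duplicated(obs$trial), ]                  # second-listed arm
    trials <- data.frame(trial = alt$trial, treat_ref = ref$treatment,
                         treat_alt = alt$treatment, stringsAsFactors = FALSE)
    if (any(trials$treat_ref == trials$treat_alt))
      stop("the two arms of a trial must have different treatments")
    seen <- unique(c(rbind(trials$treat_alt, trials$treat_ref)))
    arms <- obs
    contrast <- NULL
  }
  if (!is.null(treatment_order)) {
    unknown <- setdiff(seen, treatment_order)
    if (length(unknown))
      stop("unknown treatment label(s): ", paste(unknown, collapse = ", "))
    treatments <- intersect(treatment_order, seen)
  } else treatments <- seen
  if (length(treatments) < 2) stop("a network needs at least 2 treatments")

  # per-edge trial counts (unordered pairs, ordered by treatment list)
  a <- pmin(match(trials$treat_ref, treatments), match(trials$treat_alt, treatments))
  b <- pmax(match(trials$treat_ref, treatments), match(trials$treat_alt, treatments))
  key <- paste(a, b)
  edges <- data.frame(treat1 = treatments[a[!duplicated(key)]],
                      treat2 = treatments[b[!duplicated(key)]],
                      n_trials = as.vector(table(key)[unique(key)]),
                      stringsAsFactors = FALSE)
  edges <- edges[order(match(edges$treat1, treatments),
                       match(edges$treat2, treatments)), ]
  rownames(edges) <- NULL

  comp <- .components(treatments, edges)
  if (length(comp) > 1) {
    iso <- comp[[which.min(lengths(comp))]]
    stop("evidence network is disconnected; isolated component: ",
         paste(iso, collapse = ", "))
  }
  if (is.null(display_names)) display_names <- setNames(treatments, treatments)
  structure(list(treatments = treatments,
                 display_names = display_names[treatments],
                 outcome = outcome, trials = trials,
                 contrast = contrast, arms = arms, edges = edges),
            class = "evidence_network")
}

#' @export
print.evidence_network <- function(x, ...) {
  cat("Evidence network:", x$outcome$outcome_id,
      sprintf("(%s, better = %s)\n", x$outcome$data_kind,
              x$outcome$better_direction))
  cat(sprintf("  %d treatments, %d trials, %d direct comparisons\n",
              length(x$treatments), nrow(x$trials), nrow(x$edges)))
  for (i in seq_len(nrow(x$edges)))
    cat(sprintf("    %s vs %s: %d trial(s)\n", x$edges$treat2[i],
                x$edges$treat1[i], x$edges$n_trials[i]))
  invisible(x)
}

#' Write / read an evidence network in the delimited exchange format
#'
#' Contrast networks use columns `trial,treat_ref,treat_alt,hr,ci_low,
#' ci_high,outcome`; binary networks use `trial,treatment,n,percent,outcome`
#' (arms written experimental first, control second).  Round-tripping a
#' network through this format reproduces its observations.
#'
#' @param network an `evidence_network`.
#' @param path file path.
#' @name network_csv
#' @export
write_network_csv <- function(network, path) {
  if (network$outcome$data_kind == "contrast_loghr") {
    d <- network$contrast
    out <- data.frame(trial = d$trial, treat_ref = d$treat_ref,
                      treat_alt = d$treat_alt,
                      hr = exp(d$log_effect),
                      ci_low = exp(d$log_effect - Z95 * d$se),
                      ci_high = exp(d$log_effect + Z95 * d$se),
                      outcome = network$outcome$outcome_id)
  } else {
    d <- network$arms
    out <- data.frame(trial = d$trial, treatment = d$treatment, n = d$n,
                      percent = 100 * d$events / d$n,
                      outcome = network$outcome$outcome_id)
  }
  write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param outcome an [outcome_spec()] describing the stored outcome.
#' @param ... passed on to [build_network()].
#' @rdname network_csv
#' @export
read_network_csv <- function(path, outcome, ...) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (outcome$data_kind == "contrast_loghr") {
    eff <- Map(derive_log_hr, d$hr, d$ci_low, d$ci_high)
    obs <- data.frame(trial = d$trial, treat_ref = d$treat_ref,
                      treat_alt = d$treat_alt,
                      log_effect = vapply(eff, `[[`, 0, "log_effect"),
                      se = vapply(eff, `[[`, 0, "se"),
                      stringsAsFactors = FALSE)
  } else {
    obs <- data.frame(trial = d$trial, treatment = d$treatment, n = d$n,
                      events = reconstruct_events(d$percent, d$n),
                      stringsAsFactors = FALSE)
  }
  build_network(obs, outcome, ...)
}
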