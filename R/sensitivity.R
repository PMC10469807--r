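# Sensitivity analyses --------------------------------------------------------

#' Leave-one-study-out re-analysis
#'
#' Refits the NMA once per excluded trial.  When an exclusion drops a
#' treatment entirely (the trial was that treatment's only evidence) the
#' remaining network is refit without it; when it disconnects the network
#' the exclusion is reported as `"disconnects network"` rather than raised.
#' Each refit derives its seed from `spec$seed` plus the trial index, so
#' the whole analysis is reproducible.
#'
#' @param network an `evidence_network`.
#' @param spec an [nma_model_spec()].
#' @param comparisons optional data frame (`treat_alt`, `treat_ref`)
#'   restricting the reported contrasts; default: all pairs with the
#'   excluded trial's own comparison first.
#' @return data frame `excluded_trial`, `treat_alt`, `treat_ref`, `median`,
#'   `low`, `high`, `status` (`"ok"`, `"treatment dropped"`, or
#'   `"disconnects network"`).
#' @export
leave_one_out <- function(network, spec = nma_model_spec(),
                          comparisons = NULL) {
  tr <- network$trials
  out <- list()
  for (i in seq_len(nrow(tr))) {
    trial <- tr$trial[i]
    sub <- .drop_trial(network, trial)
    if (is.null(sub)) {
      out[[length(out) + 1L]] <- data.frame(
        excluded_trial = trial, treat_alt = NA, treat_ref = NA,
        median = NA_real_, low = NA_real_, high = NA_real_,
        status = "disconnects network", stringsAsFactors = FALSE)
      next
    }
    dropped <- setdiff(network$treatments, sub$treatments)
    status <- if (length(dropped))
      paste("treatment dropped:", paste(dropped, collapse = ",")) else "ok"
    s <- spec
    s$seed <- spec$seed + i
    if (!is.null(s$reference) && !s$reference %in% sub$treatments)
      s$reference <- NULL
    fit <- fit_nma(sub, s)
    cmp <- comparisons
    if (is.null(cmp)) {
      K <- sub$treatments
      cmp <- expand.grid(treat_alt = K, treat_ref = K,
                         stringsAsFactors = FALSE)
      cmp <- cmp[cmp$treat_alt != cmp$treat_ref, ]
    } else {
      cmp <- cmp[cmp$treat_alt %in% sub$treatments &
                 cmp$treat_ref %in% sub$treatments, , drop = FALSE]
    }
    for (j in seq_len(nrow(cmp))) {
      re <- relative_effect(fit, cmp$treat_alt[j], cmp$treat_ref[j])
      out[[length(out) + 1L]] <- data.frame(
        excluded_trial = trial, treat_alt = cmp$treat_alt[j],
        treat_ref = cmp$treat_ref[j], median = re["median"],
        low = re["low"], high = re["high"], status = status,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# network minus one trial; NULL if the remainder is disconnected
.drop_trial <- function(network, trial) {
  if (network$outcome$data_kind == "contrast_loghr") {
    obs <- network$contrast[network$contrast$trial != trial, , drop = FALSE]
  } else {
    obs <- network$arms[network$arms$trial != trial, , drop = FALSE]
  }
  if (nrow(obs) == 0 || length(unique(obs$trial)) < 1) return(NULL)
  tryCatch(build_network(obs, network$outcome,
                         treatment_order = network$treatments,
                         display_names = network$display_names),
           error = function(e) {
             if (grepl("disconnected", conditionMessage(e))) NULL
             else stop(e)
           })
}

#' Re-analysis excluding one named trial
#'
#' @param network an `evidence_network`.
#' @param trial trial id to exclude (e.g. `"PROFILE1029"`).
#' @param spec an [nma_model_spec()].
#' @return the `nma_fit` on the reduced network.
#' @export
exclude_trial <- function(network, trial, spec = nma_model_spec()) {
  if (!trial %in% network$trials$trial) stop("unknown trial: ", trial)
  sub <- .drop_trial(network, trial)
  if (is.null(sub)) stop("excluding ", trial, " disconnects the network")
  if (!is.null(spec$reference) && !spec$reference %in% sub$treatments)
    spec$reference <- NULL
  fit_nma(sub, spec)
}

#' Bland--Altman agreement of fixed- and random-effects league tables
#'
#' Pairs the log-scale point estimates of the same comparisons from a
#' fixed-effect and a random-effects fit and summarises their differences:
#' mean difference and mean +/- 1.96 SD limits of agreement.  Tight limits
#' around zero indicate that the extra between-trial variability does not
#' move the estimates.
#'
#' @param fe_league,re_league [league_table()]s over identical treatments.
#' @return list with `mean_diff`, `limits`, and the per-comparison
#'   `differences` table (log scale).
#' @export
bland_altman_fe_re <- function(fe_league, re_league) {
  if (!identical(fe_league$treatments, re_league$treatments))
    stop("league tables cover different comparison sets")
  trts <- fe_league$treatments
  K <- length(trts)
  rows <- list()
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    fe <- log(fe_league$median[a, b]); re <- log(re_league$median[a, b])
    rows[[length(rows) + 1L]] <- data.frame(
      treat_alt = trts[b], treat_ref = trts[a],
      fe_log = fe, re_log = re, diff = fe - re, mean = (fe + re) / 2)
  }
  d <- do.call(rbind, rows)
  m <- mean(d$diff); s <- sd(d$diff)
  if (is.na(s)) s <- 0
  list(mean_diff = m, limits = c(lower = m - Z95 * s, upper = m + Z95 * s),
       differences = d)
}
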