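# Bundled 12-trial ALK-inhibitor dataset -------------------------------------

.alk_treatment_order <- c("crizotinib", "alectinib", "ceritinib", "brigatinib",
                          "lorlatinib", "ensartinib", "chemotherapy")
.alk_display <- c(crizotinib = "Crizotinib", alectinib = "Alectinib",
                  ceritinib = "Ceritinib", brigatinib = "Brigatinib",
                  lorlatinib = "Lorlatinib", ensartinib = "Ensartinib",
                  chemotherapy = "Chemotherapy")

.alk_outcomes <- list(
  pfs             = c(kind = "contrast_loghr", dir = "lower"),
  os              = c(kind = "contrast_loghr", dir = "lower"),
  pfs_bm          = c(kind = "contrast_loghr", dir = "lower"),
  orr             = c(kind = "arm_binary",     dir = "higher"),
  sae             = c(kind = "arm_binary",     dir = "lower"),
  discontinuation = c(kind = "arm_binary",     dir = "lower"))

#' Load one outcome network of the bundled ALK-inhibitor dataset
#'
#' Twelve phase-III randomized trials (n = 3169) comparing crizotinib,
#' alectinib, ceritinib, brigatinib, lorlatinib, ensartinib and
#' platinum-based chemotherapy, as published trial-level summaries:
#' hazard ratios with 95% CIs for `"pfs"`, `"os"` and `"pfs_bm"`
#' (progression-free survival in patients with baseline brain metastases),
#' and arm-level event percentages for `"orr"`, `"sae"` (grade >= 3 adverse
#' events) and `"discontinuation"` (AEs leading to treatment
#' discontinuation).  Event counts are reconstructed from the printed
#' percentages and intention-to-treat arm sizes via [reconstruct_events()].
#'
#' The PROFILE1007 trial did not report discontinuation data, so the
#' `"discontinuation"` network holds 11 trials.  The CROWN discontinuation
#' percentages as printed in the source table (63.76% / 58.45%) are far
#' above the rates its primary publication describes (about 7% / 9%); the
#' row is transcribed as printed and flagged in the network's `notes`.
#'
#' @param outcome_id one of `"pfs"`, `"os"`, `"pfs_bm"`, `"orr"`, `"sae"`,
#'   `"discontinuation"`.
#' @return An [build_network()] `evidence_network`.
#' @examples
#' net <- load_fixture("pfs")
#' net$edges
#' @export
load_fixture <- function(outcome_id) {
  if (!outcome_id %in% names(.alk_outcomes))
    stop("unknown outcome id '", outcome_id, "'; available: ",
         paste(names(.alk_outcomes), collapse = ", "))
  meta <- .alk_outcomes[[outcome_id]]
  spec <- outcome_spec(outcome_id, meta[["kind"]], meta[["dir"]])
  file <- if (meta[["kind"]] == "contrast_loghr") "alk_hazard_ratios.csv"
          else "alk_binary_arms.csv"
  path <- system.file("extdata", file, package = "alknma", mustWork = TRUE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  d <- d[d$outcome == outcome_id, , drop = FALSE]
  if (meta[["kind"]] == "contrast_loghr") {
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
  net <- build_network(obs, spec, treatment_order = .alk_treatment_order,
                       display_names = .alk_display)
  if (outcome_id == "discontinuation")
    net$notes <- paste("CROWN discontinuation percentages transcribed as",
                       "printed (63.76/58.45) despite conflicting with the",
                       "trial publication (~7/9)")
  net
}
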