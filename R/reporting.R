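# Report assembly -------------------------------------------------------------

#' Read a plain-text key=value configuration file
#'
#' Blank lines and `#` comments are ignored.  Recognised keys:
#' `outcomes` (comma-separated fixture outcome ids, or `all`),
#' `hr_file` / `binary_file` (CSV paths overriding the bundled dataset),
#' `effect_model`, `reference`, `chains`, `burn_in`, `kept_iterations`,
#' `thin`, `seed`, `tau_upper`, `out_dir`.  Unknown keys raise an error
#' listing them.
#'
#' @param path config file path.
#' @return named list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lines[lengths(kv) != 2]
  if (length(bad)) stop("malformed config line(s): ", paste(bad, collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  known <- c("outcomes", "hr_file", "binary_file", "effect_model",
             "reference", "chains", "burn_in", "kept_iterations", "thin",
             "seed", "tau_upper", "out_dir")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- as.list(setNames(vals, keys))
  for (k in c("chains", "burn_in", "kept_iterations", "thin", "seed"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.integer(cfg[[k]])
  if (!is.null(cfg$tau_upper)) cfg$tau_upper <- as.numeric(cfg$tau_upper)
  cfg
}

.write_league_csv <- function(lt, path) {
  K <- length(lt$treatments)
  out <- matrix("", K, K, dimnames = list(lt$treatments, lt$treatments))
  for (a in seq_len(K)) for (b in seq_len(K))
    out[a, b] <- if (a == b) lt$treatments[a] else
      sprintf("%.4g (%.4g, %.4g)", lt$median[a, b], lt$low[a, b], lt$high[a, b])
  write.csv(out, path, quote = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline for one outcome
#'
#' Produces, as CSV files under `out_dir`: the network summary, pairwise
#' forest tables, fixed- and random-effects league tables, posterior draw
#' summaries, SUCRA table, rankogram data, convergence report, DIC
#' consistency/UME comparison, node-splitting table, publication-bias table
#' (Egger, Begg, trim-and-fill, funnel points), leave-one-out table, and a
#' Bland--Altman FE-vs-RE table, plus a `run_log.txt` recording settings and
#' seed.
#'
#' @param network an `evidence_network`.
#' @param spec an [nma_model_spec()].
#' @param out_dir output directory (created if missing).
#' @param loo run the leave-one-out refits (the slowest stage).
#' @return invisibly, a list with the fitted objects and `flagged`
#'   (TRUE when MCMC convergence failed).
#' @export
run_outcome_analysis <- function(network, spec = nma_model_spec(),
                                 out_dir, loo = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  oid <- network$outcome$outcome_id
  pre <- function(name) file.path(out_dir, paste0(oid, "_", name, ".csv"))

  write.csv(network$edges, pre("network_edges"), row.names = FALSE)
  write.csv(pairwise_all(network), pre("pairwise"), row.names = FALSE)

  fit_re <- fit_nma(network, spec)
  spec_fe <- spec; spec_fe$effect_model <- "fixed"
  fit_fe <- fit_nma(network, spec_fe)
  lt_re <- league_table(fit_re); lt_fe <- league_table(fit_fe)
  .write_league_csv(lt_re, pre("league_random"))
  .write_league_csv(lt_fe, pre("league_fixed"))

  sr <- sucra_result(fit_re)
  write.csv(data.frame(treatment = names(sr$sucra),
                       sucra_pct = round(100 * sr$sucra, 2)),
            pre("sucra"), row.names = FALSE)
  write.csv(rankogram_data(fit_re), pre("rankogram"), row.names = FALSE)

  conv <- fit_re$convergence
  write.csv(data.frame(parameter = names(conv$psrf), psrf = conv$psrf,
                       ess = conv$ess), pre("convergence"), row.names = FALSE)

  dic <- compare_consistency_dic(network, spec)
  write.csv(data.frame(model = c("consistency", "ume"),
                       Dbar = c(dic$consistency$Dbar, dic$ume$Dbar),
                       pD = c(dic$consistency$pD, dic$ume$pD),
                       DIC = c(dic$consistency$DIC, dic$ume$DIC)),
            pre("dic"), row.names = FALSE)

  ns <- node_split_all(network, spec)
  if (!is.null(ns)) write.csv(ns, pre("node_split"), row.names = FALSE)

  pb <- publication_bias(network)
  write.csv(data.frame(
    test = c("egger", "begg"),
    statistic = c(pb$egger$intercept, pb$begg$kendall_tau),
    p = c(pb$egger$p, pb$begg$p)), pre("bias_tests"), row.names = FALSE)
  tf <- pb$trim_fill
  write.csv(data.frame(k0 = tf$k0, side = tf$side,
                       original = tf$original_pooled["estimate"],
                       adjusted = tf$adjusted_pooled["estimate"]),
            pre("trim_fill"), row.names = FALSE)
  write.csv(pb$funnel$points, pre("funnel"), row.names = FALSE)

  ba <- bland_altman_fe_re(lt_fe, lt_re)
  write.csv(ba$differences, pre("bland_altman"), row.names = FALSE)

  loo_tab <- NULL
  if (loo) {
    loo_tab <- leave_one_out(network, spec)
    write.csv(loo_tab, pre("leave_one_out"), row.names = FALSE)
  }

  writeLines(c(
    sprintf("outcome: %s", oid),
    sprintf("seed: %d", spec$seed),
    sprintf("model: %s / %s", spec$effect_model, spec$consistency),
    sprintf("chains: %d, burn-in: %d, kept: %d, thin: %d", spec$chains,
            spec$burn_in, spec$kept_iterations, spec$thin),
    sprintf("max PSRF: %.4f (pass: %s)", max(conv$psrf), conv$pass),
    sprintf("package: alknma %s, R %s",
            as.character(utils::packageVersion("alknma")),
            paste(R.version$major, R.version$minor, sep = "."))),
    file.path(out_dir, paste0(oid, "_run_log.txt")))

  invisible(list(fit_random = fit_re, fit_fixed = fit_fe, sucra = sr,
                 dic = dic, node_split = ns, bias = pb,
                 bland_altman = ba, leave_one_out = loo_tab,
                 flagged = fit_re$flagged || fit_fe$flagged))
}

#' Run the pipeline from a configuration file
#'
#' @param config_path path to a key=value file, see [read_config()].
#' @return invisibly, list of per-outcome results; an attribute `flagged`
#'   is TRUE when any fit failed convergence.
#' @export
run_full_analysis <- function(config_path) {
  cfg <- read_config(config_path)
  outcomes <- cfg$outcomes %||% "all"
  outcomes <- if (outcomes == "all") names(.alk_outcomes)
              else trimws(strsplit(outcomes, ",")[[1]])
  out_dir <- cfg$out_dir %||% "alknma_report"
  spec <- nma_model_spec(
    effect_model = cfg$effect_model %||% "random",
    reference = cfg$reference,
    tau_upper = cfg$tau_upper,
    chains = cfg$chains %||% 4L, burn_in = cfg$burn_in %||% 10000L,
    kept_iterations = cfg$kept_iterations %||% 50000L,
    thin = cfg$thin %||% 2L, seed = cfg$seed %||% 20230619L)
  res <- list()
  for (oid in outcomes) {
    net <- if (!is.null(cfg$hr_file) || !is.null(cfg$binary_file)) {
      meta <- .alk_outcomes[[oid]]
      if (is.null(meta)) stop("unknown outcome id: ", oid)
      file <- if (meta[["kind"]] == "contrast_loghr") cfg$hr_file
              else cfg$binary_file
      if (is.null(file)) stop("no data file configured for outcome ", oid)
      d <- read.csv(file, stringsAsFactors = FALSE)
      tmp <- tempfile(fileext = ".csv")
      on.exit(unlink(tmp), add = TRUE)
      write.csv(d[d$outcome == oid, setdiff(names(d), "outcome")], tmp,
                row.names = FALSE)
      read_network_csv(tmp, outcome_spec(oid, meta[["kind"]], meta[["dir"]]))
    } else load_fixture(oid)
    res[[oid]] <- run_outcome_analysis(net, spec, out_dir)
  }
  attr(res, "flagged") <- any(vapply(res, `[[`, TRUE, "flagged"))
  invisible(res)
}

#' Export posterior draws as a flat table
#'
#' @param fit an `nma_fit`.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_draws_csv <- function(fit, path) {
  n_per <- table(fit$chain)
  d <- data.frame(chain = fit$chain,
                  iteration = unlist(lapply(n_per, seq_len), use.names = FALSE))
  write.csv(cbind(d, as.data.frame(fit$draws)), path, row.names = FALSE)
  invisible(path)
}
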