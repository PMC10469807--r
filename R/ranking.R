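# SUCRA treatment ranking -----------------------------------------------------

#' Rank probabilities over posterior draws
#'
#' For each retained draw the treatments are ranked by their basic
#' parameter `d_k` (the reference's 0 included): ascending when lower
#' relative effects are better (survival, adverse events), descending when
#' higher is better (response).  Rank 1 is best.  Ties -- a measure-zero
#' event that can only arise between identical columns -- are broken by
#' treatment order.
#'
#' @param fit a consistency `nma_fit`.
#' @param direction `"lower"` or `"higher"`; defaults to the network
#'   outcome's `better_direction`.
#' @return matrix treatments x ranks; rows and columns each sum to 1.
#' @export
rank_probabilities <- function(fit, direction = NULL) {
  if (is.null(direction)) direction <- fit$outcome$better_direction
  direction <- match.arg(direction, c("lower", "higher"))
  d <- .d_draws(fit)
  if (direction == "higher") d <- -d
  K <- ncol(d); n <- nrow(d)
  # rank of k = 1 + #{j : d_j < d_k} + #{j < k : d_j == d_k}
  ranks <- matrix(1L, n, K)
  for (a in 2:K) for (b in seq_len(a - 1)) {
    lt <- d[, b] < d[, a]; eq <- d[, b] == d[, a]
    ranks[, a] <- ranks[, a] + (lt | eq)
    ranks[, b] <- ranks[, b] + (!lt & !eq)
  }
  P <- matrix(0, K, K, dimnames = list(colnames(d), paste0("rank", seq_len(K))))
  for (k in seq_len(K)) P[k, ] <- tabulate(ranks[, k], K) / n
  P
}

#' Surface under the cumulative ranking curve
#'
#' `SUCRA_k = sum_{j=1}^{K-1} Pr(rank_k <= j) / (K - 1)`: 1 for a treatment
#' certainly ranked best, 0 for certainly worst; the mean across treatments
#' is exactly 0.5.
#'
#' @param rank_probability a treatments x ranks probability matrix, e.g.
#'   from [rank_probabilities()]; each row must sum to 1.
#' @return named vector of SUCRA values in \[0, 1\].
#' @export
sucra <- function(rank_probability) {
  P <- rank_probability
  if (any(abs(rowSums(P) - 1) > 1e-9))
    stop("rank probability rows must sum to 1")
  K <- ncol(P)
  cum <- t(apply(P, 1, cumsum))
  rowSums(cum[, seq_len(K - 1), drop = FALSE]) / (K - 1)
}

#' Full SUCRA result for a fitted network
#'
#' @param fit a consistency `nma_fit`.
#' @param direction see [rank_probabilities()].
#' @return An object of class `sucra_result`: `rank_probability`,
#'   `cumulative_rank`, and `sucra` (per-treatment, in \[0, 1\]).
#' @export
sucra_result <- function(fit, direction = NULL) {
  P <- rank_probabilities(fit, direction)
  structure(list(rank_probability = P,
                 cumulative_rank = t(apply(P, 1, cumsum)),
                 sucra = sucra(P)),
            class = "sucra_result")
}

#' @export
print.sucra_result <- function(x, ...) {
  s <- sort(x$sucra, decreasing = TRUE)
  cat("SUCRA (% , best first):\n")
  for (k in names(s)) cat(sprintf("  %-14s %6.2f\n", k, 100 * s[k]))
  invisible(x)
}

#' Rankogram data in long format
#'
#' @param fit a consistency `nma_fit`.
#' @param direction see [rank_probabilities()].
#' @return data frame `treatment`, `rank`, `probability`, `cumulative`.
#' @export
rankogram_data <- function(fit, direction = NULL) {
  P <- rank_probabilities(fit, direction)
  K <- ncol(P)
  data.frame(treatment = rep(rownames(P), each = K),
             rank = rep(seq_len(K), nrow(P)),
             probability = as.vector(t(P)),
             cumulative = as.vector(apply(P, 1, cumsum)))
}
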