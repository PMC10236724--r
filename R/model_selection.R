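#' Free-parameter count of a K-component mixture of Markov chains
#'
#' Simplex-constrained dimension under the package's parameterisation:
#' mixing `K - 1`, initial distributions `K (S - 1)`, transitions
#' `K S (S - 1)`.
#'
#' @param K number of components.
#' @param S number of states.
#' @return integer parameter count.
#' @export
#' @examples
#' count_free_params(4, 5)  # 99
count_free_params <- function(K, S) {
  stopifnot(K >= 1, S >= 2)
  as.integer((K - 1) + K * (S - 1) + K * S * (S - 1))
}

#' Akaike information criterion
#'
#' `2 p - 2 logL`; lower is better.
#'
#' @param log_likelihood fitted maximum log-likelihood.
#' @param p free-parameter count (>= 0).
#' @return scalar AIC.
#' @export
aic <- function(log_likelihood, p) {
  stopifnot(p >= 0)
  2 * p - 2 * log_likelihood
}

#' Yearly drug-class encounter-rate features
#'
#' Per patient, the number of encounters (states) of each class divided by
#' follow-up in 365.25-day years, where follow-up spans the occupied
#' window grid: `max(window_index) * window_days / 365.25` (1-based
#' windows). This is the feature embedding the Calinski-Harabasz score is
#' computed on.
#'
#' @param sequences list of [state_sequence()].
#' @param window_days encounter-window length (default 91).
#' @param S number of classes (default 5).
#' @return n x S matrix of rates (rows named by patient id) with attribute
#'   `"followup_years"`.
#' @export
yearly_rate_features <- function(sequences, window_days = 91, S = 5) {
  sequences <- as_state_sequences(sequences)
  stopifnot(length(sequences) > 0)
  n <- length(sequences)
  feats <- matrix(0, n, S)
  fy <- numeric(n)
  for (i in seq_len(n)) {
    s <- sequences[[i]]
    fy[i] <- max(s$window_index) * window_days / 365.25
    feats[i, ] <- tabulate(s$states, nbins = S) / fy[i]
  }
  rownames(feats) <- vapply(sequences, function(s) as.character(s$patient_id),
                            character(1))
  colnames(feats) <- if (S == 5) state_labels() else paste0("s", seq_len(S))
  attr(feats, "followup_years") <- fy
  feats
}

#' Calinski-Harabasz index
#'
#' `[B / (K - 1)] / [W / (n - K)]` with between-cluster dispersion
#' `B = sum_k n_k ||m_k - m||^2` and within-cluster dispersion
#' `W = sum_k sum_{i in k} ||x_i - m_k||^2`. Higher is better. `W = 0`
#' (all points identical within clusters) returns `+Inf` by convention.
#'
#' @param features n x d numeric matrix.
#' @param labels length-n cluster labels (>= 2 distinct, all nonempty).
#' @return scalar score.
#' @export
calinski_harabasz <- function(features, labels) {
  x <- as.matrix(features)
  n <- nrow(x)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  groups <- unique(labels)
  K <- length(groups)
  if (K < 2) stop("Calinski-Harabasz needs at least 2 clusters")
  if (n <= K) stop("Calinski-Harabasz needs n > K")
  m <- colMeans(x)
  B <- 0
  W <- 0
  for (g in groups) {
    xg <- x[labels == g, , drop = FALSE]
    mg <- colMeans(xg)
    B <- B + nrow(xg) * sum((mg - m)^2)
    W <- W + sum(sweep(xg, 2L, mg)^2)
  }
  if (W == 0) return(Inf)
  (B / (K - 1)) / (W / (n - K))
}

#' Select the number of mixture components by AIC and C-H score
#'
#' Fits [fit_em()] for each candidate K, computes AIC from the fitted
#' objective and [count_free_params()], and the Calinski-Harabasz score of
#' [yearly_rate_features()] under each K's highest-posterior labels. The
#' selected K minimises AIC; when the C-H argmax disagrees the table
#' carries a flag and both optima.
#'
#' @param sequences list of [state_sequence()].
#' @param k_candidates integer candidates (default 2:5).
#' @param n_restarts,tol,max_iter,pseudocount EM options, see [fit_em()].
#' @param seed base seed; candidate K uses `seed + K`.
#' @param window_days window length for the rate features.
#' @return object of class `model_selection`: `table` (data.frame with
#'   `K`, `log_likelihood`, `p`, `aic`, `ch_score`, `selected`,
#'   `ch_agrees`), `fits` (named list of `mm_fit`), `selected_k`,
#'   `ch_best_k`.
#' @export
select_k <- function(sequences, k_candidates = 2:5, n_restarts = 20,
                     tol = 1e-8, max_iter = 500, pseudocount = 1e-6,
                     seed = 1, window_days = 91) {
  stopifnot(length(k_candidates) > 0)
  seqs <- as_state_sequences(sequences)
  feats <- yearly_rate_features(seqs, window_days)
  fits <- list()
  rows <- list()
  for (K in sort(unique(as.integer(k_candidates)))) {
    fit <- fit_em(seqs, K, n_restarts = n_restarts, tol = tol,
                  max_iter = max_iter, pseudocount = pseudocount,
                  seed = seed + K)
    fits[[as.character(K)]] <- fit
    p <- count_free_params(K, fit$params$S)
    labels <- posterior_assign(seqs, fit$params)$cluster
    ch <- if (length(unique(labels)) >= 2)
      calinski_harabasz(feats, labels) else NA_real_
    rows[[as.character(K)]] <- data.frame(
      K = K, log_likelihood = fit$log_likelihood, p = p,
      aic = aic(fit$log_likelihood, p), ch_score = ch)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  sel_k <- tab$K[which.min(tab$aic)]
  ch_ok <- !is.na(tab$ch_score)
  ch_best <- if (any(ch_ok)) tab$K[ch_ok][which.max(tab$ch_score[ch_ok])]
             else NA_integer_
  tab$selected <- tab$K == sel_k
  tab$ch_agrees <- identical(sel_k, ch_best)
  structure(list(table = tab, fits = fits, selected_k = sel_k,
                 ch_best_k = ch_best),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("selected K = %d (AIC)%s\n", x$selected_k,
              if (isTRUE(x$table$ch_agrees[1])) ", C-H score agrees"
              else sprintf("; C-H prefers K = %s", x$ch_best_k)))
  invisible(x)
}
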