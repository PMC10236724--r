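# Independent oracles and small fixture builders. Everything here is kept
# deliberately naive (loops, products without log tricks) so it cannot share
# a bug with the package's vectorised log-space implementations.

# naive mixture likelihood: double loop over sequences and components,
# plain products (no logs until the end)
oracle_mixture_ll <- function(paths, params) {
  total <- 0
  for (st in paths) {
    lik <- 0
    for (k in seq_len(params$K)) {
      p <- params$mixing[k] * params$initial[k, st[1]]
      if (length(st) > 1)
        for (t in 2:length(st))
          p <- p * params$transition[st[t - 1], st[t], k]
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

# Calinski-Harabasz via the total-scatter identity B = T - W
oracle_ch <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  K <- length(unique(labels))
  Tss <- sum(sweep(x, 2, colMeans(x))^2)
  W <- 0
  for (g in unique(labels)) {
    xg <- x[labels == g, , drop = FALSE]
    W <- W + sum(sweep(xg, 2, colMeans(xg))^2)
  }
  ((Tss - W) / (K - 1)) / (W / (n - K))
}

# random valid mixture parameters (independent Dirichlet draws)
rand_params <- function(K, S) {
  norm <- function(v) v / sum(v)
  tr <- array(0, c(S, S, K))
  for (k in seq_len(K)) for (a in seq_len(S)) tr[a, , k] <- norm(runif(S) + 0.05)
  init <- t(sapply(seq_len(K), function(k) norm(runif(S) + 0.05)))
  if (K == 1) init <- matrix(init, 1)
  mixture_markov_params(norm(runif(K) + 0.1), init, tr)
}

# random integer state paths (plain sampling, not via the package generator)
rand_paths <- function(n, S, len_range = c(2, 6)) {
  lapply(seq_len(n), function(i)
    sample.int(S, sample(len_range[1]:len_range[2], 1), replace = TRUE))
}

# prescriptions table from explicit rows
rx_table <- function(patient_id, dates, drugs) {
  data.frame(patient_id = patient_id, date = as.Date(dates),
             drug_name = drugs, stringsAsFactors = FALSE)
}

ra_dx <- function(patient_id, dates, code = "714.0") {
  data.frame(patient_id = patient_id, date = as.Date(dates), code = code,
             stringsAsFactors = FALSE)
}

# exact round-trip comparison between built sequences and generator truth
sequences_match_truth <- function(built, cohort) {
  all(vapply(names(built$sequences), function(id) {
    b <- built$sequences[[id]]
    tr <- cohort$true_sequences[[id]]
    identical(b$states, tr$states) &&
      identical(b$window_index, tr$window_index) &&
      b$first_rx_date == tr$first_rx_date
  }, logical(1)))
}
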