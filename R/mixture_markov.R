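#' Mixture-of-Markov-chains parameters
#'
#' Container for a K-component mixture of first-order Markov chains over S
#' states: mixing proportions `pi`, per-component initial distributions
#' `alpha` (K x S) and per-component transition matrices `P` (S x S x K,
#' rows = from-state). Every probability row must sum to 1.
#'
#' @param mixing numeric length-K vector of mixing proportions.
#' @param initial K x S matrix of initial-state distributions (one row per
#'   component).
#' @param transition S x S x K array of transition matrices, or for K = 1 a
#'   single S x S matrix, or a list of K matrices.
#' @param state_labels optional character length-S state names; defaults to
#'   [state_labels()] when S = 5, else `s1..sS`.
#' @return object of class `mixture_markov_params` with elements
#'   `K`, `S`, `mixing`, `initial`, `transition`, `state_labels`.
#' @export
#' @examples
#' p <- mixture_markov_params(
#'   mixing = 1,
#'   initial = matrix(c(0.5, 0.5), 1),
#'   transition = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
#' )
mixture_markov_params <- function(mixing, initial, transition,
                                  state_labels = NULL) {
  mixing <- as.numeric(mixing)
  K <- length(mixing)
  if (is.list(transition)) transition <- simplify2array(transition)
  if (is.matrix(transition)) transition <- array(transition, c(dim(transition), 1L))
  if (is.vector(initial)) initial <- matrix(initial, nrow = 1L)
  initial <- as.matrix(initial)
  S <- ncol(initial)
  stopifnot(K >= 1, S >= 2, nrow(initial) == K,
            length(dim(transition)) == 3,
            all(dim(transition) == c(S, S, K)))
  if (any(mixing < 0) || any(initial < 0) || any(transition < 0))
    stop("probabilities must be non-negative")
  tol <- 1e-8
  if (abs(sum(mixing) - 1) > tol) stop("mixing proportions must sum to 1")
  if (any(abs(rowSums(initial) - 1) > tol))
    stop("each initial-distribution row must sum to 1")
  rs <- apply(transition, 3L, rowSums)
  if (any(abs(rs - 1) > tol))
    stop("each transition-matrix row must sum to 1")
  if (is.null(state_labels))
    state_labels <- if (S == 5) rxseq::state_labels() else paste0("s", seq_len(S))
  stopifnot(length(state_labels) == S)
  structure(
    list(K = K, S = S, mixing = mixing, initial = initial,
         transition = transition, state_labels = as.character(state_labels)),
    class = "mixture_markov_params"
  )
}

#' @export
print.mixture_markov_params <- function(x, ...) {
  cat(sprintf("Mixture of %d Markov chain(s) over %d states (%s)\n",
              x$K, x$S, paste(x$state_labels, collapse = ", ")))
  cat("mixing:", signif(x$mixing, 4), "\n")
  invisible(x)
}

#' One patient's drug-class state sequence
#'
#' @param patient_id scalar identifier.
#' @param states integer vector of state indices (1-based), length >= 1.
#' @param window_index non-decreasing integer vector (1-based 3-month window
#'   of each state); defaults to one state per consecutive window.
#' @param first_rx_date `Date` of the first b/tsDMARD prescription (anchor
#'   of the window grid), or `NA`.
#' @return object of class `state_sequence`.
#' @export
state_sequence <- function(patient_id, states,
                           window_index = seq_along(states),
                           first_rx_date = as.Date(NA)) {
  states <- as.integer(states)
  window_index <- as.integer(window_index)
  stopifnot(length(states) >= 1, all(states >= 1),
            length(window_index) == length(states),
            !is.unsorted(window_index))
  same_win <- window_index[-1] == window_index[-length(window_index)]
  if (any(same_win & states[-1] == states[-length(states)]))
    stop("consecutive equal states within one window are not a valid sequence")
  structure(list(patient_id = patient_id, first_rx_date = first_rx_date,
                 states = states, window_index = window_index),
            class = "state_sequence")
}

# Coerce a collection of sequences (state_sequence objects or bare integer
# vectors) into a list of state_sequence.
as_state_sequences <- function(x) {
  if (inherits(x, "state_sequence")) return(list(x))
  stopifnot(is.list(x), length(x) > 0)
  lapply(seq_along(x), function(i) {
    s <- x[[i]]
    if (inherits(s, "state_sequence")) s
    else state_sequence(patient_id = names(x)[i] %||% i, states = s)
  })
}

# Sufficient statistics: first state per sequence and an n x S^2 matrix of
# transition counts (column (a-1)*S + b counts a -> b). The whole likelihood
# of a first-order chain factors through these.
seq_stats <- function(sequences, S) {
  sequences <- as_state_sequences(sequences)
  n <- length(sequences)
  first <- vapply(sequences, function(s) s$states[1L], integer(1))
  trans <- matrix(0L, n, S * S)
  for (i in seq_len(n)) {
    st <- sequences[[i]]$states
    if (max(st) > S) stop("state index out of range for S = ", S)
    L <- length(st)
    if (L >= 2L) {
      idx <- (st[-L] - 1L) * S + st[-1L]
      tb <- tabulate(idx, nbins = S * S)
      trans[i, ] <- tb
    }
  }
  list(n = n, first = first, trans = trans,
       patient_id = vapply(sequences, function(s) as.character(s$patient_id),
                           character(1)))
}

# n x K matrix of per-component log-likelihoods from sufficient statistics.
# Zero-probability transitions give exact -Inf (guarded against 0 * -Inf).
loglik_matrix <- function(stats, params) {
  S <- params$S; K <- params$K
  out <- matrix(0, stats$n, K)
  for (k in seq_len(K)) {
    # vec(t(P)) puts P[a, b] at index (a-1)*S + b, matching seq_stats columns
    pk <- as.numeric(t(params$transition[, , k]))
    logP <- log(pk)
    zero <- pk == 0
    logP_safe <- ifelse(zero, 0, logP)
    ll <- log(params$initial[k, ])[stats$first] + drop(stats$trans %*% logP_safe)
    hits_zero <- drop(stats$trans %*% zero) > 0
    ll[hits_zero] <- -Inf
    out[, k] <- ll
  }
  out
}

#' Log-likelihood of one sequence under one mixture component
#'
#' `log alpha_k(s_1) + sum_t log P_k(s_{t-1}, s_t)`; a length-1 sequence
#' contributes only the initial term. `-Inf` is returned (not an error) when
#' the path uses a zero-probability transition.
#'
#' @param seq a [state_sequence()] or bare integer state vector.
#' @param k component index in 1..K.
#' @param params a [mixture_markov_params()].
#' @return scalar log-likelihood.
#' @export
component_log_likelihood <- function(seq, k, params) {
  st <- if (inherits(seq, "state_sequence")) seq$states else as.integer(seq)
  stopifnot(length(st) >= 1, k >= 1, k <= params$K)
  if (any(st < 1 | st > params$S))
    stop("state index out of range 1..", params$S)
  ll <- log(params$initial[k, st[1L]])
  if (length(st) >= 2L) {
    L <- length(st)
    ll <- ll + sum(log(params$transition[cbind(st[-L], st[-1L], k)]))
  }
  ll
}

#' Total mixture log-likelihood of a set of sequences
#'
#' `sum_i log sum_k pi_k exp(ll_ik)` with log-sum-exp stabilisation. An
#' empty sequence list returns 0 (log of an empty product).
#'
#' @param sequences list of sequences (see [state_sequence()]).
#' @param params a [mixture_markov_params()].
#' @return scalar log-likelihood.
#' @export
mixture_log_likelihood <- function(sequences, params) {
  if (length(sequences) == 0) return(0)
  stats <- seq_stats(sequences, params$S)
  ll <- loglik_matrix(stats, params)
  lw <- ifelse(params$mixing == 0, -Inf, log(params$mixing))
  sum(row_logsumexp(sweep(ll, 2L, lw, `+`)))
}

# Shared E-step on sufficient statistics; returns list(gamma, ll_rows).
estep_stats <- function(stats, params) {
  ll <- loglik_matrix(stats, params)
  lw <- ifelse(params$mixing == 0, -Inf, log(params$mixing))
  lj <- sweep(ll, 2L, lw, `+`)
  rows <- row_logsumexp(lj)
  if (any(!is.finite(rows))) {
    bad <- which(!is.finite(rows))[1L]
    stop("sequence ", stats$patient_id[bad],
         " has zero likelihood under every component; ",
         "check for zero-probability transitions (pseudocount = 0?)")
  }
  gamma <- exp(lj - rows)
  gamma <- gamma / rowSums(gamma)  # exact renormalisation
  list(gamma = gamma, ll = rows)
}

#' E-step: posterior component responsibilities
#'
#' Row i is the posterior over components for sequence i, proportional to
#' `pi_k * L_ik`; rows sum to 1.
#'
#' @inheritParams mixture_log_likelihood
#' @return n x K responsibility matrix.
#' @export
e_step <- function(sequences, params) {
  stats <- seq_stats(sequences, params$S)
  estep_stats(stats, params)$gamma
}

# Weighted M-step on sufficient statistics. `weights` multiplies each row of
# gamma (used for deduplicated data); pseudocount eps smooths alpha and P.
mstep_stats <- function(stats, gamma, pseudocount, S, state_labels = NULL,
                        weights = NULL) {
  gamma <- as.matrix(gamma)
  K <- ncol(gamma)
  w <- weights %||% rep(1, nrow(gamma))
  gw <- gamma * w
  mixing <- colSums(gw) / sum(w)
  mixing <- mixing / sum(mixing)

  # initial distributions: weighted first-state counts
  first_onehot <- matrix(0, stats$n, S)
  first_onehot[cbind(seq_len(stats$n), stats$first)] <- 1
  a_counts <- t(first_onehot) %*% gw          # S x K
  initial <- matrix(0, K, S)
  for (k in seq_len(K)) {
    row <- a_counts[, k] + pseudocount
    tot <- sum(row)
    if (tot == 0) {
      warning("component ", k, " has no initial-state mass; set to uniform")
      row <- rep(1, S)
      tot <- S
    }
    initial[k, ] <- row / tot
  }

  # transitions: weighted pooled counts, row-normalised per from-state
  t_counts <- t(stats$trans) %*% gw           # S^2 x K, index (a-1)*S + b
  transition <- array(0, c(S, S, K))
  for (k in seq_len(K)) {
    cm <- matrix(t_counts[, k], S, S, byrow = TRUE) + pseudocount
    rs <- rowSums(cm)
    for (a in seq_len(S)) {
      if (rs[a] == 0) {
        warning("unvisited state ", a, " in component ", k,
                ": transition row set to uniform")
        cm[a, ] <- 1
        rs[a] <- S
      }
    }
    transition[, , k] <- cm / rs
  }
  mixture_markov_params(mixing, initial, transition, state_labels)
}

#' M-step: closed-form weighted maximum-likelihood update
#'
#' `pi_k` is the mean responsibility; initial distributions and transition
#' rows are pseudocount-smoothed, row-normalised weighted counts. A
#' from-state row with zero weighted count and zero pseudocount is set to
#' uniform with a warning (the data say nothing about it).
#'
#' @param sequences list of sequences.
#' @param responsibilities n x K matrix with rows summing to 1.
#' @param pseudocount non-negative smoothing constant added to every
#'   initial-state and transition count.
#' @param S number of states; defaults to the largest state observed.
#' @param state_labels optional state names.
#' @return a [mixture_markov_params()].
#' @export
m_step <- function(sequences, responsibilities, pseudocount = 1e-6,
                   S = NULL, state_labels = NULL) {
  seqs <- as_state_sequences(sequences)
  S <- S %||% max(vapply(seqs, function(s) max(s$states), integer(1)))
  stats <- seq_stats(seqs, S)
  stopifnot(nrow(as.matrix(responsibilities)) == stats$n)
  mstep_stats(stats, responsibilities, pseudocount, S, state_labels)
}

# Penalised EM objective: data log-likelihood plus the Dirichlet smoothing
# term the pseudocounted M-step maximises. Monotone under MAP-EM; equals the
# plain log-likelihood when pseudocount = 0.
em_objective <- function(ll_data, params, pseudocount) {
  if (pseudocount == 0) return(ll_data)
  ll_data + pseudocount * (sum(log(params$initial)) + sum(log(params$transition)))
}

# Single EM run from given starting parameters on (deduplicated) statistics.
em_run <- function(stats, weights, init_params, tol, max_iter, pseudocount) {
  params <- init_params
  es <- estep_stats(stats, params)
  obj <- em_objective(sum(weights * es$ll), params, pseudocount)
  trace <- obj
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    params <- mstep_stats(stats, es$gamma, pseudocount, params$S,
                          params$state_labels, weights = weights)
    es <- estep_stats(stats, params)
    obj_new <- em_objective(sum(weights * es$ll), params, pseudocount)
    trace <- c(trace, obj_new)
    if (abs(obj_new - obj) <= tol * abs(obj)) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  list(params = params, objective = obj, trace = trace,
       n_iter = iter, converged = converged)
}

# Dirichlet(1) draws: independent Exp(1) per cell, row-normalised.
random_params <- function(K, S, state_labels = NULL) {
  norm <- function(x) x / sum(x)
  mixing <- norm(rgamma(K, 1))
  initial <- t(vapply(seq_len(K), function(k) norm(rgamma(S, 1)), numeric(S)))
  if (K == 1L) initial <- matrix(initial, 1L)
  transition <- array(0, c(S, S, K))
  for (k in seq_len(K))
    for (a in seq_len(S)) transition[a, , k] <- norm(rgamma(S, 1))
  mixture_markov_params(mixing, initial, transition, state_labels)
}

#' Fit a mixture of Markov chains by EM with random restarts
#'
#' Each restart starts from Dirichlet(1) draws of the mixing vector and of
#' every initial/transition row, then alternates E- and M-steps until the
#' relative change of the objective falls below `tol`. The restart with the
#' highest final objective wins. With `pseudocount > 0` the traced (and
#' reported) objective is the Dirichlet-penalised log-likelihood that the
#' smoothed M-step maximises -- it differs from the plain log-likelihood by
#' `O(pseudocount)` and is non-decreasing by construction; with
#' `pseudocount = 0` it is exactly the data log-likelihood.
#'
#' `K = 1` needs no iteration: the closed-form (pseudocount-smoothed)
#' count MLE is returned with a length-1 trace.
#'
#' @param sequences list of sequences (see [state_sequence()]).
#' @param K number of components (>= 1).
#' @param n_restarts number of random restarts.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @param pseudocount smoothing constant for the M-step (see [m_step()]).
#' @param seed integer seed; the fit is deterministic given it.
#' @param S,state_labels state-space size and names; default from the data.
#' @return object of class `mm_fit`: `params`, `log_likelihood` (final
#'   objective), `ll_trace` (best restart), `restart_traces` (all restarts),
#'   `n_iter`, `converged`, `n_restarts`, `best_restart`, `seed`,
#'   `pseudocount`.
#' @export
fit_em <- function(sequences, K, n_restarts = 20, tol = 1e-8, max_iter = 500,
                   pseudocount = 1e-6, seed = 1, S = NULL,
                   state_labels = NULL) {
  seqs <- as_state_sequences(sequences)
  stopifnot(K >= 1, length(seqs) > 0)
  S <- S %||% max(vapply(seqs, function(s) max(s$states), integer(1)))
  if (S == 5 && is.null(state_labels)) state_labels <- rxseq::state_labels()
  if (K > length(seqs))
    warning("more components (", K, ") than sequences (", length(seqs), ")")
  full <- seq_stats(seqs, S)

  # deduplicate: the likelihood depends only on (first state, count matrix)
  key <- paste(full$first, apply(full$trans, 1L, paste, collapse = ","))
  grp <- match(key, unique(key))
  keep <- !duplicated(key)
  stats <- list(n = sum(keep), first = full$first[keep],
                trans = full$trans[keep, , drop = FALSE],
                patient_id = full$patient_id[keep])
  weights <- as.numeric(tabulate(grp, nbins = sum(keep)))

  if (K == 1L) {
    gamma <- matrix(1, stats$n, 1L)
    params <- mstep_stats(stats, gamma, pseudocount, S, state_labels,
                          weights = weights)
    es <- estep_stats(stats, params)
    obj <- em_objective(sum(weights * es$ll), params, pseudocount)
    return(structure(
      list(params = params, log_likelihood = obj, ll_trace = obj,
           restart_traces = list(obj), n_iter = 1L, converged = TRUE,
           n_restarts = 1L, best_restart = 1L, seed = seed,
           pseudocount = pseudocount),
      class = "mm_fit"))
  }

  runs <- withr::with_seed(seed, {
    lapply(seq_len(n_restarts), function(r) {
      init <- random_params(K, S, state_labels)
      em_run(stats, weights, init, tol, max_iter, pseudocount)
    })
  })
  objs <- vapply(runs, `[[`, numeric(1), "objective")
  best <- which.max(objs)
  run <- runs[[best]]
  structure(
    list(params = run$params, log_likelihood = run$objective,
         ll_trace = run$trace,
         restart_traces = lapply(runs, `[[`, "trace"),
         n_iter = run$n_iter, converged = run$converged,
         n_restarts = n_restarts, best_restart = best, seed = seed,
         pseudocount = pseudocount),
    class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "Mixture Markov fit: K = %d, objective = %.4f, %d iteration(s), %s\n",
    x$params$K, x$log_likelihood, x$n_iter,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Assign sequences to their highest-posterior cluster
#'
#' Posterior rows come from [e_step()]; ties in the argmax break to the
#' lowest component index, so identical sequences always receive identical
#' assignments.
#'
#' @inheritParams mixture_log_likelihood
#' @return data.frame with `patient_id`, `cluster`, and posterior columns
#'   `p_1` .. `p_K`.
#' @export
posterior_assign <- function(sequences, params) {
  stats <- seq_stats(sequences, params$S)
  gamma <- estep_stats(stats, params)$gamma
  cluster <- max.col(gamma, ties.method = "first")
  out <- data.frame(patient_id = stats$patient_id, cluster = cluster,
                    stringsAsFactors = FALSE)
  colnames(gamma) <- paste0("p_", seq_len(params$K))
  cbind(out, as.data.frame(gamma))
}

#' Match estimated components to reference components
#'
#' Finds the permutation `perm` (exhaustive over K!) minimising the total L1
#' distance between matched transition matrices, i.e. estimated component
#' `perm[k]` corresponds to reference component `k`. Resolves label
#' switching for recovery experiments.
#'
#' @param estimated,truth two [mixture_markov_params()] with equal K and S.
#' @return integer permutation of 1..K with attribute `"distance"`.
#' @export
match_components <- function(estimated, truth) {
  if (estimated$K != truth$K || estimated$S != truth$S)
    stop("component match requires equal K and S")
  K <- truth$K
  # K x K cost: L1 between estimated j and truth k transition matrices
  cost <- matrix(0, K, K)
  for (k in seq_len(K))
    for (j in seq_len(K))
      cost[k, j] <- sum(abs(estimated$transition[, , j] - truth$transition[, , k]))
  best <- NULL
  best_d <- Inf
  for (p in all_permutations(K)) {
    d <- sum(cost[cbind(seq_len(K), p)])
    if (d < best_d) {
      best_d <- d
      best <- p
    }
  }
  structure(as.integer(best), distance = best_d)
}

#' Serialise / read a fitted model as JSON
#'
#' Arrays are written row-major with full double precision; a written model
#' read back is numerically identical.
#'
#' @param fit an `mm_fit` (or a bare `mixture_markov_params`).
#' @param path file path.
#' @return `read_model` returns an `mm_fit`.
#' @export
write_model <- function(fit, path) {
  if (inherits(fit, "mixture_markov_params"))
    fit <- list(params = fit, log_likelihood = NA_real_, n_iter = NA_integer_,
                converged = NA, seed = NA_integer_, pseudocount = NA_real_)
  p <- fit$params
  doc <- list(
    K = p$K, S = p$S, state_labels = p$state_labels,
    mixing = p$mixing,
    initial = lapply(seq_len(p$K), function(k) p$initial[k, ]),
    transition = lapply(seq_len(p$K), function(k)
      lapply(seq_len(p$S), function(a) p$transition[a, , k])),
    fit = list(log_likelihood = fit$log_likelihood, n_iter = fit$n_iter,
               converged = fit$converged, seed = fit$seed,
               pseudocount = fit$pseudocount)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  K <- doc$K; S <- doc$S
  initial <- do.call(rbind, lapply(doc$initial, function(r)
    vapply(r, as.numeric, numeric(1))))
  transition <- array(0, c(S, S, K))
  for (k in seq_len(K))
    transition[, , k] <- do.call(rbind, lapply(doc$transition[[k]],
      function(r) vapply(r, as.numeric, numeric(1))))
  params <- mixture_markov_params(
    vapply(doc$mixing, as.numeric, numeric(1)), initial, transition,
    vapply(doc$state_labels, as.character, character(1)))
  structure(
    list(params = params,
         log_likelihood = doc$fit$log_likelihood %||% NA_real_,
         ll_trace = doc$fit$log_likelihood %||% NA_real_,
         restart_traces = NULL,
         n_iter = doc$fit$n_iter %||% NA_integer_,
         converged = doc$fit$converged %||% NA,
         n_restarts = NA_integer_, best_restart = NA_integer_,
         seed = doc$fit$seed %||% NA_integer_,
         pseudocount = doc$fit$pseudocount %||% NA_real_),
    class = "mm_fit")
}
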