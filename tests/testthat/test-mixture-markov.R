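test_that("parameter container validates probability rows", {
  expect_error(mixture_markov_params(c(0.6, 0.5),
                                     matrix(0.5, 2, 2),
                                     array(0.5, c(2, 2, 2))),
               "sum to 1")
  p <- mixture_markov_params(1, matrix(c(0.5, 0.5), 1),
                             matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))
  expect_identical(p$K, 1L)
  expect_identical(p$S, 2L)
})

test_that("component log-likelihood matches hand-computed cases", {
  # uniform chain over 5 states: any length-3 path has probability (1/5)^3
  unif <- mixture_markov_params(1, matrix(0.2, 1, 5),
                                array(0.2, c(5, 5, 1)))
  expect_equal(component_log_likelihood(c(3, 1, 5), 1, unif), 3 * log(0.2))

  # deterministic probability-1 path
  det <- mixture_markov_params(1, matrix(c(1, 0), 1),
                               matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
  expect_identical(component_log_likelihood(c(1, 2, 1), 1, det), 0)

  # hand multiplication: 0.5 * 0.9 * 0.1
  p <- mixture_markov_params(1, matrix(c(0.5, 0.5), 1),
                             matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))
  expect_equal(component_log_likelihood(c(1, 1, 2), 1, p), log(0.045))

  # zero-probability transitions give -Inf, out-of-range states error
  expect_identical(component_log_likelihood(c(1, 1), 1, det), -Inf)
  expect_error(component_log_likelihood(c(1, 3), 1, det), "out of range")
})

test_that("mixture log-likelihood equals naive enumeration on random instances", {
  set.seed(421)
  for (rep in 1:20) {
    K <- sample(1:3, 1)
    S <- sample(2:5, 1)
    params <- rand_params(K, S)
    paths <- rand_paths(sample(1:20, 1), S)
    seqs <- lapply(paths, state_sequence, patient_id = "x")
    expect_equal(mixture_log_likelihood(seqs, params),
                 oracle_mixture_ll(paths, params), tolerance = 1e-10)
  }
})

test_that("mixture log-likelihood degenerate and additivity contracts hold", {
  set.seed(7)
  S <- 4
  params <- rand_params(2, S)
  paths <- rand_paths(8, S)
  seqs <- lapply(paths, state_sequence, patient_id = "x")

  # empty input: log of an empty product
  expect_identical(mixture_log_likelihood(list(), params), 0)

  # pi = (1, 0) collapses onto component 1 exactly
  p10 <- mixture_markov_params(c(1, 0), params$initial, params$transition)
  expect_equal(mixture_log_likelihood(seqs, p10),
               sum(vapply(seqs, component_log_likelihood, numeric(1),
                          k = 1, params = p10)))

  # duplicating the data doubles the log-likelihood exactly
  expect_equal(mixture_log_likelihood(c(seqs, seqs), params),
               2 * mixture_log_likelihood(seqs, params))

  # permuting component labels leaves the value unchanged
  perm <- c(2, 1)
  pp <- mixture_markov_params(params$mixing[perm],
                              params$initial[perm, ],
                              params$transition[, , perm])
  expect_identical(mixture_log_likelihood(seqs, pp),
                   mixture_log_likelihood(seqs, params))
})

test_that("E-step responsibilities match symmetry, degeneracy and hand cases", {
  two_same <- mixture_markov_params(
    c(0.5, 0.5),
    rbind(c(0.5, 0.5), c(0.5, 0.5)),
    array(rep(c(0.9, 0.2, 0.1, 0.8), 2), c(2, 2, 2)))
  seqs <- lapply(rand_paths(5, 2), state_sequence, patient_id = "x")
  g <- e_step(seqs, two_same)
  expect_equal(unname(g), matrix(0.5, 5, 2))

  p10 <- mixture_markov_params(c(1, 0), two_same$initial, two_same$transition)
  g10 <- e_step(seqs, p10)
  expect_equal(unname(g10), cbind(rep(1, 5), rep(0, 5)))

  # hand posterior: L_A = 0.5*0.9*0.1 = 0.045, L_B = 0.5*0.8*0.2 = 0.08
  pAB <- mixture_markov_params(
    c(0.5, 0.5), rbind(c(0.5, 0.5), c(0.5, 0.5)),
    array(c(0.9, 0.2, 0.1, 0.8, 0.8, 0.1, 0.2, 0.9), c(2, 2, 2)))
  g2 <- e_step(list(state_sequence("p", c(1, 1, 2))), pAB)
  expect_equal(as.numeric(g2), c(0.045, 0.08) / 0.125, tolerance = 1e-10)

  # inexplicable sequence errors with the offending id
  det <- mixture_markov_params(1, matrix(c(1, 0), 1),
                               matrix(c(1, 0, 1, 0), 2, byrow = TRUE))
  expect_error(e_step(list(state_sequence("bad1", c(1, 2))), det), "bad1")
})

test_that("M-step closed forms: K = 1 count MLE, one-hot groups, smoothing limit", {
  paths <- list(c(1, 1, 2), c(2, 1), c(1, 2, 2))
  seqs <- lapply(paths, state_sequence, patient_id = "x")
  g <- matrix(1, 3, 1)
  suppressWarnings(p <- m_step(seqs, g, pseudocount = 0, S = 2))
  expect_equal(as.numeric(p$initial), c(2 / 3, 1 / 3))
  # pooled transitions: 1->1: 1, 1->2: 2, 2->1: 1, 2->2: 1
  expect_equal(p$transition[1, , 1], c(1 / 3, 2 / 3))
  expect_equal(p$transition[2, , 1], c(1 / 2, 1 / 2))

  # one-hot responsibilities recover per-group closed forms exactly
  g2 <- rbind(c(1, 0), c(1, 0), c(0, 1))
  suppressWarnings(p2 <- m_step(seqs, g2, pseudocount = 0, S = 2))
  suppressWarnings(pa <- m_step(seqs[1:2], matrix(1, 2, 1), pseudocount = 0,
                                S = 2))
  suppressWarnings(pb <- m_step(seqs[3], matrix(1, 1, 1), pseudocount = 0,
                                S = 2))
  expect_equal(p2$transition[, , 1], pa$transition[, , 1])
  expect_equal(p2$transition[, , 2], pb$transition[, , 1])
  expect_equal(p2$mixing, c(2 / 3, 1 / 3))

  # enormous pseudocount drives every row to uniform
  p3 <- m_step(seqs, g, pseudocount = 1e9, S = 2)
  expect_equal(p3$transition[1, , 1], c(0.5, 0.5), tolerance = 1e-6)

  # unvisited states with zero pseudocount: uniform rows, one warning each
  w <- capture_warnings(
    p4 <- m_step(list(state_sequence("x", c(1, 1))),
                 matrix(1, 1, 1), pseudocount = 0, S = 3))
  expect_true(all(grepl("unvisited", w)))
  expect_length(w, 2)
  expect_equal(p4$transition[2, , 1], rep(1 / 3, 3))
})

test_that("fit_em K = 1 equals the closed-form MLE without iteration", {
  set.seed(31)
  paths <- rand_paths(30, 3, c(3, 8))
  seqs <- lapply(paths, state_sequence, patient_id = "x")
  fit <- fit_em(seqs, 1, pseudocount = 0, seed = 1)
  suppressWarnings(closed <- m_step(seqs, matrix(1, 30, 1), pseudocount = 0,
                                    S = 3))
  expect_equal(fit$params$transition, closed$transition, tolerance = 1e-12)
  expect_equal(fit$params$initial, closed$initial, tolerance = 1e-12)
  expect_lte(length(fit$ll_trace), 2)
  expect_true(fit$converged)
  expect_equal(fit$log_likelihood, mixture_log_likelihood(seqs, closed),
               tolerance = 1e-12)
})

test_that("fit_em is deterministic given the seed and warns when K > n", {
  seqs <- lapply(rand_paths(6, 3, c(3, 6)), state_sequence, patient_id = "x")
  f1 <- fit_em(seqs, 2, n_restarts = 3, seed = 5)
  f2 <- fit_em(seqs, 2, n_restarts = 3, seed = 5)
  expect_identical(f1$ll_trace, f2$ll_trace)
  expect_identical(f1$params, f2$params)
  expect_warning(fit_em(seqs, 7, n_restarts = 1, seed = 1), "components")
})

test_that("EM objective trace is non-decreasing on random data", {
  set.seed(99)
  for (rep in 1:10) {
    S <- sample(2:5, 1)
    seqs <- lapply(rand_paths(40, S, c(2, 10)), state_sequence,
                   patient_id = "x")
    fit <- fit_em(seqs, sample(2:3, 1), n_restarts = 3, seed = rep)
    for (tr in fit$restart_traces)
      expect_gte(min(diff(tr)), -1e-9)
  }
})

test_that("posterior assignment breaks ties to the lowest index", {
  two_same <- mixture_markov_params(
    c(0.5, 0.5), rbind(c(0.5, 0.5), c(0.5, 0.5)),
    array(rep(c(0.9, 0.2, 0.1, 0.8), 2), c(2, 2, 2)))
  asg <- posterior_assign(list(state_sequence("a", c(1, 2)),
                               state_sequence("b", c(2, 1))), two_same)
  expect_identical(asg$cluster, c(1L, 1L))
  expect_equal(asg$p_1, c(0.5, 0.5))

  p1000 <- mixture_markov_params(
    c(1, 0, 0, 0), matrix(0.5, 4, 2), array(0.5, c(2, 2, 4)))
  asg2 <- posterior_assign(lapply(rand_paths(5, 2), state_sequence,
                                  patient_id = "x"), p1000)
  expect_true(all(asg2$cluster == 1L))
})

test_that("component matching recovers identity and swaps", {
  set.seed(11)
  truth <- rand_params(4, 5)
  perm0 <- match_components(truth, truth)
  expect_identical(as.integer(perm0), 1:4)
  expect_equal(attr(perm0, "distance"), 0)

  shuffle <- c(3, 1, 4, 2)
  shuffled <- mixture_markov_params(truth$mixing[shuffle],
                                    truth$initial[shuffle, ],
                                    truth$transition[, , shuffle])
  # shuffled component j holds truth component shuffle[j]
  perm <- match_components(shuffled, truth)
  expect_identical(as.integer(perm), order(shuffle))

  # small perturbation still matches identity
  noisy <- truth
  noisy$transition <- noisy$transition +
    array(runif(100, 0, 0.01), c(5, 5, 4))
  noisy$transition <- array(
    apply(noisy$transition, 3, function(m) m / rowSums(m)), c(5, 5, 4))
  noisy <- mixture_markov_params(truth$mixing, truth$initial,
                                 noisy$transition)
  expect_identical(as.integer(match_components(noisy, truth)), 1:4)
  expect_error(match_components(rand_params(2, 5), truth), "equal K")
})

test_that("model JSON serialisation round-trips exactly", {
  set.seed(2)
  seqs <- lapply(rand_paths(25, 5, c(3, 8)), state_sequence, patient_id = "x")
  fit <- fit_em(seqs, 2, n_restarts = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(back$params$mixing, fit$params$mixing, tolerance = 1e-15)
  expect_equal(back$params$initial, fit$params$initial, tolerance = 1e-15)
  expect_equal(back$params$transition, fit$params$transition,
               tolerance = 1e-15)
  expect_equal(back$log_likelihood, fit$log_likelihood, tolerance = 1e-12)
  expect_identical(back$params$state_labels, fit$params$state_labels)
})
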