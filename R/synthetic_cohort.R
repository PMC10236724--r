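#' Synthetic-cohort generator configuration
#'
#' Fully specifies an EHR-style synthetic cohort: the ground-truth mixture
#' of Markov chains, per-patient sequence lengths, nuisance-event
#' probabilities that exercise the sequence-builder rules, and the CDAI
#' visit model.
#'
#' @param n_patients number of patients (>= 0).
#' @param params ground-truth [mixture_markov_params()].
#' @param seq_length_range integer pair `c(min, max)` of Markov states per
#'   patient; `min >= 2` so the inclusion filters are satisfiable. Occupied
#'   windows can be fewer than states when the multiple-encounter rule
#'   packs two distinct consecutive states into one window.
#' @param dup_rx_prob probability a state also emits a redundant duplicate
#'   prescription of the same drug inside its window.
#' @param multi_drug_prob probability the next state shares the current
#'   window (only taken when the two states are distinct classes, so the
#'   within-window collapsing rule never deletes a true state).
#' @param gap_prob probability of an empty 3-month window inserted between
#'   consecutive occupied windows.
#' @param study_start `Date`; first prescriptions are drawn on/after it.
#' @param first_rx_spread_days first-prescription dates are uniform on
#'   `study_start + 0..first_rx_spread_days`.
#' @param cdai_profiles K x 8 matrix of yearly mean CDAI (years -1..6),
#'   values in \[0, 76\].
#' @param cdai_sd non-negative Gaussian noise SD for CDAI visits (values
#'   truncated back into \[0, 76\]).
#' @param icd_late_prob probability a patient's only RA diagnosis code is
#'   dated < 90 days before the first biologic (deliberate inclusion-filter
#'   violation, default 0).
#' @param seed integer seed; the cohort is byte-identical given the config.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_patients, params, seq_length_range = c(8L, 20L),
                             dup_rx_prob = 0, multi_drug_prob = 0,
                             gap_prob = 0,
                             study_start = as.Date("2008-01-01"),
                             first_rx_spread_days = 1460L,
                             cdai_profiles = NULL, cdai_sd = 6,
                             icd_late_prob = 0, seed = 1L) {
  stopifnot(inherits(params, "mixture_markov_params"),
            n_patients >= 0, length(seq_length_range) == 2,
            seq_length_range[1] >= 2,
            seq_length_range[1] <= seq_length_range[2])
  probs <- c(dup_rx_prob, multi_drug_prob, gap_prob, icd_late_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (is.null(cdai_profiles))
    cdai_profiles <- matrix(rep(c(22, 20, 18, 16, 15, 14, 14, 14), params$K),
                            nrow = params$K, byrow = TRUE)
  cdai_profiles <- as.matrix(cdai_profiles)
  stopifnot(nrow(cdai_profiles) == params$K, ncol(cdai_profiles) == 8,
            all(cdai_profiles >= 0), all(cdai_profiles <= 76),
            cdai_sd >= 0)
  structure(
    list(n_patients = as.integer(n_patients), params = params,
         seq_length_range = as.integer(seq_length_range),
         dup_rx_prob = dup_rx_prob, multi_drug_prob = multi_drug_prob,
         gap_prob = gap_prob, study_start = as.Date(study_start),
         first_rx_spread_days = as.integer(first_rx_spread_days),
         cdai_profiles = cdai_profiles, cdai_sd = cdai_sd,
         icd_late_prob = icd_late_prob, seed = as.integer(seed)),
    class = "generator_config")
}

#' Named preset generator scenarios
#'
#' `"paper_default"` encodes the published 4-cluster structure of
#' b/tsDMARD use in RA as fixed repository constants: mixing proportions
#' (0.65, 0.08, 0.14, 0.13) and components (1) near-absorbing TNFi
#' persisters, (2) TNFi-to-abatacept with abatacept near-absorbing,
#' (3) rituximab-dominant, (4) high switching with elevated tocilizumab
#' occupancy. Rarely visited transition rows deterministically return to
#' the component's dominant class so the stated world keeps them
#' identifiable; CDAI year profiles order component 1 lowest. Defaults:
#' 2000 patients, 8-20 states, duplicate/multi-drug/gap probabilities
#' 0.2/0.1/0.1, CDAI noise SD 6.
#'
#' `"single_class"` is a K = 1 degenerate chain absorbed in TNFi, with all
#' nuisance probabilities 0, for closed-form tests.
#'
#' @param name preset identifier.
#' @param ... overrides passed to [generator_config()] (e.g. `n_patients`,
#'   `seed`, nuisance probabilities).
#' @return a [generator_config()].
#' @export
#' @examples
#' cfg <- preset_scenario("paper_default", n_patients = 100, seed = 7)
preset_scenario <- function(name, ...) {
  presets <- c("paper_default", "single_class")
  if (!name %in% presets)
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "))
  dots <- list(...)
  if (name == "paper_default") {
    mixing <- c(0.65, 0.08, 0.14, 0.13)
    initial <- rbind(
      c(0.97, 0.0075, 0.0075, 0.0075, 0.0075),
      c(0.60, 0.36, 0.02, 0.01, 0.01),
      c(0.30, 0.01, 0.01, 0.01, 0.67),
      c(0.64, 0.12, 0.19, 0.04, 0.01))
    # class-persistence rows shared across components: how patients behave
    # once on abatacept / tocilizumab / a JAKi / rituximab is modelled as a
    # property of the drug class, so components whose patients rarely reach
    # a class reuse the row of the component dominating that class's
    # traffic (keeps every row identifiable in the stated world)
    row_aba <- c(0.030, 0.956, 0.006, 0.004, 0.004)   # abatacept-persistent,
                                                      # occasional TNFi retrial
    row_il6 <- c(0.04, 0.03, 0.82, 0.07, 0.04)        # cycler IL6R row
    row_jak <- c(0.04, 0.03, 0.10, 0.79, 0.04)        # cycler JAKi row
    row_rtx <- c(0.018, 0.0015, 0.0015, 0.001, 0.978) # rituximab-persistent,
                                                      # occasional TNFi retrial
    transition <- array(0, c(5, 5, 4))
    # component 1: TNFi persisters; excursions return to TNFi immediately
    transition[, , 1] <- rbind(
      c(0.998, 0.0005, 0.0005, 0.0005, 0.0005),
      c(1, 0, 0, 0, 0),
      c(1, 0, 0, 0, 0),
      c(1, 0, 0, 0, 0),
      c(1, 0, 0, 0, 0))
    # component 2: TNFi -> abatacept, abatacept near-absorbing
    transition[, , 2] <- rbind(
      c(0.84, 0.152, 0.004, 0.002, 0.002),
      row_aba, row_il6, row_jak, row_rtx)
    # component 3: rituximab-dominant, faster TNFi abandonment
    transition[, , 3] <- rbind(
      c(0.55, 0.004, 0.004, 0.002, 0.44),
      row_aba, row_il6, row_jak, row_rtx)
    # component 4: cyclers, elevated tocilizumab (IL6R) occupancy
    transition[, , 4] <- rbind(
      c(0.70, 0.03, 0.17, 0.06, 0.04),
      c(0.03, 0.74, 0.16, 0.03, 0.04),
      row_il6, row_jak,
      c(0.02, 0.02, 0.12, 0.02, 0.82))
    params <- mixture_markov_params(mixing, initial, transition)
    profiles <- rbind(
      c(12, 10, 8, 7, 7, 6, 6, 6),
      c(22, 20, 16, 13, 11, 10, 9, 9),
      c(24, 23, 21, 22, 20, 21, 20, 21),
      c(26, 24, 22, 23, 22, 21, 22, 22))
    args <- list(n_patients = 2000L, params = params,
                 seq_length_range = c(8L, 20L), dup_rx_prob = 0.2,
                 multi_drug_prob = 0.1, gap_prob = 0.1,
                 cdai_profiles = profiles, cdai_sd = 6, seed = 1L)
  } else {
    params <- mixture_markov_params(
      mixing = 1,
      initial = matrix(c(1, 0, 0, 0, 0), 1),
      transition = diag(5))
    args <- list(n_patients = 100L, params = params,
                 seq_length_range = c(8L, 20L),
                 cdai_profiles = matrix(c(12, 10, 8, 7, 7, 6, 6, 6), 1),
                 cdai_sd = 4, seed = 1L)
  }
  args[names(dots)] <- dots
  do.call(generator_config, args)
}

#' Draw state paths from a mixture of Markov chains
#'
#' Forward simulation of the model: component `z_i` from the mixing
#' proportions, then a path of uniform random length from that component's
#' initial distribution and transition matrix.
#'
#' @param params a [mixture_markov_params()].
#' @param n number of paths.
#' @param length_range integer pair of path lengths (uniform).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return list with `z` (component index per path) and `paths` (list of
#'   integer state vectors).
#' @export
simulate_state_paths <- function(params, n, length_range = c(8L, 20L),
                                 seed = NULL) {
  draw <- function() {
    S <- params$S
    z <- sample.int(params$K, n, replace = TRUE, prob = params$mixing)
    # sample() would misread a degenerate range like 12:12
    lens <- length_range[1] +
      sample.int(length_range[2] - length_range[1] + 1L, n,
                 replace = TRUE) - 1L
    paths <- vector("list", n)
    for (i in seq_len(n)) {
      k <- z[i]
      st <- integer(lens[i])
      st[1L] <- sample.int(S, 1L, prob = params$initial[k, ])
      for (t in seq_len(lens[i] - 1L))
        st[t + 1L] <- sample.int(S, 1L, prob = params$transition[st[t], , k])
      paths[[i]] <- st
    }
    list(z = z, paths = paths)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate an EHR-style synthetic cohort
#'
#' The forward direction of the whole pipeline: draws a component and state
#' path per patient, renders states as concrete drug names dated inside
#' consecutive 91-day windows anchored at a per-patient first-prescription
#' date on/after `study_start`, injects nuisance events (duplicate
#' prescriptions, two-state windows, empty gap windows), emits one RA
#' diagnosis code 90-365 days before the first prescription, and yearly
#' CDAI visits (years -1..6) at the component's yearly mean plus truncated
#' Gaussian noise. Deterministic given the config seed.
#'
#' @param config a [generator_config()].
#' @return object of class `synthetic_cohort`: data.frames `prescriptions`
#'   (`patient_id`, `date`, `drug_name`), `diagnoses` (`patient_id`,
#'   `date`, `code`), `visits` (`patient_id`, `date`, `cdai`); named
#'   integer `true_labels`; list `true_sequences` of [state_sequence()];
#'   character `icd_late_ids`; the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  params <- config$params
  if (params$S != 5)
    stop("cohort rendering needs the 5-class drug state space")
  map <- drug_class_map()
  class_members <- split(names(map), unclass(map))
  ra_codes <- c("714.0", "714.2", "M05.79", "M06.9")
  n <- config$n_patients
  empty <- function(...) {
    df <- data.frame(...)
    df[0, , drop = FALSE]
  }
  if (n == 0) {
    return(structure(list(
      prescriptions = empty(patient_id = "", date = as.Date("2008-01-01"),
                            drug_name = ""),
      diagnoses = empty(patient_id = "", date = as.Date("2008-01-01"),
                        code = ""),
      visits = empty(patient_id = "", date = as.Date("2008-01-01"), cdai = 0),
      true_labels = setNames(integer(0), character(0)),
      true_sequences = list(), icd_late_ids = character(0),
      config = config), class = "synthetic_cohort"))
  }

  withr::with_seed(config$seed, {
    sim <- simulate_state_paths(params, n, config$seq_length_range)
    ids <- sprintf("P%05d", seq_len(n))
    rx_list <- vector("list", n)
    dx_list <- vector("list", n)
    vis_list <- vector("list", n)
    seqs <- vector("list", n)
    icd_late <- runif(n) < config$icd_late_prob

    for (i in seq_len(n)) {
      st <- sim$paths[[i]]
      L <- length(st)
      k <- sim$z[i]
      first_rx <- config$study_start +
        sample.int(config$first_rx_spread_days + 1L, 1L) - 1L

      # pack states into occupied windows: a state may join the previous
      # state's window when flagged, distinct in class, and the window holds
      # only one state so far
      win <- integer(L)
      win[1L] <- 1L
      for (t in 2:L) {
        join <- runif(1) < config$multi_drug_prob &&
          st[t] != st[t - 1L] &&
          (t == 2L || win[t - 1L] != win[t - 2L])
        win[t] <- if (join) win[t - 1L] else win[t - 1L] + 1L
      }
      # insert empty windows between occupied ones (true path unchanged)
      n_win <- win[L]
      gaps <- if (n_win > 1L) cumsum(c(0L, runif(n_win - 1L) < config$gap_prob))
              else 0L
      actual <- win + gaps[win]

      # render prescriptions: drug uniform within class, dated at window
      # start + jitter; second state of a window dated later; duplicates a
      # few days after their original
      pos_in_win <- ave(win, win, FUN = seq_along)
      dates <- as.Date(rep(NA, L))
      drugs <- character(L)
      for (t in seq_len(L)) {
        base <- first_rx + 91L * (actual[t] - 1L)
        # the very first prescription anchors the window grid: no jitter
        off <- if (t == 1L) 0L
               else if (pos_in_win[t] == 1L) sample(0:10, 1L)
               else sample(45:80, 1L)
        dates[t] <- base + off
        drugs[t] <- sample(class_members[[st[t]]], 1L)
      }
      dup <- runif(L) < config$dup_rx_prob
      rx <- data.frame(patient_id = ids[i],
                       date = c(dates, dates[dup] + sample(1:8, sum(dup),
                                                           replace = TRUE)),
                       drug_name = c(drugs, drugs[dup]),
                       stringsAsFactors = FALSE)
      rx_list[[i]] <- rx[order(rx$date), , drop = FALSE]

      lead <- if (icd_late[i]) sample(5:45, 1L) else sample(90:365, 1L)
      dx_list[[i]] <- data.frame(patient_id = ids[i],
                                 date = first_rx - lead,
                                 code = sample(ra_codes, 1L),
                                 stringsAsFactors = FALSE)

      years <- -1:6
      vdates <- first_rx + floor(365.25 * years) +
        sample(30:300, length(years), replace = TRUE)
      cdai <- config$cdai_profiles[k, ] +
        if (config$cdai_sd > 0) rnorm(length(years), 0, config$cdai_sd) else 0
      vis_list[[i]] <- data.frame(patient_id = ids[i], date = vdates,
                                  cdai = pmin(pmax(cdai, 0), 76),
                                  stringsAsFactors = FALSE)

      seqs[[i]] <- state_sequence(ids[i], st, window_index = actual,
                                  first_rx_date = first_rx)
    }

    structure(list(
      prescriptions = do.call(rbind, rx_list),
      diagnoses = do.call(rbind, dx_list),
      visits = do.call(rbind, vis_list),
      true_labels = setNames(sim$z, ids),
      true_sequences = setNames(seqs, ids),
      icd_late_ids = ids[icd_late],
      config = config), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d patients, %d prescriptions, %d visits (K = %d)\n",
    length(x$true_labels), nrow(x$prescriptions), nrow(x$visits),
    x$config$params$K))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `prescriptions.csv`, `diagnoses.csv`, `visits.csv` and
#' `truth.csv` (patient_id, component, hyphen-joined class-label state
#' path) with ISO-8601 dates.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE)
  wr(cohort$prescriptions, "prescriptions.csv")
  wr(cohort$diagnoses, "diagnoses.csv")
  wr(cohort$visits, "visits.csv")
  labels <- gsub("-", "", state_labels(), fixed = TRUE)
  truth <- data.frame(
    patient_id = names(cohort$true_labels),
    component = unname(cohort$true_labels),
    state_path = vapply(cohort$true_sequences, function(s)
      paste(labels[s$states], collapse = "-"), character(1)),
    stringsAsFactors = FALSE)
  wr(truth, "truth.csv")
  invisible(dir)
}
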