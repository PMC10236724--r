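#' Descriptive cluster profiles
#'
#' For each cluster: size and cohort share, distributions of the first and
#' last state of each patient's path, the distribution of the number of
#' distinct classes tried (bucketed 1 / 2 / 3-5), and the fraction of
#' patients staying on a single class throughout.
#'
#' @param sequences named list of [state_sequence()].
#' @param assignments data.frame with `patient_id` and `cluster` (as from
#'   [posterior_assign()]).
#' @param S number of classes (default 5).
#' @return list of per-cluster profiles (class `cluster_profiles`), each
#'   with `cluster`, `n`, `share`, `first_state_dist`, `last_state_dist`,
#'   `n_classes_dist`, `single_class_frac`.
#' @export
profile_clusters <- function(sequences, assignments, S = 5) {
  sequences <- as_state_sequences(sequences)
  ids <- vapply(sequences, function(s) as.character(s$patient_id),
                character(1))
  cl <- assignments$cluster[match(ids, as.character(assignments$patient_id))]
  if (anyNA(cl)) stop("every sequence needs an assignment")
  labels <- if (S == 5) state_labels() else paste0("s", seq_len(S))
  n_total <- length(sequences)
  out <- lapply(sort(unique(assignments$cluster)), function(k) {
    in_k <- which(cl == k)
    if (length(in_k) == 0) {
      return(list(cluster = k, n = 0L, share = 0,
                  first_state_dist = setNames(rep(NA_real_, S), labels),
                  last_state_dist = setNames(rep(NA_real_, S), labels),
                  n_classes_dist = c(`1` = NA_real_, `2` = NA_real_,
                                     `3-5` = NA_real_),
                  single_class_frac = NA_real_, empty = TRUE))
    }
    firsts <- vapply(sequences[in_k], function(s) s$states[1L], integer(1))
    lasts <- vapply(sequences[in_k], function(s)
      s$states[length(s$states)], integer(1))
    n_classes <- vapply(sequences[in_k], function(s)
      length(unique(s$states)), integer(1))
    bucket <- cut(n_classes, breaks = c(0, 1, 2, S),
                  labels = c("1", "2", "3-5"))
    list(cluster = k, n = length(in_k), share = length(in_k) / n_total,
         first_state_dist = setNames(
           as.numeric(tabulate(firsts, S)) / length(in_k), labels),
         last_state_dist = setNames(
           as.numeric(tabulate(lasts, S)) / length(in_k), labels),
         n_classes_dist = prop.table(table(bucket)),
         single_class_frac = mean(n_classes == 1L),
         empty = FALSE)
  })
  structure(out, class = "cluster_profiles")
}

#' Yearly mean CDAI per cluster
#'
#' Years are 365.25-day bins anchored at each patient's first b/tsDMARD
#' date (year 0 starts there; year -1 is the year before). Averaging is
#' two-stage: the mean CDAI per patient-year first, then the mean over
#' patients with at least one visit in the bin, so heavily-visited
#' patients do not dominate. Missing patient-years are excluded, not
#' imputed.
#'
#' @param visits data.frame `patient_id`, `date`, `cdai`.
#' @param sequences named list of [state_sequence()] (supplies
#'   `first_rx_date`).
#' @param assignments data.frame `patient_id`, `cluster`.
#' @param years integer years to report (default -1..6).
#' @return data.frame `cluster`, `year`, `mean_cdai`, `n` (patients
#'   contributing to the cell).
#' @export
cdai_yearly_means <- function(visits, sequences, assignments, years = -1:6) {
  sequences <- as_state_sequences(sequences)
  ids <- vapply(sequences, function(s) as.character(s$patient_id),
                character(1))
  first_rx <- setNames(as.Date(vapply(sequences, function(s)
    as.character(s$first_rx_date), character(1))), ids)
  cl <- setNames(assignments$cluster, as.character(assignments$patient_id))
  if (nrow(visits) == 0)
    return(data.frame(cluster = integer(0), year = integer(0),
                      mean_cdai = numeric(0), n = integer(0)))
  v <- visits[as.character(visits$patient_id) %in% ids, , drop = FALSE]
  v$date <- as.Date(v$date)
  pid <- as.character(v$patient_id)
  v$year <- floor(as.numeric(v$date - first_rx[pid]) / 365.25)
  v$cluster <- cl[pid]
  v <- v[v$year %in% years & !is.na(v$cluster), , drop = FALSE]
  # patient-year means first, then cluster-year means over patients
  py <- aggregate(cdai ~ patient_id + cluster + year, data = v, FUN = mean)
  cy <- aggregate(cdai ~ cluster + year, data = py,
                  FUN = function(x) c(mean(x), length(x)))
  out <- data.frame(cluster = cy$cluster, year = cy$year,
                    mean_cdai = cy$cdai[, 1], n = as.integer(cy$cdai[, 2]))
  out[order(out$cluster, out$year), , drop = FALSE]
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA from explicit sums of squares:
#' `F = MS_between / MS_within` on `(K - 1, n - K)` degrees of freedom.
#' Applied to 0/1 indicators it reproduces the proportions comparison used
#' alongside the cluster profiles.
#'
#' @param values numeric vector.
#' @param groups group labels, same length; >= 2 groups with >= 2 values
#'   each.
#' @return list `statistic`, `p.value`, `df` (length 2).
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  split_v <- split(as.numeric(values), groups)
  K <- length(split_v)
  n <- length(values)
  if (K < 2 || any(lengths(split_v) < 2) || n <= K)
    stop("one-way ANOVA needs >= 2 groups with >= 2 values each")
  grand <- mean(values)
  ss_between <- sum(vapply(split_v, function(g)
    length(g) * (mean(g) - grand)^2, numeric(1)))
  ss_within <- sum(vapply(split_v, function(g)
    sum((g - mean(g))^2), numeric(1)))
  df1 <- K - 1
  df2 <- n - K
  if (ss_within == 0 && ss_between == 0)
    stop("F undefined: zero variance within and between groups")
  f <- (ss_between / df1) / (ss_within / df2)
  list(statistic = f, p.value = pf(f, df1, df2, lower.tail = FALSE),
       df = c(df1, df2))
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based H statistic with the standard tie correction; p-value from
#' the chi-squared approximation on `K - 1` degrees of freedom. All values
#' identical returns `H = 0` (tie-correction guard) rather than failing.
#'
#' @inheritParams anova_oneway
#' @return list `statistic`, `p.value`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  split_idx <- split(seq_along(values), groups)
  K <- length(split_idx)
  if (K < 2 || any(lengths(split_idx) == 0))
    stop("Kruskal-Wallis needs >= 2 nonempty groups")
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(vapply(split_idx, function(ix) sum(r[ix])^2 / length(ix),
               numeric(1))) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- if (correction == 0) 0 else h / correction
  list(statistic = h,
       p.value = pchisq(h, K - 1, lower.tail = FALSE),
       df = K - 1)
}
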