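test_that("within-window multi-drug encounters collapse consecutive classes", {
  # A,A,C,C inside one 91-day window reconstructs as A -> C
  rx <- rx_table("p1", c("2010-01-01", "2010-01-10", "2010-02-01",
                         "2010-02-20"),
                 c("adalimumab", "adalimumab", "tocilizumab", "tocilizumab"))
  s <- build_sequence(rx)
  expect_identical(s$states, c(1L, 3L))
  expect_identical(s$window_index, c(1L, 1L))

  # two prescriptions of the same drug: the window is "simply B"
  rx2 <- rx_table("p2", c("2010-01-01", "2010-02-15"),
                  c("abatacept", "abatacept"))
  expect_identical(build_sequence(rx2)$states, 2L)

  # repeated states across windows are retained: TNFi -> TNFi -> TNFi
  rx3 <- rx_table("p3", c("2010-01-01", "2010-04-05", "2010-07-08"),
                  c("etanercept", "etanercept", "adalimumab"))
  s3 <- build_sequence(rx3)
  expect_identical(s3$states, c(1L, 1L, 1L))
  expect_identical(s3$window_index, 1:3)
})

test_that("zero-encounter windows contribute no state and are skipped", {
  rx <- rx_table("p", c("2010-01-01", "2010-10-01"),  # windows 1 and 4
                 c("etanercept", "rituximab"))
  s <- build_sequence(rx)
  expect_identical(s$states, c(1L, 5L))
  expect_identical(s$window_index, c(1L, 4L))
})

test_that("same-day prescriptions break ties by class index", {
  rx <- rx_table("p", rep("2010-01-01", 2), c("rituximab", "abatacept"))
  expect_identical(build_sequence(rx)$states, c(2L, 5L))
})

test_that("collapsing is only within-window for arbitrary built sequences", {
  co <- simulate_cohort(preset_scenario("paper_default", n_patients = 60,
                                        seed = 17))
  built <- build_all(co$prescriptions, co$diagnoses)
  for (s in built$sequences) {
    L <- length(s$states)
    if (L >= 2) {
      same <- s$states[-1] == s$states[-L]
      expect_true(all(s$window_index[-1][same] != s$window_index[-L][same]))
      expect_true(!is.unsorted(s$window_index))
    }
  }
})

test_that("inclusion filters apply in order with reproducible reasons", {
  cfg <- filter_config(study_start = as.Date("2008-01-01"))
  dx <- ra_dx(c("a", "b", "c", "d"),
              c("2009-09-02", "2009-12-22", "2008-06-01", "2009-10-01"))
  # a: one prescription only -> insufficient_rx
  # b: RA code 10 days before first rx -> no_prior_ra_icd
  # c: prescription before study start -> rx_before_study_start
  # d: rx on day 0 and day 95, code 120 days prior -> included
  rx <- rbind(
    rx_table("a", "2010-01-01", "etanercept"),
    rx_table("b", c("2010-01-01", "2010-06-01"), "etanercept"),
    rx_table("c", c("2007-12-01", "2010-01-01"), "etanercept"),
    rx_table("d", c("2010-01-29", "2010-05-04"), "etanercept"))
  res <- apply_cohort_filters(rx, dx, cfg)
  expect_identical(res$eligible, "d")
  expect_identical(res$exclusions$reason[match(c("a", "b", "c"),
                                               res$exclusions$patient_id)],
                   c("insufficient_rx", "no_prior_ra_icd",
                     "rx_before_study_start"))

  # sensitivity mode readmits the late-ICD patient
  res2 <- apply_cohort_filters(rx, dx, filter_config(require_icd = FALSE))
  expect_true(all(c("b", "d") %in% res2$eligible))

  # empty prescriptions: empty result, no error
  expect_identical(
    apply_cohort_filters(rx[0, ], dx, cfg)$eligible, character(0))
})

test_that("idempotence: clean one-prescription-per-window data maps 1:1", {
  dates <- as.Date("2010-01-01") + 91 * (0:5)
  rx <- rx_table("p", dates, c("etanercept", "etanercept", "tocilizumab",
                               "tocilizumab", "abatacept", "abatacept"))
  s <- build_sequence(rx)
  expect_identical(s$states, c(1L, 1L, 3L, 3L, 2L, 2L))
  expect_identical(s$window_index, 1:6)
})

test_that("build_all round-trips the nuisance-free generator and counts uniques", {
  cfg <- preset_scenario("paper_default", n_patients = 100, seed = 7,
                         dup_rx_prob = 0, multi_drug_prob = 0, gap_prob = 0)
  co <- simulate_cohort(cfg)
  built <- build_all(co$prescriptions, co$diagnoses)
  expect_identical(length(built$sequences), 100L)
  expect_true(sequences_match_truth(built, co))

  # independent recount of unique sequences from the truth table
  truth_paths <- vapply(co$true_sequences, function(s)
    paste(s$states, collapse = "-"), character(1))
  expect_identical(built$summary$n_unique_sequences,
                   length(unique(truth_paths)))
})

test_that("unknown drugs fail loudly unless downgraded to a logged skip", {
  rx <- rbind(rx_table("p", c("2010-01-01", "2010-04-15"), "etanercept"),
              rx_table("p", "2010-02-01", "methotrexate"))
  dx <- ra_dx("p", "2009-06-01")
  expect_error(build_all(rx, dx), class = "rxseq_unknown_drug")
  expect_message(res <- build_all(rx, dx, ignore_unknown_drugs = TRUE),
                 "dropping 1")
  expect_identical(res$summary$n_unknown_rx_dropped, 1L)
  expect_identical(res$sequences[["p"]]$states, c(1L, 1L))
})

test_that("sequence CSV round trip preserves states, windows and dates", {
  co <- simulate_cohort(preset_scenario("paper_default", n_patients = 30,
                                        seed = 5))
  built <- build_all(co$prescriptions, co$diagnoses)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sequences(built$sequences, path)
  back <- read_sequences(path)
  expect_identical(names(back), names(built$sequences))
  for (id in names(back)) {
    expect_identical(back[[id]]$states, built$sequences[[id]]$states)
    expect_identical(back[[id]]$window_index,
                     built$sequences[[id]]$window_index)
    expect_identical(back[[id]]$first_rx_date,
                     built$sequences[[id]]$first_rx_date)
  }
})

test_that("an extraction end date truncates prescriptions before filtering", {
  rx <- rx_table("p", c("2010-01-01", "2010-05-01", "2012-01-01"),
                 c("etanercept", "etanercept", "rituximab"))
  dx <- ra_dx("p", "2009-06-01")
  cfg <- filter_config(end_date = as.Date("2010-12-31"))
  s <- build_sequence(rx, config = cfg)
  expect_identical(s$states, c(1L, 1L))
})
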