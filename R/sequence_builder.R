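#' Cohort-inclusion filter configuration
#'
#' Operationalises the inclusion rules: first b/tsDMARD prescription on or
#' after `study_start` (and none before), an RA diagnosis code at least
#' `icd_lead_days` before the first b/tsDMARD (droppable for the
#' sensitivity analysis), and two b/tsDMARD prescriptions at least
#' `min_rx_gap_days` apart. "3 months" is 90 days for the gap rules and 91
#' days for the encounter windows; both configurable.
#'
#' @param study_start `Date` cohort entry boundary.
#' @param icd_lead_days minimum days the RA code must precede the first
#'   b/tsDMARD (default 90).
#' @param min_rx_gap_days minimum spread between two prescriptions
#'   (default 90).
#' @param require_icd `FALSE` reproduces the sensitivity analysis without
#'   the RA-code requirement.
#' @param window_days encounter-window length in days (default 91).
#' @param end_date optional data-extraction end `Date`; prescriptions after
#'   it are dropped before filtering (default: no truncation).
#' @param ra_code_pattern regex matched against diagnosis codes to flag RA
#'   (default: ICD-9 714.x and ICD-10 M05/M06).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(study_start = as.Date("2008-01-01"),
                          icd_lead_days = 90L, min_rx_gap_days = 90L,
                          require_icd = TRUE, window_days = 91L,
                          end_date = NULL,
                          ra_code_pattern = "^(714|M05|M06)") {
  stopifnot(icd_lead_days > 0, min_rx_gap_days > 0, window_days > 0)
  structure(
    list(study_start = as.Date(study_start),
         icd_lead_days = as.integer(icd_lead_days),
         min_rx_gap_days = as.integer(min_rx_gap_days),
         require_icd = isTRUE(require_icd),
         window_days = as.integer(window_days),
         end_date = if (!is.null(end_date)) as.Date(end_date),
         ra_code_pattern = ra_code_pattern),
    class = "filter_config")
}

# normalise a prescriptions data.frame: Date dates, lowercase drugs
norm_rx <- function(prescriptions) {
  stopifnot(all(c("patient_id", "date", "drug_name") %in%
                  colnames(prescriptions)))
  prescriptions$date <- as.Date(prescriptions$date)
  prescriptions$drug_name <- tolower(trimws(prescriptions$drug_name))
  prescriptions
}

#' Apply the cohort-inclusion filters
#'
#' A patient is eligible iff, in order: (a) the first b/tsDMARD
#' prescription is on/after `study_start` with none before it; (b) when
#' `require_icd`, at least one RA diagnosis is dated `icd_lead_days` or
#' more before the first b/tsDMARD; (c) two b/tsDMARD prescriptions lie
#' `min_rx_gap_days` or more apart. The exclusion log records the first
#' failing criterion per excluded patient (`"rx_before_study_start"`,
#' `"no_prior_ra_icd"`, `"insufficient_rx"`).
#'
#' @param prescriptions data.frame `patient_id`, `date`, `drug_name`
#'   (b/tsDMARD rows only; see [map_drug_to_class()]).
#' @param diagnoses data.frame `patient_id`, `date`, `code`.
#' @param config a [filter_config()].
#' @return list: `eligible` (character ids) and `exclusions` (data.frame
#'   `patient_id`, `reason`).
#' @export
apply_cohort_filters <- function(prescriptions, diagnoses,
                                 config = filter_config()) {
  out_empty <- list(eligible = character(0),
                    exclusions = data.frame(patient_id = character(0),
                                            reason = character(0)))
  if (nrow(prescriptions) == 0) return(out_empty)
  rx <- norm_rx(prescriptions)
  if (!is.null(config$end_date)) rx <- rx[rx$date <= config$end_date, ]
  if (nrow(rx) == 0) return(out_empty)
  diagnoses$date <- as.Date(diagnoses$date)
  is_ra <- grepl(config$ra_code_pattern, diagnoses$code)
  ra_dx <- diagnoses[is_ra, , drop = FALSE]

  ids <- sort(unique(as.character(rx$patient_id)))
  first_rx <- tapply(rx$date, as.character(rx$patient_id), min)[ids]
  last_rx <- tapply(rx$date, as.character(rx$patient_id), max)[ids]
  first_rx <- as.Date(first_rx, origin = "1970-01-01")
  last_rx <- as.Date(last_rx, origin = "1970-01-01")

  reasons <- character(length(ids))
  for (i in seq_along(ids)) {
    if (first_rx[i] < config$study_start) {
      reasons[i] <- "rx_before_study_start"
    } else if (config$require_icd) {
      dx_dates <- ra_dx$date[as.character(ra_dx$patient_id) == ids[i]]
      if (!any(dx_dates <= first_rx[i] - config$icd_lead_days)) {
        reasons[i] <- "no_prior_ra_icd"
      }
    }
    if (reasons[i] == "" &&
        as.integer(last_rx[i] - first_rx[i]) < config$min_rx_gap_days) {
      reasons[i] <- "insufficient_rx"
    }
  }
  keep <- reasons == ""
  list(eligible = ids[keep],
       exclusions = data.frame(patient_id = ids[!keep],
                               reason = reasons[!keep],
                               stringsAsFactors = FALSE))
}

#' Build one patient's drug-class state sequence
#'
#' Implements the 3-month encounter rules on a window grid anchored at the
#' first prescription date: a window with no prescriptions contributes no
#' state; a window whose prescriptions all map to one class contributes
#' that single state; a multi-class window orders prescriptions by date
#' (same-day ties by class index), maps them to classes and collapses
#' consecutive equal classes. Windows are concatenated in order without
#' collapsing across boundaries, so persistence shows up as repeated
#' states.
#'
#' @param prescriptions rows for one patient (`patient_id`, `date`,
#'   `drug_name`).
#' @param map a [drug_class_map()].
#' @param config a [filter_config()] (supplies `window_days`, `end_date`).
#' @return a [state_sequence()].
#' @export
build_sequence <- function(prescriptions, map = drug_class_map(),
                           config = filter_config()) {
  rx <- norm_rx(prescriptions)
  if (!is.null(config$end_date)) rx <- rx[rx$date <= config$end_date, ]
  if (nrow(rx) == 0) stop("no mappable prescriptions: cannot build a sequence")
  if (length(unique(rx$patient_id)) != 1L)
    stop("build_sequence expects one patient's prescriptions")
  cls <- map_drug_to_class(rx$drug_name, map)
  first_rx <- min(rx$date)
  win <- as.integer(floor(as.numeric(rx$date - first_rx) / config$window_days))
  ord <- order(win, rx$date, cls)
  win <- win[ord]
  cls <- cls[ord]
  states <- integer(0)
  windows <- integer(0)
  for (w in unique(win)) {
    in_w <- cls[win == w]
    collapsed <- rle(in_w)$values
    states <- c(states, collapsed)
    windows <- c(windows, rep(w + 1L, length(collapsed)))
  }
  state_sequence(patient_id = rx$patient_id[1L], states = states,
                 window_index = windows, first_rx_date = first_rx)
}

#' Filter a cohort and build all state sequences
#'
#' Applies [apply_cohort_filters()] then [build_sequence()] per eligible
#' patient. Unknown drug names abort by default; with
#' `ignore_unknown_drugs = TRUE` the offending rows are dropped up front
#' and reported in the summary.
#'
#' @inheritParams apply_cohort_filters
#' @param map a [drug_class_map()].
#' @param ignore_unknown_drugs drop (and count) unmappable rows instead of
#'   failing.
#' @return list: `sequences` (named list of [state_sequence()]),
#'   `exclusions`, and `summary` (`n_patients`, `n_prescriptions`,
#'   `n_unique_sequences`, `n_unknown_rx_dropped`).
#' @export
build_all <- function(prescriptions, diagnoses, map = drug_class_map(),
                      config = filter_config(),
                      ignore_unknown_drugs = FALSE) {
  rx <- norm_rx(prescriptions)
  known <- rx$drug_name %in% names(map)
  n_unknown <- sum(!known)
  if (n_unknown > 0) {
    if (!ignore_unknown_drugs) {
      map_drug_to_class(rx$drug_name, map)  # raises rxseq_unknown_drug
    }
    message("dropping ", n_unknown, " prescription row(s) with unmapped drugs")
    rx <- rx[known, , drop = FALSE]
  }
  flt <- apply_cohort_filters(rx, diagnoses, config)
  rx_split <- split(rx, as.character(rx$patient_id))
  seqs <- lapply(flt$eligible, function(id)
    build_sequence(rx_split[[id]], map, config))
  names(seqs) <- flt$eligible
  paths <- vapply(seqs, function(s) paste(s$states, collapse = "-"),
                  character(1))
  list(sequences = seqs, exclusions = flt$exclusions,
       summary = list(n_patients = length(seqs),
                      n_prescriptions = nrow(rx),
                      n_unique_sequences = length(unique(paths)),
                      n_unknown_rx_dropped = n_unknown))
}

#' Write / read state sequences as CSV
#'
#' Columns: `patient_id`, `first_rx_date`, `sequence` (hyphen-joined class
#' labels, e.g. `"TNFi-TNFi-IL6R"`), `windows` (hyphen-joined 1-based
#' window indices; an extension so yearly-rate features survive the round
#' trip). Labels with internal hyphens are written without them
#' (`CTLA4Ig`, `antiCD20`) so the separator stays unambiguous.
#'
#' @param sequences named list of [state_sequence()].
#' @param path CSV file path.
#' @param labels state labels used to encode/decode.
#' @return `read_sequences` returns a named list of [state_sequence()].
#' @export
write_sequences <- function(sequences, path, labels = state_labels()) {
  labels <- gsub("-", "", labels, fixed = TRUE)
  df <- data.frame(
    patient_id = vapply(sequences, function(s) as.character(s$patient_id),
                        character(1)),
    first_rx_date = as.Date(vapply(sequences, function(s)
      as.character(s$first_rx_date), character(1))),
    sequence = vapply(sequences, function(s)
      paste(labels[s$states], collapse = "-"), character(1)),
    windows = vapply(sequences, function(s)
      paste(s$window_index, collapse = "-"), character(1)),
    stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequences
#' @export
read_sequences <- function(path, labels = state_labels()) {
  labels <- gsub("-", "", labels, fixed = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  seqs <- lapply(seq_len(nrow(df)), function(i) {
    st <- match(strsplit(df$sequence[i], "-", fixed = TRUE)[[1]], labels)
    if (anyNA(st)) stop("unknown state label in ", path, " row ", i)
    win <- if ("windows" %in% colnames(df) && nzchar(df$windows[i]))
      as.integer(strsplit(df$windows[i], "-", fixed = TRUE)[[1]])
    else seq_along(st)
    state_sequence(df$patient_id[i], st, window_index = win,
                   first_rx_date = as.Date(df$first_rx_date[i]))
  })
  setNames(seqs, df$patient_id)
}
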