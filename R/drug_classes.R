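#' Drug class state labels
#'
#' The 5-class b/tsDMARD state space used throughout the package, in fixed
#' order: TNF inhibitors, CTLA4-Ig (abatacept), IL-6 receptor blockers,
#' JAK inhibitors, anti-CD20 (rituximab).
#'
#' @return character vector of length 5.
#' @export
state_labels <- function() {
  c("TNFi", "CTLA4-Ig", "IL6R", "JAKi", "anti-CD20")
}

#' Default drug name to class map
#'
#' Maps lowercase generic b/tsDMARD names to state indices 1..5 (see
#' [state_labels()]). TNFi: adalimumab, certolizumab, etanercept,
#' infliximab, golimumab; CTLA4-Ig: abatacept; IL6R: tocilizumab,
#' sarilumab; JAKi: tofacitinib, baricitinib, upadacitinib; anti-CD20:
#' rituximab.
#'
#' @param extra optional named integer vector of additional
#'   `drug_name = class_index` entries (e.g. biosimilar trade names).
#' @return named integer vector (class `drug_class_map`), values in 1..5.
#' @export
#' @examples
#' map <- drug_class_map()
#' map[["etanercept"]]  # 1 (TNFi)
drug_class_map <- function(extra = NULL) {
  map <- c(
    adalimumab = 1L, certolizumab = 1L, etanercept = 1L,
    infliximab = 1L, golimumab = 1L,
    abatacept = 2L,
    tocilizumab = 3L, sarilumab = 3L,
    tofacitinib = 4L, baricitinib = 4L, upadacitinib = 4L,
    rituximab = 5L
  )
  if (!is.null(extra)) {
    stopifnot(is.numeric(extra), !is.null(names(extra)), all(extra %in% 1:5))
    map <- c(map, setNames(as.integer(extra), tolower(names(extra))))
  }
  structure(map, class = "drug_class_map")
}

#' Map drug names to class state indices
#'
#' Case-insensitive, whitespace-trimmed lookup. Unknown drugs raise a
#' condition of class `rxseq_unknown_drug` carrying the offending names --
#' non-b/tsDMARD rows must be removed (or the caller must opt into
#' skipping) rather than silently dropped.
#'
#' @param drug_name character vector of drug names.
#' @param map a [drug_class_map()].
#' @return integer vector of state indices in 1..5.
#' @export
map_drug_to_class <- function(drug_name, map = drug_class_map()) {
  key <- tolower(trimws(drug_name))
  idx <- unname(unclass(map)[key])
  if (anyNA(idx)) {
    bad <- sort(unique(key[is.na(idx)]))
    stop(structure(
      class = c("rxseq_unknown_drug", "error", "condition"),
      list(
        message = paste0(
          "unknown drug name(s), not in the b/tsDMARD class map: ",
          paste(bad, collapse = ", ")
        ),
        call = sys.call(-1), drugs = bad
      )
    ))
  }
  as.integer(idx)
}
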