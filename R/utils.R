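#' Row-wise log-sum-exp
#'
#' Numerically stable `log(rowSums(exp(x)))`. Rows that are entirely `-Inf`
#' return `-Inf` (no NaN).
#'
#' @param x numeric matrix.
#' @return numeric vector, one value per row.
#' @keywords internal
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  out <- m + log(rowSums(exp(x - ifelse(is.finite(m), m, 0))))
  out[!is.finite(m)] <- -Inf
  out
}

#' Adjusted Rand index
#'
#' Agreement between two partitions, corrected for chance. 1 means identical
#' partitions (up to relabelling), 0 is the expectation under independent
#' random labelling.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return scalar ARI.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # degenerate: single cluster both sides
  (sum_ij - expected) / (max_idx - expected)
}

# All permutations of 1..n as a list (n! entries); used for label matching.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# FNV-1a 32-bit hash of a character scalar; used for config fingerprints in
# run manifests (no cryptographic intent).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keeps h a double below 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply split into 16-bit halves (doubles stay < 2^53)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
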