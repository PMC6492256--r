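#' Levenshtein distance and normalized distance
#'
#' Unit-cost edit distance (insertions, deletions, substitutions), computed
#' via the generalized edit distance in [utils::adist()]. The normalized
#' distance divides by the length of the longer string and is defined as 0
#' when both strings are empty; production accuracy is 1 minus the normalized
#' distance.
#'
#' @param a,b Character vectors, recycled to a common length; distances are
#'   computed element-wise.
#' @return `levenshtein()`: integer vector of edit distances.
#'   `normalized_levenshtein()`: numeric vector in `[0, 1]`.
#' @examples
#' levenshtein("an", "onk")            # 2
#' normalized_levenshtein("", "ak")    # 1
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0L) return(integer(0))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- as.integer(utils::adist(a[i], b[i])[1L, 1L])
  out
}

#' @rdname levenshtein
#' @export
normalized_levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0L) return(numeric(0))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  d <- levenshtein(a, b)
  len <- pmax(nchar(a), nchar(b))
  ifelse(len == 0L, 0, d / len)
}

#' All-pairs Levenshtein distance matrix
#'
#' @param a,b Character vectors.
#' @return Integer matrix of distances, `length(a)` x `length(b)`.
#' @export
levenshtein_matrix <- function(a, b) {
  m <- utils::adist(a, b)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}
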