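#' Segment a produced word into stem and suffix
#'
#' If some candidate stem is an exact prefix of the word, the word is split
#' there (`exact_prefix`; the longest such stem wins on ties). Otherwise every
#' split point is scored against every candidate stem by Levenshtein distance
#' and the minimizing split is chosen (`best_edit`; ties broken by longer
#' stem, then lexicographic stem order, then longer prefix) and the result is
#' flagged for manual review. An empty remainder yields the suffix code
#' `"NULL"`; `stem` is always the produced prefix, so `stem` plus the literal
#' suffix reconstructs the word.
#'
#' @param word Non-empty produced word.
#' @param candidate_stems Non-empty character vector of target stems.
#' @return List with `stem` (produced prefix), `suffix` (`"NULL"` when
#'   zero-marked), `method` (`"exact_prefix"` or `"best_edit"`),
#'   `matched_stem` (the closest candidate) and `review` (logical).
#' @examples
#' segment_word("wonak", c("won", "sum"))  # won + ak, exact_prefix
#' segment_word("snap", c("snap"))         # snap + NULL
#' @export
segment_word <- function(word, candidate_stems) {
  word <- as.character(word)
  if (length(word) != 1L || is.na(word) || !nzchar(word)) {
    stop("`word` must be a single non-empty string")
  }
  if (length(candidate_stems) == 0L) stop("`candidate_stems` must be non-empty")
  candidate_stems <- unique(as.character(candidate_stems))

  hits <- candidate_stems[startsWith(word, candidate_stems)]
  if (length(hits)) {
    s <- hits[which.max(nchar(hits))]
    rest <- substring(word, nchar(s) + 1L)
    return(list(stem = s, suffix = if (nzchar(rest)) rest else "NULL",
                method = "exact_prefix", matched_stem = s, review = FALSE))
  }

  prefixes <- substring(word, 1L, 0:nchar(word))
  d <- levenshtein_matrix(prefixes, candidate_stems)
  cand <- expand.grid(p = seq_along(prefixes), s = seq_along(candidate_stems))
  cand$dist <- d[cbind(cand$p, cand$s)]
  ord <- order(cand$dist, -nchar(candidate_stems)[cand$s],
               candidate_stems[cand$s], -nchar(prefixes)[cand$p])
  pick <- cand[ord[1L], ]
  stem <- prefixes[pick$p]
  rest <- substring(word, nchar(stem) + 1L)
  list(stem = stem, suffix = if (nzchar(rest)) rest else "NULL",
       method = "best_edit", matched_stem = candidate_stems[pick$s], review = TRUE)
}

#' Segment every word of a production against a target language
#'
#' Words are matched to word classes by position; each word is segmented
#' against the target stems of its class. Missing trailing words are returned
#' with method `"missing"`.
#'
#' @param words Character vector of produced words, in word-class order.
#' @param spec Target [language_spec()].
#' @return Data frame with one row per word class: `class`, `stem`, `suffix`,
#'   `method`, `matched_stem`, `review`.
#' @export
segment_production <- function(words, spec) {
  words <- words[!is.na(words) & nzchar(words)]
  if (length(words) > length(spec$word_classes)) {
    stop(sprintf("production has %d words but the language has %d word classes",
                 length(words), length(spec$word_classes)))
  }
  out <- lapply(seq_along(spec$word_classes), function(i) {
    cls <- spec$word_classes[i]
    if (i > length(words)) {
      return(data.frame(class = cls, stem = NA_character_, suffix = NA_character_,
                        method = "missing", matched_stem = NA_character_,
                        review = TRUE, stringsAsFactors = FALSE))
    }
    s <- segment_word(words[i], class_stems(spec, cls))
    data.frame(class = cls, stem = s$stem, suffix = s$suffix, method = s$method,
               matched_stem = s$matched_stem, review = s$review,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
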