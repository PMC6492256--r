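#' Score one production against the target language
#'
#' Each produced word is segmented against the target stems of its word class
#' ([segment_word()]); stem and suffix accuracy are then 1 minus the
#' normalized Levenshtein distance to the target stem and suffix from the
#' spec's segmentation index. A zero-marked suffix enters the distance as the
#' empty string, so producing nothing where the target has suffix `s` scores
#' `1 - normalized_levenshtein("", s)`. A missing word scores 0 on both.
#'
#' @param words Character vector of produced words in word-class order.
#' @param scene Named list / one-row data frame identifying the scene.
#' @param spec Target [language_spec()].
#' @return Data frame with one row per word class: `class`, `stem_accuracy`,
#'   `suffix_accuracy`, `method`, `review`.
#' @export
score_production <- function(words, scene, spec) {
  seg <- segment_production(words, spec)
  out <- lapply(seq_len(nrow(seg)), function(i) {
    cls <- seg$class[i]
    tgt <- target_segmentation(spec, scene, cls)
    if (seg$method[i] == "missing") {
      sa <- 0; su <- 0
    } else {
      sa <- 1 - normalized_levenshtein(seg$stem[i], tgt$stem)
      produced_suffix <- if (seg$suffix[i] == "NULL") "" else seg$suffix[i]
      su <- 1 - normalized_levenshtein(produced_suffix, tgt$suffix)
    }
    data.frame(class = cls, stem_accuracy = sa, suffix_accuracy = su,
               method = seg$method[i], review = seg$review[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Score a table of production records
#'
#' @param records Production records in the standard tabular layout (see
#'   [read_productions()]): `participant_id`, `phase`, the scene features,
#'   and `word1`, `word2`, ... in word-class order.
#' @param spec Target [language_spec()].
#' @return A tibble with one row per record x word class carrying the
#'   accuracy scores.
#' @export
score_productions <- function(records, spec) {
  records <- validate_productions(records, spec)
  feats <- names(spec$features)
  word_cols <- paste0("word", seq_along(spec$word_classes))
  out <- lapply(seq_len(nrow(records)), function(i) {
    words <- as.character(unlist(records[i, word_cols]))
    words <- words[!is.na(words)]
    sc <- as.list(records[i, feats])
    s <- score_production(words, sc, spec)
    cbind(records[rep(i, nrow(s)), c("participant_id", "phase", feats),
                  drop = FALSE], s, row.names = NULL)
  })
  tibble::as_tibble(do.call(rbind, out))
}

#' Aggregate accuracy as a mean of by-participant means
#'
#' Accuracy is first averaged within participant and round (over scenes and
#' word classes), then averaged across participants; the interval reported is
#' a 95% confidence interval on that mean of means (t-distribution for fewer
#' than 30 participants, normal otherwise; degenerate zero width for a single
#' participant).
#'
#' @param scored Output of [score_productions()].
#' @return A tibble with columns `phase`, `measure` (stem/suffix), `mean`,
#'   `ci_low`, `ci_high`, `n` (participants).
#' @export
aggregate_accuracy <- function(scored) {
  stopifnot(nrow(scored) > 0L)
  long <- rbind(
    data.frame(participant_id = scored$participant_id, phase = scored$phase,
               measure = "stem", acc = scored$stem_accuracy),
    data.frame(participant_id = scored$participant_id, phase = scored$phase,
               measure = "suffix", acc = scored$suffix_accuracy))
  by_part <- stats::aggregate(acc ~ participant_id + phase + measure, long, mean)
  agg <- stats::aggregate(acc ~ phase + measure, by_part,
                          function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  agg <- cbind(agg[c("phase", "measure")], as.data.frame(agg$acc))
  half <- ifelse(agg$n < 2, 0,
                 ifelse(agg$n < 30, stats::qt(0.975, agg$n - 1), stats::qnorm(0.975)) *
                   ifelse(is.na(agg$sd), 0, agg$sd) / sqrt(agg$n))
  tibble::tibble(phase = agg$phase, measure = agg$measure, mean = agg$mean,
                 ci_low = agg$mean - half, ci_high = agg$mean + half,
                 n = as.integer(agg$n))
}

# ---- production table I/O ----------------------------------------------

#' Read and write production record tables
#'
#' Production records are stored as UTF-8 CSV with header columns
#' `participant_id`, `phase` (an integer round or the label `"posttest"`),
#' the scene features of the governing language, the produced words `word1`,
#' `word2`, ... in word-class order, and an optional `condition` label.
#' Schema violations raise an error naming the offending rows.
#'
#' @param path CSV file path.
#' @param spec Target [language_spec()] used for validation.
#' @return `read_productions()`: a tibble of validated records.
#' @export
read_productions <- function(path, spec) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  tibble::as_tibble(validate_productions(df, spec))
}

#' @rdname read_productions
#' @param records Production record table.
#' @export
write_productions <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_productions <- function(records, spec) {
  feats <- spec$features
  word_cols <- paste0("word", seq_along(spec$word_classes))
  need <- c("participant_id", "phase", names(feats), word_cols[1])
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("production table missing column(s): ",
                         paste(miss, collapse = ", "))
  for (w in word_cols) if (!w %in% names(records)) records[[w]] <- NA_character_
  # hyphens are presentational (segmentation markers) and never part of the
  # actual strings; strip them on the way in
  for (w in word_cols) records[[w]] <- gsub("-", "", records[[w]], fixed = TRUE)
  bad <- rep(FALSE, nrow(records))
  for (f in names(feats)) {
    records[[f]] <- as.character(records[[f]])
    bad <- bad | !records[[f]] %in% feats[[f]]
  }
  ph <- as.character(records$phase)
  bad <- bad | !(ph == "posttest" | grepl("^[0-9]+$", ph))
  bad <- bad | is.na(records[[word_cols[1]]]) | !nzchar(records[[word_cols[1]]])
  if (any(bad)) {
    stop("invalid production rows (bad scene level, phase, or empty word1): ",
         paste(utils::head(which(bad), 10L), collapse = ", "))
  }
  records
}
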