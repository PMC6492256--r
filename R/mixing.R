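#' Select competent source speakers
#'
#' Identifies the participants whose early-phase stem productions exactly
#' matched the target stems for at least `criterion` of the scene labels
#' (a label counts as exact only if every word's stem is reproduced exactly).
#' These participants supply the training input for the mixed-input learning
#' conditions.
#'
#' @param records Production record table including the screening phase.
#' @param spec Target [language_spec()].
#' @param criterion Minimum exact-stem proportion (default 0.90).
#' @param phase Screening phase label (default 2).
#' @return Tibble with `participant_id`, `exact_stem_prop`, `selected`.
#' @export
select_sources <- function(records, spec, criterion = 0.90, phase = 2) {
  records <- validate_productions(records, spec)
  records <- records[as.character(records$phase) == as.character(phase), , drop = FALSE]
  if (nrow(records) == 0L) stop("no records at the screening phase")
  feats <- names(spec$features)
  word_cols <- paste0("word", seq_along(spec$word_classes))
  exact <- vapply(seq_len(nrow(records)), function(i) {
    words <- as.character(unlist(records[i, word_cols]))
    if (any(is.na(words)) || any(!nzchar(words))) return(FALSE)
    sc <- as.list(records[i, feats])
    all(vapply(seq_along(spec$word_classes), function(j) {
      tgt <- target_segmentation(spec, sc, spec$word_classes[j])$stem
      startsWith(words[j], tgt) &&
        segment_word(words[j], class_stems(spec, spec$word_classes[j]))$stem == tgt
    }, logical(1)))
  }, logical(1))
  prop <- tapply(exact, records$participant_id, mean)
  tibble::tibble(participant_id = names(prop),
                 exact_stem_prop = as.numeric(prop),
                 selected = as.numeric(prop) >= criterion)
}

#' Mixing design for multi-speaker training input
#'
#' @param population `"small"` (2 source speakers) or `"large"` (8).
#' @param composition `"complex"` (all sources contribute late-phase data) or
#'   `"mixed"` (half contribute early-phase, half late-phase data).
#' @param n_phase_items Scenes per training phase (default 9).
#' @return A `mixing_design` list with `n_sources` filled in.
#' @export
mixing_design <- function(population = c("small", "large"),
                          composition = c("complex", "mixed"),
                          n_phase_items = 9L) {
  population <- match.arg(population)
  composition <- match.arg(composition)
  structure(list(population = population, composition = composition,
                 n_sources = if (population == "small") 2L else 8L,
                 n_phase_items = as.integer(n_phase_items)),
            class = "mixing_design")
}

#' Construct one training phase of mixed multi-speaker input
#'
#' Samples `n_phase_items` scenes uniformly without replacement and divides
#' them across the source speakers: with two sources one contributes 5
#' descriptions and the other 4; with eight sources one (chosen uniformly)
#' contributes 2 and the rest 1 each. Every sampled scene is paired with the
#' description its assigned source produced for that scene at that source's
#' phase.
#'
#' @param design A [mixing_design()].
#' @param sources Data frame with `participant_id` and `phase`: which
#'   speaker supplies data from which phase (2 or 8 rows, matching the
#'   design).
#' @param records Production record table containing the sources' data.
#' @param spec Target [language_spec()].
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return Tibble of `n_phase_items` rows: scene features, `source_id`,
#'   `source_phase`, `description`.
#' @export
construct_training_phase <- function(design, sources, records, spec,
                                     seed = NULL) {
  stopifnot(inherits(design, "mixing_design"))
  if (nrow(sources) != design$n_sources) {
    stop(sprintf("design needs %d sources but %d were supplied",
                 design$n_sources, nrow(sources)))
  }
  records <- validate_productions(records, spec)
  feats <- names(spec$features)
  word_cols <- paste0("word", seq_along(spec$word_classes))
  build <- function() {
    scenes <- spec$scenes[sample.int(nrow(spec$scenes), design$n_phase_items), ,
                          drop = FALSE]
    ord <- sample.int(nrow(sources))
    counts <- if (design$n_sources == 2L) c(5L, 4L) else c(2L, rep(1L, 7L))
    src_idx <- sample(rep(ord, counts))
    desc <- character(nrow(scenes))
    for (i in seq_len(nrow(scenes))) {
      s <- sources[src_idx[i], ]
      hit <- records$participant_id == s$participant_id &
        as.character(records$phase) == as.character(s$phase) &
        scene_key(records[feats]) == scene_key(scenes[i, , drop = FALSE])
      if (!any(hit)) {
        stop(sprintf("no description from source '%s' phase %s for scene %s",
                     s$participant_id, s$phase,
                     scene_key(scenes[i, , drop = FALSE])))
      }
      w <- as.character(unlist(records[which(hit)[1L], word_cols]))
      desc[i] <- paste(w[!is.na(w) & nzchar(w)], collapse = " ")
    }
    out <- scenes
    out$source_id <- sources$participant_id[src_idx]
    out$source_phase <- sources$phase[src_idx]
    out$description <- desc
    tibble::as_tibble(out)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Build a full multi-phase training input for one learning condition
#'
#' Screens the cohort with [select_sources()], draws the required number of
#' source speakers, assigns early/late phases according to the composition
#' (complex: all late; mixed: half early, half late), and constructs
#' independently resampled training phases.
#'
#' @param design A [mixing_design()].
#' @param records Cohort production records.
#' @param spec Target [language_spec()].
#' @param seed Integer seed.
#' @param n_phases Number of training phases (default 8).
#' @param early_phase,late_phase Phase labels of simplified vs. complex data.
#' @return Tibble of training items with a `phase` column.
#' @export
construct_training_input <- function(design, records, spec, seed,
                                     n_phases = 8L, early_phase = 2,
                                     late_phase = 8) {
  sel <- select_sources(records, spec, phase = early_phase)
  pool <- sel$participant_id[sel$selected]
  if (length(pool) < design$n_sources) {
    stop(sprintf("only %d source speakers meet the criterion; %d needed",
                 length(pool), design$n_sources))
  }
  withr::with_seed(seed, {
    ids <- sample(pool, design$n_sources)
    half <- design$n_sources / 2L
    phases_of <- if (design$composition == "complex") {
      rep(late_phase, design$n_sources)
    } else {
      sample(rep(c(early_phase, late_phase), c(half, half)))
    }
    sources <- data.frame(participant_id = ids, phase = phases_of,
                          stringsAsFactors = FALSE)
    out <- lapply(seq_len(n_phases), function(ph) {
      tr <- construct_training_phase(design, sources, records, spec)
      tr$phase <- ph
      tr
    })
  })
  do.call(rbind, out)
}
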