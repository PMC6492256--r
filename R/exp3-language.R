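#' Verb forms and nouns of the reduced noun-verb languages
#'
#' The reduced 9-scene languages pair one of three fixed transparent nouns
#' (`kwako`, `grolo`, `snapo` for duck, dog, crocodile) with a verb. Five
#' candidate verb forms exist; three serve as the regular verbs for the three
#' motions and the remaining two replace a regular verb in two lexically
#' irregular noun-verb cells.
#'
#' @name exp3_lexicon
NULL

#' @rdname exp3_lexicon
#' @export
exp3_verb_forms <- c("jing", "rald", "nunj", "ferb", "yath")

#' @rdname exp3_lexicon
#' @export
exp3_nouns <- c(duck = "kwako", dog = "grolo", crocodile = "snapo")

#' Construct a reduced noun-verb language
#'
#' Builds a 9-scene language from an explicit verb assignment. The three
#' regular forms and two irregular forms must partition the five verb forms;
#' the two irregular cells may not share an animal or a motion, and an
#' irregular form must differ from the regular form of its cell's motion
#' (guaranteed by the partition).
#'
#' @param regulars Named character vector `c(straight = , bounce = , loop = )`
#'   giving the regular verb of each motion.
#' @param irregulars Data frame with columns `animal`, `motion`, `form`:
#'   exactly two rows.
#' @param meta Metadata list stored in the spec.
#' @return A [language_spec()] with word classes N, V and suffix-less words.
#' @examples
#' ex <- exp3_language(c(straight = "jing", bounce = "yath", loop = "ferb"),
#'                     data.frame(animal = c("dog", "duck"),
#'                                motion = c("bounce", "loop"),
#'                                form   = c("nunj", "rald")))
#' render_description(ex, list(animal = "dog", motion = "bounce")) # "grolo nunj"
#' @export
exp3_language <- function(regulars, irregulars, meta = list()) {
  feats <- scene_features(3)
  if (!setequal(names(regulars), feats$motion)) {
    stop("`regulars` must be named straight, bounce, loop")
  }
  regulars <- vapply(feats$motion, function(m) regulars[[m]], character(1))
  if (!is.data.frame(irregulars) || nrow(irregulars) != 2L ||
      !all(c("animal", "motion", "form") %in% names(irregulars))) {
    stop("`irregulars` must be a two-row data frame with animal, motion, form")
  }
  irregulars$animal <- as.character(irregulars$animal)
  irregulars$motion <- as.character(irregulars$motion)
  irregulars$form <- as.character(irregulars$form)
  if (anyDuplicated(irregulars$animal) || anyDuplicated(irregulars$motion)) {
    stop("the two irregular cells may not share an animal or a motion")
  }
  if (!setequal(c(regulars, irregulars$form), exp3_verb_forms) ||
      length(unique(c(regulars, irregulars$form))) != 5L) {
    stop("regular and irregular forms must partition the five verb forms")
  }

  scenes <- scene_grid(3)
  verb <- regulars[as.character(scenes$motion)]
  for (i in 1:2) {
    hit <- scenes$animal == irregulars$animal[i] & scenes$motion == irregulars$motion[i]
    verb[hit] <- irregulars$form[i]
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(scenes)), function(i) {
    an <- as.character(scenes$animal[i]); mo <- as.character(scenes$motion[i])
    data.frame(animal = an, motion = mo, class = c("N", "V"),
               stem = c(exp3_nouns[[an]], verb[i]), suffix = c("", ""),
               stringsAsFactors = FALSE)
  }))
  language_spec(c("N", "V"), rows, experiment = 3,
                irregular_cells = irregulars, meta = meta)
}

#' Randomly generate a reduced noun-verb language
#'
#' Samples three of the five verb forms (without replacement) as the regular
#' verbs for straight, bouncing and looping motion; the remaining two forms
#' become irregular verbs, placed in two noun-verb cells that share neither an
#' animal nor a motion. Which irregular form lands in which of the two chosen
#' cells is also randomized. The draw is deterministic given `seed` (R's
#' default Mersenne-Twister generator; the seed and a generator tag are
#' recorded in the spec metadata).
#'
#' @param seed Non-negative integer seed.
#' @return A [language_spec()] satisfying all reduced-language invariants.
#' @examples
#' a <- generate_exp3_language(7)
#' identical(language_table(a), language_table(generate_exp3_language(7)))
#' @export
generate_exp3_language <- function(seed) {
  stopifnot(length(seed) == 1L, is.numeric(seed), seed >= 0, seed == round(seed))
  feats <- scene_features(3)
  withr::with_seed(as.integer(seed), {
    regs <- sample(exp3_verb_forms, 3L)
    irr_forms <- sample(setdiff(exp3_verb_forms, regs))
    anims <- sample(feats$animal, 2L)
    mots <- sample(feats$motion, 2L)
    irregulars <- data.frame(animal = anims, motion = mots, form = irr_forms,
                             stringsAsFactors = FALSE)
  })
  exp3_language(stats::setNames(regs, feats$motion), irregulars,
                meta = list(seed = as.integer(seed),
                            generator = "morphocomplex-exp3-language",
                            generator_version = "1"))
}

#' All admissible placements of two irregular cells
#'
#' Enumerates the unordered pairs of cells on the 3 x 3 animal-by-motion grid
#' whose two cells share neither an animal nor a motion. Used as a brute-force
#' reference for the generator's placement constraint (there are 18).
#'
#' @return Data frame with columns `animal1`, `motion1`, `animal2`, `motion2`.
#' @export
exp3_irregular_placements <- function() {
  feats <- scene_features(3)
  cells <- expand.grid(animal = feats$animal, motion = feats$motion,
                       stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(cells) - 1L)) {
    for (j in seq(i + 1L, nrow(cells))) {
      if (cells$animal[i] != cells$animal[j] && cells$motion[i] != cells$motion[j]) {
        out[[length(out) + 1L]] <- data.frame(
          animal1 = cells$animal[i], motion1 = cells$motion[i],
          animal2 = cells$animal[j], motion2 = cells$motion[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
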