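#' Example learner suffix sets (early vs. late in training)
#'
#' Suffix productions of a single example learner of the complex target
#' language, recorded after two rounds of training (when the stems are
#' acquired but the suffix system is still simplified) and after eight rounds
#' (when the target language has been acquired perfectly). The learner's stem
#' productions matched the target exactly at both rounds, so these suffix
#' sets are the package's standard worked example for the
#' conditioning-complexity procedure: at round 2 the quantifier suffixes
#' depend only on number, while at round 8 they also depend on the animal, as
#' in the target language.
#'
#' @return A tibble with columns `number`, `animal`, `motion`, `phase`
#'   (2 or 8), `word_class` (Q/N/V) and `suffix` (18 scenes x 2 phases x 3
#'   classes = 108 rows).
#' @examples
#' ex <- example_learner_suffixes()
#' q2 <- subset(ex, phase == 2 & word_class == "Q")
#' best_model(q2$suffix, q2[c("number", "animal", "motion")])$formula
#' @export
example_learner_suffixes <- function() {
  # scene order: (one, two) within motion (straight, bounce, loop) within
  # animal (duck, bird, crocodile)
  number <- rep(rep(c("one", "two"), times = 3), times = 3)
  motion <- rep(rep(c("straight", "bounce", "loop"), each = 2), times = 3)
  animal <- rep(c("duck", "bird", "crocodile"), each = 6)

  r2 <- list(
    Q = c("a","ak","a","ak","a","ak",  "a","ak","a","ak","a","ak",  "a","ak","a","ak","a","ak"),
    N = c("o","op","o","op","o","op",  "o","op","o","o","o","op",   "o","op","o","op","o","op"),
    V = c("esp","esp","esp","esp","an","an",  "esp","esp","esp","asp","an","an",
          "esp","esp","esp","esp","an","an"))
  r8 <- list(
    Q = c("a","ak","a","ak","a","ak",  "a","ak","a","ak","a","ak",  "u","uk","u","uk","u","uk"),
    N = c("o","op","o","op","o","op",  "o","o","o","o","o","o",     "o","op","o","op","o","op"),
    V = c("an","asp","an","asp","an","onk",  "an","asp","an","asp","an","onk",
          "en","esp","en","esp","en","onk"))

  out <- do.call(rbind, lapply(c(2, 8), function(ph) {
    sets <- if (ph == 2) r2 else r8
    do.call(rbind, lapply(c("Q", "N", "V"), function(cls) {
      tibble::tibble(number = number, animal = animal, motion = motion,
                     phase = ph, word_class = cls, suffix = sets[[cls]])
    }))
  }))
  out
}

#' Example learner productions as a full record table
#'
#' The same example data as [example_learner_suffixes()], re-assembled into
#' whole-word productions (target stems plus the produced suffixes) in the
#' standard production record layout, so the complete pipeline can be run on
#' it.
#'
#' @return A production record tibble (36 rows: 18 scenes x 2 phases).
#' @export
example_learner_productions <- function() {
  spec <- build_exp1_target()
  suf <- example_learner_suffixes()
  wide <- do.call(rbind, lapply(c(2, 8), function(ph) {
    s <- suf[suf$phase == ph, ]
    q <- s[s$word_class == "Q", ]
    n <- s[s$word_class == "N", ]
    v <- s[s$word_class == "V", ]
    stopifnot(all(q$number == n$number), all(q$number == v$number))
    stems <- vapply(seq_len(nrow(q)), function(i) {
      sc <- list(number = q$number[i], animal = q$animal[i], motion = q$motion[i])
      c(target_segmentation(spec, sc, "Q")$stem,
        target_segmentation(spec, sc, "N")$stem,
        target_segmentation(spec, sc, "V")$stem)
    }, character(3))
    tibble::tibble(participant_id = "example", phase = ph,
                   number = q$number, animal = q$animal, motion = q$motion,
                   word1 = paste0(stems[1, ], q$suffix),
                   word2 = paste0(stems[2, ], n$suffix),
                   word3 = paste0(stems[3, ], v$suffix))
  }))
  wide
}
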