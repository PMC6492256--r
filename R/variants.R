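#' Predictor variants of a semantic feature
#'
#' Candidate suffix-choice models may use each semantic feature either at its
#' full granularity or collapsed to a binary one-vs-rest contrast, so that a
#' language treating, say, duck and bird alike is not penalised for levels it
#' never distinguishes. A three-level feature therefore admits four variants
#' (the full three-way contrast plus three binarizations); the two-level
#' number feature admits only its single binary contrast.
#'
#' @param feature One of `"Number"`, `"Animal"`, `"Motion"`.
#' @param experiment Scene set the levels are drawn from (1 or 3).
#' @return List of variant objects, each with `feature`, `split` (`NULL` for
#'   the full contrast, or the singled-out level) and a display `label` such
#'   as `"Animal[bird]"`.
#' @examples
#' length(expand_variants("Animal"))  # 4
#' length(expand_variants("Number"))  # 1
#' @export
expand_variants <- function(feature, experiment = 1) {
  feats <- scene_features(experiment)
  col <- tolower(feature)
  if (!col %in% names(feats)) {
    stop("unknown feature '", feature, "' for this scene set")
  }
  levels <- feats[[col]]
  if (length(levels) == 2L) {
    return(list(list(feature = feature, split = NULL, label = feature)))
  }
  c(list(list(feature = feature, split = NULL, label = feature)),
    lapply(levels, function(l) {
      list(feature = feature, split = l, label = sprintf("%s[%s]", feature, l))
    }))
}

# Code a variant as a factor over the scene rows.
variant_code <- function(variant, scenes) {
  col <- scenes[[tolower(variant$feature)]]
  if (is.null(variant$split)) {
    factor(as.character(col))
  } else {
    factor(ifelse(as.character(col) == variant$split, variant$split, "rest"),
           levels = c("rest", variant$split))
  }
}

# Features usable for a given scene data frame.
available_features <- function(scenes) {
  known <- c(number = "Number", animal = "Animal", motion = "Motion")
  unname(known[names(known) %in% names(scenes)])
}
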