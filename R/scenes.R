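#' Semantic feature levels
#'
#' The scenes described by the artificial languages vary along three semantic
#' features: the number of animals shown, the animal itself, and the motion it
#' performs. The full-language experiments use an 18-scene set (2 x 3 x 3);
#' the dyadic-interaction experiments use a reduced 9-scene set (3 x 3) with
#' no number distinction and with the bird replaced by a dog.
#'
#' @param experiment 1 for the 18-scene set, 3 for the 9-scene set.
#' @return Named list of character vectors, one per semantic feature, in
#'   canonical level order.
#' @export
scene_features <- function(experiment = 1) {
  if (experiment == 1) {
    list(number = c("one", "two"),
         animal = c("duck", "bird", "crocodile"),
         motion = c("straight", "bounce", "loop"))
  } else if (experiment == 3) {
    list(animal = c("duck", "dog", "crocodile"),
         motion = c("straight", "bounce", "loop"))
  } else {
    stop("`experiment` must be 1 or 3")
  }
}

#' Enumerate the scene set
#'
#' @inheritParams scene_features
#' @return A data frame with one row per scene, factor columns in canonical
#'   order (sorted by number, then animal, then motion).
#' @examples
#' nrow(scene_grid(1)) # 18
#' nrow(scene_grid(3)) # 9
#' @export
scene_grid <- function(experiment = 1) {
  feats <- scene_features(experiment)
  g <- expand.grid(rev(feats), stringsAsFactors = FALSE)[, names(feats), drop = FALSE]
  for (f in names(feats)) g[[f]] <- factor(g[[f]], levels = feats[[f]])
  g <- g[do.call(order, g), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# Canonical single-string key for a scene row, e.g. "one.duck.straight".
scene_key <- function(scenes) {
  do.call(paste, c(lapply(scenes, as.character), sep = "."))
}

# Coerce a scene given as named list/vector to a 1-row data frame with the
# feature columns of `features` (a scene_features() list), validating levels.
as_scene <- function(scene, features) {
  scene <- as.list(scene)
  missing <- setdiff(names(features), names(scene))
  if (length(missing)) {
    stop("scene is missing feature(s): ", paste(missing, collapse = ", "))
  }
  out <- list()
  for (f in names(features)) {
    v <- as.character(scene[[f]])
    if (length(v) != 1L || !v %in% features[[f]]) {
      stop(sprintf("unknown scene (%s): '%s' is not a level of %s",
                   paste(unlist(scene[names(features)]), collapse = ", "), v, f))
    }
    out[[f]] <- factor(v, levels = features[[f]])
  }
  as.data.frame(out)
}
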