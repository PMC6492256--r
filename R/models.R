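#' Enumerate all candidate suffix-choice models
#'
#' The candidate space contains every additive model with at most one variant
#' per semantic feature (including the intercept-only model) and, for every
#' selection of two or more variants, the same selection augmented with all
#' interaction terms among its variants (a full factorial). A collapsed
#' variant is never co-included with the full contrast of the same feature,
#' which would be collinear. The list is deterministic: selections are
#' ordered by nested iteration over Number, Animal and Motion variants
#' (absent first, then the full contrast, then one-vs-rest contrasts in level
#' order), additive models before their factorial augmentations.
#'
#' @param features Character vector of features to consider.
#' @param experiment Scene set (1 or 3).
#' @return List of candidate models, each with `variants` (possibly empty
#'   list), `interactions` (logical) and a canonical `label` like
#'   `"Suffix ~ Number + Animal[bird]"`.
#' @examples
#' length(enumerate_models())  # 90
#' @export
enumerate_models <- function(features = c("Number", "Animal", "Motion"),
                             experiment = 1) {
  choices <- lapply(features, function(f) {
    c(list(NULL), expand_variants(f, experiment))
  })
  selections <- list(list())
  for (ch in choices) {
    selections <- unlist(lapply(selections, function(sel) {
      lapply(ch, function(v) if (is.null(v)) sel else c(sel, list(v)))
    }), recursive = FALSE)
  }
  additive <- lapply(selections, function(sel) {
    list(variants = sel, interactions = FALSE, label = model_label(sel, FALSE))
  })
  augmented <- lapply(Filter(function(s) length(s) >= 2L, selections), function(sel) {
    list(variants = sel, interactions = TRUE, label = model_label(sel, TRUE))
  })
  c(additive, augmented)
}

model_label <- function(variants, interactions) {
  if (length(variants) == 0L) return("Suffix ~ 1")
  labs <- vapply(variants, `[[`, character(1), "label")
  paste("Suffix ~", paste(labs, collapse = if (interactions) " * " else " + "))
}

# Number of distinct semantic features used by a model.
model_n_features <- function(model) {
  length(unique(vapply(model$variants, `[[`, character(1), "feature")))
}
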