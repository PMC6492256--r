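#' Language specifications
#'
#' A `language_spec` maps every scene in its scene set to a fully segmented
#' description: one word per word class, each word stored as an unhyphenated
#' stem plus suffix. The segmentation index is part of the specification, so
#' scoring never has to re-derive where a target stem ends. A zero-marked
#' suffix is stored as the empty string and rendered as nothing.
#'
#' @param word_classes Ordered character vector of word classes (e.g.
#'   `c("Q", "N", "V")`).
#' @param table Data frame with the scene feature columns plus `class`,
#'   `stem`, `suffix`: one row per scene x word class.
#' @param experiment 1 or 3; selects the scene set.
#' @param irregular_cells Optional data frame (`animal`, `motion`, `form`)
#'   recording lexically irregular cells (reduced noun-verb languages only).
#' @param meta Named list of free-form metadata (seed, generator version, ...).
#' @return An object of class `language_spec`.
#' @export
language_spec <- function(word_classes, table, experiment = 1,
                          irregular_cells = NULL, meta = list()) {
  feats <- scene_features(experiment)
  need <- c(names(feats), "class", "stem", "suffix")
  if (!all(need %in% names(table))) {
    stop("spec table must have columns: ", paste(need, collapse = ", "))
  }
  for (f in names(feats)) table[[f]] <- factor(as.character(table[[f]]), levels = feats[[f]])
  table$class <- as.character(table$class)
  table$stem <- as.character(table$stem)
  table$suffix <- as.character(table$suffix)
  if (anyNA(table[names(feats)])) stop("spec table contains scene values outside the feature levels")

  scenes <- scene_grid(experiment)
  # totality: every scene x class exactly once
  k <- paste(scene_key(table[names(feats)]), table$class)
  want <- as.vector(outer(scene_key(scenes), word_classes, paste))
  if (!setequal(k, want) || anyDuplicated(k)) {
    stop("spec table must contain exactly one entry per scene and word class")
  }
  ord <- order(match(scene_key(table[names(feats)]), scene_key(scenes)),
               match(table$class, word_classes))
  table <- table[ord, c(names(feats), "class", "stem", "suffix")]
  rownames(table) <- NULL

  structure(list(word_classes = word_classes, experiment = experiment,
                 features = feats, scenes = scenes, table = table,
                 irregular_cells = irregular_cells, meta = meta),
            class = "language_spec")
}

#' @export
print.language_spec <- function(x, ...) {
  cat(sprintf("<language_spec: %d scenes, word classes %s>\n",
              nrow(x$scenes), paste(x$word_classes, collapse = " ")))
  wide <- language_table(x)
  print(utils::head(wide, 9L), row.names = FALSE)
  if (nrow(wide) > 9L) cat("... (", nrow(wide) - 9L, " more scenes)\n", sep = "")
  invisible(x)
}

#' Render one description
#'
#' Concatenates stem and suffix for every word class, joined by single spaces.
#'
#' @param spec A [language_spec()].
#' @param scene Named list or one-row data frame giving the scene's features.
#' @return A single character string.
#' @examples
#' render_description(build_exp1_target(),
#'                    list(number = "one", animal = "duck", motion = "straight"))
#' @export
render_description <- function(spec, scene) {
  sc <- as_scene(scene, spec$features)
  rows <- spec$table[scene_key(spec$table[names(spec$features)]) == scene_key(sc), ]
  rows <- rows[match(spec$word_classes, rows$class), ]
  paste(paste0(rows$stem, rows$suffix), collapse = " ")
}

#' Tabulate all descriptions of a language
#'
#' @param spec A [language_spec()].
#' @return Data frame with the scene features and the rendered `description`.
#' @export
language_table <- function(spec) {
  feats <- names(spec$features)
  words <- paste0(spec$table$stem, spec$table$suffix)
  k <- scene_key(spec$table[feats])
  desc <- tapply(words, factor(k, levels = unique(k)), paste, collapse = " ")
  out <- spec$scenes
  out$description <- as.vector(desc[scene_key(spec$scenes)])
  out
}

# Stems of one word class, most specific first (unique, longest first) --
# the candidate set used for segmentation.
class_stems <- function(spec, class) {
  s <- unique(spec$table$stem[spec$table$class == class])
  s[order(-nchar(s), s)]
}

# Target stem/suffix for one scene and class.
target_segmentation <- function(spec, scene, class) {
  sc <- as_scene(scene, spec$features)
  row <- spec$table[scene_key(spec$table[names(spec$features)]) == scene_key(sc) &
                      spec$table$class == class, ]
  if (nrow(row) != 1L) {
    stop(sprintf("unknown scene (%s) or class '%s'",
                 paste(unlist(lapply(sc, as.character)), collapse = ", "), class))
  }
  list(stem = row$stem, suffix = row$suffix)
}

#' Write a language specification to JSON
#'
#' The on-disk format lists the scene set, the ordered word classes and one
#' entry per scene (in canonical scene order) with the segmented words.
#' `parse_spec(write_spec(x, p))` is the identity, and writing a parsed file
#' again is byte-identical.
#'
#' @param spec A [language_spec()].
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_spec <- function(spec, path) {
  feats <- names(spec$features)
  scenes <- lapply(seq_len(nrow(spec$scenes)), function(i) {
    as.list(lapply(spec$scenes[i, , drop = FALSE], as.character))
  })
  tab <- spec$table
  kk <- scene_key(tab[feats])
  entries <- lapply(seq_len(nrow(spec$scenes)), function(i) {
    rows <- tab[kk == scene_key(spec$scenes[i, , drop = FALSE]), ]
    rows <- rows[match(spec$word_classes, rows$class), ]
    list(scene = as.list(lapply(spec$scenes[i, , drop = FALSE], as.character)),
         words = lapply(seq_len(nrow(rows)), function(j) {
           list(class = rows$class[j], stem = rows$stem[j], suffix = rows$suffix[j])
         }))
  })
  x <- list(experiment = spec$experiment, scenes = scenes,
            word_classes = as.list(spec$word_classes), entries = entries)
  if (!is.null(spec$irregular_cells)) {
    ic <- spec$irregular_cells
    x$irregular_cells <- lapply(seq_len(nrow(ic)), function(i) {
      list(animal = as.character(ic$animal[i]), motion = as.character(ic$motion[i]),
           form = as.character(ic$form[i]))
    })
  }
  x$meta <- spec$meta
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = 2, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a language specification from JSON
#'
#' @param path File written by [write_spec()].
#' @return A [language_spec()].
#' @export
parse_spec <- function(path) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stop("malformed language spec JSON in '", path,
                                         "': ", conditionMessage(e), call. = FALSE))
  experiment <- x$experiment
  feats <- scene_features(experiment)
  rows <- do.call(rbind, lapply(x$entries, function(e) {
    do.call(rbind, lapply(e$words, function(w) {
      d <- as.data.frame(e$scene[names(feats)], stringsAsFactors = FALSE)
      d$class <- w$class; d$stem <- w$stem
      d$suffix <- if (is.null(w$suffix)) "" else w$suffix
      d
    }))
  }))
  ic <- NULL
  if (!is.null(x$irregular_cells)) {
    ic <- do.call(rbind, lapply(x$irregular_cells, function(c0) {
      data.frame(animal = c0$animal, motion = c0$motion, form = c0$form,
                 stringsAsFactors = FALSE)
    }))
  }
  meta <- lapply(x$meta, function(v) v)
  language_spec(unlist(x$word_classes), rows, experiment = experiment,
                irregular_cells = ic, meta = meta)
}
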