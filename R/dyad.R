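#' Configuration for a simulated interaction dyad
#'
#' Two trained agents play a director-matcher game over the 9-scene reduced
#' language for a fixed number of rounds; each agent directs every scene once
#' per round, in random order, with the two directing streams interleaved.
#' In a complex dyad both agents know the full language; in a mixed dyad one
#' agent (the simple speaker) was trained only on the seven regular
#' noun-verb pairings and produces regularized forms for the two irregular
#' cells. A complex speaker who has heard their partner's regularized form
#' for an irregular cell may adopt it (accommodation) and thereafter tends to
#' persist with it.
#'
#' Default probabilities are taken from the printed counts of the study this
#' design emulates: persistence 21/22, adoption-after-exposure 27/29, case
#' receptivity 29/40 (the proportion of complex-speaker-by-cell cases that
#' ever regularized), matcher success 0.97 for forms in the matcher's
#' grammar, 0.5 for an unknown irregular form, and 119/120 regularized
#' production by simple speakers.
#'
#' @param dyad_type `"mixed"` or `"complex"`.
#' @param rounds Interaction rounds (default 3).
#' @param p_adopt_after_exposure Probability that a receptive complex
#'   speaker, once exposed, switches to the regularized form at an
#'   opportunity.
#' @param p_persist Per-trial probability that an adopted regularized form is
#'   kept rather than reverted.
#' @param p_case_adopt Probability that a complex-speaker-by-cell case is
#'   receptive to adoption at all.
#' @param p_match_known Matcher success for descriptions whose verb is in
#'   the matcher's grammar.
#' @param p_match_unknown_irregular Matcher success when a simple speaker
#'   hears an unknown irregular verb.
#' @param p_simple_regularize Probability that a simple speaker produces the
#'   regularized form for an irregular cell (rather than an irregular form
#'   they have been exposed to).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A `dyad_config` list.
#' @export
dyad_config <- function(dyad_type = c("mixed", "complex"), rounds = 3L,
                        p_adopt_after_exposure = 27 / 29,
                        p_persist = 21 / 22,
                        p_case_adopt = 29 / 40,
                        p_match_known = 0.97,
                        p_match_unknown_irregular = 0.5,
                        p_simple_regularize = 119 / 120,
                        seed = NULL) {
  dyad_type <- match.arg(dyad_type)
  p <- c(p_adopt_after_exposure, p_persist, p_case_adopt, p_match_known,
         p_match_unknown_irregular, p_simple_regularize)
  stopifnot(all(p >= 0), all(p <= 1), rounds >= 1)
  structure(list(dyad_type = dyad_type, rounds = as.integer(rounds),
                 p_adopt_after_exposure = p_adopt_after_exposure,
                 p_persist = p_persist, p_case_adopt = p_case_adopt,
                 p_match_known = p_match_known,
                 p_match_unknown_irregular = p_match_unknown_irregular,
                 p_simple_regularize = p_simple_regularize, seed = seed),
            class = "dyad_config")
}

#' Simulate one interaction dyad
#'
#' @param language A reduced noun-verb [language_spec()] with two irregular
#'   cells (e.g. from [generate_exp3_language()]).
#' @param config A [dyad_config()].
#' @param dyad_id Identifier stored in the trial records.
#' @return List with `trials` (one row per directing trial: round, director
#'   and matcher roles, scene, produced description, `regularized` — `NA` on
#'   regular cells — and `matched_correctly`) and `posttest` (one solo
#'   production pass per agent after interaction).
#' @export
simulate_dyad <- function(language, config, dyad_id = "D1") {
  stopifnot(inherits(config, "dyad_config"))
  run <- function() simulate_dyad_impl(language, config, dyad_id)
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

simulate_dyad_impl <- function(language, config, dyad_id) {
  ic <- language$irregular_cells
  if (is.null(ic) || nrow(ic) != 2L) stop("language must have two irregular cells")
  scenes <- language$scenes
  key <- scene_key(scenes)
  irr_key <- paste(ic$animal, ic$motion, sep = ".")
  stopifnot(all(irr_key %in% key))
  irr_form <- stats::setNames(ic$form, irr_key)
  # regular verb of each motion = the form used on that motion's regular cells
  tabv <- language$table[language$table$class == "V", ]
  tk <- paste(tabv$animal, tabv$motion, sep = ".")
  reg_form <- vapply(scene_features(3)$motion, function(m) {
    f <- tabv$stem[tabv$motion == m & !(tk %in% irr_key)]
    unique(f)[1]
  }, character(1))
  noun_of <- stats::setNames(language$table$stem[language$table$class == "N"],
                             scene_key(language$table[language$table$class == "N",
                                                      names(language$features)]))

  roles <- if (config$dyad_type == "mixed") c("complex", "simple") else
    c("complex", "complex")
  # per-agent state over the two irregular cells
  state <- lapply(1:2, function(a) list(
    exposed = stats::setNames(c(FALSE, FALSE), irr_key),
    adopted = stats::setNames(c(FALSE, FALSE), irr_key),
    receptive = stats::setNames(stats::runif(2) < config$p_case_adopt, irr_key)))

  produce <- function(a, k) {
    mo <- as.character(scenes$motion[match(k, key)])
    reg <- unname(reg_form[mo])
    if (!k %in% irr_key) {
      return(list(verb = reg, regularized = NA))
    }
    if (roles[a] == "simple") {
      if (state[[a]]$exposed[k] &&
          stats::runif(1) >= config$p_simple_regularize) {
        return(list(verb = unname(irr_form[k]), regularized = FALSE))
      }
      return(list(verb = reg, regularized = TRUE))
    }
    # complex speaker
    if (state[[a]]$adopted[k]) {
      if (stats::runif(1) < config$p_persist) {
        return(list(verb = reg, regularized = TRUE))
      }
      state[[a]]$adopted[k] <<- FALSE
      return(list(verb = unname(irr_form[k]), regularized = FALSE))
    }
    if (state[[a]]$exposed[k] && state[[a]]$receptive[k] &&
        stats::runif(1) < config$p_adopt_after_exposure) {
      state[[a]]$adopted[k] <<- TRUE
      return(list(verb = reg, regularized = TRUE))
    }
    list(verb = unname(irr_form[k]), regularized = FALSE)
  }

  n_tr <- config$rounds * 2L * nrow(scenes)
  trials <- data.frame(dyad_id = rep(dyad_id, n_tr), dyad_type = config$dyad_type,
                       round = 0L, trial = 0L, director = "", director_role = "",
                       matcher_role = "", animal = "", motion = "",
                       item_type = "", description = "", regularized = NA,
                       matched_correctly = NA, stringsAsFactors = FALSE)
  t0 <- 0L
  for (r in seq_len(config$rounds)) {
    starter <- sample(1:2, 1L)
    ord <- list(sample.int(nrow(scenes)), sample.int(nrow(scenes)))
    directors <- rep(c(starter, 3L - starter), nrow(scenes))
    pos <- c(0L, 0L)
    for (t in seq_along(directors)) {
      d <- directors[t]; m <- 3L - d
      pos[d] <- pos[d] + 1L
      k <- key[ord[[d]][pos[d]]]
      pr <- produce(d, k)
      # exposure: the matcher hears the form paired with the scene
      if (k %in% irr_key) {
        if (isTRUE(pr$regularized)) {
          state[[m]]$exposed[k] <- TRUE
        } else if (roles[m] == "simple") {
          # simple matcher hears the irregular form
          state[[m]]$exposed[k] <- TRUE
        }
      }
      p_match <- if (roles[m] == "simple" && identical(pr$regularized, FALSE)) {
        config$p_match_unknown_irregular
      } else {
        config$p_match_known
      }
      t0 <- t0 + 1L
      trials$round[t0] <- r; trials$trial[t0] <- t
      trials$director[t0] <- paste0(dyad_id, "_", d)
      trials$director_role[t0] <- roles[d]; trials$matcher_role[t0] <- roles[m]
      trials$animal[t0] <- as.character(scenes$animal[match(k, key)])
      trials$motion[t0] <- as.character(scenes$motion[match(k, key)])
      trials$item_type[t0] <- if (k %in% irr_key) "irregular" else "regular"
      trials$description[t0] <- paste(unname(noun_of[k]), pr$verb)
      trials$regularized[t0] <- pr$regularized
      trials$matched_correctly[t0] <- stats::runif(1) < p_match
    }
  }

  post <- do.call(rbind, lapply(1:2, function(a) {
    do.call(rbind, lapply(seq_along(key), function(i) {
      pr <- produce(a, key[i])
      data.frame(dyad_id = dyad_id, dyad_type = config$dyad_type,
                 speaker = paste0(dyad_id, "_", a), role = roles[a],
                 animal = as.character(scenes$animal[i]),
                 motion = as.character(scenes$motion[i]),
                 item_type = if (key[i] %in% irr_key) "irregular" else "regular",
                 description = paste(unname(noun_of[key[i]]), pr$verb),
                 regularized = pr$regularized, stringsAsFactors = FALSE)
    }))
  }))
  list(trials = tibble::as_tibble(trials), posttest = tibble::as_tibble(post))
}

#' Simulate a full dyadic interaction study
#'
#' Generates a fresh constrained language for every dyad and simulates the
#' interaction and post-test, for a set of complex and mixed dyads.
#'
#' @param n_complex,n_mixed Number of dyads per type (defaults 10 and 20).
#' @param seed Integer master seed.
#' @param rounds Interaction rounds per dyad.
#' @param ... Further arguments passed to [dyad_config()].
#' @return List with pooled `trials` and `posttest` tibbles.
#' @export
simulate_exp3 <- function(n_complex = 10L, n_mixed = 20L, seed = 1L,
                          rounds = 3L, ...) {
  withr::with_seed(seed, {
    lang_seeds <- sample.int(.Machine$integer.max - 1L, n_complex + n_mixed)
    res <- lapply(seq_len(n_complex + n_mixed), function(i) {
      type <- if (i <= n_complex) "complex" else "mixed"
      cfg <- dyad_config(dyad_type = type, rounds = rounds, seed = NULL, ...)
      lang <- generate_exp3_language(lang_seeds[i])
      simulate_dyad(lang, cfg, dyad_id = sprintf("D%02d", i))
    })
  })
  list(trials = do.call(rbind, lapply(res, `[[`, "trials")),
       posttest = do.call(rbind, lapply(res, `[[`, "posttest")))
}
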