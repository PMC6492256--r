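#' Fit one candidate multinomial suffix-choice model
#'
#' Maximum-likelihood multinomial logit fit of suffix choice on the coded
#' predictors of one candidate model, via [nnet::multinom()] with an
#' iteration cap of 100 and relative log-likelihood tolerance 1e-8. The
#' parameter count is `k = (C - 1) * p` for `C` suffix categories and `p`
#' design columns including the intercept, and `aic = 2k - 2 loglik`. Two
#' degenerate cases are handled analytically: a single observed suffix
#' category scores `loglik = 0, k = 0, aic = 0`, and the intercept-only model
#' uses its closed-form maximum likelihood (the empirical category
#' frequencies). Under complete separation the capped iterative fit drives
#' the log-likelihood to (numerically) zero, so a perfectly predictive model
#' scores `aic` close to `2k`; this mirrors the behaviour of the standard
#' fitting routine and keeps AIC values comparable across models.
#'
#' @param suffix Character/factor vector of suffix codes (use `"NULL"` for
#'   zero-marking), one per observation.
#' @param scenes Data frame of scene features aligned with `suffix`.
#' @param model A candidate model from [enumerate_models()].
#' @param maxit,reltol Iteration cap and relative convergence tolerance.
#' @return List with `model`, `loglik`, `k`, `aic`.
#' @export
fit_suffix_model <- function(suffix, scenes, model, maxit = 100, reltol = 1e-8) {
  if (length(suffix) == 0L) stop("no observations")
  if (length(suffix) != nrow(scenes)) stop("`suffix` and `scenes` lengths differ")
  y <- factor(as.character(suffix))
  C <- nlevels(y)
  if (C < 2L) {
    return(list(model = model, loglik = 0, k = 0L, aic = 0))
  }
  # drop variants that do not vary over these observations; they contribute
  # no design column (the equivalent smaller model exists in the enumeration
  # and wins any tie through its lower parameter count)
  active <- Filter(function(v) nlevels(droplevels(variant_code(v, scenes))) > 1L,
                   model$variants)
  if (length(active) == 0L) {
    counts <- table(y)
    ll <- sum(counts * log(counts / length(y)))
    k <- C - 1L
    return(list(model = model, loglik = ll, k = k, aic = 2 * k - 2 * ll))
  }
  dat <- data.frame(.suffix = y)
  vars <- character(length(active))
  for (i in seq_along(active)) {
    vars[i] <- paste0("v", i)
    dat[[vars[i]]] <- droplevels(variant_code(active[[i]], scenes))
  }
  op <- if (model$interactions && length(vars) > 1L) " * " else " + "
  f <- stats::as.formula(paste(".suffix ~", paste(vars, collapse = op)))
  fit <- nnet::multinom(f, data = dat, trace = FALSE, maxit = maxit,
                        reltol = reltol)
  ll <- as.numeric(stats::logLik(fit))
  k <- as.integer(fit$edf)
  list(model = model, loglik = ll, k = k, aic = 2 * k - 2 * ll)
}

#' Conditioning complexity: AIC-best suffix-choice model
#'
#' Fits every candidate model in the enumeration to one participant's suffix
#' choices for one word class at one phase and selects the model with the
#' lowest AIC (ties within 1e-9 broken by fewer parameters, then by canonical
#' enumeration order). The conditioning complexity is the number of distinct
#' semantic features used by the winning model: 0 (a single invariant
#' suffix) up to 3 (suffix choice depends on number, animal and motion).
#'
#' @param suffix Suffix codes, one per observed scene.
#' @param scenes Data frame of scene features aligned with `suffix`.
#' @param models Candidate list; defaults to the full enumeration over the
#'   features present in `scenes`.
#' @param experiment Scene set used when enumerating by default.
#' @return An object of class `complexity_score`: list with `complexity`,
#'   `best` (the winning fit), `formula` (canonical label) and `fits`, a
#'   tibble of all candidate fits (`label`, `n_features`, `loglik`, `k`,
#'   `aic`).
#' @examples
#' tgt <- build_exp1_target()
#' v <- tgt$table[tgt$table$class == "V", ]
#' best_model(v$suffix, v[c("number", "animal", "motion")])$complexity  # 3
#' @export
best_model <- function(suffix, scenes, models = NULL, experiment = 1) {
  if (is.null(models)) {
    models <- enumerate_models(available_features(scenes), experiment)
  }
  fits <- lapply(models, function(m) fit_suffix_model(suffix, scenes, m))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, `[[`, numeric(1), "k")
  cand <- which(aic <= min(aic) + 1e-9)
  cand <- cand[k[cand] == min(k[cand])]
  win <- cand[1L]
  tab <- tibble::tibble(
    label = vapply(fits, function(f) f$model$label, character(1)),
    n_features = vapply(fits, function(f) model_n_features(f$model), integer(1)),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    k = as.integer(k), aic = aic)
  structure(list(complexity = model_n_features(fits[[win]]$model),
                 best = fits[[win]], formula = fits[[win]]$model$label,
                 fits = tab),
            class = "complexity_score")
}

#' @export
print.complexity_score <- function(x, ...) {
  cat(sprintf("Conditioning complexity: %d\n  best model: %s\n  loglik %.4f, k %d, AIC %.4f\n",
              x$complexity, x$formula, x$best$loglik, x$best$k, x$best$aic))
  invisible(x)
}

#' Shannon entropy of a suffix distribution
#'
#' Token entropy, in bits, of the empirical distribution of suffix forms
#' within one word class; a meaning-independent companion to the
#' conditioning-complexity score. Invariant under relabeling of the forms and
#' bounded by `log2` of the number of distinct forms.
#'
#' @param suffix Character vector of suffix codes (include `"NULL"` tokens).
#' @return Entropy in bits.
#' @examples
#' suffix_entropy(rep(c("a", "ak"), each = 9))  # 1
#' @export
suffix_entropy <- function(suffix) {
  if (length(suffix) == 0L) stop("no observations")
  p <- table(as.character(suffix)) / length(suffix)
  -sum(p * log2(p))
}

#' Complexity table for a set of production records
#'
#' Segments each production against the target language, then scores
#' conditioning complexity and suffix entropy for every participant x phase x
#' word class cell.
#'
#' @param records Production record table (see [read_productions()]).
#' @param spec Target [language_spec()].
#' @return A tibble with `participant_id`, `phase`, `word_class`,
#'   `best_model_formula`, `loglik`, `k`, `aic`, `complexity`,
#'   `entropy_bits`, `n_scenes`.
#' @export
complexity_table <- function(records, spec) {
  records <- validate_productions(records, spec)
  feats <- names(spec$features)
  word_cols <- paste0("word", seq_along(spec$word_classes))
  models <- enumerate_models(available_features(spec$scenes), spec$experiment)

  # segment all words once
  seg <- lapply(seq_len(nrow(records)), function(i) {
    words <- as.character(unlist(records[i, word_cols]))
    words <- words[!is.na(words) & nzchar(words)]
    s <- segment_production(words, spec)
    cbind(records[rep(i, nrow(s)), c("participant_id", "phase", feats),
                  drop = FALSE], s, row.names = NULL)
  })
  seg <- do.call(rbind, seg)
  seg <- seg[seg$method != "missing", , drop = FALSE]

  groups <- unique(seg[c("participant_id", "phase", "class")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- seg[seg$participant_id == groups$participant_id[i] &
               seg$phase == groups$phase[i] &
               seg$class == groups$class[i], , drop = FALSE]
    bm <- best_model(g$suffix, g[feats], models = models)
    tibble::tibble(participant_id = groups$participant_id[i],
                   phase = groups$phase[i], word_class = groups$class[i],
                   best_model_formula = bm$formula, loglik = bm$best$loglik,
                   k = bm$best$k, aic = bm$best$aic,
                   complexity = bm$complexity,
                   entropy_bits = suffix_entropy(g$suffix),
                   n_scenes = nrow(g))
  })
  do.call(rbind, out)
}
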