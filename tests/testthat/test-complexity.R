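scene18 <- scene_grid(1)

test_that("variant expansion gives full and one-vs-rest contrasts", {
  expect_length(expand_variants("Number"), 1L)
  expect_length(expand_variants("Animal"), 4L)
  expect_length(expand_variants("Motion"), 4L)
  labs <- vapply(expand_variants("Animal"), `[[`, "", "label")
  expect_setequal(labs, c("Animal", "Animal[duck]", "Animal[bird]",
                          "Animal[crocodile]"))
  expect_error(expand_variants("Colour"), "unknown feature")
})

test_that("the candidate model space has the derived size and structure", {
  models <- enumerate_models()
  # product count: each feature absent or one of its variants, additive
  n_additive <- prod(1 + c(1, 4, 4))
  # every selection of >= 2 variants additionally appears with interactions
  n_augmented <- n_additive - 1 - (1 + 4 + 4)
  expect_length(models, n_additive + n_augmented)  # 50 + 40 = 90
  labs <- vapply(models, `[[`, "", "label")
  expect_false(anyDuplicated(labs) > 0)
  expect_true("Suffix ~ 1" %in% labs)
  expect_true("Suffix ~ Number + Animal[bird] + Motion[bounce]" %in% labs)
  expect_true("Suffix ~ Number * Animal * Motion" %in% labs)
  # deterministic canonical order
  expect_identical(labs, vapply(enumerate_models(), `[[`, "", "label"))
  # no model co-includes two variants of one feature
  for (m in models) {
    feats <- vapply(m$variants, `[[`, "", "feature")
    expect_false(anyDuplicated(feats) > 0)
  }
})

test_that("degenerate and intercept-only fits use their closed forms", {
  const <- rep("o", 18)
  f <- fit_suffix_model(const, scene18, enumerate_models()[[1]])
  expect_equal(f[c("loglik", "k", "aic")], list(loglik = 0, k = 0L, aic = 0))
  half <- rep(c("a", "ak"), each = 9)
  f0 <- fit_suffix_model(half, scene18, enumerate_models()[[1]])
  expect_equal(f0$loglik, 18 * log(0.5))
  expect_equal(f0$k, 1L)
  expect_equal(f0$aic, 2 + 36 * log(2), tolerance = 1e-12)
  expect_error(fit_suffix_model(character(0), scene18[0, ],
                                enumerate_models()[[1]]), "no observations")
})

test_that("a perfectly number-conditioned split is fit to near-certain predictions", {
  half <- rep(c("a", "ak"), each = 9)  # aligned with scene18$number
  expect_identical(as.character(scene18$number), rep(c("one", "two"), each = 9))
  m <- Filter(function(m) m$label == "Suffix ~ Number", enumerate_models())[[1]]
  f <- fit_suffix_model(half, scene18, m)
  # capped iterative fit drives per-observation probabilities >= 0.99
  expect_gte(exp(f$loglik / 18), 0.99)
  expect_equal(f$k, 2L)
})

test_that("log-likelihood is non-decreasing under model nesting", {
  ex <- example_subset(8, "V")
  models <- enumerate_models()
  fits <- lapply(models, function(m) fit_suffix_model(ex$suffix, scene18, m))
  refines <- function(a, b) { # does B contain a refinement of variant a?
    any(vapply(b$variants, function(v) {
      v$feature == a$feature && (is.null(v$split) || identical(v$split, a$split))
    }, logical(1)))
  }
  nested <- function(A, B) {
    if (A$interactions && !B$interactions) return(FALSE)
    all(vapply(A$variants, refines, logical(1), b = B))
  }
  n_pairs <- 0L
  for (i in seq_along(models)) {
    for (j in seq_along(models)) {
      if (i == j || !nested(models[[i]], models[[j]])) next
      n_pairs <- n_pairs + 1L
      expect_gte(fits[[j]]$loglik, fits[[i]]$loglik - 1e-3)
    }
  }
  expect_gt(n_pairs, 100L)
})

test_that("the worked-example suffix sets yield the printed best models", {
  expected <- list(list(2, "Q", 1, "Suffix ~ Number"),
                   list(2, "N", 3, "Suffix ~ Number + Animal[bird] + Motion[bounce]"),
                   list(2, "V", 1, "Suffix ~ Motion[loop]"),
                   list(8, "Q", 2, "Suffix ~ Number + Animal[crocodile]"),
                   list(8, "N", 2, "Suffix ~ Number + Animal[bird]"),
                   list(8, "V", 3, "Suffix ~ Number + Animal[crocodile] + Motion[loop]"))
  for (e in expected) {
    d <- example_subset(e[[1]], e[[2]])
    bm <- best_model(d$suffix, d[c("number", "animal", "motion")])
    expect_equal(bm$complexity, e[[3]])
    expect_equal(bm$formula, e[[4]])
  }
})

test_that("the target language scores Q=2, N=2, V=3", {
  tgt <- build_exp1_target()
  for (cl in c("Q", "N", "V")) {
    d <- tgt$table[tgt$table$class == cl, ]
    got <- best_model(d$suffix, d[c("number", "animal", "motion")])$complexity
    expect_equal(got, c(Q = 2L, N = 2L, V = 3L)[[cl]])
  }
})

test_that("constant suffixes give complexity 0 and AIC ties break to fewer parameters", {
  bm <- best_model(rep("a", 18), scene18)
  expect_equal(bm$complexity, 0L)
  expect_equal(bm$formula, "Suffix ~ 1")
  expect_equal(bm$best$aic, 0)
})

test_that("suffix entropy matches closed forms and its invariances", {
  expect_equal(suffix_entropy(rep(c("a", "ak"), each = 9)), 1)
  expect_equal(suffix_entropy(rep("onk", 18)), 0)
  expect_equal(suffix_entropy(rep(c("x", "y"), c(12, 6))),
               -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3))
  set.seed(7)
  for (i in 1:20) {
    x <- sample(letters[1:4], 18, replace = TRUE)
    h <- suffix_entropy(x)
    expect_gte(h, 0)
    expect_lte(h, log2(length(unique(x))) + 1e-12)
    relabel <- stats::setNames(sample(LETTERS[1:4]), letters[1:4])
    expect_equal(suffix_entropy(relabel[x]), h)
  }
})

test_that("pooling idiosyncratically simplified sources raises suffix entropy", {
  # two number-conditioned systems with disjoint form inventories; the pooled
  # data is more variable than either source on its own
  s1 <- rep(c("a", "ak"), each = 9)
  s2 <- rep(c("u", "uk"), each = 9)
  pooled <- c(s1, s2)
  expect_gt(suffix_entropy(pooled), suffix_entropy(s1))
  expect_gt(suffix_entropy(pooled), suffix_entropy(s2))
})
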