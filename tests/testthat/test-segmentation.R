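exp1_stems <- c("won", "sum", "snap", "kwak", "twit", "woosh", "boing", "loop")

test_that("exact-prefix segmentation splits at the stem and codes zero-marking", {
  s <- segment_word("wonak", c("won", "sum"))
  expect_equal(s[c("stem", "suffix", "method")],
               list(stem = "won", suffix = "ak", method = "exact_prefix"))
  expect_false(s$review)
  s <- segment_word("snap", exp1_stems)
  expect_equal(s$suffix, "NULL")
  expect_equal(s$method, "exact_prefix")
  # longest matching stem wins ties between nested candidate stems
  s <- segment_word("loopan", c("loo", "loop"))
  expect_equal(s$stem, "loop")
  expect_equal(s$suffix, "an")
})

test_that("best-edit segmentation minimizes distance with deterministic tie-breaks", {
  s <- segment_word("wanak", exp1_stems)
  expect_equal(s$stem, "wan")          # produced prefix: reconstruction holds
  expect_equal(s$suffix, "ak")
  expect_equal(s$matched_stem, "won")  # closest candidate at distance 1
  expect_equal(s$method, "best_edit")
  expect_true(s$review)
  expect_equal(paste0(s$stem, s$suffix), "wanak")
  expect_error(segment_word("", exp1_stems), "non-empty")
  expect_error(segment_word("wona", character(0)), "non-empty")
})

test_that("productions are segmented by word-class position with missing words flagged", {
  tgt <- build_exp1_target()
  seg <- segment_production(c("wona", "kwako"), tgt)
  expect_equal(seg$class, c("Q", "N", "V"))
  expect_equal(seg$method, c("exact_prefix", "exact_prefix", "missing"))
  expect_error(segment_production(c("a", "b", "c", "d"), tgt), "word classes")
})

test_that("scoring matches the normalized-distance definition per morpheme", {
  tgt <- build_exp1_target()
  sc <- list(number = "one", animal = "duck", motion = "straight")
  perfect <- score_production(c("wona", "kwako", "wooshan"), sc, tgt)
  expect_equal(perfect$stem_accuracy, c(1, 1, 1))
  expect_equal(perfect$suffix_accuracy, c(1, 1, 1))
  # wrong verb suffix: "onk" vs "an" is distance 2 over max length 3
  off <- score_production(c("wona", "kwako", "wooshonk"), sc, tgt)
  expect_equal(off$suffix_accuracy[3], 1 - 2 / 3)
  # zero-marked quantifier: NULL vs "a" scores 1 - d("", "a")/1 = 0
  zm <- score_production(c("won", "kwako", "wooshan"), sc, tgt)
  expect_equal(zm$stem_accuracy[1], 1)
  expect_equal(zm$suffix_accuracy[1], 0)
  # missing verb scores 0 on both
  ms <- score_production(c("wona", "kwako"), sc, tgt)
  expect_equal(ms$stem_accuracy[3], 0)
  expect_equal(ms$suffix_accuracy[3], 0)
  expect_error(score_production(c("wona", "kwako", "wooshan"),
                                list(number = "one", animal = "emu",
                                     motion = "straight"), tgt), "emu")
})

test_that("scoring is invariant to word-internal hyphens stripped at parse time", {
  tgt <- build_exp1_target()
  rec <- tibble::tibble(participant_id = "p", phase = 2, number = "one",
                        animal = "duck", motion = "straight",
                        word1 = "won-a", word2 = "kwak-o", word3 = "woosh-an")
  plain <- rec
  plain$word1 <- "wona"; plain$word2 <- "kwako"; plain$word3 <- "wooshan"
  expect_equal(score_productions(rec, tgt), score_productions(plain, tgt))
})

test_that("accuracy aggregation is a mean of by-participant means with CIs", {
  tgt <- build_exp1_target()
  lt <- language_table(tgt)
  words <- strsplit(lt$description, " ")
  base <- tibble::tibble(participant_id = "p1", phase = 2,
                         number = as.character(lt$number),
                         animal = as.character(lt$animal),
                         motion = as.character(lt$motion),
                         word1 = vapply(words, `[`, "", 1),
                         word2 = vapply(words, `[`, "", 2),
                         word3 = vapply(words, `[`, "", 3))
  agg1 <- aggregate_accuracy(score_productions(base, tgt))
  expect_equal(agg1$mean, c(1, 1))
  expect_equal(agg1$ci_low, c(1, 1))   # single participant: degenerate CI
  # second participant with zero-marked quantifiers everywhere:
  # Q suffix accuracy 0 on 18 of 54 morphemes -> participant suffix mean 2/3
  p2 <- base
  p2$participant_id <- "p2"
  p2$word1 <- vapply(seq_len(nrow(p2)), function(i) {
    target_segmentation(tgt, as.list(p2[i, c("number", "animal", "motion")]),
                        "Q")$stem
  }, "")
  agg2 <- aggregate_accuracy(score_productions(rbind(base, p2), tgt))
  suff <- agg2[agg2$measure == "suffix", ]
  expect_equal(suff$mean, mean(c(1, 2 / 3)))
  expect_equal(suff$n, 2L)
  # t-based interval: mean +/- qt(.975, 1) * sd / sqrt(2)
  half <- stats::qt(0.975, 1) * stats::sd(c(1, 2 / 3)) / sqrt(2)
  expect_equal(suff$ci_high - suff$mean, half)
})

test_that("accuracy is non-increasing in the number of random edits, in expectation", {
  tgt <- build_exp1_target()
  sc <- list(number = "one", animal = "duck", motion = "straight")
  corrupt <- function(word, n_edits) {
    for (i in seq_len(n_edits)) {
      pos <- sample(nchar(word), 1)
      substr(word, pos, pos) <- sample(letters, 1)
    }
    word
  }
  set.seed(99)
  means <- vapply(0:3, function(ne) {
    mean(vapply(1:40, function(r) {
      w <- c(corrupt("wona", ne), corrupt("kwako", ne), corrupt("wooshan", ne))
      s <- score_production(w, sc, tgt)
      mean(c(s$stem_accuracy, s$suffix_accuracy))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) <= 0.02))  # monotone up to Monte-Carlo slack
})
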