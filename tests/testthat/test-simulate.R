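tgt <- build_exp1_target()

test_that("learner simulation is bit-reproducible and faithful at zero noise", {
  cfg <- sim_learner_config(suffix_source = "target", noise_rate = 0,
                            zero_marking_rate = 0, seed = 11)
  a <- simulate_learner_productions(tgt, cfg, phases = c(2, 8))
  b <- simulate_learner_productions(tgt, cfg, phases = c(2, 8))
  expect_identical(a, b)
  # verbatim-target grammar with no noise reproduces the target language
  lt <- language_table(tgt)
  got <- paste(a$word1, a$word2, a$word3)[a$phase == 8]
  want <- lt$description[match(paste(a$number, a$animal, a$motion)[a$phase == 8],
                               paste(lt$number, lt$animal, lt$motion))]
  expect_identical(got, want)
  # and the complexity pipeline recovers the target's (2, 2, 3)
  ct <- complexity_table(a[a$phase == 8, ], tgt)
  expect_equal(stats::setNames(ct$complexity, ct$word_class),
               c(Q = 2L, N = 2L, V = 3L))
})

test_that("number-only learners measure at complexity at most 1 per class", {
  for (s in 1:5) {
    cfg <- sim_learner_config(conditioning = list(Q = "Number", N = "Number",
                                                  V = "Number"),
                              suffix_source = "sampled_from_target",
                              noise_rate = 0, zero_marking_rate = 0, seed = s)
    pr <- simulate_learner_productions(tgt, cfg, phases = 2)
    ct <- complexity_table(pr, tgt)
    expect_true(all(ct$complexity <= 1L))
  }
})

test_that("full zero-marking yields all-NULL suffixes and zero entropy", {
  cfg <- sim_learner_config(conditioning = list(Q = "Number", N = "Number",
                                                V = "Motion"),
                            noise_rate = 0, zero_marking_rate = 1, seed = 3)
  pr <- simulate_learner_productions(tgt, cfg, phases = 2)
  ct <- complexity_table(pr, tgt)
  expect_equal(ct$entropy_bits, c(0, 0, 0))
  expect_equal(ct$complexity, c(0L, 0L, 0L))
  seg <- segment_production(unlist(pr[1, c("word1", "word2", "word3")]), tgt)
  expect_equal(seg$suffix, c("NULL", "NULL", "NULL"))
})

test_that("source selection applies the exact-stem criterion per label", {
  lt <- language_table(tgt)
  words <- do.call(rbind, strsplit(lt$description, " "))
  mk <- function(id) tibble::tibble(participant_id = id, phase = 2,
                                    number = as.character(lt$number),
                                    animal = as.character(lt$animal),
                                    motion = as.character(lt$motion),
                                    word1 = words[, 1], word2 = words[, 2],
                                    word3 = words[, 3])
  perfect <- mk("perfect")
  one_off <- mk("one_off")
  one_off$word1[1] <- "wina"                               # 17/18 = 0.944
  two_off <- mk("two_off")
  two_off$word1[1] <- "wina"
  two_off$word3[9] <- "wuushan"                            # 16/18 = 0.889
  sel <- select_sources(rbind(perfect, one_off, two_off), tgt)
  expect_equal(sel$selected[sel$participant_id == "perfect"], TRUE)
  expect_equal(sel$exact_stem_prop[sel$participant_id == "one_off"], 17 / 18)
  expect_equal(sel$selected[sel$participant_id == "one_off"], TRUE)
  expect_equal(sel$exact_stem_prop[sel$participant_id == "two_off"], 16 / 18)
  expect_equal(sel$selected[sel$participant_id == "two_off"], FALSE)
})

test_that("training phases divide scenes across sources as 5+4 or 2+1x7", {
  coh <- simulate_exp1_cohort(10, seed = 4)
  ids <- unique(coh$participant_id)
  small <- mixing_design("small", "mixed")
  src2 <- data.frame(participant_id = ids[1:2], phase = c(2, 8))
  for (s in 1:20) {
    tp <- construct_training_phase(small, src2, coh, tgt, seed = s)
    expect_equal(nrow(tp), 9L)
    expect_false(anyDuplicated(paste(tp$number, tp$animal, tp$motion)) > 0)
    expect_equal(sort(as.vector(table(tp$source_id))), c(4L, 5L))
  }
  large <- mixing_design("large", "complex")
  src8 <- data.frame(participant_id = ids[1:8], phase = rep(8, 8))
  for (s in 1:20) {
    tp <- construct_training_phase(large, src8, coh, tgt, seed = s)
    expect_equal(sort(as.vector(table(tp$source_id))), c(rep(1L, 7L), 2L))
  }
  expect_error(construct_training_phase(small, src8, coh, tgt, seed = 1),
               "2 sources")
})

test_that("every scene is included in a training phase about half the time", {
  coh <- simulate_exp1_cohort(2, seed = 8)
  ids <- unique(coh$participant_id)
  small <- mixing_design("small", "complex")
  src2 <- data.frame(participant_id = ids, phase = c(8, 8))
  n <- 2000L
  hits <- integer(18)
  withr::with_seed(123, {
    for (i in seq_len(n)) {
      tp <- construct_training_phase(small, src2, coh, tgt)
      key <- paste(tp$number, tp$animal, tp$motion)
      all_key <- paste(tgt$scenes$number, tgt$scenes$animal, tgt$scenes$motion)
      hits <- hits + as.integer(all_key %in% key)
    }
  })
  freq <- hits / n
  # binomial sd at p = .5, n = 2000 is 0.011; allow 4.5 sd
  expect_true(all(abs(freq - 0.5) < 0.05))
})

test_that("mixed training input draws half its sources from each phase", {
  coh <- simulate_exp1_cohort(26, seed = 15)
  inp <- construct_training_input(mixing_design("large", "mixed"), coh, tgt,
                                  seed = 2, n_phases = 3)
  expect_equal(nrow(inp), 27L)
  src <- unique(inp[c("source_id", "source_phase")])
  expect_equal(sum(src$source_phase == 2), 4L)
  expect_equal(sum(src$source_phase == 8), 4L)
  # descriptions really come from the named source's records
  i <- 1L
  rec <- coh[coh$participant_id == inp$source_id[i] &
               coh$phase == inp$source_phase[i] &
               coh$number == inp$number[i] & coh$animal == inp$animal[i] &
               coh$motion == inp$motion[i], ]
  expect_equal(inp$description[i], paste(rec$word1, rec$word2, rec$word3))
})
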