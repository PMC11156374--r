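test_that("word-class ratios use all words as the denominator", {
  g1 <- gold_sentence_one()
  wc <- word_class_ratios(g1)
  expect_equal(unname(wc["noun_ratio"]), 1 / 8)
  expect_equal(unname(wc["verb_ratio"]), 2 / 8)

  no_nouns <- g1[g1$pos != "NOUN", ]
  expect_equal(unname(word_class_ratios(no_nouns)["noun_ratio"]), 0)
  expect_error(word_class_ratios(g1[0, ]), "empty")

  # direct count on a synthetic stream: 60 nouns, 50 verbs, 90 other
  tg <- data.frame(
    surface = "w",
    pos = rep(c("NOUN", "VERB", "DET"), c(60, 50, 90)),
    person = "none"
  )
  expect_equal(unname(word_class_ratios(tg)), c(0.30, 0.25))
})

test_that("person ratios count each marker of a pronoun-verb tandem", {
  expect_equal(unname(person_ratios(gold_sentence_one())), c(0.5, 0.5))
  expect_equal(unname(person_ratios(gold_sentence_two())), c(0.5, 0.5))

  all_first <- data.frame(surface = "yo", pos = "PRON",
                          person = rep("first", 4))
  expect_equal(unname(person_ratios(all_first)), c(1, 0))

  none <- data.frame(surface = "casa", pos = "NOUN", person = "none")
  expect_warning(pr <- person_ratios(none), "undefined")
  expect_true(all(is.na(pr)))
})

test_that("second-person markers are discarded unless configured otherwise", {
  tg <- data.frame(surface = "v", pos = "VERB",
                   person = c("first", "third", "second", "second"))
  expect_equal(unname(person_ratios(tg)), c(0.5, 0.5))
  expect_equal(unname(person_ratios(tg, include_second = TRUE)),
               c(0.25, 0.25))
})

test_that("property means average over content tokens and report coverage", {
  lex <- data.frame(surface = c("casa", "perro"),
                    log_freq = c(1.0, 3.0),
                    phon_neighbors = c(10L, 2L),
                    length_phonemes = c(4L, 5L))
  one <- data.frame(surface = "casa", pos = "NOUN", person = "none")
  expect_equal(unname(lexical_property_means(one, lex)["mean_log_freq"]), 1.0)

  two <- data.frame(surface = c("casa", "perro"), pos = "NOUN",
                    person = "none")
  expect_equal(unname(lexical_property_means(two, lex)["mean_log_freq"]), 2.0)

  oov <- data.frame(surface = c("casa", "xilo", "perro"), pos = "NOUN",
                    person = "none")
  lp <- lexical_property_means(oov, lex)
  expect_equal(unname(lp["mean_log_freq"]), 2.0)
  expect_equal(unname(lp["coverage"]), 2 / 3)

  gone <- data.frame(surface = "xilo", pos = "NOUN", person = "none")
  expect_error(lexical_property_means(gone, lex, id = "p9"),
               "zero lexicon hits.*p9")
  # stop words are not content words
  det <- data.frame(surface = "la", pos = "DET", person = "none")
  expect_error(lexical_property_means(det, lex), "no content words")
})

test_that("semantic variability matches the hand-computed cases", {
  tg <- function(words) data.frame(surface = words, pos = "NOUN",
                                   person = "none")
  emb <- rbind(a = c(1, 0), b = c(0, 1), c = c(-1, 0), d = c(1, 1))

  # constant distance series: orthogonal steps -> variance 0
  expect_equal(semantic_variability(tg(c("a", "b", "c")), emb), 0)
  # distances (1, 1 - 1/sqrt(2)) -> two-point sample variance 0.25
  expect_equal(semantic_variability(tg(c("a", "b", "d")), emb), 0.25,
               tolerance = 1e-12)
  # population variance halves the two-point sample variance
  expect_equal(
    semantic_variability(tg(c("a", "b", "d")), emb, variance = "population"),
    0.125, tolerance = 1e-12)
  # fewer than three embeddable words
  expect_warning(sv <- semantic_variability(tg(c("a", "b")), emb),
                 "fewer than 3")
  expect_true(is.na(sv))
})

test_that("semantic variability is invariant to global embedding scale", {
  set.seed(42)
  emb <- matrix(rnorm(50 * 8), 50,
                dimnames = list(paste0("w", 1:50), NULL))
  tg <- data.frame(surface = sample(rownames(emb), 30, replace = TRUE),
                   pos = "NOUN", person = "none")
  v1 <- semantic_variability(tg, emb)
  v2 <- semantic_variability(tg, emb * 7.3)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("repetition handling distinguishes global and adjacent modes", {
  emb <- rbind(a = c(1, 0), b = c(0, 1), d = c(1, 1))
  tg <- data.frame(surface = c("a", "b", "a", "d"), pos = "NOUN",
                   person = "none")
  # global: a b d; adjacent: a b a d (no immediate repeats to collapse)
  v_global <- semantic_variability(tg, emb, dedup = "global")
  v_adj <- semantic_variability(tg, emb, dedup = "adjacent")
  expect_equal(v_global, 0.25, tolerance = 1e-12)
  expect_gt(abs(v_adj - v_global), 1e-6)
})

test_that("feature extraction is deterministic and handles degenerate input", {
  lex <- demo_tag_lexicon()
  props <- demo_properties()
  set.seed(3)
  emb <- matrix(rnorm(nrow(props) * 8), nrow(props),
                dimnames = list(props$surface, NULL))
  tr <- transcript("p1", "HC",
                   "Mi hijo llega y dice que quiero las llaves. Voy yo.")
  f1 <- extract_features(tr, demo_tag_lexicon(), props, emb)
  f2 <- extract_features(tr, demo_tag_lexicon(), props, emb)
  expect_identical(f1, f2)
  expect_equal(f1$first_person_ratio + f1$third_person_ratio, 1)
  expect_true(f1$noun_ratio + f1$verb_ratio <= 1)

  # one repeated content word: ratios defined, variability missing
  rep_tr <- transcript("p2", "AD", "casa casa casa casa.")
  suppressWarnings(f3 <- extract_features(rep_tr, demo_tag_lexicon(),
                                          props, emb))
  expect_true(is.na(f3$semantic_variability))
  expect_equal(f3$noun_ratio, 1)
})
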