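test_that("lexicon generation is deterministic and internally complete", {
  l1 <- make_lexicon(120L, seed = 5L)
  l2 <- make_lexicon(120L, seed = 5L)
  expect_identical(l1$properties, l2$properties)
  expect_identical(l1$tags$entries, l2$tags$entries)
  expect_identical(unclass(l1$embeddings), unclass(l2$embeddings))

  # everything the generator can emit is covered by all three resources
  emittable <- c(l1$pools$NOUN$surface, as.vector(l1$pools$VERB$forms),
                 l1$pools$ADJ$surface, l1$pools$ADV$surface,
                 spanish_function_words()$surface)
  expect_true(all(emittable %in% l1$tags$entries$surface))
  expect_true(all(emittable %in% l1$properties$surface))
  expect_true(all(emittable %in% rownames(l1$embeddings)))
  expect_error(make_lexicon(20L), "n_words")
})

test_that("lexicon frequencies follow the configured Zipf law", {
  lex <- make_lexicon(480L, seed = 2L, zipf_slope = 1.0)
  props <- lex$properties
  nouns <- data.frame(surface = lex$pools$NOUN$surface,
                      rank = lex$pools$NOUN$rank)
  nouns$log_freq <- props$log_freq[match(nouns$surface, props$surface)]
  slope <- coef(lm(log_freq ~ log10(rank), data = nouns))[[2L]]
  expect_equal(slope, -1.0, tolerance = 0.1)
  # log frequency spans at least two decades
  expect_gte(diff(range(props$log_freq)), 2)
  # neighborhood counts decrease with phoneme length on average
  expect_lt(cor(props$phon_neighbors, props$length_phonemes,
                method = "spearman"), 0)
})

test_that("generated verb inflections resolve to the intended person", {
  lex <- make_lexicon(100L, seed = 6L)
  forms <- lex$pools$VERB$forms
  for (person in c("first", "second", "third")) {
    tg <- tag_stream(forms[, person], lex$tags, resolve = FALSE)
    expect_true(all(tg$pos == "VERB"))
    expect_true(all(tg$person == person))
  }
  # the imperfect form is lexically ambiguous, then defaults to third
  amb <- tag_stream(forms[1:5, "imperfect"], lex$tags, resolve = FALSE)
  expect_true(all(amb$person == "ambiguous"))
  res <- tag_stream(forms[1:5, "imperfect"], lex$tags)
  expect_true(all(res$person == "third"))
})

test_that("clause person probability drives the person ratios", {
  lex <- make_lexicon(100L, seed = 7L)
  tr <- generate_transcript(
    list(p_first = 1, p_nounslot = 0.5, temp = 1,
         clause = list(p_second = 0)),
    lex, length_target = 200L, seed = 1L)
  expect_equal(unname(person_ratios(tr$gold)), c(1, 0))
  tr3 <- generate_transcript(
    list(p_first = 0, p_nounslot = 0.5, temp = 1,
         clause = list(p_second = 0)),
    lex, length_target = 200L, seed = 1L)
  expect_equal(unname(person_ratios(tr3$gold)), c(0, 1))
})

test_that("explicit pronoun-verb tandems contribute two person markers", {
  lex <- make_lexicon(100L, seed = 3L)
  tr <- generate_transcript(
    list(p_first = 1, p_nounslot = 0, temp = 1,
         clause = list(p_second = 0, p_pronoun = 1, p_imperfect = 0,
                       p_possessive = 0)),
    lex, length_target = 60L, seed = 2L)
  g <- tr$gold
  # every clause carries exactly two first-person markers: yo + verb
  for (s in unique(g$sentence)) {
    cl <- g[g$sentence == s, ]
    expect_equal(sum(cl$person == "first"), 2L)
    expect_equal(cl$pos[cl$person == "first"], c("PRON", "VERB"))
  }
})

test_that("realized noun ratio increases with the noun-slot probability", {
  lex <- make_lexicon(100L, seed = 4L)
  set.seed(1)
  mean_ratio <- sapply(c(0.1, 0.5, 0.9), function(p) {
    mean(replicate(8, {
      tr <- generate_transcript(list(p_first = 0.7, p_nounslot = p,
                                     temp = 1), lex, length_target = 150L)
      word_class_ratios(tr$gold)[["noun_ratio"]]
    }))
  })
  expect_true(all(diff(mean_ratio) > 0))
})

test_that("cohort generation is deterministic and loads back with matched counts", {
  cfg <- tiny_config(seed = 12L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$participants, c2$participants)
  id <- c1$participants$participant_id[7L]
  expect_identical(c1$transcripts[[id]], c2$transcripts[[id]])

  expect_equal(as.integer(table(c1$participants$split)), c(9L, 15L))
  dir <- withr::local_tempdir()
  write_cohort(c1, dir)
  main <- load_corpus(file.path(dir, "manifest_main.json"))
  expect_equal(unname(c(attr(main, "group_counts"))), c(5L, 5L, 5L))
})

test_that("gold tags agree with the reference tagger on full-coverage text", {
  cohort <- generate_cohort(tiny_config(seed = 21L))
  ids <- cohort$participants$participant_id[1:6]
  for (id in ids) {
    tr <- cohort$transcripts[[id]]
    tagged <- tag_stream(clean_word_stream(tokenize(tr$text)),
                         cohort$lexicon$tags)
    ag <- tag_agreement(tagged[, c("pos", "person")],
                        tr$gold[, c("pos", "person")])
    expect_gte(ag$accuracy, 0.99)
  }
})

test_that("a null configuration plants no group differences", {
  cfg <- cohort_config(
    n_main = c(AD = 150L, bvFTD = 2L, HC = 150L),
    n_holdout = c(AD = 0L, bvFTD = 0L, HC = 0L),
    offsets = list(AD = c(), bvFTD = c(), HC = c()),
    lexicon_spec = list(n_words = 150L, embed_dim = 16L, zipf_slope = 1.0),
    seed = 31L
  )
  gf <- gold_features(generate_cohort(cfg))
  hc <- gf[gf$group == "HC", ]
  ad <- gf[gf$group == "AD", ]
  d <- function(a, b) (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  expect_lt(abs(d(hc$noun_ratio, ad$noun_ratio)), 0.2)
  expect_lt(abs(d(hc$first_person_ratio, ad$first_person_ratio)), 0.2)
  expect_lt(abs(d(hc$mean_log_freq, ad$mean_log_freq)), 0.2)
})

test_that("effect calibration is self-consistent and bounded", {
  cfg <- cohort_config(
    length_mean = c(AD = 120, bvFTD = 120, HC = 120), length_sd = 15,
    length_min = 80,
    lexicon_spec = list(n_words = 120L, embed_dim = 16L, zipf_slope = 1.0)
  )
  off <- calibrate_effect("p_first", target_d = 0.9, config = cfg,
                          n_sim = 500L, tol = 0.1, seed = 17L)
  expect_lt(off, 0)
  expect_equal(abs(attr(off, "realized_d")), 0.9, tolerance = 0.1)
  # re-measuring at the returned offset reproduces the target
  d2 <- speechmarkers:::measure_planted_d(cfg, "p_first", as.numeric(off),
                                          "first_person_ratio", 500L,
                                          seed = 18L)
  expect_equal(abs(d2), 0.9, tolerance = 0.25)
  expect_error(
    calibrate_effect("p_first", target_d = 8, config = cfg, n_sim = 200L,
                     seed = 3L),
    "not reachable"
  )
})

test_that("simulated cognitive scores are independent of the speech features", {
  cfg <- cohort_config(
    n_main = c(AD = 120L, bvFTD = 2L, HC = 2L),
    n_holdout = c(AD = 0L, bvFTD = 0L, HC = 0L),
    lexicon_spec = list(n_words = 120L, embed_dim = 16L, zipf_slope = 1.0),
    seed = 77L
  )
  gf <- gold_features(generate_cohort(cfg))
  ad <- gf[gf$group == "AD", ]
  expect_lt(abs(cor(ad$noun_ratio, ad$moca)), 0.25)
  expect_lt(abs(cor(ad$mean_log_freq, ad$ifs)), 0.25)
})
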