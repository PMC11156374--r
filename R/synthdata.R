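#' Spanish function words of the generator's closed class
#'
#' Determiners (including the person-carrying possessives), subject and
#' clitic pronouns, adpositions, conjunctions and a few high-frequency
#' adverbs. Possessive determiners carry grammatical person (e.g. "mi" is a
#' first-person marker), subject pronouns carry person, articles do not.
#'
#' @return a `data.frame` with columns `surface`, `pos`, `person`.
#' @export
spanish_function_words <- function() {
  data.frame(
    surface = c("el", "la", "los", "las", "un", "una",
                "mi", "tu", "su",
                "yo", "me", "tú", "él", "ella", "se", "eso", "algo",
                "en", "de", "a", "con", "por",
                "y", "que", "pero", "si",
                "no", "entonces", "después", "siempre", "primero"),
    pos = c(rep("DET", 6), rep("DET", 3),
            rep("PRON", 8),
            rep("ADP", 5),
            rep("CONJ", 4),
            rep("ADV", 5)),
    person = c(rep("none", 6), "first", "second", "third",
               "first", "first", "second", "third", "third", "third",
               "none", "none",
               rep("none", 5),
               rep("none", 4),
               rep("none", 5)),
    stringsAsFactors = FALSE
  )
}

make_surfaces <- function(n, syllables = 2:3, final_consonant = FALSE,
                          taken = character(0)) {
  cons <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t", "v")
  vows <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    need <- 3L * (n - length(out))
    k <- sample(syllables, need, replace = TRUE)
    cand <- vapply(k, function(ki) {
      paste0(paste0(sample(cons, ki, replace = TRUE),
                    sample(vows, ki, replace = TRUE)), collapse = "")
    }, character(1))
    if (final_consonant) {
      cand <- paste0(cand, sample(c("n", "r", "s", "l", "t"),
                                  length(cand), replace = TRUE))
    }
    cand <- setdiff(unique(cand), c(taken, out))
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

VERB_FORM_SUFFIX <- c(first = "o", second = "as", third = "a",
                      imperfect = "aba")

#' Generate a synthetic Spanish-like lexicon
#'
#' Builds, under one seed, the three coupled resources every pipeline stage
#' consumes: a tagging lexicon (closed-class function words plus generated
#' open-class nouns, verbs, adjectives and adverbs, with verbs inflected for
#' person by the same suffixes the reference tagger's fallback rules use), a
#' psycholinguistic property table (Zipfian log frequency per million over
#' lemma ranks, lengths in phonemes, neighborhood counts decreasing in
#' length), and a unit-norm embedding table with part-of-speech-clustered
#' structure. Coverage is total: everything the transcript generator can
#' emit is in all three resources.
#'
#' @param n_words number of open-class lemmas (>= 50); split 45/25/17/13
#'   percent into nouns/verbs/adjectives/adverbs.
#' @param seed RNG seed; identical seeds give identical lexicons.
#' @param embed_dim embedding dimension.
#' @param zipf_slope magnitude of the log10 frequency vs. log10 rank slope.
#' @return a list of class `synthetic_lexicon` with elements `tags`
#'   (a [tag_lexicon()]), `properties`, `embeddings`, and `pools`
#'   (per-class surfaces with Zipf ranks, used by the transcript generator).
#' @export
make_lexicon <- function(n_words = 480L, seed = 1L, embed_dim = 32L,
                         zipf_slope = 1.0) {
  stopifnot(n_words >= 50L)
  set.seed(seed)
  shares <- c(NOUN = 0.45, VERB = 0.25, ADJ = 0.17, ADV = 0.13)
  n_pos <- pmax(round(shares * n_words), 1L)
  if (any(n_pos < 5L)) {
    stop("n_words too small to fill all word classes", call. = FALSE)
  }
  closed <- spanish_function_words()
  taken <- closed$surface
  nouns <- make_surfaces(n_pos[["NOUN"]], taken = taken)
  taken <- c(taken, nouns)
  stems <- make_surfaces(n_pos[["VERB"]], final_consonant = TRUE,
                         taken = taken)
  forms <- vapply(VERB_FORM_SUFFIX, function(s) paste0(stems, s),
                  character(length(stems)))
  taken <- c(taken, as.vector(forms))
  adjs <- make_surfaces(n_pos[["ADJ"]], taken = taken)
  taken <- c(taken, adjs)
  advs <- make_surfaces(n_pos[["ADV"]], taken = taken)

  # each class carries its own Zipf rank sequence 1..n: the frequency
  # structure every pool exposes to the sampler is then identical across
  # lexicon realizations
  n_open <- sum(n_pos)
  rank_of <- lapply(n_pos, seq_len)
  ranks <- unlist(rank_of, use.names = FALSE)
  lemma_freq <- 3.2 - zipf_slope * log10(ranks) + stats::rnorm(n_open, 0, 0.08)

  # property table covers every emittable surface (verb forms inherit the
  # lemma frequency; function words get uniformly high frequency)
  form_mat <- forms
  verb_ix <- seq(n_pos[["NOUN"]] + 1L, n_pos[["NOUN"]] + n_pos[["VERB"]])
  prop_surf <- c(nouns, as.vector(form_mat), adjs, advs, closed$surface)
  prop_freq <- c(lemma_freq[seq_len(n_pos[["NOUN"]])],
                 rep(lemma_freq[verb_ix], length(VERB_FORM_SUFFIX)),
                 lemma_freq[-seq_len(n_pos[["NOUN"]] + n_pos[["VERB"]])],
                 stats::runif(nrow(closed), 3.0, 3.6))
  len <- nchar(prop_surf)
  properties <- data.frame(
    surface = prop_surf,
    log_freq = prop_freq,
    phon_neighbors = round(exp(pmax(0, 3.8 - 0.35 * len) +
                                 stats::rnorm(length(len), 0, 0.3))),
    length_phonemes = len,
    stringsAsFactors = FALSE
  )

  open_entries <- data.frame(
    surface = c(nouns,
                as.vector(form_mat),
                adjs, advs),
    pos = c(rep("NOUN", length(nouns)),
            rep("VERB", length(form_mat)),
            rep("ADJ", length(adjs)), rep("ADV", length(advs))),
    person = c(rep("none", length(nouns)),
               rep(c("first", "second", "third", "ambiguous"),
                   each = length(stems)),
               rep("none", length(adjs) + length(advs))),
    stringsAsFactors = FALSE
  )
  tags <- tag_lexicon(rbind(closed, open_entries), default_suffix_rules())

  centers <- matrix(stats::rnorm(5L * embed_dim), 5L,
                    dimnames = list(c("NOUN", "VERB", "ADJ", "ADV", "FN"),
                                    NULL))
  cls <- c(rep("NOUN", length(nouns)), rep("VERB", length(form_mat)),
           rep("ADJ", length(adjs)), rep("ADV", length(advs)),
           rep("FN", nrow(closed)))
  emb <- 0.8 * centers[cls, , drop = FALSE] +
    matrix(stats::rnorm(length(cls) * embed_dim), length(cls))
  emb <- emb / sqrt(rowSums(emb^2))
  rownames(emb) <- prop_surf
  class(emb) <- c("embedding_table", class(emb))

  structure(
    list(
      tags = tags, properties = properties, embeddings = emb,
      pools = list(
        NOUN = list(surface = nouns, rank = rank_of[["NOUN"]]),
        VERB = list(stems = stems, forms = form_mat,
                    rank = rank_of[["VERB"]]),
        ADJ = list(surface = adjs, rank = rank_of[["ADJ"]]),
        ADV = list(surface = advs, rank = rank_of[["ADV"]])
      ),
      zipf_slope = zipf_slope, seed = seed
    ),
    class = "synthetic_lexicon"
  )
}

default_clause_params <- function() {
  list(p_pronoun = 0.5, p_nounsubj = 0.4, p_second = 0.011,
       p_imperfect = 0.06, p_possessive = 0.12, p_object_adj = 0.3,
       p_adverb = 0.35, p_adp_phrase = 0.2, p_conj = 0.25)
}

default_disfluency_params <- function() {
  list(p_filler = 0.06, p_fragment = 0.012, p_unintelligible = 0.004)
}

sample_pool <- function(pool_surface, pool_rank, n, temp) {
  if (n == 0L) return(character(0))
  w <- pool_rank^(-temp)
  pool_surface[sample.int(length(pool_surface), n, replace = TRUE, prob = w)]
}

#' Generate one synthetic routine-description transcript
#'
#' Emits a first-person-dominant clause loop (Subject-Verb-Object-Adjunct)
#' until the target word count is reached, together with parallel gold tags.
#' Subjects are realized as dropped pronouns (the verb inflection alone
#' carries person), explicit pronoun + verb tandems (two person markers, as
#' pro-drop counting requires), or noun phrases with third-person verbs.
#' Content words are drawn from the lexicon's Zipf ranks with weight
#' `rank^-temp`, so the `temp` parameter shifts the transcript toward more
#' frequent vocabulary. A configurable fraction of clauses carries fillers,
#' interrupted-word fragments or unintelligible spans in the raw text; these
#' never enter the gold tags.
#'
#' @param params list with `p_first` (first- vs third-person clause
#'   probability), `p_nounslot` (object noun-phrase probability), `temp`
#'   (frequency temperature), and optionally `clause` / `disfluency`
#'   sub-lists overriding the defaults.
#' @param lexicon a [make_lexicon()] result.
#' @param length_target minimum number of words.
#' @param seed optional RNG seed.
#' @return a list with `text` (raw transcript), `gold` (tagged token
#'   `data.frame` with `surface`, `pos`, `person`, `sentence`), and
#'   `word_count`.
#' @export
generate_transcript <- function(params, lexicon, length_target = 270L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cl <- utils::modifyList(default_clause_params(),
                          params$clause %||% list())
  df <- utils::modifyList(default_disfluency_params(),
                          params$disfluency %||% list())
  M <- ceiling(length_target / 3) + 12L

  u_person <- stats::runif(M)
  person <- ifelse(u_person < cl$p_second, "second",
                   ifelse(u_person < cl$p_second +
                            (1 - cl$p_second) * params$p_first,
                          "first", "third"))
  subj_noun <- person == "third" & stats::runif(M) < cl$p_nounsubj
  pron <- !subj_noun & stats::runif(M) < cl$p_pronoun
  imperf <- pron & person != "second" & stats::runif(M) < cl$p_imperfect
  object <- stats::runif(M) < params$p_nounslot
  poss <- object & person != "second" & stats::runif(M) < cl$p_possessive
  obj_adj <- object & stats::runif(M) < cl$p_object_adj
  adp <- stats::runif(M) < cl$p_adp_phrase
  adv <- stats::runif(M) < cl$p_adverb
  conj <- stats::runif(M) < cl$p_conj

  pools <- lexicon$pools
  nouns_needed <- sum(subj_noun) + sum(object) + sum(adp)
  noun_draw <- sample_pool(pools$NOUN$surface, pools$NOUN$rank,
                           nouns_needed, params$temp)
  ni <- 0L
  take_nouns <- function(n) {
    out <- noun_draw[ni + seq_len(n)]
    ni <<- ni + n
    out
  }
  verb_lemma <- sample.int(length(pools$VERB$stems), M, replace = TRUE,
                           prob = pools$VERB$rank^(-params$temp))
  form_col <- ifelse(imperf, "imperfect", person)
  verb_surf <- pools$VERB$forms[cbind(verb_lemma,
                                      match(form_col,
                                            colnames(pools$VERB$forms)))]
  adj_draw <- sample_pool(pools$ADJ$surface, pools$ADJ$rank, sum(obj_adj),
                          params$temp)
  adv_draw <- sample_pool(pools$ADV$surface, pools$ADV$rank, sum(adv),
                          params$temp)

  articles <- c("el", "la", "un", "una")
  poss_det <- c(first = "mi", third = "su")
  pron_surf <- c(first = "yo", second = "tú", third = "él")

  S <- 11L  # slots: conj sdet snoun pron verb odet onoun oadj adp pnoun adv
  surf <- matrix(NA_character_, M, S)
  posm <- matrix(NA_character_, M, S)
  perm <- matrix("none", M, S)
  surf[conj, 1L] <- "y"; posm[conj, 1L] <- "CONJ"
  surf[subj_noun, 2L] <- sample(articles, sum(subj_noun), replace = TRUE)
  posm[subj_noun, 2L] <- "DET"
  surf[subj_noun, 3L] <- take_nouns(sum(subj_noun))
  posm[subj_noun, 3L] <- "NOUN"
  surf[pron, 4L] <- pron_surf[person[pron]]
  posm[pron, 4L] <- "PRON"; perm[pron, 4L] <- person[pron]
  surf[, 5L] <- verb_surf; posm[, 5L] <- "VERB"; perm[, 5L] <- person
  surf[object, 6L] <- ifelse(poss[object], poss_det[person[object]],
                             sample(articles, sum(object), replace = TRUE))
  posm[object, 6L] <- "DET"
  perm[object, 6L] <- ifelse(poss[object], person[object], "none")
  surf[object, 7L] <- take_nouns(sum(object))
  posm[object, 7L] <- "NOUN"
  # unrealized noun slots surface as a pro-form instead: speakers low on
  # noun retrieval fall back on "eso"/"algo", keeping clause length stable
  surf[!object, 7L] <- sample(c("eso", "algo"), sum(!object), replace = TRUE)
  posm[!object, 7L] <- "PRON"
  surf[obj_adj, 8L] <- adj_draw; posm[obj_adj, 8L] <- "ADJ"
  surf[adp, 9L] <- sample(c("en", "de", "con", "por"), sum(adp),
                          replace = TRUE)
  posm[adp, 9L] <- "ADP"
  surf[adp, 10L] <- take_nouns(sum(adp)); posm[adp, 10L] <- "NOUN"
  surf[adv, 11L] <- adv_draw; posm[adv, 11L] <- "ADV"

  flat <- as.vector(t(surf))
  keep <- !is.na(flat)
  gold <- data.frame(
    surface = flat[keep],
    pos = as.vector(t(posm))[keep],
    person = as.vector(t(perm))[keep],
    sentence = rep(seq_len(M), each = S)[keep],
    stringsAsFactors = FALSE
  )
  words_per_clause <- tabulate(gold$sentence, nbins = M)
  last <- which(cumsum(words_per_clause) >= length_target)[1L]
  if (is.na(last)) last <- M
  gold <- gold[gold$sentence <= last, , drop = FALSE]
  rownames(gold) <- NULL

  clause_tokens <- split(gold$surface, gold$sentence)
  filler_pool <- c("eh", "em", "mmm")
  has_filler <- stats::runif(last) < df$p_filler
  has_frag <- stats::runif(last) < df$p_fragment
  has_unint <- stats::runif(last) < df$p_unintelligible
  text_clauses <- vapply(seq_len(last), function(ci) {
    toks <- clause_tokens[[ci]]
    if (has_filler[ci]) {
      toks <- c(sample(filler_pool, 1L), ",", toks)
    }
    if (has_frag[ci]) {
      w <- sample(toks, 1L)
      frag <- paste0(substr(w, 1L, max(2L, nchar(w) - 2L)), "…")
      at <- sample(length(toks), 1L)
      toks <- append(toks, frag, after = at - 1L)
    }
    if (has_unint[ci]) {
      toks <- append(toks, "[inaudible]", after = sample(length(toks), 1L))
    }
    paste0(paste(toks, collapse = " "), ".")
  }, character(1))
  list(text = paste(text_clauses, collapse = " "), gold = gold,
       word_count = nrow(gold))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort generator configuration
#'
#' Encodes the study conditions the generator emulates: three groups (AD,
#' bvFTD, HC) of 21 participants in the main split and 11 each in the
#' hold-out split; truncated-normal transcript lengths with group means
#' 238.57 / 253.95 / 304.14 words; and group parameter offsets planted so
#' the realized feature differences against HC reproduce the target effect
#' sizes (noun-ratio deficit d = 1.145 and word-frequency excess d = 1.13
#' in AD; first-person deficit d = 0.91, third-person excess d = 0.915 and
#' frequency excess d = 0.98 in bvFTD). Offsets are expressed on the logit
#' scale for probabilities and additively for the frequency temperature;
#' the defaults were fixed once with [calibrate_effect()] against those
#' targets. Participant-level trait dispersion around each group mean
#' (`trait_sd`) creates realistic between-subject variance. Cognitive
#' scores (MoCA, IFS) are simulated from group-typical distributions
#' independently of the linguistic features, giving correlation analyses a
#' true null.
#'
#' @param n_main,n_holdout named group sizes.
#' @param length_mean,length_sd,length_min transcript length distribution
#'   (truncated normal, words).
#' @param baseline HC parameter set: `p_nounslot`, `p_first`, `temp`.
#' @param offsets per-group parameter offsets from the HC baseline.
#' @param trait_sd participant-level SDs of the three traits.
#' @param target_d documented target effect sizes (not used at run time).
#' @param lexicon_spec arguments for [make_lexicon()].
#' @param score_params group mean (sd) of the simulated MoCA and IFS scores.
#' @param seed master seed; every derived random stream is a function of it.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_main = c(AD = 21L, bvFTD = 21L, HC = 21L),
    n_holdout = c(AD = 11L, bvFTD = 11L, HC = 11L),
    length_mean = c(AD = 238.57, bvFTD = 253.95, HC = 304.14),
    length_sd = 80, length_min = 80,
    baseline = list(p_nounslot = 0.5, p_first = 0.75, temp = 1.0),
    offsets = list(
      AD = c(logit_p_nounslot = -0.5, temp = 0.176),
      bvFTD = c(logit_p_first = -0.539, temp = 0.155),
      HC = c()
    ),
    trait_sd = c(logit_p_nounslot = 0.25, logit_p_first = 0.5, temp = 0.15),
    target_d = c(noun_ratio_AD = 1.145, first_person_bvFTD = 0.91,
                 third_person_bvFTD = 0.915, mean_log_freq_AD = 1.13,
                 mean_log_freq_bvFTD = 0.98),
    lexicon_spec = list(n_words = 480L, embed_dim = 32L, zipf_slope = 1.0),
    score_params = list(
      MoCA = list(AD = c(14.53, 5.46), bvFTD = c(17.67, 9.55),
                  HC = c(24.91, 4.11)),
      IFS = list(AD = c(12.62, 6.29), bvFTD = c(13.14, 6.33),
                 HC = c(20.1, 4.37))
    ),
    seed = 20240606L) {
  stopifnot(all(n_main >= 2L), all(n_holdout >= 0L))
  structure(
    list(n_main = n_main, n_holdout = n_holdout, length_mean = length_mean,
         length_sd = length_sd, length_min = length_min, baseline = baseline,
         offsets = offsets, trait_sd = trait_sd, target_d = target_d,
         lexicon_spec = lexicon_spec, score_params = score_params,
         seed = seed),
    class = "cohort_config"
  )
}

group_params <- function(config, group) {
  off <- config$offsets[[group]] %||% c()
  g <- function(name, base, logit = FALSE) {
    o <- if (logit) off[paste0("logit_", name)] else off[name]
    o <- if (length(o) == 0L || is.na(o)) 0 else unname(o)
    if (logit) stats::plogis(stats::qlogis(base) + o) else base + o
  }
  list(p_nounslot = g("p_nounslot", config$baseline$p_nounslot, TRUE),
       p_first = g("p_first", config$baseline$p_first, TRUE),
       temp = g("temp", config$baseline$temp))
}

draw_traits <- function(config, group, n, severity_load = 0.6) {
  gp <- group_params(config, group)
  sd_ <- config$trait_sd
  # a shared latent factor correlates the trait channels within a
  # participant (|corr| = severity_load between any two), signed so the
  # deficit directions align: low noun retrieval goes with low
  # self-reference and with a retreat to high-frequency vocabulary.
  # Marginal SDs are unaffected
  z <- stats::rnorm(n)
  dev <- function(sd_k, sign_k = 1) {
    sd_k * (sign_k * sqrt(severity_load) * z +
              sqrt(1 - severity_load) * stats::rnorm(n))
  }
  data.frame(
    p_nounslot = stats::plogis(stats::qlogis(gp$p_nounslot) +
                                 dev(sd_[["logit_p_nounslot"]])),
    p_first = stats::plogis(stats::qlogis(gp$p_first) +
                              dev(sd_[["logit_p_first"]])),
    temp = pmax(0.2, gp$temp + dev(sd_[["temp"]], sign_k = -1))
  )
}

draw_lengths <- function(config, group, n) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::rnorm(2L * n, config$length_mean[[group]],
                         config$length_sd)
    out <- c(out, cand[cand >= config$length_min])
  }
  round(out[seq_len(n)])
}

draw_scores <- function(config, group, n) {
  sp <- config$score_params
  clip <- function(x) pmin(30, pmax(0, round(x, 1)))
  data.frame(
    moca = clip(stats::rnorm(n, sp$MoCA[[group]][1], sp$MoCA[[group]][2])),
    ifs = clip(stats::rnorm(n, sp$IFS[[group]][1], sp$IFS[[group]][2]))
  )
}

#' Generate a full synthetic cohort
#'
#' Produces, deterministically under the config's master seed, the lexicon,
#' the main and hold-out splits of raw transcripts with parallel gold tags,
#' simulated cognitive scores, and a truth record of the planted per-
#' participant parameters.
#'
#' @param config a [cohort_config()].
#' @return a list of class `synthetic_cohort` with elements `lexicon`,
#'   `participants` (id, group, split, planted traits, target length,
#'   scores), `transcripts` (named list of `text` + `gold`), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  lex <- do.call(make_lexicon,
                 c(config$lexicon_spec,
                   list(seed = config$seed %% 1000003L + 1L)))
  set.seed(config$seed + 1L)
  parts <- list()
  txts <- list()
  for (split in c("main", "holdout")) {
    ns <- if (split == "main") config$n_main else config$n_holdout
    for (group in names(ns)) {
      n <- ns[[group]]
      if (n == 0L) next
      traits <- draw_traits(config, group, n)
      lens <- draw_lengths(config, group, n)
      scores <- draw_scores(config, group, n)
      ids <- sprintf("%s-%s-%02d", split, group, seq_len(n))
      for (i in seq_len(n)) {
        tr <- generate_transcript(
          list(p_first = traits$p_first[i],
               p_nounslot = traits$p_nounslot[i],
               temp = traits$temp[i]),
          lex, length_target = lens[i]
        )
        txts[[ids[i]]] <- tr
      }
      parts[[length(parts) + 1L]] <- cbind(
        data.frame(participant_id = ids, group = group, split = split,
                   length_target = lens, stringsAsFactors = FALSE),
        traits, scores
      )
    }
  }
  structure(
    list(lexicon = lex, participants = do.call(rbind, parts),
         transcripts = txts, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$participants$split, x$participants$group)
  cat("<synthetic_cohort>\n")
  print(tab)
  invisible(x)
}

#' Feature table computed from a cohort's gold tags
#'
#' Bypasses tokenization and tagging: the generator's gold tags feed the
#' feature operations directly, isolating feature behavior from tagger
#' behavior (useful for calibration and power studies).
#'
#' @param cohort a [generate_cohort()] result.
#' @param split restrict to `"main"`, `"holdout"`, or `"all"`.
#' @param ... feature options passed to [extract_features()].
#' @return per-participant feature `data.frame` including `split`, `moca`,
#'   `ifs`.
#' @export
gold_features <- function(cohort, split = "all", ...) {
  keep <- if (split == "all") rep(TRUE, nrow(cohort$participants))
          else cohort$participants$split == split
  parts <- cohort$participants[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(parts)), function(i) {
    id <- parts$participant_id[i]
    extract_features(
      list(participant_id = id, group = parts$group[i]),
      properties = cohort$lexicon$properties,
      embeddings = cohort$lexicon$embeddings,
      tagged = cohort$transcripts[[id]]$gold, ...
    )
  })
  out <- do.call(rbind, rows)
  out$split <- parts$split
  out$moca <- parts$moca
  out$ifs <- parts$ifs
  rownames(out) <- NULL
  out
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Emits per-participant UTF-8 transcript files, `manifest_main.json` and
#' `manifest_holdout.json`, the tag lexicon and suffix rules as TSV, the
#' property lexicon TSV, the embedding TSV, and a `truth.json` record of
#' planted parameters.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "transcripts"), recursive = TRUE,
             showWarnings = FALSE)
  parts <- cohort$participants
  for (i in seq_len(nrow(parts))) {
    id <- parts$participant_id[i]
    writeLines(cohort$transcripts[[id]]$text,
               file.path(dir, "transcripts", paste0(id, ".txt")),
               useBytes = TRUE)
  }
  for (split in unique(parts$split)) {
    sub <- parts[parts$split == split, , drop = FALSE]
    man <- list(
      split = split,
      entries = data.frame(
        id = sub$participant_id, group = sub$group,
        file = file.path("transcripts", paste0(sub$participant_id, ".txt")),
        moca = sub$moca, ifs = sub$ifs, stringsAsFactors = FALSE
      )
    )
    jsonlite::write_json(man, file.path(dir,
                                        paste0("manifest_", split, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  write_tag_lexicon(cohort$lexicon$tags,
                    file.path(dir, "tag_lexicon.tsv"),
                    file.path(dir, "suffix_rules.tsv"))
  utils::write.table(cohort$lexicon$properties,
                     file.path(dir, "properties.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  emb <- cohort$lexicon$embeddings
  emb_df <- data.frame(surface = rownames(emb),
                       unclass(emb)[, , drop = FALSE],
                       stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(emb_df, file.path(dir, "embeddings.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(
    list(config = cohort$config[c("baseline", "offsets", "trait_sd",
                                  "target_d", "seed")],
         participants = parts),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE
  )
  invisible(dir)
}

measure_planted_d <- function(config, param, offset, feature, n_sim, seed,
                              group = "AD") {
  cfg <- config
  key <- switch(param,
                p_nounslot = "logit_p_nounslot",
                p_first = "logit_p_first",
                temp = "temp")
  # calibrate on top of the group's other (already fixed) offsets
  cfg$offsets$AD <- config$offsets[[group]]
  cfg$offsets$AD[key] <- offset
  cfg$length_mean[["AD"]] <- config$length_mean[[group]]
  n_arm <- max(2L, ceiling(n_sim / 2))
  set.seed(seed)
  lex <- do.call(make_lexicon, c(cfg$lexicon_spec, list(seed = seed)))
  val <- function(group) {
    traits <- draw_traits(cfg, group, n_arm)
    lens <- draw_lengths(cfg, group, n_arm)
    vapply(seq_len(n_arm), function(i) {
      tr <- generate_transcript(
        list(p_first = traits$p_first[i], p_nounslot = traits$p_nounslot[i],
             temp = traits$temp[i]), lex, length_target = lens[i])
      g <- tr$gold
      switch(feature,
             noun_ratio = word_class_ratios(g)[["noun_ratio"]],
             first_person_ratio =
               person_ratios(g)[["first_person_ratio"]],
             mean_log_freq = {
               content <- g[g$pos %in% CONTENT_POS, ]
               mean(lex$properties$log_freq[
                 match(content$surface, lex$properties$surface)],
                 na.rm = TRUE)
             })
    }, numeric(1))
  }
  x_hc <- val("HC")
  x_pt <- val("AD")
  sp <- sqrt((stats::var(x_hc) + stats::var(x_pt)) / 2)
  (mean(x_hc) - mean(x_pt)) / sp
}

#' Calibrate a generator parameter against a target effect size
#'
#' Bisection on a group-parameter offset (logit scale for probabilities,
#' additive for the frequency temperature) until the Monte-Carlo estimated
#' Cohen's d of the mapped feature — noun ratio for `p_nounslot`,
#' first-person ratio for `p_first`, mean log frequency for `temp` —
#' between an offset group and the HC baseline matches `target_d` within
#' `tol`. Common random numbers (the same seed for every evaluation) make
#' the d-versus-offset response smooth, so bisection is reliable.
#'
#' @param param one of `"p_nounslot"`, `"p_first"`, `"temp"`.
#' @param target_d target |Cohen's d| (patient deficit for probabilities,
#'   patient excess for `temp`).
#' @param config base [cohort_config()] (its baseline and trait SDs are the
#'   conditions under which the offset is calibrated).
#' @param n_sim transcripts per Monte-Carlo evaluation (split across arms).
#' @param tol tolerance on |realized - target|.
#' @param seed seed for the common-random-number evaluations.
#' @param max_offset search bound on the offset magnitude.
#' @param group patient group whose transcript-length distribution the
#'   offset arm uses.
#' @return the signed offset; attribute `realized_d` gives the achieved d.
#' @export
calibrate_effect <- function(param = c("p_nounslot", "p_first", "temp"),
                             target_d, config = cohort_config(),
                             n_sim = 2000L, tol = 0.05, seed = 1L,
                             max_offset = 3, group = "AD") {
  param <- match.arg(param)
  feature <- switch(param, p_nounslot = "noun_ratio",
                    p_first = "first_person_ratio", temp = "mean_log_freq")
  sign_ <- if (param == "temp") 1 else -1
  f <- function(mag) {
    measure_planted_d(config, param, sign_ * mag, feature, n_sim, seed,
                      group = group)
  }
  lo <- 0; hi <- max_offset
  d_hi <- f(hi)
  if (abs(d_hi) < target_d) {
    stop("target effect size not reachable within parameter bounds ",
         sprintf("(d at bound = %.2f)", d_hi), call. = FALSE)
  }
  for (iter in 1:40) {
    mid <- (lo + hi) / 2
    d_mid <- f(mid)
    if (abs(abs(d_mid) - target_d) < tol) {
      out <- sign_ * mid
      attr(out, "realized_d") <- d_mid
      return(out)
    }
    if (abs(d_mid) < target_d) lo <- mid else hi <- mid
  }
  out <- sign_ * (lo + hi) / 2
  attr(out, "realized_d") <- f((lo + hi) / 2)
  out
}
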