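# Small Spanish demo lexicon for the worked examples: the generator's
# function words plus the content words of the routine-description
# sentences used throughout the docs.
demo_tag_lexicon <- function() {
  extra <- data.frame(
    surface = c("señora", "hijo", "llaves", "puertas", "hospital", "casa",
                "levanta", "voy", "llega", "deja", "dice", "quiero",
                "camino", "caminas", "camina", "caminaba", "caminé",
                "caminaré", "llegaba", "salgo",
                "abiertas"),
    pos = c(rep("NOUN", 6),
            rep("VERB", 14),
            "ADJ"),
    person = c(rep("none", 6),
               "third", "first", "third", "third", "third", "first",
               "first", "second", "third", "ambiguous", "first",
               "first", "ambiguous", "first",
               "none"),
    stringsAsFactors = FALSE
  )
  tag_lexicon(rbind(spanish_function_words(), extra))
}

demo_properties <- function() {
  lex <- demo_tag_lexicon()$entries
  data.frame(
    surface = lex$surface,
    log_freq = 1.5,
    phon_neighbors = 5L,
    length_phonemes = nchar(lex$surface),
    stringsAsFactors = FALSE
  )
}

# gold tags for "La señora se levanta primero, después voy yo."
gold_sentence_one <- function() {
  data.frame(
    surface = c("La", "señora", "se", "levanta", "primero", "después",
                "voy", "yo"),
    pos = c("DET", "NOUN", "PRON", "VERB", "ADV", "ADV", "VERB", "PRON"),
    person = c("none", "none", "third", "third", "none", "none",
               "first", "first"),
    sentence = 1L,
    stringsAsFactors = FALSE
  )
}

# gold tags for "Mi hijo llega y entonces me deja las llaves y dice que
# si quiero me deja las puertas abiertas."
gold_sentence_two <- function() {
  data.frame(
    surface = c("Mi", "hijo", "llega", "y", "entonces", "me", "deja",
                "las", "llaves", "y", "dice", "que", "si", "quiero",
                "me", "deja", "las", "puertas", "abiertas"),
    pos = c("DET", "NOUN", "VERB", "CONJ", "ADV", "PRON", "VERB",
            "DET", "NOUN", "CONJ", "VERB", "CONJ", "CONJ", "VERB",
            "PRON", "VERB", "DET", "NOUN", "ADJ"),
    person = c("first", "none", "third", "none", "none", "first", "third",
               "none", "none", "none", "third", "none", "none", "first",
               "first", "third", "none", "none", "none"),
    sentence = 1L,
    stringsAsFactors = FALSE
  )
}

# long-format table for the 2x2 mixed design from a wide feature table
make_long <- function(sub, cols) {
  data.frame(
    participant_id = rep(sub$participant_id, times = 2L),
    group = rep(ifelse(sub$group == "HC", "HC", "patient"), times = 2L),
    within = rep(names(cols), each = nrow(sub)),
    value = c(sub[[cols[[1L]]]], sub[[cols[[2L]]]]),
    stringsAsFactors = FALSE
  )
}

# a small, fast cohort configuration for smoke tests
tiny_config <- function(seed = 1L) {
  cohort_config(
    n_main = c(AD = 5L, bvFTD = 5L, HC = 5L),
    n_holdout = c(AD = 3L, bvFTD = 3L, HC = 3L),
    length_mean = c(AD = 120, bvFTD = 120, HC = 140),
    length_sd = 20, length_min = 80,
    lexicon_spec = list(n_words = 120L, embed_dim = 16L, zipf_slope = 1.0),
    seed = seed
  )
}
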