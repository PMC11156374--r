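POS_LEVELS <- c("NOUN", "VERB", "ADJ", "ADV", "PRON", "DET", "ADP",
                "CONJ", "INTJ", "NUM", "OTHER")
PERSON_LEVELS <- c("first", "second", "third", "none", "ambiguous")

#' Construct a tagging lexicon
#'
#' A tag lexicon maps surface forms (case-insensitively) to a word class and
#' a grammatical-person attribute, plus an ordered list of verb-ending
#' suffix rules used as a fallback for out-of-lexicon forms. Person may be
#' `"ambiguous"` for endings shared by first and third person (e.g. the
#' imperfect `-aba`); ambiguity is resolved from sentence context by
#' [resolve_person_ambiguity()].
#'
#' @param entries `data.frame` with columns `surface`, `pos`, `person`.
#' @param rules `data.frame` with columns `suffix`, `person`; matched
#'   longest-suffix-first against unknown words and interpreted as verb
#'   inflections.
#' @return an object of class `tag_lexicon`.
#' @export
tag_lexicon <- function(entries, rules = default_suffix_rules()) {
  stopifnot(all(c("surface", "pos", "person") %in% names(entries)))
  stopifnot(all(entries$pos %in% POS_LEVELS),
            all(entries$person %in% PERSON_LEVELS))
  entries$surface <- tolower(entries$surface)
  entries <- entries[!duplicated(entries$surface), , drop = FALSE]
  if (!is.null(rules)) {
    stopifnot(all(c("suffix", "person") %in% names(rules)))
    rules <- rules[order(-nchar(rules$suffix)), , drop = FALSE]
  }
  structure(list(entries = entries, rules = rules), class = "tag_lexicon")
}

#' Default Spanish verb-ending person rules
#'
#' Present-tense `-o` marks first person exclusively, `-as`/`-es` second,
#' `-a`/`-e` third; the simple past `-é` and future `-aré` mark first; the
#' imperfect `-aba`/`-ía` is ambiguous between first and third person.
#'
#' @return a `data.frame` of `(suffix, person)` rules.
#' @export
default_suffix_rules <- function() {
  data.frame(
    suffix = c("aba", "ía", "aré", "as", "es", "é", "o", "a", "e"),
    person = c("ambiguous", "ambiguous", "first", "second", "second",
               "first", "first", "third", "third"),
    stringsAsFactors = FALSE
  )
}

#' Read a tag lexicon from TSV files
#'
#' @param entries_path TSV with columns `surface`, `pos`, `person`.
#' @param rules_path optional TSV with columns `suffix`, `person`; when
#'   `NULL` the bundled default Spanish rules are used.
#' @return a `tag_lexicon`.
#' @export
read_tag_lexicon <- function(entries_path, rules_path = NULL) {
  entries <- utils::read.delim(entries_path, stringsAsFactors = FALSE,
                               fileEncoding = "UTF-8")
  rules <- if (is.null(rules_path)) {
    default_suffix_rules()
  } else {
    utils::read.delim(rules_path, stringsAsFactors = FALSE,
                      fileEncoding = "UTF-8")
  }
  tag_lexicon(entries, rules)
}

#' Write a tag lexicon to TSV files
#'
#' @param lexicon a `tag_lexicon`.
#' @param entries_path,rules_path output TSV paths.
#' @export
write_tag_lexicon <- function(lexicon, entries_path, rules_path = NULL) {
  utils::write.table(lexicon$entries, entries_path, sep = "\t",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  if (!is.null(rules_path)) {
    utils::write.table(lexicon$rules, rules_path, sep = "\t",
                       row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(lexicon)
}

#' Assign word-class and person tags to a cleaned word stream
#'
#' The bundled reference tagger is deterministic: each word is looked up in
#' the lexicon (case-insensitive); unknown words fall through to the verb
#' suffix rules, and words matching no rule are tagged `OTHER`/`none` and
#' counted against coverage. The tagger backend contract is simply "stream
#' of surfaces in, one tagged token per input token out, order preserved",
#' so any external part-of-speech/morphological tagger can be plugged in by
#' producing the same data frame.
#'
#' @param tokens cleaned word-token `data.frame` (from [clean_word_stream()])
#'   or a character vector of surfaces.
#' @param lexicon a [tag_lexicon()].
#' @param resolve resolve person-ambiguous verbs from context (default TRUE).
#' @param coverage_warn emit a warning when lexicon+rule coverage falls below
#'   this fraction.
#' @return a `data.frame` with columns `surface`, `pos`, `person` (and
#'   `sentence` when available); attribute `coverage` gives the fraction of
#'   tokens tagged from the lexicon or a suffix rule.
#' @export
tag_stream <- function(tokens, lexicon, resolve = TRUE, coverage_warn = 0.8) {
  if (is.character(tokens)) {
    tokens <- data.frame(surface = tokens, sentence = 1L,
                         stringsAsFactors = FALSE)
  }
  stopifnot(inherits(lexicon, "tag_lexicon"))
  n <- nrow(tokens)
  if (n == 0L) stop("empty word stream", call. = FALSE)
  key <- tolower(tokens$surface)
  hit <- match(key, lexicon$entries$surface)
  pos <- ifelse(is.na(hit), NA_character_, lexicon$entries$pos[hit])
  person <- ifelse(is.na(hit), NA_character_, lexicon$entries$person[hit])

  known <- !is.na(hit)
  if (any(!known) && !is.null(lexicon$rules) && nrow(lexicon$rules)) {
    for (i in which(!known)) {
      w <- key[i]
      for (r in seq_len(nrow(lexicon$rules))) {
        suf <- lexicon$rules$suffix[r]
        if (nchar(w) > nchar(suf) + 1L && endsWith(w, suf)) {
          pos[i] <- "VERB"
          person[i] <- lexicon$rules$person[r]
          known[i] <- TRUE
          break
        }
      }
    }
  }
  pos[is.na(pos)] <- "OTHER"
  person[is.na(person)] <- "none"
  out <- data.frame(
    surface = tokens$surface, pos = pos, person = person,
    sentence = if ("sentence" %in% names(tokens)) tokens$sentence else 1L,
    stringsAsFactors = FALSE
  )
  coverage <- mean(known)
  if (coverage < coverage_warn) {
    warning(sprintf("tagger coverage %.1f%% below %.0f%%", 100 * coverage,
                    100 * coverage_warn), call. = FALSE)
  }
  if (resolve) out <- resolve_person_ambiguity(out)
  attr(out, "coverage") <- coverage
  out
}

#' Resolve person-ambiguous verb inflections from context
#'
#' Endings such as the Spanish imperfect `-aba` mark both first and third
#' person; each ambiguous verb is resolved, in order of preference, to the
#' person of (i) the nearest preceding first/third-person subject pronoun in
#' the same sentence, (ii) the nearest preceding person-marked verb in the
#' same sentence, (iii) the nearest person marker in the previous sentence,
#' and otherwise (iv) defaults to third person, the unmarked narrative
#' baseline. Unambiguous tags are never altered.
#'
#' @param tagged a tagged token `data.frame` (columns `surface`, `pos`,
#'   `person`, optionally `sentence`).
#' @return the same data frame with no `"ambiguous"` person values left.
#' @export
resolve_person_ambiguity <- function(tagged) {
  amb <- which(tagged$person == "ambiguous")
  if (!length(amb)) return(tagged)
  sent <- if ("sentence" %in% names(tagged)) tagged$sentence else
    rep(1L, nrow(tagged))
  person <- tagged$person
  for (i in amb) {
    prev <- seq_len(i - 1L)
    marked <- person[prev] %in% c("first", "third")
    same <- sent[prev] == sent[i]
    cand <- prev[marked & same & tagged$pos[prev] == "PRON"]
    if (!length(cand)) cand <- prev[marked & same & tagged$pos[prev] == "VERB"]
    if (!length(cand)) cand <- prev[marked & sent[prev] == sent[i] - 1L]
    person[i] <- if (length(cand)) person[max(cand)] else "third"
  }
  tagged$person <- person
  tagged
}

#' Agreement between predicted and gold tag sequences
#'
#' Overall accuracy is the fraction of positions whose `(pos, person)` pair
#' matches exactly; per-class confusion counts are returned for inspection,
#' mirroring a manual quality check of automated tags.
#'
#' @param predicted,gold aligned tagged token data frames of equal length.
#' @return a list with `accuracy`, `n`, and `confusion` (a table of
#'   gold vs. predicted `pos:person` pairs for mismatching positions).
#' @export
tag_agreement <- function(predicted, gold) {
  if (nrow(predicted) != nrow(gold)) {
    stop("alignment error: predicted and gold have different lengths",
         call. = FALSE)
  }
  ok <- predicted$pos == gold$pos & predicted$person == gold$person
  mism <- which(!ok)
  confusion <- table(
    gold = paste(gold$pos[mism], gold$person[mism], sep = ":"),
    predicted = paste(predicted$pos[mism], predicted$person[mism], sep = ":")
  )
  list(accuracy = mean(ok), n = length(ok), confusion = confusion)
}
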