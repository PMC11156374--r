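#' Tokenize a connected-speech transcript
#'
#' Splits a verbatim transcript into an ordered token stream, separating
#' punctuation from words and classifying disfluencies so they can be
#' excluded before feature extraction. Four non-word kinds are recognized:
#' `punctuation`, `filler` (filled pauses / hesitations from a closed,
#' configurable list), `fragment` (interrupted words, marked by a trailing
#' fragment marker, e.g. "hospi…"), and `unintelligible` (a configurable
#' inline marker, default `"[inaudible]"`). Everything else containing a
#' letter or digit is a `word`; digit-written numerals count as words since
#' transcription keeps dates and numbers in the text.
#'
#' Sentence ids increase at every `.`, `!` or `?` punctuation token; they
#' delimit the agreement scope used when resolving grammatical-person
#' ambiguity downstream.
#'
#' @param text a length-1 UTF-8 character string.
#' @param fillers closed list of filler surfaces (matched case-insensitively).
#' @param fragment_marker suffix marking an interrupted word.
#' @param unintelligible_marker inline marker for unintelligible spans.
#' @return a `data.frame` with columns `surface`, `index` (0-based position),
#'   `kind`, and `sentence` (1-based sentence id).
#' @examples
#' tok <- tokenize("La sé, digo. Eh, voy yo.")
#' table(tok$kind)
#' @export
tokenize <- function(text,
                     fillers = c("eh", "em", "mmm", "este"),
                     fragment_marker = "…",
                     unintelligible_marker = "[inaudible]") {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) {
    stop("empty transcript: no analyzable text", call. = FALSE)
  }
  sentinel <- "UNINT"
  text <- gsub(unintelligible_marker, sentinel, text, fixed = TRUE)
  chunks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  chunks <- chunks[nzchar(chunks)]

  surfaces <- character(0)
  kinds <- character(0)
  is_letterdigit <- function(x) grepl("[[:alpha:][:digit:]]", x)
  punct_chars <- c(".", ",", ";", ":", "!", "?", "(", ")", "[", "]",
                   "\"", "'", "¡", "¿", "—", "-")

  for (ch in chunks) {
    frag <- FALSE
    # trailing fragment marker: consume it, flag the word part
    if (endsWith(ch, fragment_marker)) {
      ch <- substr(ch, 1L, nchar(ch) - nchar(fragment_marker))
      frag <- TRUE
    }
    # peel leading punctuation
    lead <- character(0)
    while (nchar(ch) > 0L && substr(ch, 1L, 1L) %in% punct_chars) {
      lead <- c(lead, substr(ch, 1L, 1L))
      ch <- substr(ch, 2L, nchar(ch))
    }
    trail <- character(0)
    while (nchar(ch) > 0L && substr(ch, nchar(ch), nchar(ch)) %in% punct_chars) {
      trail <- c(substr(ch, nchar(ch), nchar(ch)), trail)
      ch <- substr(ch, 1L, nchar(ch) - 1L)
    }
    surfaces <- c(surfaces, lead)
    kinds <- c(kinds, rep("punctuation", length(lead)))
    if (nchar(ch) > 0L) {
      if (ch == sentinel) {
        kind <- "unintelligible"
        ch <- unintelligible_marker
      } else if (frag) {
        kind <- "fragment"
      } else if (tolower(ch) %in% tolower(fillers)) {
        kind <- "filler"
      } else if (is_letterdigit(ch)) {
        kind <- "word"
      } else {
        kind <- "punctuation"
      }
      surfaces <- c(surfaces, ch)
      kinds <- c(kinds, kind)
    }
    surfaces <- c(surfaces, trail)
    kinds <- c(kinds, rep("punctuation", length(trail)))
  }
  if (length(surfaces) == 0L) {
    stop("empty transcript: no analyzable text", call. = FALSE)
  }
  terminal <- kinds == "punctuation" & surfaces %in% c(".", "!", "?")
  sentence <- cumsum(c(1L, utils::head(terminal, -1L)))
  data.frame(
    surface = surfaces,
    index = seq_along(surfaces) - 1L,
    kind = kinds,
    sentence = as.integer(sentence),
    stringsAsFactors = FALSE
  )
}

#' Reduce a token stream to analyzable words
#'
#' Drops punctuation, fillers, fragments and unintelligible tokens, keeping
#' only `kind == "word"` tokens in their original order. The number of
#' removed tokens per kind is attached as attribute `"removed"` — the word
#' count of the returned stream is the single source of truth for the
#' word-class ratio denominator.
#'
#' @param x a token `data.frame` from [tokenize()], or a transcript object
#'   with a `$tokens` element.
#' @return the word-only token `data.frame`; attribute `removed` holds the
#'   per-kind counts of dropped tokens.
#' @export
clean_word_stream <- function(x) {
  tokens <- if (is.data.frame(x)) x else x$tokens
  stopifnot(is.data.frame(tokens), all(c("surface", "kind") %in% names(tokens)))
  keep <- tokens$kind == "word"
  removed <- table(factor(
    tokens$kind[!keep],
    levels = c("punctuation", "filler", "fragment", "unintelligible")
  ))
  out <- tokens[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    stop("empty analyzable transcript: no word tokens survive cleaning",
         call. = FALSE)
  }
  attr(out, "removed") <- c(removed)
  out
}

GROUP_LEVELS <- c("AD", "bvFTD", "HC")

#' Build a transcript object
#'
#' @param participant_id opaque participant identifier.
#' @param group one of `"AD"`, `"bvFTD"`, `"HC"`.
#' @param text raw transcript text (tokenized on construction), or `NULL`
#'   when `tokens` is supplied directly.
#' @param tokens pre-built token data frame (alternative to `text`).
#' @param scores optional named numeric vector of cognitive scores
#'   (e.g. `c(MoCA = 24, IFS = 21)`).
#' @param ... passed to [tokenize()].
#' @return an object of class `speech_transcript`.
#' @export
transcript <- function(participant_id, group, text = NULL, tokens = NULL,
                       scores = NULL, ...) {
  group <- match.arg(group, GROUP_LEVELS)
  if (is.null(tokens)) tokens <- tokenize(text, ...)
  structure(
    list(participant_id = as.character(participant_id), group = group,
         tokens = tokens, scores = scores),
    class = "speech_transcript"
  )
}

#' @export
print.speech_transcript <- function(x, ...) {
  cat(sprintf("<speech_transcript> %s [%s]: %d tokens (%d words)\n",
              x$participant_id, x$group, nrow(x$tokens),
              sum(x$tokens$kind == "word")))
  invisible(x)
}

#' Load a corpus from a JSON manifest
#'
#' The manifest is a JSON object with fields `split` (`"main"` or
#' `"holdout"`) and `entries`, an array of objects with `id`, `group`,
#' `file` (path to a UTF-8 plain-text transcript, relative to the manifest)
#' and optional `moca` / `ifs` scores. Each transcript is read and tokenized.
#'
#' @param manifest path to the manifest JSON file.
#' @param ... passed to [tokenize()].
#' @return a list of `speech_transcript` objects, class `speech_corpus`,
#'   with attributes `split` and `group_counts`.
#' @export
load_corpus <- function(manifest, ...) {
  man <- jsonlite::fromJSON(manifest, simplifyDataFrame = TRUE)
  entries <- man$entries
  if (is.null(entries) || nrow(entries) == 0L) {
    stop("manifest has no entries: ", manifest, call. = FALSE)
  }
  if (anyDuplicated(entries$id)) {
    stop("duplicate participant id(s) in manifest: ",
         paste(unique(entries$id[duplicated(entries$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(entries$group), GROUP_LEVELS)
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  root <- dirname(normalizePath(manifest))
  out <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    path <- entries$file[i]
    if (!file.exists(path)) path <- file.path(root, entries$file[i])
    if (!file.exists(path)) {
      stop("transcript file for entry '", entries$id[i], "' not readable: ",
           entries$file[i], call. = FALSE)
    }
    txt <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                 collapse = "\n")
    scores <- NULL
    sc <- c(
      MoCA = if ("moca" %in% names(entries)) entries$moca[i] else NA_real_,
      IFS  = if ("ifs" %in% names(entries)) entries$ifs[i] else NA_real_
    )
    if (any(!is.na(sc))) scores <- sc
    out[[i]] <- transcript(entries$id[i], entries$group[i], text = txt,
                           scores = scores, ...)
  }
  names(out) <- entries$id
  structure(out,
            class = "speech_corpus",
            split = if (!is.null(man$split)) man$split else "main",
            group_counts = table(factor(entries$group, GROUP_LEVELS)))
}

#' @export
print.speech_corpus <- function(x, ...) {
  gc_ <- attr(x, "group_counts")
  cat(sprintf("<speech_corpus> split=%s, %d transcripts (%s)\n",
              attr(x, "split"), length(x),
              paste(names(gc_), gc_, sep = "=", collapse = ", ")))
  invisible(x)
}
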