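CONTENT_POS <- c("NOUN", "VERB", "ADJ", "ADV")

#' Noun and verb ratios of a tagged stream
#'
#' Ratios are taken with respect to the total number of words in the
#' cleaned stream — stop words (determiners, adpositions, conjunctions,
#' interjections, numbers) are counted in the denominator; punctuation and
#' disfluencies were already removed upstream.
#'
#' @param tagged tagged token `data.frame` from [tag_stream()].
#' @return named numeric vector `c(noun_ratio, verb_ratio)`.
#' @export
word_class_ratios <- function(tagged) {
  n <- nrow(tagged)
  if (is.null(n) || n == 0L) stop("empty tagged stream", call. = FALSE)
  c(noun_ratio = sum(tagged$pos == "NOUN") / n,
    verb_ratio = sum(tagged$pos == "VERB") / n)
}

#' First- and third-person marker ratios
#'
#' Every person-carrying token counts individually: in a pronoun-verb tandem
#' like "yo salgo" both the pronoun and the inflected verb contribute a
#' first-person marker (no deduplication), reflecting how pro-drop languages
#' encode person both lexically and morphologically. Second-person markers
#' are discarded before the ratio is formed; with `include_second = TRUE`
#' they are instead retained in the denominator.
#'
#' @param tagged tagged token `data.frame`.
#' @param include_second keep second-person markers in the denominator
#'   (default `FALSE`, i.e. denominator = first + third counts).
#' @return named numeric vector `c(first_person_ratio, third_person_ratio)`;
#'   both `NA` (with a warning) when no first/third marker exists.
#' @export
person_ratios <- function(tagged, include_second = FALSE) {
  n1 <- sum(tagged$person == "first")
  n3 <- sum(tagged$person == "third")
  denom <- n1 + n3 + if (include_second) sum(tagged$person == "second") else 0L
  if (n1 + n3 == 0L) {
    warning("no first/third person markers; person ratios undefined",
            call. = FALSE)
    return(c(first_person_ratio = NA_real_, third_person_ratio = NA_real_))
  }
  c(first_person_ratio = n1 / denom, third_person_ratio = n3 / denom)
}

#' Read a psycholinguistic property lexicon from TSV
#'
#' @param path TSV with columns `surface`, `log_freq` (log10 frequency per
#'   million), `phon_neighbors` (phonological neighborhood size) and
#'   `length_phonemes`.
#' @return a `data.frame`, surfaces lower-cased and de-duplicated.
#' @export
read_property_lexicon <- function(path) {
  lex <- utils::read.delim(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  stopifnot(all(c("surface", "log_freq", "phon_neighbors",
                  "length_phonemes") %in% names(lex)))
  lex$surface <- tolower(lex$surface)
  lex[!duplicated(lex$surface), , drop = FALSE]
}

#' Mean psycholinguistic properties of content words
#'
#' Averages log frequency, phonological neighborhood and phoneme length over
#' content-word tokens (nouns, verbs, adjectives, adverbs), repetitions
#' included. Tokens absent from the lexicon are skipped and reported through
#' the `coverage` element (lexicon hits / content tokens).
#'
#' @param tagged tagged token `data.frame`.
#' @param lexicon property `data.frame` as from [read_property_lexicon()].
#' @param id participant label used in error messages.
#' @return named numeric vector `c(mean_log_freq, mean_phon_neighbors,
#'   mean_length, coverage)`.
#' @export
lexical_property_means <- function(tagged, lexicon, id = "participant") {
  content <- tagged[tagged$pos %in% CONTENT_POS, , drop = FALSE]
  if (nrow(content) == 0L) {
    stop("no content words for ", id, call. = FALSE)
  }
  hit <- match(tolower(content$surface), lexicon$surface)
  found <- !is.na(hit)
  if (!any(found)) {
    stop("zero lexicon hits for ", id, call. = FALSE)
  }
  rows <- lexicon[hit[found], , drop = FALSE]
  c(mean_log_freq = mean(rows$log_freq),
    mean_phon_neighbors = mean(rows$phon_neighbors),
    mean_length = mean(rows$length_phonemes),
    coverage = mean(found))
}

#' Read an embedding table from TSV
#'
#' @param path TSV whose first column is the surface form and remaining
#'   columns are the vector components (fixed dimension).
#' @return a numeric matrix with lower-cased surfaces as row names, class
#'   `embedding_table`.
#' @export
read_embeddings <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- tolower(tab[[1L]])
  class(mat) <- c("embedding_table", class(mat))
  mat
}

cosine_distance <- function(a, b) {
  1 - sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}

#' Semantic variability of a tagged stream
#'
#' The text is reduced to its content words in order of appearance,
#' repetitions are omitted (globally by default: only the first occurrence
#' of each surface form is kept), each remaining word is mapped to its
#' embedding vector, distances between adjacent vectors form a series, and
#' semantic variability is the variance of that series. A text whose
#' successive words jump inconsistently through semantic space scores high.
#'
#' @param tagged tagged token `data.frame`.
#' @param embeddings embedding matrix (rows named by surface) or any matrix
#'   coercible to one.
#' @param dedup `"global"` (default) keeps the first occurrence of each
#'   surface; `"adjacent"` only collapses immediate repetitions.
#' @param metric `"cosine"` (default) or `"euclidean"` adjacent distance.
#' @param variance `"sample"` (default, n-1 denominator over the distance
#'   series) or `"population"`.
#' @return a single number, or `NA` with a warning when fewer than 3
#'   distinct embeddable content words remain.
#' @export
semantic_variability <- function(tagged, embeddings,
                                 dedup = c("global", "adjacent"),
                                 metric = c("cosine", "euclidean"),
                                 variance = c("sample", "population")) {
  dedup <- match.arg(dedup)
  metric <- match.arg(metric)
  variance <- match.arg(variance)
  content <- tolower(tagged$surface[tagged$pos %in% CONTENT_POS])
  if (dedup == "global") {
    content <- content[!duplicated(content)]
  } else {
    keep <- c(TRUE, content[-1L] != content[-length(content)])
    content <- content[keep]
  }
  hit <- match(content, rownames(embeddings))
  vecs <- embeddings[hit[!is.na(hit)], , drop = FALSE]
  k <- nrow(vecs)
  if (k < 3L) {
    warning("fewer than 3 distinct embeddable content words; ",
            "semantic variability undefined", call. = FALSE)
    return(NA_real_)
  }
  d <- vapply(seq_len(k - 1L), function(i) {
    if (metric == "cosine") cosine_distance(vecs[i, ], vecs[i + 1L, ])
    else sqrt(sum((vecs[i, ] - vecs[i + 1L, ])^2))
  }, numeric(1))
  v <- stats::var(d)
  if (variance == "population") v <- v * (length(d) - 1) / length(d)
  v
}

#' Extract the full connected-speech feature vector of one transcript
#'
#' Composes cleaning, tagging and the four feature families into the
#' eight-value participant feature vector: noun/verb ratios,
#' first/third-person ratios, mean log frequency, mean phonological
#' neighborhood, mean phoneme length and semantic variability, plus word
#' count and coverage diagnostics.
#'
#' @param transcript a `speech_transcript` (or a list with `$participant_id`,
#'   `$group`, `$tokens`).
#' @param tag_lex a [tag_lexicon()]; alternatively pass pre-tagged tokens
#'   via `tagged`.
#' @param properties property lexicon `data.frame`.
#' @param embeddings embedding matrix.
#' @param tagged optional pre-tagged token data frame (e.g. gold tags),
#'   bypassing the tagger.
#' @param ... feature options forwarded to [semantic_variability()] and
#'   [person_ratios()] (`dedup`, `metric`, `variance`, `include_second`).
#' @return one-row `data.frame` of features and diagnostics.
#' @export
extract_features <- function(transcript, tag_lex = NULL, properties,
                             embeddings, tagged = NULL, ...) {
  dots <- list(...)
  sv_args <- dots[names(dots) %in% c("dedup", "metric", "variance")]
  pr_args <- dots[names(dots) %in% "include_second"]
  if (is.null(tagged)) {
    words <- clean_word_stream(transcript$tokens)
    tagged <- tag_stream(words, tag_lex)
  }
  wc <- word_class_ratios(tagged)
  pr <- do.call(person_ratios, c(list(tagged), pr_args))
  lp <- lexical_property_means(tagged, properties,
                               id = transcript$participant_id)
  sv <- do.call(semantic_variability,
                c(list(tagged, embeddings), sv_args))
  data.frame(
    participant_id = transcript$participant_id,
    group = transcript$group,
    word_count = nrow(tagged),
    noun_ratio = unname(wc["noun_ratio"]),
    verb_ratio = unname(wc["verb_ratio"]),
    first_person_ratio = unname(pr["first_person_ratio"]),
    third_person_ratio = unname(pr["third_person_ratio"]),
    mean_log_freq = unname(lp["mean_log_freq"]),
    mean_phon_neighbors = unname(lp["mean_phon_neighbors"]),
    mean_length = unname(lp["mean_length"]),
    semantic_variability = sv,
    lexicon_coverage = unname(lp["coverage"]),
    tagger_coverage = if (!is.null(attr(tagged, "coverage")))
      attr(tagged, "coverage") else NA_real_,
    stringsAsFactors = FALSE
  )
}

FEATURE_COLS <- c("noun_ratio", "verb_ratio", "first_person_ratio",
                  "third_person_ratio", "mean_log_freq",
                  "mean_phon_neighbors", "mean_length",
                  "semantic_variability")

#' Feature table for a whole corpus
#'
#' @param corpus a `speech_corpus` (list of transcripts).
#' @param ... passed to [extract_features()].
#' @return a `data.frame` with one row per participant.
#' @export
extract_corpus_features <- function(corpus, ...) {
  rows <- lapply(corpus, extract_features, ...)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
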