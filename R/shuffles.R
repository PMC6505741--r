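#' Level randomization surrogates
#'
#' Shuffle a document at one organizational level, destroying correlations
#' at and above that level while preserving the unit multiset exactly:
#' sentence shuffling keeps every sentence but randomizes their order;
#' word shuffling keeps every word; character shuffling keeps only the
#' character histogram; fixed-width unit shuffling (e.g. width 3 for DNA
#' codons) is the analogue for sequences whose units have a known width
#' rather than a delimiter.
#'
#' `shuffle_sentences` operates on canonical text (periods still mark
#' sentence ends): it splits on '.', drops empty sentences, permutes,
#' rejoins with periods, and then finalizes (periods to spaces), so its
#' output is commensurate with the final form of the original document.  A
#' trailing fragment without a final period counts as a sentence.
#'
#' @param canonical canonical text (see [filter_text()]).
#' @param final final 27-symbol text (see [finalize_text()]).
#' @param seed optional integer seed; `NULL` uses the caller's RNG stream.
#' @param collapse_spaces passed to [finalize_text()] when rejoining.
#' @param delimiter word delimiter, a single character (default space).
#'   Alternative delimiters define artificial word units.
#' @return A string (sentence/word/character shuffles) or a
#'   [symbol_seq()] (`shuffle_fixed_width_units`).
#' @examples
#' shuffle_sentences("ab. cd.", seed = 1)
#' shuffle_words("the cat sat", seed = 1)
#' @name level_shuffles
NULL

#' @rdname level_shuffles
#' @export
shuffle_sentences <- function(canonical, seed = NULL, collapse_spaces = TRUE) {
  stopifnot(is.character(canonical), length(canonical) == 1L)
  parts <- strsplit(canonical, ".", fixed = TRUE)[[1L]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) stop("no sentences found in canonical text")
  ord <- with_seed(seed, sample.int(length(parts)))
  rejoined <- paste0(paste(parts[ord], collapse = ". "), ".")
  finalize_text(rejoined, collapse_spaces = collapse_spaces)
}

#' @rdname level_shuffles
#' @export
shuffle_words <- function(final, seed = NULL, delimiter = " ") {
  stopifnot(is.character(final), length(final) == 1L,
            is.character(delimiter), nchar(delimiter) == 1L)
  words <- strsplit(final, delimiter, fixed = TRUE)[[1L]]
  words <- words[nzchar(words)]
  if (length(words) == 0L) stop("no words found in text")
  ord <- with_seed(seed, sample.int(length(words)))
  paste(words[ord], collapse = delimiter)
}

#' @rdname level_shuffles
#' @export
shuffle_characters <- function(final, seed = NULL) {
  stopifnot(is.character(final), length(final) == 1L)
  chars <- strsplit(final, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) stop("cannot shuffle an empty text")
  ord <- with_seed(seed, sample.int(length(chars)))
  paste(chars[ord], collapse = "")
}

#' @rdname level_shuffles
#' @param seq a [symbol_seq()] (or coercible).
#' @param width unit width in symbols (>= 1); width 1 is a character
#'   shuffle, width 3 a codon shuffle.
#' @export
shuffle_fixed_width_units <- function(seq, width, seed = NULL) {
  if (!is.numeric(width) || length(width) != 1L || width < 1)
    stop("width must be a single integer >= 1")
  block_shuffle(seq, block_length = width, seed = seed, remainder = "pool")
}

#' Build the full variant set of a document
#'
#' Produce, under one seed, the sentence-, word-, and character-shuffled
#' surrogates of a [text_document()] alongside its original final text.
#' Shuffles act on the full (untruncated) canonical text; each surrogate is
#' then finalized and truncated to the length of the original final text,
#' so all four variants are commensurate.
#'
#' @param doc a [text_document()].
#' @param seed integer run seed; per-level substreams are derived
#'   deterministically from it.
#' @param word_delimiter passed to [shuffle_words()].
#' @return An object of class `"level_variants"`: fields `doc_id`,
#'   `original`, `sentence`, `word`, `character` (final texts), `seed`.
#' @examples
#' d <- text_document("the cat sat. the dog ran. all was well.", "demo")
#' v <- level_variants(d, seed = 7)
#' @export
level_variants <- function(doc, seed = NULL, word_delimiter = " ") {
  stopifnot(inherits(doc, "text_document"))
  if (is.null(seed)) seed <- with_seed(NULL, sample.int(2147483646L, 1L))
  full_final <- finalize_text(doc$canonical,
                              collapse_spaces = doc$collapse_spaces)
  target <- nchar(doc$final)
  fit <- function(x) {
    if (is.null(doc$truncate_to)) return(x)
    if (nchar(x) < target)
      stop("surrogate shorter than the original final text; ",
           "this indicates inconsistent collapse settings")
    substr(x, 1L, target)
  }
  sent <- shuffle_sentences(doc$canonical, seed = substream_seed(seed, 1L, 1L),
                            collapse_spaces = doc$collapse_spaces)
  word <- shuffle_words(full_final, seed = substream_seed(seed, 2L, 1L),
                        delimiter = word_delimiter)
  chr <- shuffle_characters(full_final, seed = substream_seed(seed, 3L, 1L))
  structure(list(doc_id = doc$doc_id,
                 original = doc$final,
                 sentence = fit(sent),
                 word = fit(word),
                 character = fit(chr),
                 seed = seed),
            class = "level_variants")
}

#' @export
print.level_variants <- function(x, ...) {
  cat("Level variants for", sQuote(x$doc_id), " (seed", x$seed, ")\n",
      " lengths:", nchar(x$original), "/", nchar(x$sentence), "/",
      nchar(x$word), "/", nchar(x$character),
      "(original / sentence / word / character)\n")
  invisible(x)
}
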