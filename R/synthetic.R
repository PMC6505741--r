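#' Seeded synthetic sequence generators
#'
#' Sources with known information-theoretic properties, used to validate
#' the estimators and to demonstrate the level decomposition: i.i.d.
#' draws (entropy rate \eqn{-\sum p \log_2 p}, zero excess entropy),
#' periodic repetition (zero entropy rate, positive excess entropy), and
#' first-order Markov chains (closed-form entropy rate).
#'
#' @name synthetic_sources
NULL

#' @rdname synthetic_sources
#' @param alphabet an [alphabet()] or character vector of symbols.
#' @param probabilities symbol probabilities (default uniform); must sum
#'   to 1.
#' @param n sequence length.
#' @param seed integer seed; `NULL` uses the caller's RNG stream.
#' @return A [symbol_seq()].
#' @examples
#' generate_iid(c("0", "1"), n = 100, seed = 1)
#' @export
generate_iid <- function(alphabet, probabilities = NULL, n, seed = NULL) {
  if (!inherits(alphabet, "lz_alphabet")) alphabet <- alphabet(alphabet)
  k <- attr(alphabet, "size")
  if (is.null(probabilities)) probabilities <- rep(1 / k, k)
  if (length(probabilities) != k || any(probabilities < 0) ||
      abs(sum(probabilities) - 1) > 1e-9)
    stop("probabilities must be a length-", k, " distribution summing to 1")
  stopifnot(n >= 0)
  codes <- with_seed(seed,
    sample.int(k, size = n, replace = TRUE, prob = probabilities))
  symbol_seq(codes, alphabet = alphabet)
}

#' @rdname synthetic_sources
#' @param motif a nonempty string (or symbol vector) to repeat.
#' @export
generate_periodic <- function(motif, n) {
  seq <- symbol_seq(motif)
  if (length(seq) == 0L) stop("motif must be nonempty")
  stopifnot(n >= 0)
  codes <- rep_len(seq$codes, n)
  symbol_seq(codes, alphabet = seq$alphabet)
}

#' First-order Markov sources
#'
#' Define a stationary Markov source from a row-stochastic transition
#' matrix.  The stationary distribution is obtained as the normalized
#' left null vector of \eqn{P - I}, and the analytic entropy rate is
#' \deqn{h = -\sum_i \pi_i \sum_j P_{ij} \log_2 P_{ij}}
#' in bits per symbol.
#'
#' @param transition square row-stochastic matrix of next-symbol
#'   probabilities.
#' @param alphabet symbols (defaults to matrix dimnames, else letters).
#' @return An object of class `"markov_source"` with fields `alphabet`,
#'   `transition`, `stationary`, `analytic_h`.
#' @examples
#' src <- markov_source(matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
#' src$analytic_h  # 0.4690 bits/symbol
#' @export
markov_source <- function(transition, alphabet = NULL) {
  transition <- as.matrix(transition)
  k <- nrow(transition)
  if (ncol(transition) != k || k < 1L)
    stop("transition must be a square matrix")
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-12))
    stop("transition rows must be nonnegative and sum to 1")
  if (is.null(alphabet)) {
    syms <- rownames(transition) %||% as.character(seq_len(k))
    alphabet <- alphabet(syms)
  } else if (!inherits(alphabet, "lz_alphabet")) {
    alphabet <- alphabet(alphabet)
  }
  if (attr(alphabet, "size") != k)
    stop("alphabet size must match the transition matrix dimension")
  # stationary distribution: solve t(P - I) pi = 0 with sum(pi) = 1
  a <- rbind(t(transition) - diag(k), rep(1, k))
  b <- c(rep(0, k), 1)
  pi_ <- as.vector(qr.solve(a, b))
  pi_ <- pmax(pi_, 0)
  pi_ <- pi_ / sum(pi_)
  rowent <- apply(transition, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  structure(list(alphabet = alphabet, transition = transition,
                 stationary = pi_,
                 analytic_h = sum(pi_ * rowent)),
            class = "markov_source")
}

#' @export
print.markov_source <- function(x, ...) {
  cat("Markov source over", attr(x$alphabet, "size"), "symbols;",
      sprintf("analytic h = %.4f bits/symbol\n", x$analytic_h))
  invisible(x)
}

#' @rdname synthetic_sources
#' @param source a [markov_source()].
#' @export
generate_markov <- function(source, n, seed = NULL) {
  stopifnot(inherits(source, "markov_source"), n >= 1)
  k <- attr(source$alphabet, "size")
  codes <- with_seed(seed, {
    out <- integer(n)
    out[1L] <- sample.int(k, 1L, prob = source$stationary)
    if (n > 1L) {
      # presample uniforms; walk the chain with cumulative rows
      cum <- t(apply(source$transition, 1L, cumsum))
      u <- stats::runif(n - 1L)
      for (i in 2L:n) {
        out[i] <- findInterval(u[i - 1L], cum[out[i - 1L], ]) + 1L
      }
    }
    out
  })
  symbol_seq(codes, alphabet = source$alphabet)
}

#' Recipes for synthetic hierarchical corpora
#'
#' A corpus recipe fixes the statistical structure of a generated text at
#' three levels, so that each level shuffle has signal to destroy:
#' \itemize{
#'   \item character level: words are fixed spellings over a nonuniform
#'     letter distribution, so character shuffling destroys word-internal
#'     structure;
#'   \item word level: word tokens are drawn from a Zipf-like rank
#'     distribution and sentences are often reused from a template pool,
#'     so word shuffling destroys recurring word sequences;
#'   \item sentence level: the template choice follows a sticky Markov
#'     process (the same template tends to repeat in runs), so sentence
#'     shuffling destroys adjacency correlations between sentences.
#' }
#'
#' @param vocabulary_size number of distinct words available.
#' @param zipf_exponent exponent of the rank-frequency law for word
#'   choice.
#' @param word_length_range inclusive range of word lengths (letters).
#' @param sentence_length_range inclusive range of sentence lengths
#'   (words).
#' @param n_templates size of the sentence-template pool.
#' @param template_reuse probability that a sentence is drawn from the
#'   template pool rather than composed freshly.
#' @param template_stickiness probability that a template sentence
#'   repeats the previous template rather than drawing a new one.
#' @param letter_floor minimum relative weight of any letter in word
#'   spellings (guarantees rare letters appear in long corpora).
#' @param decorate add raw-text noise exercised by the filter: sentence
#'   capitalization, commas, digits, occasional diacritics, and '?'/'!'
#'   endings.
#' @return An object of class `"corpus_recipe"`.
#' @seealso [generate_corpus()]
#' @export
corpus_recipe <- function(vocabulary_size = 2000L,
                          zipf_exponent = 1.0,
                          word_length_range = c(2L, 9L),
                          sentence_length_range = c(5L, 25L),
                          n_templates = 50L,
                          template_reuse = 0.6,
                          template_stickiness = 0.6,
                          letter_floor = 0.005,
                          decorate = TRUE) {
  stopifnot(vocabulary_size >= 2L, zipf_exponent >= 0,
            length(word_length_range) == 2L,
            word_length_range[1L] >= 1L,
            diff(word_length_range) >= 0,
            length(sentence_length_range) == 2L,
            sentence_length_range[1L] >= 1L,
            diff(sentence_length_range) >= 0,
            n_templates >= 1L,
            template_reuse >= 0, template_reuse <= 1,
            template_stickiness >= 0, template_stickiness <= 1,
            letter_floor > 0, letter_floor <= 1 / 26)
  structure(list(vocabulary_size = as.integer(vocabulary_size),
                 zipf_exponent = zipf_exponent,
                 word_length_range = as.integer(word_length_range),
                 sentence_length_range = as.integer(sentence_length_range),
                 n_templates = as.integer(n_templates),
                 template_reuse = template_reuse,
                 template_stickiness = template_stickiness,
                 letter_floor = letter_floor,
                 decorate = decorate),
            class = "corpus_recipe")
}

#' @export
print.corpus_recipe <- function(x, ...) {
  cat("Corpus recipe: V =", x$vocabulary_size,
      " zipf =", x$zipf_exponent,
      " templates =", x$n_templates,
      sprintf(" reuse = %.2f, stickiness = %.2f\n",
              x$template_reuse, x$template_stickiness))
  invisible(x)
}

# letter weights: English-like ordering with a hard floor
letter_weights <- function(floor_w) {
  freq <- c(a = 8.2, b = 1.5, c = 2.8, d = 4.3, e = 12.7, f = 2.2, g = 2.0,
            h = 6.1, i = 7.0, j = 0.15, k = 0.77, l = 4.0, m = 2.4,
            n = 6.7, o = 7.5, p = 1.9, q = 0.1, r = 6.0, s = 6.3,
            t = 9.1, u = 2.8, v = 0.98, w = 2.4, x = 0.15, y = 2.0,
            z = 0.074)
  w <- freq / sum(freq)
  w <- pmax(w, floor_w)
  w / sum(w)
}

#' Generate a synthetic hierarchical document
#'
#' Sample a document from a [corpus_recipe()]: a vocabulary of fixed
#' spellings, Zipf-weighted word use, a reusable sentence-template pool
#' with sticky repetition, and optional raw-text decoration (uppercase,
#' digits, diacritics, punctuation).  The raw text is filtered through the
#' canonical pipeline and the final text is truncated to exactly
#' `target_length` characters.
#'
#' @param recipe a [corpus_recipe()].
#' @param target_length length of the final text (default 78000).
#' @param seed integer seed.
#' @param doc_id document label.
#' @return A [text_document()] whose `final` text has exactly
#'   `target_length` characters.
#' @examples
#' doc <- generate_corpus(corpus_recipe(vocabulary_size = 100),
#'                        target_length = 2000, seed = 1)
#' @export
generate_corpus <- function(recipe = corpus_recipe(), target_length = 78000L,
                            seed = NULL, doc_id = "synthetic") {
  stopifnot(inherits(recipe, "corpus_recipe"), target_length >= 1)
  with_seed(seed, {
    lw <- letter_weights(recipe$letter_floor)
    wl <- recipe$word_length_range
    mean_wl <- mean(wl)
    mean_sl <- mean(recipe$sentence_length_range)
    # feasibility: enough distinct spellings for the vocabulary
    if (recipe$vocabulary_size > 0.5 * sum(26^(wl[1L]:wl[2L])))
      stop("vocabulary_size too large for the word-length range")
    vocab <- character(0)
    while (length(vocab) < recipe$vocabulary_size) {
      need <- recipe$vocabulary_size - length(vocab)
      lens <- sample(wl[1L]:wl[2L], 2L * need + 10L, replace = TRUE)
      words <- vapply(lens, function(l) {
        paste(sample(letters, l, replace = TRUE, prob = lw), collapse = "")
      }, character(1))
      vocab <- unique(c(vocab, words))
    }
    vocab <- vocab[seq_len(recipe$vocabulary_size)]
    zipf_w <- (seq_len(recipe$vocabulary_size))^(-recipe$zipf_exponent)
    zipf_w <- zipf_w / sum(zipf_w)

    rand_sentence <- function() {
      len <- sample(recipe$sentence_length_range[1L]:
                      recipe$sentence_length_range[2L], 1L)
      sample.int(recipe$vocabulary_size, len, replace = TRUE, prob = zipf_w)
    }
    templates <- replicate(recipe$n_templates, rand_sentence(),
                           simplify = FALSE)

    # grow sentences until the filtered text safely covers target_length
    cur_template <- sample.int(recipe$n_templates, 1L)
    sentences <- character(0)
    total <- 0
    goal <- 1.1 * target_length + 50 * mean_sl * (mean_wl + 1)
    while (total < goal) {
      if (stats::runif(1) < recipe$template_reuse) {
        if (stats::runif(1) >= recipe$template_stickiness)
          cur_template <- sample.int(recipe$n_templates, 1L)
        ids <- templates[[cur_template]]
      } else {
        ids <- rand_sentence()
      }
      s <- paste(vocab[ids], collapse = " ")
      sentences <- c(sentences, s)
      total <- total + nchar(s) + 2L
    }

    if (recipe$decorate) {
      sentences <- vapply(sentences, decorate_sentence, character(1),
                          USE.NAMES = FALSE)
      enders <- sample(c(".", ".", ".", ".", "?", "!"),
                       length(sentences), replace = TRUE)
    } else {
      enders <- rep(".", length(sentences))
    }
    raw <- paste0(paste0(sentences, enders, collapse = " "))
    text_document(raw, doc_id = doc_id, truncate_to = target_length)
  })
}

# raw-text noise: capitalization, commas, digits, a few diacritics
decorate_sentence <- function(s) {
  s <- paste0(toupper(substr(s, 1L, 1L)), substr(s, 2L, nchar(s)))
  words <- strsplit(s, " ", fixed = TRUE)[[1L]]
  nw <- length(words)
  if (nw > 3L && stats::runif(1) < 0.5) {
    at <- sample(2L:(nw - 1L), 1L)
    words[at] <- paste0(words[at], ",")
  }
  if (stats::runif(1) < 0.1) {
    at <- sample.int(nw, 1L)
    words[at] <- paste0(words[at], " ", sample(10:999, 1L))
  }
  if (stats::runif(1) < 0.1) {
    at <- sample.int(nw, 1L)
    words[at] <- chartr("aeiou", "áéíóú", words[at])
  }
  paste(words, collapse = " ")
}
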