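#' Decompose information and excess-entropy gains across levels
#'
#' The central analysis: estimate entropy rate and excess entropy for a
#' document and its level surrogates, and split the differences into
#' per-level gains.  With the standard text levels,
#' \deqn{I_s = h_s - h,\quad I_w = h_w - h_s,\quad I_c = h_c - h_w}
#' are the amounts of information invested in organizing sentences in the
#' text, words within sentences, and letters within words, and
#' \deqn{\Delta E_s = E - E_s,\quad \Delta E_w = E_s - E_w,\quad
#'       \Delta E_c = E_w - E_c}
#' are the corresponding excess-entropy (correlation) gains.  The gains
#' telescope exactly: their sums equal \eqn{h_c - h} and \eqn{E - E_c}.
#' Gains are reported unclamped; small negative values signal estimator
#' noise, not errors.
#'
#' `variants` may be a [level_variants()] object (text analysis; levels
#' sentence, word, character) or a named list of texts or [symbol_seq()]s
#' whose first element is the original and whose remaining elements are
#' surrogates ordered from the highest organizational level to the lowest
#' (e.g. `list(original = s, codon = ..., character = ...)` for DNA).
#'
#' @param variants a `"level_variants"` object or a named list; see
#'   Details.
#' @param m_max,realizations,seed estimator settings passed to
#'   [excess_entropy()].
#' @return An object of class `"gain_decomposition"` with named numeric
#'   vectors `h` (bits/symbol) and `e` (bits) over `c("original", levels)`,
#'   `info_gain` and `ee_gain` over the levels, `d_s` (word-order
#'   information, `h_word - h_original`, when both levels exist), `c_lz`,
#'   `n`, `doc_id`, and the settings used.
#' @examples
#' d <- text_document(paste(rep("the cat sat on the mat.", 40), collapse = " "))
#' v <- level_variants(d, seed = 1)
#' g <- decompose_levels(v, m_max = 5, realizations = 2, seed = 1)
#' coef(g)
#' @seealso [map_points()], [d_s_statistic()]
#' @export
decompose_levels <- function(variants, m_max = 40L, realizations = 10L,
                             seed = NULL) {
  if (inherits(variants, "level_variants")) {
    doc_id <- variants$doc_id
    texts <- list(original = variants$original,
                  sentence = variants$sentence,
                  word = variants$word,
                  character = variants$character)
    if (is.null(seed)) seed <- variants$seed
  } else if (is.list(variants)) {
    if (is.null(names(variants)) || any(!nzchar(names(variants))))
      stop("variant list must be fully named, original first")
    doc_id <- attr(variants, "doc_id") %||% "doc"
    texts <- variants
  } else {
    stop("variants must be a level_variants object or a named list")
  }
  if (length(texts) < 2L) stop("need the original plus at least one surrogate")
  seqs <- lapply(texts, symbol_seq)
  ns <- vapply(seqs, length, integer(1))
  if (any(ns == 0L)) stop("all variant texts must be nonempty")
  if (is.null(seed)) seed <- with_seed(NULL, sample.int(2147483646L, 1L))

  # one shared surrogate seed: identical variants then get identical
  # estimates, so degenerate inputs decompose to exactly zero gains
  est <- lapply(seqs, function(s) {
    excess_entropy(s, m_max = m_max, realizations = realizations,
                   seed = seed)
  })
  h <- vapply(est, `[[`, numeric(1), "h")
  e <- vapply(est, `[[`, numeric(1), "e")
  names(h) <- names(e) <- names(texts)
  c_lz <- vapply(seqs, lz_complexity, integer(1))

  lv <- names(texts)[-1L]
  info_gain <- diff(h)
  ee_gain <- -diff(e)
  names(info_gain) <- names(ee_gain) <- lv

  d_s <- if (all(c("original", "word") %in% names(h)))
    unname(h[["word"]] - h[["original"]]) else NA_real_

  structure(list(doc_id = doc_id, levels = lv, h = h, e = e,
                 info_gain = info_gain, ee_gain = ee_gain, d_s = d_s,
                 c_lz = c_lz, n = ns,
                 m_max = as.integer(m_max),
                 realizations = as.integer(realizations), seed = seed),
            class = "gain_decomposition")
}

#' @export
print.gain_decomposition <- function(x, digits = 4L, ...) {
  cat("Level decomposition of", sQuote(x$doc_id),
      sprintf(" (n = %d, M_m = %d, R = %d, seed = %s)\n",
              x$n[[1L]], x$m_max, x$realizations, format(x$seed)))
  tab <- data.frame(h = round(x$h, digits), E = round(x$e, digits),
                    C_LZ = x$c_lz, row.names = names(x$h))
  print(tab)
  cat("information gains (bits/symbol): ",
      paste(sprintf("I_%s = %.*f", names(x$info_gain), digits, x$info_gain),
            collapse = ", "), "\n")
  cat("excess-entropy gains (bits):     ",
      paste(sprintf("dE_%s = %.*f", names(x$ee_gain), digits, x$ee_gain),
            collapse = ", "), "\n")
  if (!is.na(x$d_s))
    cat(sprintf("word-order information D_s = %.*f bits/symbol\n",
                digits, x$d_s))
  invisible(x)
}

#' @export
summary.gain_decomposition <- function(object, ...) {
  structure(list(decomp = object,
                 sum_info = sum(object$info_gain),
                 sum_ee = sum(object$ee_gain)),
            class = "summary.gain_decomposition")
}

#' @export
print.summary.gain_decomposition <- function(x, ...) {
  print(x$decomp)
  cat(sprintf("total: sum(I) = %.4f = h_%s - h_original;  sum(dE) = %.4f = E_original - E_%s\n",
              x$sum_info, utils::tail(x$decomp$levels, 1L),
              x$sum_ee, utils::tail(x$decomp$levels, 1L)))
  invisible(x)
}

#' @export
coef.gain_decomposition <- function(object, ...) {
  c(setNames(object$info_gain, paste0("i_", names(object$info_gain))),
    setNames(object$ee_gain, paste0("de_", names(object$ee_gain))),
    d_s = object$d_s)
}

#' Word-order information statistic
#'
#' The entropy-rate gap between the word-shuffled surrogate and the
#' original text, \eqn{D_s = h_w - h}: the information per symbol carried
#' by word ordering (within and across sentences).  It equals
#' \eqn{I_s + I_w}.  Note that the sign convention in the literature is
#' inconsistent; this package reports the nonnegative word-order reading.
#'
#' @param h_w entropy rate of the word-shuffled text (bits/symbol), or a
#'   `"gain_decomposition"` object.
#' @param h_orig entropy rate of the original text (ignored when `h_w` is
#'   a decomposition).
#' @return Numeric, bits per symbol.
#' @export
d_s_statistic <- function(h_w, h_orig = NULL) {
  if (inherits(h_w, "gain_decomposition")) return(h_w$d_s)
  stopifnot(is.finite(h_w), is.finite(h_orig))
  h_w - h_orig
}

#' Vocabulary and word-use statistics of a document
#'
#' Summary statistics of a canonical text: vocabulary size V (distinct
#' words), word-use entropy S (Shannon entropy of the word-frequency
#' histogram, bits), and the entropy of the sentence-length histogram
#' (lengths in words).
#'
#' @param x canonical text (string) or a [text_document()].
#' @return A list of class `"corpus_stats"`: `doc_id`, `vocabulary_size`,
#'   `word_use_entropy`, `sentence_length_entropy`, `n_words`,
#'   `n_sentences`.
#' @examples
#' corpus_stats("the cat. the dog.")
#' @export
corpus_stats <- function(x) {
  doc_id <- "doc"
  if (inherits(x, "text_document")) {
    doc_id <- x$doc_id
    x <- x$canonical
  }
  stopifnot(is.character(x), length(x) == 1L)
  sentences <- trimws(strsplit(x, ".", fixed = TRUE)[[1L]])
  sentences <- sentences[nzchar(sentences)]
  words <- strsplit(gsub(".", " ", x, fixed = TRUE), " ", fixed = TRUE)[[1L]]
  words <- words[nzchar(words)]
  if (length(words) == 0L) stop("text contains no words")
  shannon <- function(counts) {
    p <- counts / sum(counts)
    -sum(p * log2(p))
  }
  sent_lengths <- vapply(strsplit(sentences, " ", fixed = TRUE),
                         function(w) sum(nzchar(w)), integer(1))
  structure(list(doc_id = doc_id,
                 vocabulary_size = length(unique(words)),
                 word_use_entropy = shannon(table(words)),
                 sentence_length_entropy =
                   if (length(sent_lengths)) shannon(table(sent_lengths))
                   else NA_real_,
                 n_words = length(words),
                 n_sentences = length(sentences)),
            class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf("Corpus stats for %s: V = %d, S = %.3f bits (%d words, %d sentences, sentence-length entropy %.3f)\n",
              sQuote(x$doc_id), x$vocabulary_size, x$word_use_entropy,
              x$n_words, x$n_sentences, x$sentence_length_entropy))
  invisible(x)
}

#' Complexity-entropy map points
#'
#' Flatten one or more decompositions into a table of (h, E) points, one
#' row per document and variant — the tabular form of a
#' complexity-entropy diagram.
#'
#' @param decomps a `"gain_decomposition"` or a list of them.
#' @return A data.frame with columns `doc_id`, `variant`, `n`, `c_lz`,
#'   `h_bits`, `e_bits`, ordered by `doc_id` then variant.
#' @export
map_points <- function(decomps) {
  if (inherits(decomps, "gain_decomposition")) decomps <- list(decomps)
  rows <- lapply(decomps, function(g) {
    data.frame(doc_id = g$doc_id, variant = names(g$h),
               n = unname(g$n), c_lz = unname(g$c_lz),
               h_bits = unname(g$h), e_bits = unname(g$e),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$doc_id), ]  # stable: variant order within doc kept
  rownames(out) <- NULL
  out
}

#' Group centers of mass on the map
#'
#' Mean (h, E) — or mean gain coordinates — per group of documents, the
#' "center of mass" summary used to compare groups (e.g. authors) on a
#' complexity-entropy diagram.
#'
#' @param points a data.frame with numeric columns and a `doc_id` column,
#'   e.g. from [map_points()].
#' @param groups group label per row (recycled against rows); defaults to
#'   `doc_id`.
#' @return A data.frame of per-group means of every numeric column.
#' @export
group_centers <- function(points, groups = points$doc_id) {
  stopifnot(is.data.frame(points))
  num <- vapply(points, is.numeric, logical(1))
  agg <- stats::aggregate(points[num], by = list(group = groups), FUN = mean)
  agg
}

#' Least-squares line on the complexity-entropy map
#'
#' Convenience fit of `e_bits ~ h_bits` over map points.  Purely
#' descriptive: the slope and intercept depend entirely on the corpus at
#' hand.
#'
#' @param points data.frame from [map_points()] (or any with `h_bits`,
#'   `e_bits`).
#' @param variant restrict to one variant (default `"original"`); `NULL`
#'   uses all rows.
#' @return An `lm` object.
#' @export
fit_map_line <- function(points, variant = "original") {
  if (!is.null(variant)) points <- points[points$variant %in% variant, ]
  stats::lm(e_bits ~ h_bits, data = points)
}

#' Plot a complexity-entropy diagram
#'
#' Excess entropy against entropy rate, one point per (document, variant).
#'
#' @param x a `"gain_decomposition"`, a list of them, or a [map_points()]
#'   data.frame.
#' @param ... further arguments passed to [graphics::plot()].
#' @return Invisibly, the plotted points table.
#' @export
plot_ce_map <- function(x, ...) {
  pts <- if (is.data.frame(x)) x else map_points(x)
  variants <- unique(pts$variant)
  cols <- setNames(seq_along(variants), variants)
  pch <- setNames(rep_len(c(19, 17, 15, 18, 1, 2), length(variants)), variants)
  graphics::plot(pts$h_bits, pts$e_bits,
                 col = cols[pts$variant], pch = pch[pts$variant],
                 xlab = expression(h[LZ] ~ "(bits/symbol)"),
                 ylab = expression(E[LZ] ~ "(bits)"), ...)
  graphics::legend("topright", legend = variants, col = cols[variants],
                   pch = pch[variants], bty = "n")
  invisible(pts)
}

#' @export
plot.gain_decomposition <- function(x, ...) plot_ce_map(x, ...)
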