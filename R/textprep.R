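#' Canonical text filtering
#'
#' Reduce arbitrary UTF-8 text to the canonical representation used by the
#' estimators: lowercase letters 'a'-'z', spaces, and sentence-ending
#' periods.  Rules are applied in a fixed order: lowercasing; diacritic
#' stripping (canonical decomposition, then removal of combining marks);
#' digit removal; '?' and '!' to '.'; every other non-letter, non-period
#' character to space; optional collapsing of space runs.  Letters with no
#' decomposition that fall outside a-z (such as 'ø') map to space.
#'
#' With `collapse_spaces = TRUE` runs of spaces become a single space,
#' spaces before periods are removed, and the result is trimmed.  The
#' operation is idempotent either way.
#'
#' @param raw a single string of UTF-8 text.
#' @param collapse_spaces collapse runs of spaces (default `TRUE`).
#' @return Canonical text: a string over 'a'-'z', space, and '.'.
#' @examples
#' filter_text("Hello, World!")            # "hello world."
#' @export
filter_text <- function(raw, collapse_spaces = TRUE) {
  stopifnot(is.character(raw), length(raw) == 1L)
  x <- tolower(raw)
  x <- stringi::stri_trans_nfd(x)
  x <- gsub("\\p{Mn}", "", x, perl = TRUE)
  x <- gsub("\\p{Nd}", "", x, perl = TRUE)
  x <- gsub("[?!]", ".", x)
  x <- gsub("[^a-z.]", " ", x)
  if (collapse_spaces) {
    x <- gsub(" +\\.", ".", x)
    x <- gsub(" +", " ", x)
    x <- gsub("^ | $", "", x)
  }
  x
}

#' Finalize canonical text
#'
#' Replace sentence periods by spaces, producing the final 27-symbol text
#' ('a'-'z' plus space), and optionally truncate it to an exact length.
#' Truncation to the common document length makes estimates from different
#' documents directly comparable.
#'
#' @param canonical canonical text as produced by [filter_text()].
#' @param truncate_to target length in characters, or `NULL` for no
#'   truncation.  The conventional document length for comparative text
#'   analysis is 78000.
#' @param collapse_spaces collapse space runs created by the period
#'   substitution.
#' @param allow_short if the text is shorter than `truncate_to`, emit a
#'   warning and return it untruncated instead of raising an error.
#' @return Final text over at most 27 symbols; exactly `truncate_to`
#'   characters when truncation applies.
#' @examples
#' finalize_text("ab. cd.")             # "ab cd"
#' @export
finalize_text <- function(canonical, truncate_to = NULL,
                          collapse_spaces = TRUE, allow_short = FALSE) {
  stopifnot(is.character(canonical), length(canonical) == 1L)
  if (grepl("[^a-z. ]", canonical))
    stop("input is not canonical text (only 'a'-'z', space and '.' allowed)")
  x <- gsub(".", " ", canonical, fixed = TRUE)
  if (collapse_spaces) {
    x <- gsub(" +", " ", x)
    x <- gsub("^ | $", "", x)
  }
  if (!is.null(truncate_to)) {
    stopifnot(is.numeric(truncate_to), truncate_to >= 1)
    if (nchar(x) < truncate_to) {
      if (allow_short) {
        warning("text of length ", nchar(x),
                " is shorter than truncate_to = ", truncate_to,
                "; returning untruncated")
        return(x)
      }
      stop("text of length ", nchar(x), " is shorter than truncate_to = ",
           truncate_to, " (set allow_short = TRUE to keep it)")
    }
    x <- substr(x, 1L, as.integer(truncate_to))
  }
  x
}

#' Text documents
#'
#' Bundle a raw text with its canonical and final filtered forms.  The
#' canonical form retains sentence periods (needed for sentence
#' shuffling); the final form is the 27-symbol text the estimators run on.
#'
#' @param raw the original UTF-8 text (single string).
#' @param doc_id document label.
#' @param truncate_to final-text truncation length, or `NULL`.
#' @param collapse_spaces passed to [filter_text()] and [finalize_text()].
#' @param allow_short passed to [finalize_text()].
#' @return An object of class `"text_document"` with fields `doc_id`,
#'   `raw`, `canonical`, `final`, `truncate_to`, `collapse_spaces`.
#' @examples
#' d <- text_document("One ring. To rule! Them all?", "demo")
#' d$final
#' @seealso [read_text_document()], [level_variants()]
#' @export
text_document <- function(raw, doc_id = "doc", truncate_to = NULL,
                          collapse_spaces = TRUE, allow_short = FALSE) {
  canonical <- filter_text(raw, collapse_spaces = collapse_spaces)
  final <- finalize_text(canonical, truncate_to = truncate_to,
                         collapse_spaces = collapse_spaces,
                         allow_short = allow_short)
  structure(list(doc_id = doc_id, raw = raw, canonical = canonical,
                 final = final, truncate_to = truncate_to,
                 collapse_spaces = collapse_spaces),
            class = "text_document")
}

#' @export
print.text_document <- function(x, ...) {
  cat("Text document", sQuote(x$doc_id), "\n",
      " raw:", nchar(x$raw), "chars;  final:", nchar(x$final),
      "chars over", attr(alphabet_of(x$final), "size") %||% 0L, "symbols\n")
  invisible(x)
}
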