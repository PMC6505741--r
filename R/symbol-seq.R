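#' Symbol alphabets
#'
#' An alphabet is an ordered set of distinct single symbols over which a
#' [symbol_seq()] is defined.  Symbols are arbitrary non-empty strings,
#' although in practice they are single characters ('a'-'z' plus space for
#' filtered text, A/C/G/T/N for DNA).
#'
#' @param symbols character vector of distinct symbols.
#' @return An object of class `"lz_alphabet"`: the symbol vector with a
#'   `size` attribute.
#' @examples
#' alphabet(c("A", "C", "G", "T"))
#' @export
alphabet <- function(symbols) {
  symbols <- as.character(symbols)
  if (length(symbols) < 1L) stop("alphabet must contain at least one symbol")
  if (anyDuplicated(symbols)) stop("alphabet symbols must be distinct")
  if (anyNA(symbols)) stop("alphabet symbols must not be NA")
  structure(symbols, size = length(symbols), class = "lz_alphabet")
}

#' @export
print.lz_alphabet <- function(x, ...) {
  cat("Alphabet of", attr(x, "size"), "symbols:",
      paste(utils::head(unclass(x), 30L), collapse = " "),
      if (length(x) > 30L) "..." else "", "\n")
  invisible(x)
}

#' Symbolic sequences
#'
#' Construct a finite sequence of symbols over an explicit alphabet, the
#' universal input of the entropy-rate and excess-entropy estimators.  A
#' single string is split into characters; a character vector of length
#' greater than one is taken as one symbol per element.
#'
#' @param x a single string, a character vector of symbols, or an integer
#'   vector of 1-based codes into `alphabet`.
#' @param alphabet an [alphabet()], or `NULL` to infer the alphabet from the
#'   symbols in order of first appearance.
#' @return An object of class `"symbol_seq"` holding integer symbol codes
#'   and the alphabet.
#' @examples
#' s <- symbol_seq("10010101110")
#' length(s)
#' @export
symbol_seq <- function(x, alphabet = NULL) {
  if (inherits(x, "symbol_seq")) return(x)
  if (is.numeric(x)) {
    if (is.null(alphabet)) stop("an alphabet is required for integer codes")
    codes <- as.integer(x)
    if (length(codes) && (anyNA(codes) || min(codes) < 1L ||
                          max(codes) > attr(alphabet, "size")))
      stop("integer codes out of range for the declared alphabet")
    syms <- unclass(alphabet)
  } else {
    if (length(x) == 1L && !inherits(x, "AsIs")) {
      x <- strsplit(x, "", fixed = TRUE)[[1L]]
    }
    x <- as.character(x)
    if (is.null(alphabet)) {
      syms <- unique(x)
      if (length(syms) == 0L) syms <- character(0)
      codes <- match(x, syms)
    } else {
      syms <- unclass(alphabet)
      codes <- match(x, syms)
      if (anyNA(codes)) {
        bad <- sort(unique(x[is.na(codes)]))
        stop("symbols not in declared alphabet: ",
             paste(sQuote(bad), collapse = ", "))
      }
    }
  }
  if (length(syms) == 0L && length(codes) > 0L)
    stop("non-empty sequence over an empty alphabet")
  structure(list(codes = codes,
                 alphabet = if (length(syms)) alphabet(syms) else character(0)),
            class = "symbol_seq")
}

#' @export
length.symbol_seq <- function(x) length(x$codes)

#' @export
as.character.symbol_seq <- function(x, collapse = "", ...) {
  if (length(x$codes) == 0L) return("")
  paste(unclass(x$alphabet)[x$codes], collapse = collapse)
}

#' @export
print.symbol_seq <- function(x, ...) {
  n <- length(x)
  cat("Symbol sequence: n =", n, "over",
      if (length(x$alphabet)) attr(x$alphabet, "size") else 0L, "symbols\n")
  if (n > 0L) {
    shown <- as.character(symbol_seq(x$codes[seq_len(min(n, 60L))],
                                     alphabet = x$alphabet))
    cat(" ", shown, if (n > 60L) "..." else "", "\n")
  }
  invisible(x)
}

#' Alphabet of a text
#'
#' Distinct symbols of a string, in order of first appearance.
#'
#' @param text a single string.
#' @return An [alphabet()], or an empty character vector for empty input.
#' @examples
#' alphabet_of("abca")
#' @export
alphabet_of <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- unique(strsplit(text, "", fixed = TRUE)[[1L]])
  if (length(chars) == 0L) return(character(0))
  alphabet(chars)
}
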