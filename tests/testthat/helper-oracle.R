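# Naive reference factorizer: direct substring search for the two
# exhaustiveness conditions.  A candidate factor ending at 1-based
# position e is reproducible iff it occurs as a substring of the prefix
# ending at e-1; the factor is the shortest non-reproducible candidate,
# and the trailing factor may remain reproducible.
oracle_factorize <- function(x) {
  n <- nchar(x)
  factors <- character(0)
  start <- 1L
  while (start <= n) {
    e <- start
    repeat {
      cand <- substr(x, start, e)
      reproducible <- e > 1L && grepl(cand, substr(x, 1L, e - 1L),
                                      fixed = TRUE)
      if (!reproducible || e == n) break
      e <- e + 1L
    }
    factors <- c(factors, substr(x, start, e))
    start <- e + 1L
  }
  factors
}

# Check the two pi-operator conditions on a factorization directly:
# (A) every factor minus its last symbol occurs in the prefix truncated
#     two symbols before the factor's end;
# (B) no factor except possibly the last occurs in the prefix truncated
#     one symbol before its end.
check_exhaustive <- function(x, factors) {
  if (paste(factors, collapse = "") != x) return(FALSE)
  ends <- cumsum(nchar(factors))
  for (k in seq_along(factors)) {
    f <- factors[k]
    body <- substr(f, 1L, nchar(f) - 1L)
    cond_a <- nchar(body) == 0L ||
      grepl(body, substr(x, 1L, ends[k] - 2L), fixed = TRUE)
    if (!cond_a) return(FALSE)
    if (k < length(factors)) {
      cond_b <- !(ends[k] > 1L &&
                    grepl(f, substr(x, 1L, ends[k] - 1L), fixed = TRUE))
      if (ends[k] == 1L) cond_b <- TRUE
      if (!cond_b) return(FALSE)
    }
  }
  TRUE
}

random_string <- function(len, alpha_size) {
  syms <- c(letters, " ")[seq_len(alpha_size)]
  paste(sample(syms, len, replace = TRUE), collapse = "")
}
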