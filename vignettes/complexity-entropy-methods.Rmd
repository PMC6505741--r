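---
title: "Methods: LZ76 complexity-entropy analysis of symbolic sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LZ76 complexity-entropy analysis of symbolic sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lzce)
```

## The measures

A stationary symbolic source can be placed on a plane spanned by two
complementary quantities. The **entropy rate** $h_\mu$ (bits/symbol) is the
asymptotic rate at which the source produces new, unpredictable
information. The **excess entropy** $E$ (bits) is the mutual information
between the two halves of a long realization: the amount of information
the past stores that is useful for predicting the future. A purely random
source has maximal $h$ and $E \approx 0$; a repetitive source has
$h \approx 0$ and large $E$. The scatter of $E$ against $h$ — the
complexity-entropy diagram — summarizes the balance a source strikes
between innovation and structure.

Both quantities are defined for bi-infinite sequences and must be
estimated from finite data. This package estimates both through a single
primitive: the exhaustive Lempel-Ziv (LZ76) factorization.

### The LZ76 factorization

Scanning left to right, each factor is the *shortest* prefix of the
unscanned remainder that does not occur as a substring of the text
truncated one symbol before the factor's end. Equivalently, a factor
starting at position $i$ extends a longest previous match by one fresh
symbol; the earlier occurrence may start before $i$ and overlap the
factor itself. The final factor is exempt and may remain fully
reproducible. This parsing is unique. For `10010101110` it gives

```{r}
lz76_factorize("10010101110")
```

The factor count $C_{LZ}$ yields the entropy-rate estimator

$$h_{LZ} = \frac{C_{LZ}\,\log_2 n}{n},$$

the finite-$n$ reading of the limit $C_{LZ}\,\log n / n \to h_\mu$. All
logarithms in the package are base 2, so estimates are in bits. For
$n \le 1$ we set $h = 0$ (consistent with $\log_2 1 = 0$ at $n = 1$).
This estimator is a factorization count, not a compression ratio; it is
unrelated to running a general-purpose compressor.

The estimator's finite-size error grows with alphabet size: at
$n = 10^5$ an i.i.d. uniform binary source measures within about 2% of
1 bit/symbol, while an i.i.d. uniform 27-symbol source measures about
9% below $\log_2 27 = 4.75$. Comparative analyses should therefore hold
$n$ fixed across documents, which is exactly what the truncation
convention below does.

### Excess entropy from block-shuffled surrogates

The excess entropy is estimated as

$$E_{LZ} = \sum_{M=1}^{M_m}\bigl(h_{LZ}(S_{(M)}) - h_{LZ}(S)\bigr),$$

where $S_{(M)}$ partitions the sequence into non-overlapping blocks of
length $M$ and permutes them uniformly. Each shuffle destroys
correlations at scales beyond $M$ while preserving the full symbol
multiset, so each term isolates the entropy-rate cost of the structure
living above scale $M$; the sum accumulates correlation information over
all scales up to $M_m$.

Numerical choices, each fixed in code and exposed as an argument:

* **$M_m$ (default 40).** Conventional cap for documents of order
  $10^4$–$10^5$ symbols; doubling it to 80 does not change results
  materially on such lengths. Per-$M$ terms are returned in the
  `lz_excess` object so convergence can be inspected.
* **Realizations $R$ (default 10).** Each term is the mean over $R$
  independent shuffles, taming single-shuffle noise; $R = 1$ reproduces
  the minimal single-surrogate reading.
* **Remainder rule.** When $M \nmid n$ the trailing partial block joins
  the shuffle pool as one unit, so the symbol multiset is preserved
  exactly; a `truncate` option drops it instead.
* **No clamping.** $E_{LZ}$ may fluctuate slightly below zero on
  memoryless input; it is reported as computed.
* **RNG contract.** One run seed; the seed for each
  $(M, r)$ pair is derived from it by a fixed affine hash, so results do
  not depend on evaluation order and single terms can be recomputed in
  isolation. `decompose_levels()` passes the *same* surrogate seed to
  every variant, so identical variants yield exactly zero gains.

## The text pipeline

`filter_text()` reduces arbitrary UTF-8 text to a canonical form:
lowercase; canonical (NFD) decomposition with combining marks removed;
digits deleted; `?` and `!` to `.`; every other non-letter, non-period
character to space. Letters with no decomposition outside a–z (e.g.
`ø`) map to space. `finalize_text()` then replaces periods by spaces,
leaving the 27-symbol alphabet 'a'–'z' plus space, and truncates to a
fixed length (default 78000 characters) so documents are commensurate.

Two points are deliberately configurable because either convention is
defensible: space runs are collapsed by default (punctuation-to-space
otherwise creates artificial low-entropy space runs), with a flag to
keep them verbatim; and truncation is applied last, after all filtering
and any shuffling, so surrogates are cut to the same length as the
original.

## Level randomization and the gain decomposition

Three surrogates destroy structure level by level: sentence shuffling
(permutes sentences split on periods of the canonical text, then
finalizes), word shuffling (permutes space-delimited tokens), and
character shuffling (permutes all characters). Each preserves its unit
multiset exactly; empty units from consecutive delimiters are dropped,
and a trailing fragment without a final period counts as a sentence.
For sequences whose units have a known width rather than a delimiter
(DNA codons), `shuffle_fixed_width_units()` plays the role of the word
shuffle.

With $h_s, h_w, h_c$ and $E_s, E_w, E_c$ the estimates for the
sentence-, word-, and character-shuffled variants, the information gains
and excess-entropy gains are

$$I_s = h_s - h,\qquad I_w = h_w - h_s,\qquad I_c = h_c - h_w,$$
$$\Delta E_s = E - E_s,\qquad \Delta E_w = E_s - E_w,\qquad
  \Delta E_c = E_w - E_c.$$

$I_s$ is the information per symbol invested in arranging sentences in
the document, $I_w$ in arranging words within sentences, $I_c$ in
arranging letters within words. The gains telescope by construction:
$I_s + I_w + I_c = h_c - h$ and
$\Delta E_s + \Delta E_w + \Delta E_c = E - E_c$. Gains are reported
unclamped; small negative values are estimator noise.

The word-order statistic $D_s$ is reported as $h_w - h$, the nonnegative
"information in word order" reading, equal to $I_s + I_w$. The sign
convention for this statistic is inconsistent in the literature — both
$h_\mu - h_w$ and $h_w - h_\mu$ appear — so the package documents its
choice and users comparing against published values should check signs.

## The synthetic hierarchical corpus

Real literary corpora are curated and cannot ship with a package, so the
test bed is a generator, `generate_corpus()`, whose documents carry
genuine structure at each of the three levels the shuffles target:

* **Character level:** words are fixed spellings over an English-like
  letter distribution, so character shuffling destroys word-internal
  structure. A floor of 0.5% on every letter weight guarantees all 26
  letters appear at the 78000-character scale, giving the full
  27-symbol alphabet.
* **Word level:** tokens are drawn from a Zipf-like rank law (exponent
  1.0) over a vocabulary of 2000 words (matching the few-thousand-word
  vocabularies typical of book-length documents), and sentences are
  frequently reused from a 50-template pool — recurring word sequences
  that word shuffling destroys.
* **Sentence level:** the template choice is a sticky Markov process
  (reuse probability 0.6, stickiness 0.6), so identical sentences
  cluster in runs; sentence shuffling destroys that adjacency while
  preserving the sentence multiset.

Word lengths are uniform on 2–9 letters and sentence lengths on 5–25
words. With `decorate = TRUE` the raw text also carries capitalization,
commas, digits, diacritics, and `?`/`!` endings, exercising every
filter rule. These settings were chosen once, on the grounds above, as
the package's study conditions.

What the generator does *not* emulate: syntax, semantics, long-range
topical drift, Herdan–Heaps vocabulary growth, or realistic letter
bigrams within invented words. Passing tests on this corpus therefore
demonstrate that the estimators detect and decompose hierarchical
structure of the kind natural text has — not that any particular
literary corpus would reproduce specific published coordinates.

Validation sources with closed-form answers back the estimators
independently: i.i.d. sequences ($h = -\sum p\log_2 p$, $E \approx 0$),
periodic sequences ($C_{LZ} \le |w| + 2$ for motif $w$, so $h \to 0$,
with $E$ capturing the stored phase information), and first-order
Markov chains ($h = -\sum_i \pi_i \sum_j P_{ij}\log_2 P_{ij}$, with the
stationary distribution solved from $\pi P = \pi$ and chains started at
stationarity to avoid burn-in ambiguity).

## Degenerate inputs and edge rules

Empty sequences factorize to zero factors and have $h = 0$; estimators
reject empty variant texts. A one-sentence document cannot be
sentence-shuffled into anything new and passes through unchanged.
Constant sequences are invariant under every shuffle, so $E_{LZ}$ is
exactly 0. `excess_entropy()` refuses $M_m > n$ with advice to lower
$M_m$. Truncating a document longer than its text is an error by
default (silent shortfall would skew cross-document comparison); an
`allow_short` flag downgrades it to a warning.

## Problem sizes

The shipped tests validate the factorizer span-for-span against a naive
direct-substring-search reference on 1000 random strings (lengths
1–300, alphabets 2–27), recover analytic entropy rates at $n = 10^5$,
and run the full level decomposition at the standard document length of
78000 characters over 5 corpus seeds with $M_m = 40$, $R = 10$. Unit
tests use documents of a few thousand characters, where one level
decomposition takes well under a second.

## Known limitations

* $h_{LZ}$ is biased downward at finite $n$, increasingly so for larger
  alphabets; compare only estimates at equal $n$.
* $E_{LZ}$ is a surrogate-based proxy for the mutual-information excess
  entropy, not the block-entropy definition itself. Its absolute scale
  depends on $M_m$: a shuffle at block length $M$ cuts the sequence at
  $n/M$ boundaries and each cut costs roughly the cross-boundary mutual
  information, so the per-$M$ terms decay like $1/M$ and the sum grows
  slowly (logarithmically) with the cap even for short-memory sources.
  $E_{LZ}$ values are therefore comparable only at a common $M_m$;
  the per-$M$ terms returned in the `lz_excess` object make the
  dependence inspectable.
* Short inputs (a few thousand symbols or less) give noisy gains; the
  decomposition is meant for document-scale sequences.
* Sentence detection is purely period-based by design; abbreviation
  handling and other segmentation niceties are out of scope, as is
  play-script curation (speaker labels, stage directions), which must
  happen before text enters the pipeline.
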