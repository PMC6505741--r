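# lzce — Lempel-Ziv complexity-entropy analysis of symbolic sequences

`lzce` places symbolic sequences — filtered natural-language text, DNA,
or any string over a finite alphabet — on the complexity-entropy plane,
and decomposes their information content across organizational levels
(sentences, words, characters; or codons for DNA). It is aimed at
quantitative-linguistics and sequence-analysis work where one wants to
measure how much information a document invests in *each* level of its
hierarchy, not just how unpredictable it is overall.

## The measures

Everything rests on the exhaustive **LZ76 factorization**: scanning left
to right, each factor is the shortest prefix of the remainder that does
not occur as a (possibly self-overlapping) substring of the text
truncated one symbol before the factor's end; the last factor may remain
reproducible. The parsing is unique, e.g.
`10010101110 → 1.0.01.01011.10` (5 factors). From the factor count
C<sub>LZ</sub>:

- **Entropy rate** (bits/symbol): h<sub>LZ</sub> = C<sub>LZ</sub> log₂(n)/n
  — the source's rate of new-information production.
- **Excess entropy** (bits):
  E<sub>LZ</sub> = Σ<sub>M=1..M<sub>m</sub></sub> (h<sub>LZ</sub>(S<sub>(M)</sub>) − h<sub>LZ</sub>(S)),
  where S<sub>(M)</sub> is a random permutation of the sequence's
  non-overlapping length-M blocks — the information stored in
  correlations, accumulated over scales up to M<sub>m</sub> (default 40).

Shuffling a document at one level and re-estimating yields the
**information gains** I<sub>s</sub> = h<sub>s</sub> − h,
I<sub>w</sub> = h<sub>w</sub> − h<sub>s</sub>,
I<sub>c</sub> = h<sub>c</sub> − h<sub>w</sub> and the matching
**excess-entropy gains** ΔE<sub>s</sub>, ΔE<sub>w</sub>, ΔE<sub>c</sub>:
the information invested in arranging sentences in the text, words
within sentences, and letters within words. They telescope exactly:
I<sub>s</sub>+I<sub>w</sub>+I<sub>c</sub> = h<sub>c</sub> − h.

Text enters through the canonical 27-symbol filter (lowercase,
de-diacritic, digits removed, `?`/`!` → `.`, other punctuation → space,
periods → spaces after sentence handling) and is truncated to a common
length (default 78000 characters) so documents are comparable.

## Worked example

```r
library(lzce)

# the canonical parsing
lz76_factorize("10010101110")
#> LZ76 exhaustive factorization: n = 11  C_LZ = 5
#>   1.0.01.01011.10

# a synthetic hierarchical document: Zipfian vocabulary, reused
# sentence templates in sticky runs, English-like letter weights
doc <- generate_corpus(corpus_recipe(vocabulary_size = 300),
                       target_length = 5000, seed = 2)
v <- level_variants(doc, seed = 9)
g <- decompose_levels(v, m_max = 10, realizations = 3, seed = 4)
g
#> Level decomposition of 'synthetic'  (n = 5000, M_m = 10, R = 3, seed = 4)
#>                h       E C_LZ
#> original  1.5163 14.1915  617
#> sentence  1.5949 14.0342  649
#> word      1.8776 11.3907  764
#> character 3.7478 -0.2236 1525
#> information gains (bits/symbol):  I_sentence = 0.0786, I_word = 0.2826, I_character = 1.8702
#> excess-entropy gains (bits):      dE_sentence = 0.1573, dE_word = 2.6435, dE_character = 11.6143
#> word-order information D_s = 0.3613 bits/symbol
```

Reading the table: each shuffle level destroys one layer of structure,
so the entropy rate climbs from the original (1.52 bits/symbol) to the
character shuffle (3.75, approaching but below the 27-symbol cap
log₂ 27 = 4.75) while the excess entropy collapses from 14.2 bits to
about zero — randomized characters retain no correlations beyond letter
frequencies. The largest gains sit at the character level (word
spellings), with successively smaller investments in word-in-sentence
and sentence-in-text organization. `plot(g)` draws the four variants on
the complexity-entropy map; `run_analysis()` does all of the above for
a set of files and writes a TSV/JSON table; `inst/cli/lzce.R` exposes
the same pipeline as a command line.

For DNA, `read_fasta()` plus `shuffle_fixed_width_units(seq, 3)` gives
the codon-level analogue of word shuffling.

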