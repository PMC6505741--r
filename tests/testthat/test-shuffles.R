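test_that("sentence shuffling permutes sentences and finalizes", {
  outs <- vapply(1:20, function(s) shuffle_sentences("ab. cd.", seed = s),
                 character(1))
  expect_true(all(outs %in% c("ab cd", "cd ab")))
  expect_true(length(unique(outs)) == 2L)  # both orders occur over 20 seeds
  expect_identical(shuffle_sentences("ab. cd.", seed = 5),
                   shuffle_sentences("ab. cd.", seed = 5))
  # one sentence: unchanged up to final period handling
  expect_identical(shuffle_sentences("hello there.", seed = 1),
                   "hello there")
  # trailing fragment without a period counts as a sentence
  expect_setequal(strsplit(shuffle_sentences("ab. cd", seed = 2), " ")[[1L]],
                  c("ab", "cd"))
  expect_error(shuffle_sentences(" . . "), "no sentences")
})

test_that("word and sentence shuffles preserve the word multiset", {
  canon <- "the cat sat. the dog ran away. all was well."
  final <- finalize_text(canon)
  for (s in 1:10) {
    ws <- shuffle_words(final, seed = s)
    expect_identical(sort(strsplit(ws, " ")[[1L]]),
                     sort(strsplit(final, " ")[[1L]]))
    ss <- shuffle_sentences(canon, seed = s)
    expect_identical(sort(strsplit(ss, " ")[[1L]]),
                     sort(strsplit(final, " ")[[1L]]))
  }
  expect_identical(shuffle_words("word", seed = 1), "word")
  expect_error(shuffle_words("   "), "no words")
})

test_that("character shuffles preserve the histogram exactly", {
  expect_identical(shuffle_characters("aaa", seed = 1), "aaa")
  x <- "information theory"
  for (s in 1:5) {
    y <- shuffle_characters(x, seed = s)
    expect_identical(sort(strsplit(y, "")[[1L]]), sort(strsplit(x, "")[[1L]]))
  }
  expect_error(shuffle_characters(""), "empty")
})

test_that("fixed-width unit shuffles behave like block shuffles", {
  s <- symbol_seq("ACGTTT")
  outs <- vapply(1:20, function(sd)
    as.character(shuffle_fixed_width_units(s, 3, seed = sd)), character(1))
  expect_true(all(outs %in% c("ACGTTT", "TTTACG")))
  expect_true(length(unique(outs)) == 2L)
  # width >= n is the identity
  expect_identical(as.character(shuffle_fixed_width_units(s, 6, seed = 1)),
                   "ACGTTT")
  # width 1 is a character shuffle under the same seed policy
  expect_identical(as.character(shuffle_fixed_width_units(s, 1, seed = 7)),
                   as.character(block_shuffle(s, 1, seed = 7)))
  expect_error(shuffle_fixed_width_units(s, 0), "width")
})

test_that("word shuffling supports alternative delimiters", {
  x <- "abecbeda"
  y <- shuffle_words(x, seed = 3, delimiter = "e")
  expect_identical(sort(strsplit(y, "e")[[1L]]),
                   sort(Filter(nzchar, strsplit(x, "e")[[1L]])))
})

test_that("variant sets are commensurate and seed-reproducible", {
  doc <- generate_corpus(corpus_recipe(vocabulary_size = 150),
                         target_length = 3000, seed = 11)
  v1 <- level_variants(doc, seed = 21)
  v2 <- level_variants(doc, seed = 21)
  expect_identical(v1[c("original", "sentence", "word", "character")],
                   v2[c("original", "sentence", "word", "character")])
  lens <- nchar(c(v1$original, v1$sentence, v1$word, v1$character))
  expect_true(all(lens == 3000L))
  # all variants stay on the 27-symbol alphabet
  for (txt in list(v1$sentence, v1$word, v1$character))
    expect_false(grepl("[^a-z ]", txt))
  # character variant is an exact permutation (no truncation case)
  doc2 <- text_document("one fish. two fish. red fish. blue fish.")
  v3 <- level_variants(doc2, seed = 2)
  expect_identical(sort(strsplit(v3$character, "")[[1L]]),
                   sort(strsplit(v3$original, "")[[1L]]))
  expect_identical(sort(strsplit(v3$word, " ")[[1L]]),
                   sort(strsplit(v3$original, " ")[[1L]]))
})
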