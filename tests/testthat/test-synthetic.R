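test_that("generators are deterministic per seed", {
  a <- generate_iid(c("x", "y", "z"), n = 500, seed = 3)
  b <- generate_iid(c("x", "y", "z"), n = 500, seed = 3)
  expect_identical(a$codes, b$codes)
  src <- markov_source(matrix(c(.8, .2, .3, .7), 2, byrow = TRUE),
                       alphabet = c("0", "1"))
  expect_identical(generate_markov(src, 300, seed = 4)$codes,
                   generate_markov(src, 300, seed = 4)$codes)
  d1 <- generate_corpus(corpus_recipe(vocabulary_size = 80),
                        target_length = 1500, seed = 6)
  d2 <- generate_corpus(corpus_recipe(vocabulary_size = 80),
                        target_length = 1500, seed = 6)
  expect_identical(d1$raw, d2$raw)
})

test_that("iid sources hit their analytic entropy rates", {
  # point mass: constant sequence
  s <- generate_iid(c("a", "b"), probabilities = c(1, 0), n = 1e4, seed = 1)
  expect_identical(unique(s$codes), 1L)
  expect_lt(entropy_rate(s)$h, 0.005)
  # uniform binary at moderate n: near 1 bit/symbol
  h <- entropy_rate(generate_iid(c("0", "1"), n = 2e4, seed = 2))$h
  expect_lt(abs(h - 1), 0.1)
  expect_error(generate_iid(c("a", "b"), probabilities = c(0.6, 0.6), n = 10),
               "distribution")
})

test_that("periodic generator repeats and truncates the motif", {
  expect_identical(as.character(generate_periodic("ab", 10)), "ababababab")
  expect_identical(as.character(generate_periodic("abc", 5)), "abcab")
  expect_error(generate_periodic("", 5), "nonempty")
})

test_that("markov analytic entropy matches brute force and edge cases", {
  p <- matrix(c(.9, .1, .1, .9), 2, byrow = TRUE)
  src <- markov_source(p)
  # closed form: binary entropy of the stay probability
  expect_equal(src$analytic_h, -(.9 * log2(.9) + .1 * log2(.1)),
               tolerance = 1e-12)
  expect_equal(src$stationary, c(.5, .5), tolerance = 1e-10)
  # brute force from stationary x rows
  brute <- -sum(vapply(1:2, function(i) {
    sum(src$stationary[i] * p[i, ] * log2(p[i, ]))
  }, numeric(1)))
  expect_equal(src$analytic_h, brute, tolerance = 1e-12)
  # uniform rows are i.i.d. uniform: h = 1
  expect_equal(markov_source(matrix(.5, 2, 2))$analytic_h, 1.0)
  # asymmetric chain: stationary from pi P = pi
  src2 <- markov_source(matrix(c(.7, .3, .2, .8), 2, byrow = TRUE))
  expect_equal(as.vector(src2$stationary %*% src2$transition),
               src2$stationary, tolerance = 1e-10)
  expect_error(markov_source(matrix(c(1, 1, 0, 1), 2)), "sum to 1")
})

test_that("the estimator approaches analytic h as n grows", {
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    median(vapply(1:5, function(s)
      abs(entropy_rate(generate_iid(c("0", "1"), n = n, seed = s))$h - 1),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("corpus generator produces genuine three-level structure", {
  doc <- generate_corpus(corpus_recipe(vocabulary_size = 150),
                         target_length = 4000, seed = 17)
  expect_identical(nchar(doc$final), 4000L)
  expect_false(grepl("[^a-z ]", doc$final))
  st <- corpus_stats(doc)
  expect_gt(st$vocabulary_size, 50L)
  expect_lte(st$word_use_entropy, log2(st$vocabulary_size))
  # raw text exercises the filter: uppercase and punctuation present
  expect_true(grepl("[A-Z]", doc$raw))
  expect_true(grepl("[.?!]", doc$raw))
})

test_that("template-free recipes carry no sentence-level signal", {
  recipe <- corpus_recipe(vocabulary_size = 150, template_reuse = 0,
                          n_templates = 1L)
  doc <- generate_corpus(recipe, target_length = 20000, seed = 23)
  v <- level_variants(doc, seed = 24)
  h_orig <- entropy_rate(v$original)$h
  h_sent <- entropy_rate(v$sentence)$h
  expect_lt(abs(h_sent - h_orig), 0.05)
})

test_that("near-uniform word use recovers V and S ~ log2 V", {
  recipe <- corpus_recipe(vocabulary_size = 100, zipf_exponent = 0,
                          template_reuse = 0, n_templates = 1L)
  doc <- generate_corpus(recipe, target_length = 20000, seed = 31)
  st <- corpus_stats(doc)
  expect_identical(st$vocabulary_size, 100L)
  expect_gt(st$word_use_entropy, 0.95 * log2(100))
})
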