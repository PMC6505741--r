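write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("text documents read from disk with derived ids", {
  p <- write_tmp("Hello!")
  doc <- read_text_document(p)
  expect_identical(doc$raw, "Hello!")
  expect_identical(doc$doc_id, sub("\\.txt$", "", basename(p)))
  expect_identical(doc$final, "hello")
  # empty file is accepted at read; estimators reject it downstream
  p0 <- write_tmp(character(0))
  d0 <- read_text_document(p0)
  expect_identical(d0$final, "")
  expect_error(read_text_document(tempfile()), "cannot read")
})

test_that("FASTA records round-trip with normalization and validation", {
  p <- write_tmp(c(">x", "ACGT", ">y desc", "acg", "ttn"), ext = ".fa")
  seqs <- read_fasta(p, dna = TRUE)
  expect_length(seqs, 2L)
  expect_identical(names(seqs), c("x", "y"))
  expect_identical(as.character(seqs$x), "ACGT")
  expect_identical(as.character(seqs$y), "ACGTTN")
  stripped <- read_fasta(p, dna = TRUE, strip_n = TRUE)
  expect_identical(as.character(stripped$y), "ACGTT")
  bad <- write_tmp(c(">z", "ACGU"), ext = ".fa")
  expect_error(read_fasta(bad, dna = TRUE), "outside the DNA alphabet")
})

test_that("run_analysis produces the expected row counts and determinism", {
  docs <- lapply(1:2, function(i)
    generate_corpus(corpus_recipe(vocabulary_size = 100),
                    target_length = 2000, seed = i,
                    doc_id = paste0("doc", i)))
  cfg <- run_config(truncate_to = 2000, m_max = 6, realizations = 2,
                    seed = 5)
  res <- run_analysis(cfg, docs = docs)
  expect_identical(nrow(res$points), 8L)  # 2 docs x 4 variants
  expect_identical(nrow(res$gains), 2L)
  expect_length(res$stats, 2L)
  # same config, same seed: identical output
  res2 <- run_analysis(cfg, docs = docs)
  expect_identical(res$points, res2$points)
  expect_identical(res$gains, res2$gains)
  # telescoping verifiable from the gains table alone
  for (i in 1:2) {
    hs <- res$points$h_bits[res$points$doc_id == paste0("doc", i)]
    gsum <- sum(res$gains[i, c("i_sentence", "i_word", "i_character")])
    expect_equal(gsum, hs[4] - hs[1], tolerance = 1e-12)
  }
})

test_that("dna-mode analysis includes codon-shuffle variant rows", {
  seqs <- list(generate_iid(c("A", "C", "G", "T"), n = 3000, seed = 8))
  attr(seqs[[1]], "doc_id") <- "chrTest"
  cfg <- run_config(format = "fasta", m_max = 6, realizations = 2,
                    seed = 9, unit_width = 3)
  res <- run_analysis(cfg, docs = seqs)
  expect_identical(res$points$variant, c("original", "unit", "character"))
  expect_identical(res$points$doc_id, rep("chrTest", 3L))
  expect_true(all(c("i_unit", "i_character") %in% names(res$gains)))
})

test_that("result tables round-trip through TSV and JSON", {
  docs <- list(generate_corpus(corpus_recipe(vocabulary_size = 80),
                               target_length = 1500, seed = 3))
  cfg <- run_config(truncate_to = 1500, m_max = 5, realizations = 2,
                    seed = 7)
  res <- run_analysis(cfg, docs = docs)
  for (fmt in c("tsv", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_results(res, path, fmt)
    back <- read_results(path, fmt)
    expect_identical(nrow(back$points), nrow(res$points))
    expect_identical(back$points$variant, res$points$variant)
    # lossless at the written 6-significant-digit precision
    expect_equal(back$points$h_bits, res$points$h_bits, tolerance = 1e-5)
    expect_equal(back$gains$i_word, res$gains$i_word, tolerance = 1e-5)
  }
  # rerun writes byte-identical output
  p1 <- tempfile(); p2 <- tempfile()
  write_results(run_analysis(cfg, docs = docs), p1, "tsv")
  write_results(run_analysis(cfg, docs = docs), p2, "tsv")
  expect_identical(readLines(p1), readLines(p2))
  # header-only file for empty record sets
  empty <- list(points = res$points[0, ], gains = res$gains[0, ],
                config = cfg)
  p3 <- tempfile()
  write_results(empty, p3, "tsv")
  lines <- readLines(p3)
  expect_true(any(startsWith(lines, "doc_id\t")))
  expect_identical(sum(!startsWith(lines, "#")), 1L)
})
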