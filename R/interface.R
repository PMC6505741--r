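#' Read a plain-text document
#'
#' Read a UTF-8 text file into a [text_document()], deriving `doc_id`
#' from the file name unless overridden.
#'
#' @param path path to a UTF-8 text file.
#' @param doc_id document label; default is the file name without
#'   extension.
#' @param ... passed to [text_document()] (`truncate_to`,
#'   `collapse_spaces`, `allow_short`).
#' @return A [text_document()].
#' @export
read_text_document <- function(path, doc_id = NULL, ...) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  raw <- tryCatch(
    paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n"),
    error = function(e) stop("failed to read ", path, ": ",
                             conditionMessage(e)))
  if (is.null(doc_id)) doc_id <- sub("\\.[^.]*$", "", basename(path))
  text_document(raw, doc_id = doc_id, ...)
}

#' Read FASTA sequences
#'
#' Read a FASTA file into a list of [symbol_seq()]s, one per record,
#' uppercase-normalized, with record ids preserved as names.  In DNA mode
#' the alphabet is validated against A/C/G/T/N ('N' is retained as a
#' fifth symbol by default; `strip_n = TRUE` removes it).
#'
#' @param path path to a FASTA file.
#' @param dna validate symbols against the DNA alphabet.
#' @param strip_n drop 'N' symbols (DNA mode only).
#' @return Named list of `symbol_seq` objects, in file order.
#' @export
read_fasta <- function(path, dna = FALSE, strip_n = FALSE) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                       whole.header = FALSE),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e)))
  if (length(recs) == 0L) stop("no FASTA records found in ", path)
  out <- lapply(seq_along(recs), function(i) {
    s <- toupper(as.character(recs[[i]]))
    if (dna) {
      if (strip_n) s <- gsub("N", "", s, fixed = TRUE)
      chars <- unique(strsplit(s, "", fixed = TRUE)[[1L]])
      bad <- setdiff(chars, c("A", "C", "G", "T", "N"))
      if (length(bad))
        stop("record ", names(recs)[i],
             " contains symbols outside the DNA alphabet: ",
             paste(sQuote(bad), collapse = ", "))
    }
    symbol_seq(s)
  })
  names(out) <- names(recs)
  out
}

#' Run configuration
#'
#' Bundle all pipeline parameters.  Defaults reproduce the conventional
#' comparative-text settings: truncation to 78000 characters, block-length
#' cap \eqn{M_m = 40}, 10 shuffle realizations per block length, and the
#' 27-symbol filtered alphabet.
#'
#' @param inputs character vector of input file paths.
#' @param format `"text"` or `"fasta"`.
#' @param truncate_to final-text truncation length (text mode).
#' @param m_max,realizations [excess_entropy()] settings.
#' @param seed integer run seed.
#' @param collapse_spaces passed to the filter.
#' @param word_delimiter word delimiter for word shuffles.
#' @param unit_width fixed-width unit size for FASTA mode (e.g. 3 for
#'   codons), or `NULL` to skip the unit level.
#' @param output optional output file path.
#' @param output_format `"tsv"` or `"json"`.
#' @param dna,strip_n FASTA options, see [read_fasta()].
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(inputs = character(0), format = c("text", "fasta"),
                       truncate_to = 78000L, m_max = 40L, realizations = 10L,
                       seed = 1L, collapse_spaces = TRUE,
                       word_delimiter = " ", unit_width = NULL,
                       output = NULL, output_format = c("tsv", "json"),
                       dna = TRUE, strip_n = FALSE) {
  format <- match.arg(format)
  output_format <- match.arg(output_format)
  stopifnot(m_max >= 1L, realizations >= 1L,
            is.null(truncate_to) || truncate_to >= 1,
            is.null(unit_width) || unit_width >= 1)
  structure(list(inputs = inputs, format = format,
                 truncate_to = truncate_to, m_max = as.integer(m_max),
                 realizations = as.integer(realizations),
                 seed = as.integer(seed),
                 collapse_spaces = collapse_spaces,
                 word_delimiter = word_delimiter,
                 unit_width = if (is.null(unit_width)) NULL
                              else as.integer(unit_width),
                 output = output, output_format = output_format,
                 dna = dna, strip_n = strip_n),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' For each input document: preprocess (text mode), build the level
#' variant set, estimate entropy rate and excess entropy for every
#' variant, decompose the gains, and compute corpus statistics.  In FASTA
#' mode the levels are the fixed-width unit (when `unit_width` is set)
#' and the character shuffle.
#'
#' In addition to file paths, `docs` may carry pre-built
#' [text_document()]s (text mode) or `symbol_seq`s (fasta mode), which
#' makes the pipeline usable on synthetic corpora without touching disk.
#'
#' @param config a [run_config()].
#' @param docs optional list of in-memory documents overriding
#'   `config$inputs`.
#' @return A list of class `"lzce_results"`: `points` (data.frame, one
#'   row per document and variant), `gains` (one row per document),
#'   `stats` (corpus statistics, text mode), `decompositions`, `config`.
#'   If `config$output` is set the results are also written via
#'   [write_results()].
#' @export
run_analysis <- function(config, docs = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(docs)) {
    if (length(config$inputs) == 0L) stop("no inputs in config")
    docs <- if (config$format == "text") {
      lapply(config$inputs, function(p)
        read_text_document(p, truncate_to = config$truncate_to,
                           collapse_spaces = config$collapse_spaces))
    } else {
      unlist(lapply(config$inputs, function(p) {
        recs <- read_fasta(p, dna = config$dna, strip_n = config$strip_n)
        for (i in seq_along(recs)) attr(recs[[i]], "doc_id") <- names(recs)[i]
        recs
      }), recursive = FALSE)
    }
  }
  decomps <- vector("list", length(docs))
  stats_list <- list()
  for (i in seq_along(docs)) {
    d <- docs[[i]]
    doc_seed <- substream_seed(config$seed, 0L, i)
    if (config$format == "text") {
      stopifnot(inherits(d, "text_document"))
      v <- level_variants(d, seed = doc_seed,
                          word_delimiter = config$word_delimiter)
      g <- decompose_levels(v, m_max = config$m_max,
                            realizations = config$realizations,
                            seed = doc_seed)
      stats_list[[d$doc_id]] <- corpus_stats(d)
    } else {
      s <- symbol_seq(d)
      did <- attr(d, "doc_id") %||% paste0("seq", i)
      vars <- list(original = s)
      if (!is.null(config$unit_width)) {
        vars$unit <- shuffle_fixed_width_units(
          s, config$unit_width, seed = substream_seed(doc_seed, 1L, 1L))
      }
      vars$character <- block_shuffle(
        s, 1L, seed = substream_seed(doc_seed, 2L, 1L))
      attr(vars, "doc_id") <- did
      g <- decompose_levels(vars, m_max = config$m_max,
                            realizations = config$realizations,
                            seed = doc_seed)
    }
    decomps[[i]] <- g
  }
  points <- map_points(decomps)
  gains <- do.call(rbind, lapply(decomps, gains_row))
  structure_res <- structure(list(points = points, gains = gains,
                                  stats = stats_list,
                                  decompositions = decomps,
                                  config = config),
                             class = "lzce_results")
  if (!is.null(config$output))
    write_results(structure_res, config$output, config$output_format)
  structure_res
}

gains_row <- function(g) {
  row <- data.frame(doc_id = g$doc_id, stringsAsFactors = FALSE)
  for (lv in names(g$info_gain)) row[[paste0("i_", lv)]] <- g$info_gain[[lv]]
  for (lv in names(g$ee_gain)) row[[paste0("de_", lv)]] <- g$ee_gain[[lv]]
  row$d_s <- g$d_s
  row
}

#' @export
print.lzce_results <- function(x, ...) {
  cat("LZ complexity-entropy analysis:", length(x$decompositions),
      "document(s)\n\nPoints:\n")
  print(x$points, digits = 4)
  cat("\nGains:\n")
  print(x$gains, digits = 4)
  invisible(x)
}

# fixed significant-digit formatting so written output is byte-stable
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", trimws(formatC(x, format = "g", digits = 6)))
}

#' Write and read result tables
#'
#' Serialize analysis results as a single delimited table (or JSON
#' lines): one `point` row per (document, variant) and one `gains` row
#' per document, with the run configuration in `#`-prefixed header lines.
#' Floats are written with 6 significant digits; `read_results()` reads
#' the table back losslessly at that precision.
#'
#' @param results an `"lzce_results"` object (or a list with `points` and
#'   `gains` data.frames).
#' @param path output file path.
#' @param format `"tsv"` or `"json"` (JSON lines).
#' @return `write_results()`: the path, invisibly.  `read_results()`: a
#'   list with `points` and `gains` data.frames.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  points <- results$points
  gains <- results$gains
  gcols <- setdiff(names(gains), "doc_id")
  pcols <- setdiff(names(points), "doc_id")
  all_cols <- c("doc_id", "row_type", "variant", "n", "c_lz", "h_bits",
                "e_bits", gcols)
  prows <- points
  prows$row_type <- rep("point", nrow(points))
  grows <- gains
  grows$row_type <- rep("gains", nrow(gains))
  for (cc in setdiff(all_cols, names(prows)))
    prows[[cc]] <- rep(NA, nrow(prows))
  for (cc in setdiff(all_cols, names(grows)))
    grows[[cc]] <- rep(NA, nrow(grows))
  tab <- rbind(prows[all_cols], grows[all_cols])

  header <- character(0)
  cfg <- results$config
  if (!is.null(cfg)) {
    keep <- c("format", "truncate_to", "m_max", "realizations", "seed",
              "collapse_spaces", "word_delimiter", "unit_width")
    vals <- lapply(keep, function(k) cfg[[k]])
    header <- vapply(seq_along(keep), function(i) {
      paste0("# ", keep[i], "=",
             if (is.null(vals[[i]])) "NULL" else format(vals[[i]]))
    }, character(1))
  }
  num <- vapply(tab, is.numeric, logical(1))
  out <- tab
  for (cc in names(tab)[num]) out[[cc]] <- fmt_num(tab[[cc]])

  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header)) writeLines(header, con)
    writeLines(paste(all_cols, collapse = "\t"), con)
    apply_rows <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(apply_rows, con)
  } else {
    lines <- vapply(seq_len(nrow(tab)), function(i) {
      jsonlite::toJSON(as.list(tab[i, , drop = FALSE]), auto_unbox = TRUE,
                       digits = NA, na = "null")
    }, character(1))
    writeLines(c(header, lines), path)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    rows <- lapply(lines, function(l) {
      r <- jsonlite::fromJSON(l)
      r[vapply(r, is.null, logical(1))] <- NA
      as.data.frame(r, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
  }
  pts <- tab[tab$row_type == "point",
             c("doc_id", "variant", "n", "c_lz", "h_bits", "e_bits")]
  gcols <- setdiff(names(tab),
                   c("row_type", "variant", "n", "c_lz", "h_bits", "e_bits"))
  gns <- tab[tab$row_type == "gains", gcols]
  rownames(pts) <- rownames(gns) <- NULL
  list(points = pts, gains = gns)
}
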