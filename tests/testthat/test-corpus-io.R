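bg_text <- function(n) paste(rep("x", n), collapse = "")

test_that("split_document cuts at periods and respects max_len", {
  # 300 chars with periods at 0-based offsets 99 and 199 -> three windows of
  # 100 (each keeps its terminal period)
  txt <- paste0(bg_text(99), "。", bg_text(99), "。", bg_text(100))
  doc <- raw_document("d1", txt)
  w <- split_document(doc, max_len = 128L)
  expect_length(w, 3L)
  expect_equal(vapply(w, function(x) length(x$chars), integer(1)),
               c(100L, 100L, 100L))
  expect_equal(vapply(w, function(x) x$doc_offset, integer(1)),
               c(0L, 100L, 200L))
  # no period, exactly max_len -> a single window
  w2 <- split_document(raw_document("d2", bg_text(128)), max_len = 128L)
  expect_length(w2, 1L)
  expect_length(w2[[1L]]$chars, 128L)
})

test_that("annotations are re-offset into window coordinates", {
  txt <- paste0(bg_text(99), "。", bg_text(200))
  doc <- raw_document("d", txt, entity_mentions(150, 155, "DIS"))
  w <- split_document(doc, max_len = 128L)
  second <- w[[2L]]
  expect_equal(second$doc_offset, 100L)
  expect_identical(second$mentions, entity_mentions(50, 55, "DIS"))
  # slicing the document at the recovered coordinates gives the same chars
  loc <- second$mentions
  expect_identical(second$chars[(loc$start + 1L):loc$end],
                   doc$chars[(second$doc_offset + loc$start + 1L):
                               (second$doc_offset + loc$end)])
})

test_that("mention crossing a period boundary is an error", {
  txt <- paste0(bg_text(10), "。", bg_text(10))
  doc <- raw_document("bad-doc", txt, entity_mentions(8, 13, "DIS"))
  expect_error(split_document(doc), "bad-doc.*crosses", perl = TRUE)
})

test_that("hard splits back off to mention gaps and flag unavoidable cuts", {
  # sentence of 40 chars, max_len 30, mention at (25, 35): the cut backs off
  # to 25 so the mention stays whole in the second window
  doc <- raw_document("d", bg_text(40), entity_mentions(25, 35, "DIS"))
  w <- split_document(doc, max_len = 30L)
  expect_equal(vapply(w, function(x) x$doc_offset, integer(1)), c(0L, 25L))
  expect_identical(w[[2L]]$mentions, entity_mentions(0, 10, "DIS"))
  expect_false(any(vapply(w, function(x) x$truncated_mention, logical(1))))
  # a single mention longer than max_len is split and flagged
  doc2 <- raw_document("d2", bg_text(20), entity_mentions(0, 15, "DIS"))
  w2 <- split_document(doc2, max_len = 10L)
  expect_true(any(vapply(w2, function(x) x$truncated_mention, logical(1))))
})

test_that("splitting preserves text and total mention count", {
  spec <- generator_spec(seed = 3)
  docs <- generate_documents(spec, 5, sentences_per_doc = 3)
  for (doc in docs) {
    w <- split_document(doc, max_len = 128L)
    expect_identical(paste(unlist(lapply(w, `[[`, "chars")), collapse = ""),
                     doc$text)
    expect_equal(sum(vapply(w, function(x) nrow(x$mentions), integer(1))),
                 nrow(doc$annotations))
  }
})

test_that("CoNLL write/read round-trips and validates input", {
  spec <- generator_spec(seed = 9)
  sents <- generate_corpus(spec, 100)
  path <- withr::local_tempfile(fileext = ".conll")
  write_conll(sents, path)
  back <- read_conll(path)
  expect_length(back, length(sents))
  for (i in seq_along(sents)) {
    expect_identical(back[[i]]$chars, sents[[i]]$chars)
    expect_identical(back[[i]]$tags, sents[[i]]$tags)
  }
  # single line parses into char + label
  p2 <- withr::local_tempfile()
  writeLines(c("胃 B-DIS", "癌 I-DIS"), p2)
  s <- read_conll(p2)
  expect_identical(s[[1L]]$chars, c("胃", "癌"))
  expect_identical(s[[1L]]$tags, c("B-DIS", "I-DIS"))
  # unknown label reported with its line number
  p3 <- withr::local_tempfile()
  writeLines(c("a O", "b B-XYZ"), p3)
  expect_error(read_conll(p3), ":2:.*B-XYZ")
  p4 <- withr::local_tempfile()
  writeLines(c("a O b"), p4)
  expect_error(read_conll(p4), ":1:")
  p5 <- withr::local_tempfile()
  writeLines(character(), p5)
  expect_error(read_conll(p5), "empty")
})

test_that("span-json reader maps type names and validates offsets", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  rec <- jsonlite::toJSON(list(
    doc_id = "r1", originalText = "0123456789",
    entities = data.frame(start_pos = 0L, end_pos = 2L,
                          label_type = "疾病和诊断")),
    auto_unbox = TRUE)
  writeLines(enc2utf8(rec), path, useBytes = TRUE)
  docs <- read_span_json(path,
                         type_map = c("疾病和诊断" = "DIS"))
  expect_identical(docs[[1L]]$annotations, entity_mentions(0, 2, "DIS"))
  # inclusive-end dialect
  docs2 <- read_span_json(path, end_exclusive = FALSE,
                          type_map = c("疾病和诊断" = "DIS"))
  expect_equal(docs2[[1L]]$annotations$end, 3L)
  # unmapped type name
  expect_error(read_span_json(path, type_map = c(other = "DIS")), "unmapped")
  # overlapping mentions rejected, empty annotation list accepted
  p2 <- withr::local_tempfile()
  bad <- jsonlite::toJSON(list(
    doc_id = "r2", originalText = "0123456789",
    entities = data.frame(start_pos = c(0L, 2L), end_pos = c(3L, 5L),
                          label_type = c("DIS", "OPE"))), auto_unbox = TRUE)
  writeLines(bad, p2)
  expect_error(read_span_json(p2), "overlap")
  p3 <- withr::local_tempfile()
  writeLines(jsonlite::toJSON(list(doc_id = "r3", originalText = "abc",
                                   entities = list()), auto_unbox = TRUE), p3)
  expect_equal(nrow(read_span_json(p3)[[1L]]$annotations), 0L)
})

test_that("span-json write/read round-trips generated documents", {
  spec <- generator_spec(seed = 21)
  docs <- generate_documents(spec, 4, sentences_per_doc = 2)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_span_json(docs, path)
  back <- read_span_json(path)
  expect_length(back, length(docs))
  for (i in seq_along(docs)) {
    expect_identical(back[[i]]$text, docs[[i]]$text)
    expect_equal(back[[i]]$annotations$start, docs[[i]]$annotations$start)
    expect_equal(back[[i]]$annotations$end, docs[[i]]$annotations$end)
    expect_equal(back[[i]]$annotations$type, docs[[i]]$annotations$type)
  }
})
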