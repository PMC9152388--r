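#' A span-annotated clinical document
#'
#' A raw record as distributed in span-annotated corpora: the full text plus
#' document-level entity mentions (0-based, half-open offsets).
#'
#' @param doc_id Document identifier string.
#' @param text Single string (the record text).
#' @param annotations An [entity_mentions()] data frame in document offsets.
#' @param schema A [tag_schema()].
#' @return An object of class `raw_document`.
#' @export
raw_document <- function(doc_id, text, annotations = entity_mentions(),
                         schema = tag_schema()) {
  chars <- strsplit(text, "")[[1L]]
  tryCatch(
    validate_mentions(annotations, length(chars), schema),
    error = function(e) stop("document ", doc_id, ": ", conditionMessage(e))
  )
  structure(list(doc_id = doc_id, text = text, chars = chars,
                 annotations = annotations),
            class = "raw_document")
}

#' Split a document into sentence windows
#'
#' Cuts the record text at the ideographic full stop (`"。"`), keeping
#' each period with the preceding sentence. Any sentence still longer than
#' `max_len` is hard-split at `max_len` boundaries, backing off to the
#' nearest gap between mentions so that no annotated span is cut when that
#' is avoidable; a single mention longer than `max_len` is split and the
#' affected windows are flagged. Document-level annotations are re-offset
#' into window-local coordinates. A mention that straddles a period boundary
#' is an error.
#'
#' @param doc A [raw_document()].
#' @param max_len Maximum window length in characters (default 128).
#' @param schema A [tag_schema()].
#' @return A list of `sentence_window` objects, each with `doc_id`,
#'   `sentence_index`, `doc_offset`, `chars`, `tags`, `mentions` and
#'   `truncated_mention` (flag).
#' @export
split_document <- function(doc, max_len = 128L, schema = tag_schema()) {
  max_len <- as.integer(max_len)
  if (max_len < 2L) stop("max_len must be >= 2")
  chars <- doc$chars
  n <- length(chars)
  ann <- doc$annotations
  # sentence boundaries: period kept with preceding sentence
  stops <- which(chars == "。")
  sent_ends <- unique(c(stops, n))
  sent_starts <- c(0L, sent_ends[-length(sent_ends)])
  windows <- list()
  si <- 0L
  for (k in seq_along(sent_starts)) {
    s0 <- sent_starts[k]; e0 <- sent_ends[k]   # [s0, e0) 0-based
    if (e0 <= s0) next
    cross <- which(ann$start < e0 & ann$end > e0 & ann$start >= s0)
    straddle <- which(ann$start < e0 & ann$end > e0)
    if (length(straddle)) {
      i <- straddle[1L]
      stop(sprintf("document %s: mention (%d,%d,%s) crosses a period boundary at %d",
                   doc$doc_id, ann$start[i], ann$end[i], ann$type[i], e0))
    }
    # sub-split the sentence at max_len with mention-aware backoff
    pos <- s0
    while (pos < e0) {
      flag <- FALSE
      cut <- min(pos + max_len, e0)
      if (cut < e0) {
        inside <- which(ann$start < cut & ann$end > cut)
        if (length(inside)) {
          back <- ann$start[inside[1L]]
          if (back > pos) {
            cut <- back
          } else {
            # a single mention longer than max_len: split it and flag
            flag <- TRUE
          }
        }
      }
      w_ann <- ann[ann$start >= pos & ann$end <= cut, , drop = FALSE]
      if (flag) {
        part <- which(ann$start < cut & ann$end > cut)
        for (i in part) {
          w_ann <- rbind(w_ann, data.frame(start = max(ann$start[i], pos),
                                           end = cut, type = ann$type[i],
                                           stringsAsFactors = FALSE))
        }
      }
      # mentions begun by an earlier flagged split
      lead <- which(ann$start < pos & ann$end > pos & ann$end <= cut)
      for (i in lead) {
        flag <- TRUE
        w_ann <- rbind(w_ann, data.frame(start = pos, end = ann$end[i],
                                         type = ann$type[i],
                                         stringsAsFactors = FALSE))
      }
      w_ann$start <- as.integer(w_ann$start - pos)
      w_ann$end <- as.integer(w_ann$end - pos)
      class(w_ann) <- c("entity_mentions", "data.frame")
      w_ann <- w_ann[order(w_ann$start), , drop = FALSE]
      w_chars <- chars[(pos + 1L):cut]
      si <- si + 1L
      windows[[si]] <- structure(
        list(doc_id = doc$doc_id, sentence_index = si, doc_offset = pos,
             chars = w_chars,
             tags = encode_tags(w_ann, length(w_chars), schema),
             mentions = w_ann, truncated_mention = flag),
        class = c("sentence_window", "labeled_sentence"))
      pos <- cut
    }
  }
  windows
}

#' Read a CoNLL-style corpus
#'
#' One character and one BIO label per line separated by whitespace; blank
#' lines separate sentences. Labels are validated against the schema with the
#' strict decoding policy (gold data must be well-formed).
#'
#' @param path File path (UTF-8).
#' @param schema A [tag_schema()].
#' @param strict Validate tag sequences with `decode_tags(policy="strict")`.
#' @return List of [labeled_sentence()] objects.
#' @export
read_conll <- function(path, schema = tag_schema(), strict = TRUE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines)))) {
    stop("empty CoNLL file: ", path)
  }
  sentences <- list()
  chars <- character(); tags <- character()
  flush <- function() {
    if (length(chars)) {
      ts <- tags
      if (strict) decode_tags(ts, schema, policy = "strict")
      sentences[[length(sentences) + 1L]] <<-
        labeled_sentence(chars, ts, schema = schema)
    }
    chars <<- character(); tags <<- character()
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) { flush(); next }
    fields <- strsplit(trimws(line), "[ \t]+")[[1L]]
    if (length(fields) != 2L) {
      stop(sprintf("%s:%d: expected 'char label', got %d field(s)",
                   path, ln, length(fields)))
    }
    if (!fields[2L] %in% schema$tags) {
      stop(sprintf("%s:%d: unknown label '%s'", path, ln, fields[2L]))
    }
    chars[length(chars) + 1L] <- fields[1L]
    tags[length(tags) + 1L] <- fields[2L]
  }
  flush()
  sentences
}

#' Write a CoNLL-style corpus
#'
#' @param sentences List of [labeled_sentence()] objects.
#' @param path Output file path.
#' @export
write_conll <- function(sentences, path) {
  blocks <- vapply(sentences, function(s) {
    paste(paste(s$chars, s$tags), collapse = "\n")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(paste(blocks, collapse = "\n\n")), con, useBytes = TRUE)
  invisible(path)
}

#' Read span-annotated documents (line-delimited JSON)
#'
#' Each line is a JSON record with fields `originalText` and `entities`, the
#' latter a list of `{start_pos, end_pos, label_type}`. Type names are mapped
#' to schema codes via `type_map` so that native-language category names and
#' bare codes both load. End offsets may be exclusive (default) or inclusive.
#'
#' @param path File path.
#' @param type_map Named character vector, label name -> type code. Defaults
#'   to the identity map over the schema's own codes.
#' @param end_exclusive Logical; if `FALSE`, `end_pos` is inclusive and 1 is
#'   added on load.
#' @param schema A [tag_schema()].
#' @return List of [raw_document()] objects.
#' @export
read_span_json <- function(path, type_map = NULL, end_exclusive = TRUE,
                           schema = tag_schema()) {
  if (is.null(type_map)) {
    type_map <- stats::setNames(schema$types, schema$types)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[i], simplifyVector = TRUE)
    doc_id <- if (!is.null(rec$doc_id)) rec$doc_id else paste0("doc", i)
    ents <- rec$entities
    if (is.null(ents) || NROW(ents) == 0L) {
      ann <- entity_mentions()
    } else {
      labs <- as.character(ents$label_type)
      unmapped <- setdiff(labs, names(type_map))
      if (length(unmapped)) {
        stop("document ", doc_id, ": unmapped entity type name(s): ",
             paste(unique(unmapped), collapse = ", "))
      }
      ends <- as.integer(ents$end_pos) + if (end_exclusive) 0L else 1L
      ann <- entity_mentions(as.integer(ents$start_pos), ends,
                             unname(type_map[labs]))
      ann <- ann[order(ann$start), , drop = FALSE]
      class(ann) <- c("entity_mentions", "data.frame")
    }
    docs[[i]] <- raw_document(doc_id, rec$originalText, ann, schema)
  }
  docs
}

#' Write span-annotated documents as line-delimited JSON
#'
#' Inverse of [read_span_json()] with `end_exclusive = TRUE` and identity
#' type mapping.
#'
#' @param docs List of [raw_document()] objects.
#' @param path Output file path.
#' @export
write_span_json <- function(docs, path) {
  lines <- vapply(docs, function(d) {
    ents <- if (nrow(d$annotations)) {
      data.frame(start_pos = d$annotations$start,
                 end_pos = d$annotations$end,
                 label_type = d$annotations$type,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(start_pos = integer(), end_pos = integer(),
                 label_type = character())
    }
    jsonlite::toJSON(list(doc_id = d$doc_id, originalText = d$text,
                          entities = ents),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}
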