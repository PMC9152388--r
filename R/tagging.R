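#' BIO tag schema over clinical entity types
#'
#' Builds the closed label inventory used throughout the package: the null
#' label `"O"` first, then `B-X`/`I-X` for each entity type `X`, in type
#' order. The default types are the six clinical categories: disease (DIS),
#' exam (EXA), test (TES), operation (OPE), drug (DRU) and anatomy (ANA).
#'
#' Label integer indices are 0-based with `"O"` fixed at index 0, so
#' zero-initialized predictions decode to the null label.
#'
#' @param types Character vector of entity-type codes, in reporting order.
#' @return An object of class `tag_schema` with elements `types`, `tags`
#'   (label strings), and `tag_index` (named integer vector, label -> 0-based
#'   index).
#' @examples
#' sch <- tag_schema()
#' sch$tags[1:3]   # "O" "B-DIS" "I-DIS"
#' @export
tag_schema <- function(types = c("DIS", "EXA", "TES", "OPE", "DRU", "ANA")) {
  types <- as.character(types)
  if (length(types) < 1L || anyDuplicated(types) || any(!nzchar(types))) {
    stop("`types` must be a non-empty vector of distinct, non-empty codes")
  }
  tags <- c("O", as.vector(rbind(paste0("B-", types), paste0("I-", types))))
  idx <- seq_along(tags) - 1L
  names(idx) <- tags
  structure(
    list(types = types, tags = tags, tag_index = idx),
    class = "tag_schema"
  )
}

#' @export
print.tag_schema <- function(x, ...) {
  cat("<tag_schema> ", length(x$types), " entity types, ",
      length(x$tags), " labels\n", sep = "")
  cat("  types:", paste(x$types, collapse = " "), "\n")
  invisible(x)
}

n_labels <- function(schema) length(schema$tags)

#' Create an entity-mention table
#'
#' Mentions are stored as a data frame with 0-based, half-open character
#' offsets: `start` is the first character of the mention, `end` is one past
#' the last. Columns: `start`, `end`, `type`.
#'
#' @param start,end Integer vectors of offsets, `0 <= start < end`.
#' @param type Character vector of entity-type codes.
#' @return A data frame with class `entity_mentions`.
#' @export
entity_mentions <- function(start = integer(), end = integer(),
                            type = character()) {
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   type = as.character(type), stringsAsFactors = FALSE)
  class(df) <- c("entity_mentions", "data.frame")
  df
}

validate_mentions <- function(mentions, length, schema) {
  if (nrow(mentions) == 0L) return(invisible(mentions))
  bad_type <- setdiff(mentions$type, schema$types)
  if (length(bad_type)) {
    stop("unknown entity type(s): ", paste(bad_type, collapse = ", "))
  }
  if (any(mentions$start < 0L) || any(mentions$start >= mentions$end) ||
      any(mentions$end > length)) {
    i <- which(mentions$start < 0L | mentions$start >= mentions$end |
                 mentions$end > length)[1L]
    stop(sprintf("mention (%d,%d,%s) out of range for length %d",
                 mentions$start[i], mentions$end[i], mentions$type[i], length))
  }
  o <- order(mentions$start)
  s <- mentions$start[o]; e <- mentions$end[o]
  if (nrow(mentions) > 1L && any(s[-1L] < e[-nrow(mentions)])) {
    k <- which(s[-1L] < e[-nrow(mentions)])[1L]
    stop(sprintf("overlapping mentions: (%d,%d) and (%d,%d)",
                 s[k], e[k], s[k + 1L], e[k + 1L]))
  }
  invisible(mentions)
}

#' Encode entity mentions as a BIO tag sequence
#'
#' Position `start` receives `B-type`, positions `start+1 .. end-1` receive
#' `I-type`, and every other position is `"O"`. Offsets are 0-based and
#' half-open.
#'
#' @param mentions An [entity_mentions()] data frame (non-overlapping spans).
#' @param length Sentence length in characters.
#' @param schema A [tag_schema()].
#' @return Character vector of `length` labels.
#' @examples
#' encode_tags(entity_mentions(3, 5, "DIS"), 6)
#' @export
encode_tags <- function(mentions, length, schema = tag_schema()) {
  length <- as.integer(length)
  validate_mentions(mentions, length, schema)
  tags <- rep("O", length)
  for (i in seq_len(nrow(mentions))) {
    s <- mentions$start[i]; e <- mentions$end[i]; ty <- mentions$type[i]
    tags[s + 1L] <- paste0("B-", ty)
    if (e - s > 1L) tags[(s + 2L):e] <- paste0("I-", ty)
  }
  tags
}

#' Decode a BIO tag sequence into entity mentions
#'
#' Maximal `B-X (I-X)*` runs become mentions. Under `policy = "strict"` an
#' `I-X` not preceded by `B-X`/`I-X` of the same type is an error (use this
#' for gold data); under `policy = "repair"` such an `I-X` opens a new
#' mention as if it were `B-X` (use this for model predictions, which may be
#' ill-formed).
#'
#' @param tags Character vector of labels, all members of `schema$tags`.
#' @param schema A [tag_schema()].
#' @param policy `"repair"` (default) or `"strict"`.
#' @return An [entity_mentions()] data frame.
#' @export
decode_tags <- function(tags, schema = tag_schema(),
                        policy = c("repair", "strict")) {
  policy <- match.arg(policy)
  unknown <- setdiff(tags, schema$tags)
  if (length(unknown)) {
    stop("unknown label(s): ", paste(unique(unknown), collapse = ", "))
  }
  starts <- integer(); ends <- integer(); types <- character()
  cur_type <- NA_character_; cur_start <- NA_integer_
  close_cur <- function(pos) {
    if (!is.na(cur_type)) {
      starts[[length(starts) + 1L]] <<- cur_start
      ends[[length(ends) + 1L]] <<- pos
      types[[length(types) + 1L]] <<- cur_type
    }
  }
  for (t in seq_along(tags)) {
    lab <- tags[t]
    if (lab == "O") {
      close_cur(t - 1L); cur_type <- NA_character_
    } else {
      pre <- substr(lab, 1L, 1L)
      ty <- substring(lab, 3L)
      if (pre == "B") {
        close_cur(t - 1L)
        cur_type <- ty; cur_start <- t - 1L
      } else { # I-
        if (!is.na(cur_type) && cur_type == ty) {
          # continue current mention
        } else if (policy == "strict") {
          stop(sprintf("illegal tag sequence at position %d: %s not preceded by B-%s/I-%s",
                       t - 1L, lab, ty, ty))
        } else {
          close_cur(t - 1L)
          cur_type <- ty; cur_start <- t - 1L
        }
      }
    }
  }
  close_cur(length(tags))
  entity_mentions(starts, ends, types)
}

#' Is a label transition legal under BIO semantics?
#'
#' A transition is legal iff the next label is `"O"`, any `B-X`, or `I-X`
#' preceded by `B-X`/`I-X` of the same type `X`.
#'
#' @param from,to Label strings in `schema$tags`.
#' @param schema A [tag_schema()].
#' @return Logical scalar (vectorized over `from`/`to`).
#' @export
legal_transition <- function(from, to, schema = tag_schema()) {
  bad <- setdiff(c(from, to), schema$tags)
  if (length(bad)) stop("unknown label(s): ", paste(unique(bad), collapse = ", "))
  n <- max(length(from), length(to))
  from <- rep_len(from, n); to <- rep_len(to, n)
  to_pre <- substr(to, 1L, 1L)
  ok <- to == "O" | to_pre == "B"
  is_i <- to_pre == "I"
  if (any(is_i)) {
    ty <- substring(to[is_i], 3L)
    ok[is_i] <- from[is_i] == paste0("B-", ty) | from[is_i] == paste0("I-", ty)
  }
  ok
}

#' A labeled sentence: characters with aligned BIO tags
#'
#' @param chars Character vector, one code point per element (a single string
#'   is split into characters).
#' @param tags Character vector of labels, same length as `chars`; if `NULL`,
#'   derived from `mentions`.
#' @param mentions Optional [entity_mentions()] used when `tags` is `NULL`.
#' @param schema A [tag_schema()].
#' @return An object of class `labeled_sentence` with `chars`, `tags` and the
#'   derived `mentions`.
#' @export
labeled_sentence <- function(chars, tags = NULL, mentions = NULL,
                             schema = tag_schema()) {
  if (length(chars) == 1L && nchar(chars[1L]) > 1L) {
    chars <- strsplit(chars, "", fixed = FALSE)[[1L]]
  }
  if (is.null(tags)) {
    if (is.null(mentions)) mentions <- entity_mentions()
    tags <- encode_tags(mentions, length(chars), schema)
  }
  if (length(chars) != length(tags)) {
    stop("chars and tags must have equal length (",
         length(chars), " vs ", length(tags), ")")
  }
  structure(
    list(chars = chars, tags = tags,
         mentions = decode_tags(tags, schema, policy = "repair")),
    class = "labeled_sentence"
  )
}

#' @export
print.labeled_sentence <- function(x, ...) {
  cat("<labeled_sentence> ", length(x$chars), " chars, ",
      nrow(x$mentions), " mentions\n", sep = "")
  cat(" ", paste(x$chars, collapse = ""), "\n")
  invisible(x)
}
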