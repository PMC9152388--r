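#' Sinusoidal positional encoding
#'
#' The fixed transformer-style encoding: even coordinate `2i` of position
#' `pos` is `sin(pos / 10000^(2i/d_model))` and odd coordinate `2i+1` is
#' `cos(pos / 10000^(2i/d_model))`. Both `pos` and `dim_index` are 0-based.
#'
#' @param pos Position index (0-based), vectorized.
#' @param dim_index Coordinate index in `0 .. d_model-1`, vectorized.
#' @param d_model Encoding dimension (even).
#' @return Numeric vector of encoding values.
#' @examples
#' positional_encoding(0, 0, 128)  # sin(0) = 0
#' positional_encoding(0, 1, 128)  # cos(0) = 1
#' @export
positional_encoding <- function(pos, dim_index, d_model) {
  if (any(dim_index < 0) || any(dim_index >= d_model)) {
    stop("dim_index must lie in [0, d_model)")
  }
  i2 <- dim_index - dim_index %% 2          # 2i for both members of a pair
  angle <- pos / 10000^(i2 / d_model)
  ifelse(dim_index %% 2 == 0, sin(angle), cos(angle))
}

#' Positional-encoding matrix for a sequence
#'
#' @param n Sequence length; rows cover positions `0 .. n-1`.
#' @param d_model Encoding dimension (must be even).
#' @return An `n x d_model` matrix.
#' @export
positional_encoding_matrix <- function(n, d_model) {
  if (d_model %% 2 != 0) stop("d_model must be even for sinusoidal encoding")
  pos <- seq_len(n) - 1
  i2 <- 2 * (seq_len(d_model / 2) - 1)
  angles <- outer(pos, 10000^(i2 / d_model), "/")
  out <- matrix(0, n, d_model)
  out[, seq(1, d_model, by = 2)] <- sin(angles)
  out[, seq(2, d_model, by = 2)] <- cos(angles)
  out
}

PAD_ID <- 0L
UNK_ID <- 1L
PAD_TOKEN <- "<pad>"
UNK_TOKEN <- "<unk>"

#' Build a character vocabulary from a corpus
#'
#' Ids are 0-based: 0 is reserved for padding, 1 for unknown characters;
#' corpus characters follow in order of first appearance.
#'
#' @param sentences List of [labeled_sentence()] objects (or character
#'   vectors of characters).
#' @return An object of class `vocabulary` with `chars` (including the
#'   reserved tokens) and `char_to_id` (named 0-based integer vector).
#' @export
build_vocabulary <- function(sentences) {
  seen <- unique(unlist(lapply(sentences, function(s) {
    if (is.list(s)) s$chars else s
  })))
  chars <- c(PAD_TOKEN, UNK_TOKEN, seen)
  ids <- seq_along(chars) - 1L
  names(ids) <- chars
  structure(list(chars = chars, char_to_id = ids), class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("<vocabulary> ", length(x$chars), " entries (incl. <pad>, <unk>)\n",
      sep = "")
  invisible(x)
}

#' Map characters to vocabulary ids
#'
#' @param chars Character vector of single characters.
#' @param vocab A [build_vocabulary()] object.
#' @return Integer vector of 0-based ids; unseen characters map to the
#'   unknown id.
#' @export
chars_to_ids <- function(chars, vocab) {
  ids <- vocab$char_to_id[chars]
  ids[is.na(ids)] <- UNK_ID
  unname(ids)
}

#' Write / read a vocabulary as one character per line
#'
#' The serialized form lists every entry (including the reserved padding and
#' unknown tokens) one per line; the id of the entry on line `k` is `k - 1`.
#'
#' @param vocab A vocabulary object.
#' @param path File path.
#' @return `read_vocabulary` returns a vocabulary object.
#' @export
write_vocabulary <- function(vocab, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(vocab$chars), con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  chars <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(chars) < 2L || chars[1L] != PAD_TOKEN || chars[2L] != UNK_TOKEN) {
    stop("not a vocabulary file (must start with ", PAD_TOKEN, " and ",
         UNK_TOKEN, "): ", path)
  }
  ids <- seq_along(chars) - 1L
  names(ids) <- chars
  structure(list(chars = chars, char_to_id = ids), class = "vocabulary")
}

#' Embedding configuration
#'
#' @param d_model Output vector dimension (default 128; must be even when
#'   `position_mode = "sinusoidal"`).
#' @param position_mode `"sinusoidal"` (fixed, default) or `"learned"`.
#' @param max_len Maximum supported sequence length (default 128).
#' @return An `embedding_config` list.
#' @export
embedding_config <- function(d_model = 128L, position_mode = c("sinusoidal", "learned"),
                             max_len = 128L) {
  position_mode <- match.arg(position_mode)
  d_model <- as.integer(d_model)
  if (d_model <= 0L) stop("d_model must be positive")
  if (position_mode == "sinusoidal" && d_model %% 2L != 0L) {
    stop("d_model must be even when position_mode is 'sinusoidal'")
  }
  structure(list(d_model = d_model, position_mode = position_mode,
                 max_len = as.integer(max_len)),
            class = "embedding_config")
}

#' Initialize embedding parameters
#'
#' The token table has one row per vocabulary id (the padding row is zero and
#' stays zero), the segment table has two rows (single-sentence inputs use
#' segment 0), and a learned position table is allocated when configured.
#'
#' @param vocab A vocabulary.
#' @param config An [embedding_config()].
#' @param init_sd Standard deviation of the random initialization.
#' @return List of parameter matrices `token`, `segment`, and optionally
#'   `position`.
#' @export
init_embedding_params <- function(vocab, config, init_sd = 0.1) {
  v <- length(vocab$chars)
  token <- matrix(stats::rnorm(v * config$d_model, sd = init_sd),
                  v, config$d_model)
  token[PAD_ID + 1L, ] <- 0
  segment <- matrix(stats::rnorm(2L * config$d_model, sd = init_sd),
                    2L, config$d_model)
  params <- list(token = token, segment = segment)
  if (config$position_mode == "learned") {
    params$position <- matrix(stats::rnorm(config$max_len * config$d_model,
                                           sd = init_sd),
                              config$max_len, config$d_model)
  }
  params
}

#' Embed a character-id sequence
#'
#' Output row `t` is `token[char_ids[t]] + segment[segment_ids[t]] +
#' position(t)`. Padding positions (id 0) produce the padding embedding (the
#' zero token row plus segment and position terms are suppressed: the whole
#' row is zero). Dropout is applied downstream by the model, not here.
#'
#' @param char_ids Integer vector of 0-based vocabulary ids.
#' @param segment_ids Integer vector of 0/1 segment ids (same length);
#'   defaults to all zeros.
#' @param config An [embedding_config()].
#' @param params Parameters from [init_embedding_params()].
#' @return An `n x d_model` numeric matrix.
#' @export
embed_sequence <- function(char_ids, segment_ids = NULL, config, params) {
  n <- length(char_ids)
  if (is.null(segment_ids)) segment_ids <- integer(n)
  if (length(segment_ids) != n) {
    stop("char_ids and segment_ids must have equal length")
  }
  if (any(char_ids < 0L) || any(char_ids >= nrow(params$token))) {
    stop("character id out of vocabulary range")
  }
  if (any(segment_ids < 0L) || any(segment_ids > 1L)) {
    stop("segment ids must be 0 or 1")
  }
  if (n == 0L) return(matrix(0, 0L, config$d_model))
  pe <- if (config$position_mode == "sinusoidal") {
    positional_encoding_matrix(n, config$d_model)
  } else {
    if (n > nrow(params$position)) stop("sequence longer than max_len")
    params$position[seq_len(n), , drop = FALSE]
  }
  out <- params$token[char_ids + 1L, , drop = FALSE] +
    params$segment[segment_ids + 1L, , drop = FALSE] + pe
  pad <- char_ids == PAD_ID
  if (any(pad)) out[pad, ] <- 0
  out
}

#' Wrap an external contextual embedder behind the embedder contract
#'
#' `provider` maps a character vector to a per-character embedding matrix of
#' a declared dimension. The adapter enforces the length contract (one vector
#' per input character) and, when the provider dimension differs from
#' `d_model`, applies a fixed linear projection.
#'
#' @param provider Function: `character vector -> n x provider_dim matrix`.
#' @param provider_dim Output dimension declared by the provider.
#' @param d_model Target dimension.
#' @param projection Optional `provider_dim x d_model` matrix; a seeded
#'   random projection is created when dimensions differ and none is given.
#' @return A function of class `embedder`: `chars -> n x d_model matrix`.
#' @export
external_embedder_adapter <- function(provider, provider_dim, d_model,
                                      projection = NULL) {
  if (provider_dim != d_model && is.null(projection)) {
    projection <- matrix(stats::rnorm(provider_dim * d_model,
                                      sd = 1 / sqrt(provider_dim)),
                         provider_dim, d_model)
  }
  if (!is.null(projection) &&
      (nrow(projection) != provider_dim || ncol(projection) != d_model)) {
    stop("projection must be provider_dim x d_model")
  }
  f <- function(chars) {
    out <- provider(chars)
    if (!is.matrix(out) || nrow(out) != length(chars)) {
      stop("embedder contract violation: provider returned ",
           NROW(out), " rows for ", length(chars),
           " characters (tokenizer mismatch?)")
    }
    if (ncol(out) != provider_dim) {
      stop("provider dimension ", ncol(out), " != declared ", provider_dim)
    }
    if (provider_dim != d_model) out <- out %*% projection
    out
  }
  class(f) <- c("embedder", "function")
  f
}
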