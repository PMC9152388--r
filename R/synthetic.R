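# Deterministic generator of synthetic EMR-like labeled corpora. Characters
# come from the Unicode private-use area so tests can never depend on real
# lexical statistics; entities are lexicon strings embedded in background
# text, with knobs reproducing the confusions seen in real clinical records:
# operation strings nesting a disease string as a prefix, parenthetical
# supplements inside long entity spans, and dependent entity pairs
# co-occurring at long character distance in one sentence.

pua_chars <- function(base, n) {
  vapply(seq_len(n) - 1L, function(i) intToUtf8(base + i), character(1))
}

BACKGROUND_BASE <- 0xE000L
ENTITY_BASE <- 0xE100L
OPEN_BRACKET <- intToUtf8(0xE1F0L)
CLOSE_BRACKET <- intToUtf8(0xE1F1L)
OPERATION_SUFFIX <- c(intToUtf8(0xE1FEL), intToUtf8(0xE1FFL))

#' Specification of the synthetic corpus generator
#'
#' Default type mix follows the empirical frequencies of entity types in
#' clinical-record corpora (disease and anatomy dominant; exam, test and
#' drug rarer). Confusion knobs: `p_nested_lookalike` is the probability
#' that an operation lexicon entry is a disease entry extended by a fixed
#' suffix (a look-alike nesting); `p_parenthetical` the probability that a
#' long entity span carries a bracketed supplement inside its gold span;
#' `p_cooccur` the probability that a sentence contains a dependent
#' disease/operation pair placed at least `cooccur_distance` characters
#' apart.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param alphabet_size Background character inventory size (default 60).
#' @param entity_alphabet_size Entity character inventory size (default 48;
#'   disjoint from the background inventory).
#' @param lexicon_sizes Named integer vector of entries per type.
#' @param length_ranges Named list of `c(min, max)` entity lengths per type.
#' @param type_weights Named sampling weights over the six types.
#' @param sentence_length `c(min, max)` sentence length in characters
#'   (before the terminal period).
#' @param entity_density Mean number of entities per sentence (Poisson).
#' @param p_nested_lookalike,p_parenthetical,p_cooccur Confusion
#'   probabilities in `[0, 1]`.
#' @param cooccur_distance Minimum separation (characters) of a co-occurring
#'   pair (default 10).
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(seed = 0L,
                           alphabet_size = 60L,
                           entity_alphabet_size = 48L,
                           lexicon_sizes = c(DIS = 30L, EXA = 12L, TES = 12L,
                                             OPE = 20L, DRU = 15L, ANA = 25L),
                           length_ranges = list(DIS = c(3L, 7L),
                                                EXA = c(2L, 4L),
                                                TES = c(2L, 4L),
                                                OPE = c(4L, 8L),
                                                DRU = c(2L, 5L),
                                                ANA = c(3L, 6L)),
                           type_weights = c(DIS = 0.395, EXA = 0.041,
                                            TES = 0.059, OPE = 0.143,
                                            DRU = 0.085, ANA = 0.277),
                           sentence_length = c(20L, 60L),
                           entity_density = 2.5,
                           p_nested_lookalike = 0.3,
                           p_parenthetical = 0.2,
                           p_cooccur = 0.2,
                           cooccur_distance = 10L) {
  probs <- c(p_nested_lookalike, p_parenthetical, p_cooccur)
  if (any(probs < 0) || any(probs > 1)) {
    stop("confusion probabilities must lie in [0, 1]")
  }
  structure(list(seed = as.integer(seed),
                 alphabet_size = as.integer(alphabet_size),
                 entity_alphabet_size = as.integer(entity_alphabet_size),
                 lexicon_sizes = lexicon_sizes,
                 length_ranges = length_ranges,
                 type_weights = type_weights / sum(type_weights),
                 sentence_length = as.integer(sentence_length),
                 entity_density = entity_density,
                 p_nested_lookalike = p_nested_lookalike,
                 p_parenthetical = p_parenthetical,
                 p_cooccur = p_cooccur,
                 cooccur_distance = as.integer(cooccur_distance)),
            class = "generator_spec")
}

random_entity_string <- function(pool, len) {
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

#' Build per-type entity lexicons
#'
#' Reproducible given `spec$seed`. With probability `p_nested_lookalike`
#' an operation entry is formed as a disease entry plus the fixed operation
#' suffix (so the disease string is a strict prefix of the operation
#' string); with `p_nested_lookalike = 0` no operation entry has a disease
#' entry as a prefix.
#'
#' @param spec A [generator_spec()].
#' @return Named list of character vectors, one per type, with attribute
#'   `nested` (logical vector over the operation lexicon marking derived
#'   entries).
#' @export
build_lexicons <- function(spec) {
  with_seed(spec$seed, {
    pool <- pua_chars(ENTITY_BASE, spec$entity_alphabet_size)
    lex <- list()
    for (ty in names(spec$lexicon_sizes)) {
      rng <- spec$length_ranges[[ty]]
      n <- spec$lexicon_sizes[[ty]]
      entries <- character(0)
      while (length(entries) < n) {
        cand <- random_entity_string(pool, sample(rng[1]:rng[2], 1L))
        if (!cand %in% entries) entries <- c(entries, cand)
      }
      lex[[ty]] <- entries
    }
    # look-alike nesting: operation = disease + fixed suffix
    n_ope <- length(lex$OPE)
    nested <- stats::runif(n_ope) < spec$p_nested_lookalike
    suffix <- paste(OPERATION_SUFFIX, collapse = "")
    dis_src <- sample(lex$DIS, n_ope, replace = TRUE)
    lex$OPE[nested] <- paste0(dis_src[nested], suffix)
    if (spec$p_nested_lookalike == 0) {
      # reject any accidental disease-prefix among plain operation entries
      for (i in seq_len(n_ope)) {
        while (any(startsWith(lex$OPE[i], lex$DIS))) {
          rng <- spec$length_ranges$OPE
          lex$OPE[i] <- random_entity_string(pool, sample(rng[1]:rng[2], 1L))
        }
      }
    }
    lex$OPE <- make.unique(lex$OPE, sep = OPERATION_SUFFIX[1L])
    attr(lex, "nested") <- nested
    lex
  })
}

decorate_parenthetical <- function(surface, pool) {
  supp <- random_entity_string(pool, sample(2:3, 1L))
  if (stats::runif(1) < 0.5) {
    paste0(OPEN_BRACKET, supp, CLOSE_BRACKET, surface)
  } else {
    paste0(surface, OPEN_BRACKET, supp, CLOSE_BRACKET)
  }
}

# assemble one sentence; returns list(chars, tags, mentions)
assemble_sentence <- function(spec, lex, pool_bg, pool_ent, schema) {
  target <- sample(spec$sentence_length[1]:spec$sentence_length[2], 1L)
  k <- stats::rpois(1L, spec$entity_density)
  cooccur <- spec$p_cooccur > 0 && stats::runif(1) < spec$p_cooccur
  surfaces <- character(0); types <- character(0)
  if (cooccur) {
    nested <- attr(lex, "nested")
    if (any(nested)) {
      j <- sample(which(nested), 1L)
      ope <- lex$OPE[j]
      suffix <- paste(OPERATION_SUFFIX, collapse = "")
      dis <- sub(paste0(suffix, ".*$"), "", ope)
      if (!dis %in% lex$DIS) dis <- sample(lex$DIS, 1L)
    } else {
      dis <- sample(lex$DIS, 1L); ope <- sample(lex$OPE, 1L)
    }
    surfaces <- c(dis, ope); types <- c("DIS", "OPE")
    k <- max(k - 2L, 0L)
  }
  if (k > 0L) {
    extra_ty <- sample(names(spec$type_weights), k, replace = TRUE,
                       prob = spec$type_weights)
    extra <- vapply(extra_ty, function(ty) sample(lex[[ty]], 1L), character(1))
    surfaces <- c(surfaces, unname(extra)); types <- c(types, extra_ty)
  }
  # parenthetical supplements on long entities
  if (length(surfaces)) {
    long <- nchar(surfaces) >= 5L
    deco <- long & stats::runif(length(surfaces)) < spec$p_parenthetical
    surfaces[deco] <- vapply(surfaces[deco], decorate_parenthetical,
                             character(1), pool = pool_ent)
  }
  if (length(surfaces) && max(nchar(surfaces)) + 1L > spec$sentence_length[2]) {
    stop("entity of length ", max(nchar(surfaces)),
         " cannot fit in a sentence of at most ",
         spec$sentence_length[2], " characters")
  }
  # drop entities (from the end) until they fit with one-char gaps
  need <- function(sf) sum(nchar(sf)) + length(sf) + 1L
  while (length(surfaces) && need(surfaces) > target) {
    if (length(surfaces) == 1L && nchar(surfaces) + 2L <= target) break
    surfaces <- surfaces[-length(surfaces)]
    types <- types[-length(types)]
  }
  m <- length(surfaces)
  if (m > 1L && !cooccur) {
    ord <- sample.int(m)
    surfaces <- surfaces[ord]; types <- types[ord]
  }
  ent_len <- sum(nchar(surfaces))
  bg_total <- max(target - 1L - ent_len, m + 1L)
  # distribute background across the m+1 gaps, each interior gap >= 1
  gaps <- rep(1L, m + 1L)
  gaps[1L] <- 0L
  spare <- bg_total - sum(gaps)
  if (spare > 0L) {
    add <- tabulate(sample.int(m + 1L, spare, replace = TRUE), m + 1L)
    gaps <- gaps + add
  }
  if (cooccur && m >= 2L) {
    # enforce the minimum separation between the pair (slots 1 and 2)
    sep <- gaps[2L]
    if (sep < spec$cooccur_distance) gaps[2L] <- spec$cooccur_distance
  }
  chars <- character(0)
  starts <- integer(m); ends <- integer(m)
  for (i in seq_len(m + 1L)) {
    if (gaps[i] > 0L) {
      chars <- c(chars, sample(pool_bg, gaps[i], replace = TRUE))
    }
    if (i <= m) {
      s <- length(chars)
      e_chars <- strsplit(surfaces[i], "")[[1L]]
      chars <- c(chars, e_chars)
      starts[i] <- s; ends[i] <- length(chars)
    }
  }
  chars <- c(chars, "。")  # terminal ideographic full stop
  mentions <- entity_mentions(starts, ends, types)
  o <- order(mentions$start)
  mentions <- mentions[o, , drop = FALSE]
  class(mentions) <- c("entity_mentions", "data.frame")
  list(chars = chars, tags = encode_tags(mentions, length(chars), schema),
       mentions = mentions)
}

#' Generate a synthetic labeled corpus
#'
#' Deterministic given `spec$seed + seed_offset`: use distinct offsets for
#' train/dev/test so the splits are generated disjointly rather than by
#' shuffling one pool. Every sentence ends with the ideographic full stop
#' and its tags are produced by [encode_tags()], so gold validation with the
#' strict decoding policy always passes.
#'
#' @param spec A [generator_spec()].
#' @param n_sentences Number of sentences (>= 1).
#' @param seed_offset Integer offset added to the spec seed for the sentence
#'   stream (lexicons always use the spec seed itself, so all splits share
#'   one lexicon).
#' @param schema A [tag_schema()].
#' @return List of [labeled_sentence()] objects.
#' @export
generate_corpus <- function(spec, n_sentences, seed_offset = 0L,
                            schema = tag_schema()) {
  if (n_sentences < 1L) stop("n_sentences must be >= 1")
  lex <- build_lexicons(spec)
  pool_bg <- pua_chars(BACKGROUND_BASE, spec$alphabet_size)
  pool_ent <- pua_chars(ENTITY_BASE, spec$entity_alphabet_size)
  with_seed(spec$seed + 7L + as.integer(seed_offset), {
    lapply(seq_len(n_sentences), function(i) {
      s <- assemble_sentence(spec, lex, pool_bg, pool_ent, schema)
      structure(list(chars = s$chars, tags = s$tags, mentions = s$mentions),
                class = "labeled_sentence")
    })
  })
}

#' Generate synthetic span-annotated documents
#'
#' Concatenates generated sentences into multi-sentence records with
#' document-level mention offsets, for exercising the span-annotation
#' reader/writer and [split_document()].
#'
#' @param spec A [generator_spec()].
#' @param n_docs Number of documents.
#' @param sentences_per_doc Sentences concatenated per document.
#' @param seed_offset Passed to [generate_corpus()].
#' @param schema A [tag_schema()].
#' @return List of [raw_document()] objects.
#' @export
generate_documents <- function(spec, n_docs, sentences_per_doc = 4L,
                               seed_offset = 0L, schema = tag_schema()) {
  sents <- generate_corpus(spec, n_docs * sentences_per_doc, seed_offset,
                           schema)
  lapply(seq_len(n_docs), function(d) {
    idx <- ((d - 1L) * sentences_per_doc + 1L):(d * sentences_per_doc)
    off <- 0L
    chars <- character(0)
    ms <- list()
    for (i in idx) {
      s <- sents[[i]]
      m <- s$mentions
      if (nrow(m)) {
        m$start <- m$start + off
        m$end <- m$end + off
        ms[[length(ms) + 1L]] <- m
      }
      chars <- c(chars, s$chars)
      off <- off + length(s$chars)
    }
    ann <- if (length(ms)) do.call(rbind, ms) else entity_mentions()
    class(ann) <- c("entity_mentions", "data.frame")
    raw_document(sprintf("synthetic-%03d", d), paste(chars, collapse = ""),
                 ann, schema)
  })
}
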