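# Independent brute-force oracles and random-case generators used across the
# suite. Everything here is deliberately naive (loops, enumeration) so it
# stays independent of the vectorized/dynamic-programming implementations it
# checks.

SCHEMA <- tag_schema()

# random non-overlapping mention set on a sentence of given length
random_mentions <- function(len, max_mentions = 4L,
                            types = SCHEMA$types) {
  starts <- integer(); ends <- integer(); tys <- character()
  pos <- 0L
  for (i in seq_len(max_mentions)) {
    gap <- sample(0:4, 1L)
    s <- pos + gap
    w <- sample(1:5, 1L)
    if (s + w > len) break
    starts <- c(starts, s); ends <- c(ends, s + w)
    tys <- c(tys, sample(types, 1L))
    pos <- s + w
  }
  entity_mentions(starts, ends, tys)
}

# exhaustive log partition by enumerating all L^n label sequences
enum_log_partition <- function(P, W) {
  n <- nrow(P); L <- ncol(P)
  ys <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  scores <- apply(ys, 1L, function(y) sequence_score(P, W, y))
  m <- max(scores)
  m + log(sum(exp(scores - m)))
}

# exhaustive Viterbi: max score, ties toward the lowest label index at the
# latest differing position (compare reversed sequences lexicographically)
enum_viterbi <- function(P, W) {
  n <- nrow(P); L <- ncol(P)
  ys <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  scores <- apply(ys, 1L, function(y) sequence_score(P, W, y))
  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    rev_keys <- apply(ys[best, , drop = FALSE], 1L,
                      function(y) paste(sprintf("%03d", rev(y)), collapse = ""))
    best <- best[order(rev_keys)[1L]]
  }
  list(path = unname(ys[best[1L], ]), score = max(scores))
}

# naive scaled dot-product attention with explicit loops
naive_attention <- function(Q, K, V) {
  n_q <- nrow(Q); n_k <- nrow(K)
  out <- matrix(0, n_q, ncol(V))
  for (q in seq_len(n_q)) {
    logits <- numeric(n_k)
    for (k in seq_len(n_k)) logits[k] <- sum(Q[q, ] * K[k, ]) / sqrt(ncol(Q))
    w <- exp(logits - max(logits)); w <- w / sum(w)
    for (k in seq_len(n_k)) out[q, ] <- out[q, ] + w[k] * V[k, ]
  }
  out
}

# naive dilated convolution with an explicit per-position tap loop
naive_dilated_conv <- function(x, kernel, bias, dilation,
                               activation = "identity") {
  n <- nrow(x); K <- dim(kernel)[1L]; d_out <- dim(kernel)[3L]
  center <- (K + 1L) %/% 2L
  out <- matrix(0, n, d_out)
  for (t in seq_len(n)) {
    for (o in seq_len(d_out)) {
      s <- bias[o]
      for (k in seq_len(K)) {
        tt <- t + (k - center) * dilation
        if (tt >= 1L && tt <= n) s <- s + sum(x[tt, ] * kernel[k, , o])
      }
      out[t, o] <- s
    }
  }
  if (activation == "relu") out <- pmax(out, 0) else out
}

# tiny deterministic corpus for model-level tests
tiny_corpus <- function(n = 4L, seed = 11L) {
  spec <- generator_spec(seed = seed, sentence_length = c(12L, 20L),
                         entity_density = 1.5)
  generate_corpus(spec, n)
}

small_model_config <- function(...) {
  model_config(d_model = 8L, filters = 8L, heads = 2L, iterations = 2L,
               dropout = 0, seed = 5L, ...)
}
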