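test_that("sinusoidal encoding matches its closed form", {
  expect_equal(positional_encoding(0, 0, 128), 0)
  expect_equal(positional_encoding(0, 6, 128), 0)
  expect_equal(positional_encoding(0, 1, 128), 1)
  expect_equal(positional_encoding(0, 7, 128), 1)
  expect_equal(positional_encoding(1, 0, 4), sin(1), tolerance = 1e-12)
  expect_equal(positional_encoding(1, 2, 4), sin(1 / 10000^(2 / 4)),
               tolerance = 1e-12)
  expect_equal(positional_encoding(1, 3, 4), cos(1 / 10000^(2 / 4)),
               tolerance = 1e-12)
  expect_error(positional_encoding(0, 4, 4), "dim_index")
})

test_that("encoding matrix agrees with the scalar form and has unit pairs", {
  M <- positional_encoding_matrix(17, 10)
  for (pos in c(0, 5, 16)) {
    for (d in 0:9) {
      expect_equal(M[pos + 1, d + 1], positional_encoding(pos, d, 10),
                   tolerance = 1e-12)
    }
  }
  # sin^2 + cos^2 = 1 for every (pos, pair)
  pairs <- M[, seq(1, 9, by = 2)]^2 + M[, seq(2, 10, by = 2)]^2
  expect_equal(as.vector(pairs), rep(1, length(pairs)), tolerance = 1e-12)
})

test_that("vocabulary reserves padding=0 and unknown=1 and round-trips", {
  sents <- list(labeled_sentence("abca", rep("O", 4)))
  v <- build_vocabulary(sents)
  expect_identical(unname(v$char_to_id[c("<pad>", "<unk>")]), c(0L, 1L))
  expect_identical(chars_to_ids(c("a", "z"), v),
                   c(unname(v$char_to_id["a"]), 1L))
  path <- withr::local_tempfile()
  write_vocabulary(v, path)
  expect_identical(read_vocabulary(path), v)
})

test_that("embed_sequence sums token, segment and position terms", {
  sents <- list(labeled_sentence("ab", c("O", "O")))
  v <- build_vocabulary(sents)
  cfg <- embedding_config(d_model = 6, max_len = 16)
  set.seed(1)
  par <- init_embedding_params(v, cfg)
  # zero token and segment tables isolate the positional term
  par0 <- par
  par0$token[] <- 0; par0$segment[] <- 0
  out <- embed_sequence(chars_to_ids("a", v), config = cfg, params = par0)
  expect_equal(as.vector(out), c(0, 1, 0, 1, 0, 1), tolerance = 1e-12)
  # identical chars at positions 0 and 5 differ exactly by the PE difference
  ids <- chars_to_ids(rep("a", 6), v)
  E <- embed_sequence(ids, config = cfg, params = par)
  pe <- positional_encoding_matrix(6, 6)
  expect_equal(E[1, ] - E[6, ], pe[1, ] - pe[6, ], tolerance = 1e-12)
  # padding rows are all-zero
  Epad <- embed_sequence(c(0L, ids[1]), config = cfg, params = par)
  expect_equal(Epad[1, ], rep(0, 6))
  expect_error(embed_sequence(c(99L), config = cfg, params = par),
               "out of vocabulary")
})

test_that("token-table relabeling leaves outputs unchanged", {
  sents <- list(labeled_sentence("abcd", rep("O", 4)))
  v <- build_vocabulary(sents)
  cfg <- embedding_config(d_model = 4, max_len = 8)
  set.seed(2)
  par <- init_embedding_params(v, cfg)
  ids <- chars_to_ids(c("a", "c", "b"), v)
  out1 <- embed_sequence(ids, config = cfg, params = par)
  # permute the non-reserved vocabulary entries and table rows consistently
  perm <- c(1L, 2L, sample(3:6))
  par2 <- par
  par2$token <- par$token[perm, ]
  remap <- order(perm) - 1L
  ids2 <- remap[ids + 1L]
  out2 <- embed_sequence(ids2, config = cfg, params = par2)
  expect_equal(out1, out2, tolerance = 1e-12)
})

test_that("external embedder adapter enforces the contract and projects", {
  ident <- function(chars) matrix(seq_along(chars), length(chars), 4)
  ad <- external_embedder_adapter(ident, 4, 4)
  expect_equal(ad(c("a", "b")), ident(c("a", "b")))
  set.seed(3)
  ad2 <- external_embedder_adapter(function(chars)
    matrix(1, length(chars), 312), 312, 128)
  expect_equal(dim(ad2(c("a", "b", "c"))), c(3L, 128L))
  merger <- function(chars) matrix(1, max(1, length(chars) - 1L), 4)
  ad3 <- external_embedder_adapter(merger, 4, 4)
  expect_error(ad3(c("a", "b")), "tokenizer mismatch")
})
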