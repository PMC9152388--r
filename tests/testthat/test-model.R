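test_that("two builds with the same seed are identical; forward is n x L", {
  corp <- tiny_corpus(3)
  vocab <- build_vocabulary(corp)
  cfg <- small_model_config()
  m1 <- build_model(cfg, SCHEMA, vocab)
  m2 <- build_model(cfg, SCHEMA, vocab)
  expect_identical(m1$params, m2$params)
  enc <- chars_to_ids(corp[[1]]$chars, vocab)
  P <- cner:::model_forward(m1$params, m1, enc)$P
  expect_equal(dim(P), c(length(enc), length(SCHEMA$tags)))
  # evaluation-mode forwards are deterministic
  expect_identical(P, cner:::model_forward(m1$params, m1, enc)$P)
})

test_that("incompatible dimensions are rejected at build time", {
  expect_error(model_config(filters = 30, heads = 4), "divisible")
  expect_error(model_config(dropout = 1), "dropout")
})

test_that("end-to-end analytic gradients match central differences", {
  corp <- tiny_corpus(2, seed = 13)
  vocab <- build_vocabulary(corp)
  mod <- build_model(small_model_config(), SCHEMA, vocab)
  bg <- model_batch_gradients(mod, corp)
  h <- 1e-5
  set.seed(50)
  for (nm in names(mod$params)) {
    for (idx in sample(length(mod$params[[nm]]),
                       min(4, length(mod$params[[nm]])))) {
      pp <- mod$params; pp[[nm]][idx] <- pp[[nm]][idx] + h
      up <- model_batch_loss(mod, corp, pp)
      pp[[nm]][idx] <- pp[[nm]][idx] - 2 * h
      dn <- model_batch_loss(mod, corp, pp)
      expect_equal(bg$grads[[nm]][idx], (up - dn) / (2 * h),
                   tolerance = 1e-3, label = paste0(nm, "[", idx, "]"))
    }
  }
})

test_that("predictions are empty on empty input, all-O with zeroed head", {
  corp <- tiny_corpus(3)
  vocab <- build_vocabulary(corp)
  mod <- build_model(small_model_config(), SCHEMA, vocab)
  expect_identical(predict(mod, list()), list())
  mod$params$wem[] <- 0
  mod$params$bem[] <- 0
  mod$params$wcrf[] <- 0
  pred <- predict(mod, corp)
  for (p in pred) {
    expect_true(all(p$tags == "O"))
    expect_equal(nrow(p$mentions), 0L)
  }
})

test_that("prediction does not depend on batch composition", {
  corp <- tiny_corpus(6)
  vocab <- build_vocabulary(corp)
  mod <- build_model(small_model_config(), SCHEMA, vocab)
  all_at_once <- predict(mod, corp)
  one_by_one <- unlist(lapply(corp, function(s) predict(mod, list(s))),
                       recursive = FALSE)
  expect_identical(all_at_once, one_by_one)
})

test_that("over-long sentences are rejected with guidance", {
  corp <- tiny_corpus(2)
  vocab <- build_vocabulary(corp)
  cfg <- small_model_config(max_len = 10L)
  mod <- build_model(cfg, SCHEMA, vocab)
  long <- labeled_sentence(paste(rep("x", 40), collapse = ""), rep("O", 40))
  expect_error(predict(mod, list(long)), "split_document")
})

test_that("a few steps of training reduce the loss deterministically", {
  corp <- tiny_corpus(6, seed = 17)
  vocab <- build_vocabulary(corp)
  cfg <- small_model_config(learning_rate = 5e-3, batch_size = 6L,
                            epochs = 15L, patience = 100L)
  mod <- build_model(cfg, SCHEMA, vocab)
  before <- model_batch_loss(mod, corp)
  t1 <- train_model(mod, corp)
  t2 <- train_model(mod, corp)
  expect_identical(t1$params, t2$params)   # seeded reproducibility
  expect_lt(tail(t1$report$epochs$loss, 1), before)
})

test_that("the no-MHA ablation keeps every I/O contract", {
  corp <- tiny_corpus(4)
  vocab <- build_vocabulary(corp)
  cfg <- small_model_config(use_mha = FALSE)
  mod <- build_model(cfg, SCHEMA, vocab)
  expect_false(any(grepl("^w[qkv]", names(mod$params))))
  pred <- predict(mod, corp)
  expect_length(pred, 4L)
  bg <- model_batch_gradients(mod, corp)
  expect_true(is.finite(bg$loss))
  expect_identical(sort(names(bg$grads)), sort(names(mod$params)))
})

test_that("checkpoints reload to identical predictions", {
  corp <- tiny_corpus(3, seed = 19)
  vocab <- build_vocabulary(corp)
  mod <- build_model(small_model_config(), SCHEMA, vocab)
  mod <- train_model(mod, corp, epochs = 2L)
  dir <- withr::local_tempdir()
  save_model(mod, dir)
  back <- load_model(dir)
  expect_equal(back$params, mod$params, tolerance = 1e-12)
  expect_identical(predict(back, corp), predict(mod, corp))
})
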