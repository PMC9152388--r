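zero_W <- function(L) matrix(0, L + 2, L + 2)

test_that("sequence_score sums emissions and all transitions", {
  P <- matrix(c(2, 5), 1, 2)
  expect_equal(sequence_score(P, zero_W(2), 1L), 2)
  expect_equal(sequence_score(P, zero_W(2), 2L), 5)
  P3 <- matrix(0, 3, 3)
  expect_equal(sequence_score(P3, zero_W(3), c(1L, 2L, 3L)), 0)
  # random instance vs term-by-term summation
  set.seed(30)
  P <- matrix(rnorm(9), 3, 3)
  W <- matrix(rnorm(25), 5, 5)
  y <- c(2L, 3L, 1L)
  hand <- P[1, 2] + P[2, 3] + P[3, 1] +
    W[4, 2] + W[2, 3] + W[3, 1] + W[1, 5]
  expect_equal(sequence_score(P, W, y), hand, tolerance = 1e-12)
})

test_that("log_partition equals exhaustive enumeration", {
  expect_equal(log_partition(matrix(0, 1, 2), zero_W(2)), log(2),
               tolerance = 1e-12)
  set.seed(31)
  for (case in 1:20) {
    n <- sample(1:4, 1); L <- sample(2:4, 1)
    P <- matrix(rnorm(n * L, sd = 2), n, L)
    W <- matrix(rnorm((L + 2)^2), L + 2, L + 2)
    expect_equal(log_partition(P, W), enum_log_partition(P, W),
                 tolerance = 1e-8)
  }
})

test_that("adding a constant to P shifts log_partition by n*c", {
  set.seed(32)
  P <- matrix(rnorm(12), 4, 3)
  W <- matrix(rnorm(25), 5, 5)
  base <- log_partition(P, W)
  expect_equal(log_partition(P + 1.7, W), base + 4 * 1.7, tolerance = 1e-9)
})

test_that("negative log-likelihood behaves as -log P(y|X)", {
  # single feasible sequence: near-zero NLL
  L <- 3; n <- 3
  P <- matrix(-1e4, n, L)
  y <- c(1L, 3L, 2L)
  P[cbind(1:n, y)] <- 0
  expect_lt(neg_log_likelihood(P, zero_W(L), y), 1e-8)
  # uniform scores: every sequence equally likely
  expect_equal(neg_log_likelihood(matrix(0, 2, 3), zero_W(3), c(1L, 1L)),
               log(9), tolerance = 1e-12)
  # probabilities over all sequences sum to one
  set.seed(33)
  P <- matrix(rnorm(9), 3, 3)
  W <- matrix(rnorm(25), 5, 5)
  ys <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  total <- sum(apply(ys, 1, function(y)
    exp(-neg_log_likelihood(P, W, y))))
  expect_equal(total, 1, tolerance = 1e-8)
  expect_gte(neg_log_likelihood(P, W, c(1L, 2L, 3L)), 0)
})

test_that("CRF gradients match central differences", {
  set.seed(34)
  n <- 4; L <- 3
  P <- matrix(rnorm(n * L), n, L)
  W <- matrix(rnorm((L + 2)^2), L + 2, L + 2)
  y <- sample(L, n, replace = TRUE)
  g <- crf_gradients(P, W, y)
  h <- 1e-5
  for (idx in sample(length(P), 6)) {
    Pp <- P; Pp[idx] <- Pp[idx] + h
    Pm <- P; Pm[idx] <- Pm[idx] - h
    num <- (neg_log_likelihood(Pp, W, y) - neg_log_likelihood(Pm, W, y)) /
      (2 * h)
    expect_equal(g$dP[idx], num, tolerance = 1e-4)
  }
  for (idx in sample(length(W), 8)) {
    Wp <- W; Wp[idx] <- Wp[idx] + h
    Wm <- W; Wm[idx] <- Wm[idx] - h
    num <- (neg_log_likelihood(P, Wp, y) - neg_log_likelihood(P, Wm, y)) /
      (2 * h)
    expect_equal(g$dW[idx], num, tolerance = 1e-4)
  }
})

test_that("viterbi matches independent per-position argmax when W = 0", {
  set.seed(35)
  P <- matrix(rnorm(20), 5, 4)
  vd <- viterbi_decode(P, zero_W(4))
  expect_identical(vd$path, apply(P, 1, which.max))
  expect_equal(vd$score, sum(apply(P, 1, max)), tolerance = 1e-12)
})

test_that("viterbi matches exhaustive argmax with deterministic ties", {
  set.seed(36)
  for (case in 1:20) {
    n <- sample(1:4, 1); L <- sample(2:4, 1)
    P <- matrix(rnorm(n * L), n, L)
    W <- matrix(rnorm((L + 2)^2), L + 2, L + 2)
    vd <- viterbi_decode(P, W)
    ex <- enum_viterbi(P, W)
    expect_identical(vd$path, ex$path)
    expect_equal(vd$score, ex$score, tolerance = 1e-9)
    expect_equal(vd$score, sequence_score(P, W, vd$path), tolerance = 1e-9)
  }
  # all-zero scores: tie rule selects the all-O (index 1) sequence
  vd0 <- viterbi_decode(matrix(0, 4, 13), zero_W(13))
  expect_identical(vd0$path, rep(1L, 4))
})

test_that("viterbi score never exceeds the log partition", {
  set.seed(37)
  for (case in 1:10) {
    P <- matrix(rnorm(12, sd = 2), 4, 3)
    W <- matrix(rnorm(25), 5, 5)
    expect_lt(viterbi_decode(P, W)$score, log_partition(P, W))
  }
})

test_that("hard BIO constraints make decoded sequences well-formed", {
  sch <- tag_schema()
  L <- length(sch$tags)
  mask <- bio_transition_mask(sch)
  set.seed(38)
  for (case in 1:25) {
    n <- sample(2:8, 1)
    P <- matrix(rnorm(n * L, sd = 3), n, L)
    W <- matrix(rnorm((L + 2)^2), L + 2, L + 2)
    vd <- viterbi_decode(P, W, constraints = mask)
    tags <- sch$tags[vd$path]
    expect_silent(decode_tags(tags, sch, policy = "strict"))
    # the returned score is the unmasked score of the decoded path
    expect_equal(vd$score, sequence_score(P, W, vd$path), tolerance = 1e-9)
  }
})
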