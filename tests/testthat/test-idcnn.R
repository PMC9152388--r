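test_that("delta kernel at the center tap is the identity (pre-activation)", {
  set.seed(7)
  x <- matrix(rnorm(8 * 3), 8, 3)
  kern <- array(0, c(3, 3, 3))
  kern[2, , ] <- diag(3)
  out <- dilated_conv_layer(x, kern, rep(0, 3), dilation = 1,
                            activation = "identity")
  expect_equal(out, x, tolerance = 1e-12)
  expect_equal(dilated_conv_layer(x, kern, rep(0, 3), 1, activation = "relu"),
               pmax(x, 0), tolerance = 1e-12)
})

test_that("length-1 input depends only on its own position", {
  set.seed(8)
  kern <- array(rnorm(3 * 2 * 2), c(3, 2, 2))
  x <- matrix(rnorm(2), 1, 2)
  for (dil in c(1, 2, 5)) {
    out <- dilated_conv_layer(x, kern, c(0, 0), dil, activation = "identity")
    expect_equal(as.vector(out), as.vector(x %*% kern[2, , ]),
                 tolerance = 1e-12)
  }
})

test_that("dilated convolution matches the per-position loop oracle", {
  set.seed(9)
  for (case in 1:10) {
    n <- sample(4:12, 1); d_in <- sample(2:4, 1); d_out <- sample(2:4, 1)
    dil <- sample(1:3, 1)
    x <- matrix(rnorm(n * d_in), n, d_in)
    kern <- array(rnorm(3 * d_in * d_out), c(3, d_in, d_out))
    bias <- rnorm(d_out)
    expect_equal(dilated_conv_layer(x, kern, bias, dil, activation = "relu"),
                 naive_dilated_conv(x, kern, bias, dil, activation = "relu"),
                 tolerance = 1e-6)
  }
})

test_that("idcnn_encode iterates the shared block", {
  set.seed(10)
  cfg1 <- idcnn_config(filters = 4, iterations = 1)
  cfg4 <- idcnn_config(filters = 4, iterations = 4)
  par <- init_idcnn_params(4, cfg1)
  x <- matrix(rnorm(10 * 4), 10, 4)
  one_block <- function(h) {
    for (l in 1:3) {
      h <- dilated_conv_layer(h, par$kernels[[l]], par$biases[[l]],
                              cfg1$dilations[l], activation = "relu")
    }
    h
  }
  expect_equal(idcnn_encode(x, cfg1, par), one_block(x), tolerance = 1e-12)
  manual <- x
  for (i in 1:4) manual <- one_block(manual)
  expect_equal(idcnn_encode(x, cfg4, par), manual, tolerance = 1e-6)
})

test_that("parameter count is independent of iterations", {
  count <- function(iters) {
    cfg <- idcnn_config(filters = 8, iterations = iters)
    set.seed(1)
    par <- init_idcnn_params(8, cfg)
    sum(vapply(par$kernels, length, integer(1))) +
      sum(vapply(par$biases, length, integer(1)))
  }
  expect_identical(count(1), count(4))
  expect_identical(count(4), count(16))
})

test_that("receptive field follows the layer-accumulation formula", {
  expect_identical(receptive_field_1d(3, 1, 1), 3L)
  expect_identical(receptive_field_1d(3, c(1, 1, 2), 1), 9L)
  expect_identical(receptive_field_1d(3, c(1, 1, 2), 4), 33L)
  expect_identical(receptive_field_1d(5, c(1, 2), 2), 25L)
  expect_identical(receptive_field_eq2(1), 7L)
})

test_that("perturbations propagate exactly to the receptive-field edge", {
  set.seed(12)
  cfg <- idcnn_config(filters = 3, iterations = 4)
  par <- init_idcnn_params(3, cfg)
  n <- 200
  x <- matrix(rnorm(n * 3), n, 3)
  base <- idcnn_encode(x, cfg, par)
  x2 <- x
  x2[1, ] <- x2[1, ] + 10
  pert <- idcnn_encode(x2, cfg, par)
  changed <- which(rowSums(abs(pert - base)) > 0)
  r <- receptive_field_1d(cfg$kernel_size, cfg$dilations, cfg$iterations)
  half <- (r - 1) / 2   # influence reaches half the field on either side
  expect_true(max(changed) <= 1 + half)
  expect_true(max(changed) > half - 2)  # ReLU may zero the extreme edge
})

test_that("shifting a padded input shifts the output identically", {
  set.seed(13)
  cfg <- idcnn_config(filters = 3, iterations = 2)
  par <- init_idcnn_params(3, cfg)
  core <- matrix(rnorm(10 * 3), 10, 3)
  pad <- matrix(0, 20, 3)
  x1 <- rbind(pad, core, pad)
  x2 <- rbind(pad[1:15, ], core, pad, pad[1:5, ])
  y1 <- idcnn_encode(x1, cfg, par)
  y2 <- idcnn_encode(x2, cfg, par)
  # the region around the core (within the receptive field) is shifted by 5
  expect_equal(y1[6:45, ], y2[1:40, ], tolerance = 1e-10)
})
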