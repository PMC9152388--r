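#' Iterated dilated CNN configuration
#'
#' One block of dilated 1-D convolution layers (dilation schedule
#' `dilations`, default `c(1, 1, 2)`) applied `iterations` times with the
#' SAME parameters, each iteration feeding the next. Parameter sharing across
#' iterations keeps the parameter count constant while the receptive field
#' grows linearly in `iterations`.
#'
#' @param filters Channel count (default 128).
#' @param kernel_size Odd kernel width (default 3).
#' @param dilations Integer vector of per-layer dilation widths within one
#'   block (default `c(1, 1, 2)`).
#' @param iterations Number of block repetitions (default 4).
#' @param activation Nonlinearity name; `"relu"` (default) or `"identity"`.
#' @return An `idcnn_config` list.
#' @export
idcnn_config <- function(filters = 128L, kernel_size = 3L,
                         dilations = c(1L, 1L, 2L), iterations = 4L,
                         activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  kernel_size <- as.integer(kernel_size)
  if (kernel_size %% 2L != 1L) stop("kernel_size must be odd")
  dilations <- as.integer(dilations)
  if (any(dilations < 1L)) stop("dilations must all be >= 1")
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1")
  structure(list(filters = as.integer(filters), kernel_size = kernel_size,
                 dilations = dilations, iterations = iterations,
                 activation = activation),
            class = "idcnn_config")
}

#' Initialize IDCNN parameters
#'
#' One kernel/bias pair per layer within the block; shared across all
#' iterations, so the parameter count is independent of `iterations`.
#'
#' @param input_dim Input vector dimension (the block's first layer maps
#'   `input_dim -> filters`; later layers map `filters -> filters`).
#' @param config An [idcnn_config()].
#' @param init_sd Initialization standard deviation; default scaled by fan-in.
#' @return List with `kernels` (list of `K x in x out` arrays) and `biases`.
#' @export
init_idcnn_params <- function(input_dim, config, init_sd = NULL) {
  K <- config$kernel_size
  f <- config$filters
  kernels <- list(); biases <- list()
  d_in <- input_dim
  for (l in seq_along(config$dilations)) {
    sd_l <- if (is.null(init_sd)) sqrt(2 / (K * d_in)) else init_sd
    kernels[[l]] <- array(stats::rnorm(K * d_in * f, sd = sd_l), c(K, d_in, f))
    biases[[l]] <- numeric(f)
    d_in <- f
  }
  list(kernels = kernels, biases = biases)
}

apply_activation <- function(x, activation) {
  if (activation == "relu") pmax(x, 0) else x
}

# shift rows of X by `offset` positions (rows moving out are dropped, vacated
# rows are zero): result[t, ] = X[t + offset, ] when in range, else 0
shift_rows <- function(X, offset) {
  n <- nrow(X)
  out <- matrix(0, n, ncol(X))
  if (abs(offset) >= n) return(out)
  if (offset >= 0) {
    keep <- seq_len(n - offset)
    out[keep, ] <- X[keep + offset, , drop = FALSE]
  } else {
    keep <- seq_len(n + offset)
    out[keep - offset, ] <- X[keep, , drop = FALSE]
  }
  out
}

#' One dilated 1-D convolution layer
#'
#' `output[t] = activation(sum_k kernel[k] . x[t + (k - (K+1)/2) * dilation]
#' + bias)` with zero padding outside the sequence ("same" padding: output
#' length equals input length). Padding positions indicated by `mask` are
#' forced to zero after the layer.
#'
#' @param x `n x d_in` input matrix.
#' @param kernel `K x d_in x d_out` array.
#' @param bias Length-`d_out` vector.
#' @param dilation Dilation width (>= 1).
#' @param mask Logical vector of length `n`, `TRUE` for real positions
#'   (default all real).
#' @param activation `"relu"` (default) or `"identity"`.
#' @return `n x d_out` matrix.
#' @export
dilated_conv_layer <- function(x, kernel, bias, dilation, mask = NULL,
                               activation = "relu") {
  K <- dim(kernel)[1L]
  n <- nrow(x)
  if (!is.null(mask)) x[!mask, ] <- 0
  center <- (K + 1L) %/% 2L
  z <- matrix(rep(bias, each = n), n, dim(kernel)[3L])
  for (k in seq_len(K)) {
    off <- (k - center) * dilation
    Wk <- matrix(kernel[k, , ], dim(kernel)[2L], dim(kernel)[3L])
    z <- z + shift_rows(x, off) %*% Wk
  }
  out <- apply_activation(z, activation)
  if (!is.null(mask)) out[!mask, ] <- 0
  out
}

#' Encode a sequence with the iterated dilated CNN
#'
#' Projects the input to `filters` channels, then applies the dilation block
#' `iterations` times with shared parameters, each iteration's output feeding
#' the next. Returns the final per-position feature sequence.
#'
#' @param x `n x input_dim` embedded input.
#' @param config An [idcnn_config()].
#' @param params Parameters from [init_idcnn_params()] built for
#'   `input_dim = filters` layers, plus an input projection `proj` (list with
#'   `W`: `input_dim x filters`, `b`) when `ncol(x) != filters`; when
#'   `ncol(x) == filters` and no `proj` is supplied the input is used as is.
#' @param mask Logical vector marking real positions (default all real).
#' @return `n x filters` matrix.
#' @export
idcnn_encode <- function(x, config, params, mask = NULL) {
  h <- x
  if (!is.null(params$proj)) {
    h <- sweep(h %*% params$proj$W, 2L, params$proj$b, "+")
    if (!is.null(mask)) h[!mask, ] <- 0
  } else if (ncol(x) != config$filters) {
    stop("input dimension ", ncol(x), " != filters ", config$filters,
         " and no input projection supplied")
  }
  for (it in seq_len(config$iterations)) {
    for (l in seq_along(config$dilations)) {
      h <- dilated_conv_layer(h, params$kernels[[l]], params$biases[[l]],
                              config$dilations[l], mask, config$activation)
    }
  }
  h
}

#' Receptive field of an iterated dilated 1-D convolution stack
#'
#' `r = 1 + iterations * sum_layers (kernel_size - 1) * dilation_layer`: the
#' number of input positions that can influence one output position.
#'
#' @param kernel_size Odd kernel width.
#' @param dilations Per-layer dilation schedule of one block.
#' @param iterations Number of shared-parameter block repetitions.
#' @return Integer receptive-field width.
#' @examples
#' receptive_field_1d(3, c(1, 1, 2), 4)  # 33
#' @export
receptive_field_1d <- function(kernel_size, dilations, iterations) {
  as.integer(1 + iterations * sum((kernel_size - 1) * dilations))
}

#' Two-dimensional exponential receptive-field reference formula
#'
#' The textbook image-domain expression `(2^(i+2) - 1) x (2^(i+2) - 1)` for
#' the receptive field after `i` doubling dilation layers. It applies to 2-D
#' convolution stacks with exponentially increasing dilation and is exposed
#' only as a reference calculator; it does not describe the 1-D text encoder,
#' for which [receptive_field_1d()] is the applicable formula.
#'
#' @param i Layer index.
#' @return Side length of the square receptive field.
#' @export
receptive_field_eq2 <- function(i) {
  as.integer(2^(i + 2) - 1)
}
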