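# Masked attention logits use a large negative constant rather than -Inf so
# that softmax stays finite in double precision; exp(NEG_LOGIT) == 0 exactly.
NEG_LOGIT <- -1e9

#' Multi-head attention configuration
#'
#' @param h Head count (default 4). `d_model` must be divisible by `h`; each
#'   head works in dimension `d_k = d_v = d_model / h`.
#' @param d_model Model dimension.
#' @param residual Add the input back to the attention output (default
#'   `FALSE`: the bare attention layer feeds the decoder directly).
#' @return An `mha_config` list with derived `d_k`.
#' @export
mha_config <- function(h = 4L, d_model = 128L, residual = FALSE) {
  h <- as.integer(h); d_model <- as.integer(d_model)
  if (h < 1L) stop("h must be >= 1")
  if (d_model %% h != 0L) {
    stop("d_model (", d_model, ") must be divisible by h (", h, ")")
  }
  structure(list(h = h, d_model = d_model, d_k = d_model %/% h,
                 residual = isTRUE(residual)),
            class = "mha_config")
}

#' Initialize multi-head attention parameters
#'
#' Per head `i`: query/key/value projections `Wq[[i]]`, `Wk[[i]]`, `Wv[[i]]`
#' of shape `d_model x d_k`; one output projection `Wo` of shape
#' `(h * d_k) x d_model`.
#'
#' @param config An [mha_config()].
#' @param init_sd Initialization standard deviation; default `1/sqrt(d_model)`.
#' @return Parameter list `Wq`, `Wk`, `Wv` (lists of matrices) and `Wo`.
#' @export
init_mha_params <- function(config, init_sd = NULL) {
  d <- config$d_model; dk <- config$d_k
  if (is.null(init_sd)) init_sd <- 1 / sqrt(d)
  mk <- function() matrix(stats::rnorm(d * dk, sd = init_sd), d, dk)
  list(
    Wq = replicate(config$h, mk(), simplify = FALSE),
    Wk = replicate(config$h, mk(), simplify = FALSE),
    Wv = replicate(config$h, mk(), simplify = FALSE),
    Wo = matrix(stats::rnorm(config$h * dk * d, sd = init_sd),
                config$h * dk, d)
  )
}

row_softmax <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, with masked (padding) keys given the large
#' negative logit so they receive zero weight; each output row's attention
#' weights over real keys sum to 1. Rows of `Q` at padded query positions
#' are returned as zero vectors.
#'
#' @param Q,K,V Matrices with `nrow(K) == nrow(V)` and
#'   `ncol(Q) == ncol(K) == d_k`.
#' @param mask Logical vector over key positions, `TRUE` = real (default all
#'   real). Also applied to query rows when `nrow(Q) == nrow(K)`.
#' @param return_weights Also return the attention-weight matrix.
#' @return `nrow(Q) x ncol(V)` matrix, or a list `(output, weights)`.
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL,
                                 return_weights = FALSE) {
  d_k <- ncol(Q)
  if (ncol(K) != d_k) stop("Q and K must share dimension d_k")
  if (nrow(K) != nrow(V)) stop("K and V must have the same number of rows")
  S <- tcrossprod(Q, K) / sqrt(d_k)
  if (!is.null(mask)) {
    if (!any(mask)) stop("all keys are masked: softmax is degenerate")
    S[, !mask] <- NEG_LOGIT
  }
  A <- row_softmax(S)
  out <- A %*% V
  if (!is.null(mask) && nrow(Q) == length(mask)) {
    out[!mask, ] <- 0
    A[!mask, ] <- 0
  }
  if (return_weights) list(output = out, weights = A) else out
}

#' Multi-head self-attention over an encoded sequence
#'
#' Head `i` computes `Attention(Y Wq_i, Y Wk_i, Y Wv_i)`; the head outputs
#' are concatenated and projected by `Wo` back to `d_model`. Queries, keys
#' and values all come from the same sequence (self-attention). Padding
#' positions are zeroed in the output. With `config$residual = TRUE` the
#' input `Y` is added to the projected output.
#'
#' @param Y `n x d_model` input sequence (e.g. the IDCNN output).
#' @param config An [mha_config()].
#' @param params Parameters from [init_mha_params()].
#' @param mask Logical vector of real positions (default all real).
#' @return `n x d_model` matrix.
#' @export
multi_head_attention <- function(Y, config, params, mask = NULL) {
  d <- config$d_model; dk <- config$d_k; h <- config$h
  if (ncol(Y) != d) stop("Y has dimension ", ncol(Y), ", expected ", d)
  if (length(params$Wq) != h || length(params$Wk) != h ||
      length(params$Wv) != h) {
    stop("parameter/config mismatch: expected ", h, " head projections")
  }
  for (i in seq_len(h)) {
    for (M in list(params$Wq[[i]], params$Wk[[i]], params$Wv[[i]])) {
      if (nrow(M) != d || ncol(M) != dk) {
        stop("head projection must be d_model x d_k (", d, " x ", dk, ")")
      }
    }
  }
  if (nrow(params$Wo) != h * dk || ncol(params$Wo) != d) {
    stop("Wo must be (h*d_k) x d_model")
  }
  heads <- matrix(0, nrow(Y), h * dk)
  for (i in seq_len(h)) {
    heads[, ((i - 1L) * dk + 1L):(i * dk)] <- scaled_dot_attention(
      Y %*% params$Wq[[i]], Y %*% params$Wk[[i]], Y %*% params$Wv[[i]],
      mask = mask)
  }
  out <- heads %*% params$Wo
  if (config$residual) out <- out + Y
  if (!is.null(mask)) out[!mask, ] <- 0
  out
}
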