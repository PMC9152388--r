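#' Linear-chain CRF parameters
#'
#' The transition matrix `W` is square of size `L + 2`, where `L` is the
#' number of labels: rows/columns `1..L` are the labels in schema order
#' (0-based schema index + 1), row `L+1` is the START boundary state and
#' column `L+2` the STOP boundary state. `W[i, j]` is the score of moving
#' from label `i` to label `j`.
#'
#' @param n_labels Label count `L`.
#' @param init_sd Standard deviation of random initialization (0 gives an
#'   all-zero matrix).
#' @return An `(L+2) x (L+2)` numeric matrix.
#' @export
init_crf_params <- function(n_labels, init_sd = 0.01) {
  L <- as.integer(n_labels)
  W <- matrix(stats::rnorm((L + 2L)^2, sd = init_sd), L + 2L, L + 2L)
  # entries that can never be used stay zero for readability
  W[, L + 1L] <- 0   # nothing transitions into START
  W[L + 2L, ] <- 0   # nothing leaves STOP
  W
}

crf_start_index <- function(L) L + 1L
crf_stop_index <- function(L) L + 2L

#' Score of one label sequence under a linear-chain CRF
#'
#' `S = sum_t P[t, y_t] + W[START, y_1] + sum_t W[y_t, y_{t+1}] +
#' W[y_n, STOP]`: the emission scores of the chosen labels plus all
#' transition scores including the boundary transitions.
#'
#' @param P `n x L` emission score matrix.
#' @param W `(L+2) x (L+2)` transition matrix (see [init_crf_params()]).
#' @param y Integer vector of 1-based label indices, length `n`.
#' @return Numeric scalar score.
#' @export
sequence_score <- function(P, W, y) {
  n <- nrow(P); L <- ncol(P)
  if (length(y) != n) stop("length(y) must equal nrow(P)")
  if (any(y < 1L) || any(y > L)) stop("label indices out of range")
  s <- sum(P[cbind(seq_len(n), y)]) + W[crf_start_index(L), y[1L]] +
    W[y[n], crf_stop_index(L)]
  if (n > 1L) s <- s + sum(W[cbind(y[-n], y[-1L])])
  s
}

#' Log partition function of a linear-chain CRF
#'
#' `log sum_y exp S(X, y)` over all `L^n` label sequences, computed by the
#' forward algorithm in log space (numerically stable log-sum-exp).
#'
#' @inheritParams sequence_score
#' @return Numeric scalar.
#' @export
log_partition <- function(P, W) {
  crf_forward_cpp(P, W)$log_partition
}

#' Negative log-likelihood of a label sequence
#'
#' `-log P(y | X) = log_partition(P, W) - sequence_score(P, W, y)`; always
#' non-negative.
#'
#' @inheritParams sequence_score
#' @return Numeric scalar.
#' @export
neg_log_likelihood <- function(P, W, y) {
  log_partition(P, W) - sequence_score(P, W, y)
}

#' Gradients of the CRF negative log-likelihood
#'
#' Exact gradients from the forward-backward marginals: the gradient with
#' respect to `P` is the node marginals minus the one-hot encoding of `y`,
#' and with respect to `W` the expected transition counts minus the observed
#' transition counts (including boundary transitions).
#'
#' @inheritParams sequence_score
#' @return List with `nll`, `dP` (`n x L`) and `dW` (`(L+2) x (L+2)`).
#' @export
crf_gradients <- function(P, W, y) {
  n <- nrow(P); L <- ncol(P)
  m <- crf_marginals_cpp(P, W)
  dP <- m$node
  dP[cbind(seq_len(n), y)] <- dP[cbind(seq_len(n), y)] - 1
  dW <- m$transition
  dW[crf_start_index(L), y[1L]] <- dW[crf_start_index(L), y[1L]] - 1
  dW[y[n], crf_stop_index(L)] <- dW[y[n], crf_stop_index(L)] - 1
  if (n > 1L) {
    for (t in seq_len(n - 1L)) {
      dW[y[t], y[t + 1L]] <- dW[y[t], y[t + 1L]] - 1
    }
  }
  list(nll = m$log_partition - sequence_score(P, W, y), dP = dP, dW = dW)
}

#' Transition mask enforcing hard BIO constraints
#'
#' An additive `(L+2) x (L+2)` matrix that is 0 on transitions legal under
#' [legal_transition()] (plus boundary rules: START may not enter `I-X`;
#' every label may stop) and the large negative constant `-1e9` on illegal
#' ones. Added to `W` at decode time to make Viterbi output well-formed.
#'
#' @param schema A [tag_schema()].
#' @return Additive mask matrix.
#' @export
bio_transition_mask <- function(schema = tag_schema()) {
  L <- n_labels(schema)
  mask <- matrix(0, L + 2L, L + 2L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (!legal_transition(schema$tags[i], schema$tags[j], schema)) {
        mask[i, j] <- NEG_LOGIT
      }
    }
  }
  istart <- startsWith(schema$tags, "I-")
  mask[crf_start_index(L), which(istart)] <- NEG_LOGIT
  mask
}

#' Viterbi decoding of the optimal label sequence
#'
#' Returns `y* = argmax_y S(X, y)` and its score by dynamic programming.
#' Ties are broken toward the lowest label index at the latest differing
#' position, so an all-zero score matrix decodes to the all-`"O"` sequence
#' (label index 1). With `constraints`, the additive mask (e.g.
#' [bio_transition_mask()]) is applied to `W` before decoding; the returned
#' score is the unmasked [sequence_score()] of the decoded path.
#'
#' @inheritParams sequence_score
#' @param constraints Optional additive `(L+2) x (L+2)` mask.
#' @return List with `path` (1-based label indices) and `score`.
#' @export
viterbi_decode <- function(P, W, constraints = NULL) {
  Wd <- if (is.null(constraints)) W else W + constraints
  res <- crf_viterbi_cpp(P, Wd)
  if (!is.null(constraints)) {
    res$score <- sequence_score(P, W, res$path)
  }
  res
}
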