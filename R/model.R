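# Full sequence-labeling model: embeddings -> dropout -> input projection ->
# iterated dilated CNN -> multi-head self-attention -> linear emission layer
# -> linear-chain CRF. Forward pass and exact backpropagation are implemented
# over a flat named parameter list so any optimizer in optimizers.R applies.

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Model configuration
#'
#' Defaults follow the reference training setup for clinical records:
#' embedding size and filter count 128, 4 attention heads, dilation schedule
#' `c(1, 1, 2)` iterated 4 times, dropout 0.5 between the embedding and
#' convolutional layers, batch size 20. The default learning rate is `1e-3`
#' for the from-scratch trainable embedder; `3e-5` is the appropriate value
#' when fine-tuning a pretrained contextual embedder through the adapter.
#'
#' @param d_model Embedding dimension (default 128).
#' @param filters IDCNN channel count and attention model dimension
#'   (default 128).
#' @param heads Attention head count (default 4).
#' @param kernel_size Convolution kernel width (odd, default 3).
#' @param dilations Per-block dilation schedule (default `c(1, 1, 2)`).
#' @param iterations Shared-parameter block repetitions (default 4).
#' @param dropout Dropout rate in `[0, 1)` applied to the embeddings during
#'   training (default 0.5).
#' @param optimizer Optimizer name, see [make_optimizer()].
#' @param learning_rate Learning rate (default `1e-3`).
#' @param batch_size Sentences per gradient step (default 20).
#' @param epochs Maximum training epochs (default 30).
#' @param patience Early-stopping patience in epochs on dev F1 (default 5).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @param use_mha Include the multi-head attention layer (default `TRUE`;
#'   `FALSE` gives the convolution-only ablation).
#' @param residual Residual connection around the attention layer (default
#'   `TRUE`). Without it every emission is a softmax-mixture of value
#'   vectors, so positional identity only reaches the decoder once the
#'   attention matrix has learned to be near-diagonal; training from scratch
#'   stalls. The bare layer is available with `residual = FALSE`.
#' @param position_mode `"sinusoidal"` or `"learned"`.
#' @param max_len Maximum sentence length (default 128).
#' @param constrained_decode Apply [bio_transition_mask()] at decode time
#'   (default `TRUE`); training always uses the unconstrained transition
#'   matrix.
#' @return A `model_config` list.
#' @export
model_config <- function(d_model = 128L, filters = 128L, heads = 4L,
                         kernel_size = 3L, dilations = c(1L, 1L, 2L),
                         iterations = 4L, dropout = 0.5,
                         optimizer = "adam", learning_rate = 1e-3,
                         batch_size = 20L, epochs = 30L, patience = 5L,
                         seed = 0L, use_mha = TRUE, residual = TRUE,
                         position_mode = "sinusoidal", max_len = 128L,
                         constrained_decode = TRUE) {
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (filters %% heads != 0L) {
    stop("filters (", filters, ") must be divisible by heads (", heads, ")")
  }
  cfg <- list(d_model = as.integer(d_model), filters = as.integer(filters),
              heads = as.integer(heads), kernel_size = as.integer(kernel_size),
              dilations = as.integer(dilations),
              iterations = as.integer(iterations), dropout = dropout,
              optimizer = optimizer, learning_rate = learning_rate,
              batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              patience = as.integer(patience), seed = as.integer(seed),
              use_mha = isTRUE(use_mha), residual = isTRUE(residual),
              position_mode = position_mode, max_len = as.integer(max_len),
              constrained_decode = isTRUE(constrained_decode))
  structure(cfg, class = "model_config")
}

#' Build a model instance
#'
#' Allocates all parameters with a deterministic seeded initialization. Two
#' builds under the same configuration and vocabulary produce identical
#' parameters.
#'
#' @param config A [model_config()].
#' @param schema A [tag_schema()].
#' @param vocab A [build_vocabulary()] vocabulary.
#' @return An object of class `cner_model` holding `config`, `schema`,
#'   `vocab` and the flat parameter list `params`.
#' @export
build_model <- function(config, schema = tag_schema(), vocab) {
  emb_cfg <- embedding_config(config$d_model, config$position_mode,
                              config$max_len)
  idc_cfg <- idcnn_config(config$filters, config$kernel_size,
                          config$dilations, config$iterations)
  mha_cfg <- mha_config(config$heads, config$filters,
                        residual = config$residual)
  L <- n_labels(schema)
  params <- with_seed(config$seed, {
    emb <- init_embedding_params(vocab, emb_cfg)
    p <- list(tok = emb$token, seg = emb$segment)
    if (config$position_mode == "learned") p$pos <- emb$position
    p$win <- matrix(stats::rnorm(config$d_model * config$filters,
                                 sd = sqrt(1 / config$d_model)),
                    config$d_model, config$filters)
    p$bin <- numeric(config$filters)
    idc <- init_idcnn_params(config$filters, idc_cfg)
    for (l in seq_along(idc_cfg$dilations)) {
      # tap-stacked form: rows (k-1)*F + (1:F) hold kernel tap k, so one
      # conv layer is a single matmul against the concatenated shifted input
      kern <- idc$kernels[[l]]
      p[[paste0("conv_k", l)]] <- do.call(rbind, lapply(
        seq_len(config$kernel_size),
        function(k) matrix(kern[k, , ], config$filters, config$filters)))
      p[[paste0("conv_b", l)]] <- idc$biases[[l]]
    }
    if (config$use_mha) {
      mha <- init_mha_params(mha_cfg)
      for (i in seq_len(config$heads)) {
        p[[paste0("wq", i)]] <- mha$Wq[[i]]
        p[[paste0("wk", i)]] <- mha$Wk[[i]]
        p[[paste0("wv", i)]] <- mha$Wv[[i]]
      }
      # zero-initialized output projection: with the residual connection the
      # attention branch starts as the identity map and its contribution
      # grows only as it is learned, which stabilizes early training
      p$wo <- if (config$residual) mha$Wo * 0 else mha$Wo
    }
    p$wem <- matrix(stats::rnorm(config$filters * L,
                                 sd = sqrt(1 / config$filters)),
                    config$filters, L)
    p$bem <- numeric(L)
    p$wcrf <- init_crf_params(L)
    p
  })
  structure(list(config = config, schema = schema, vocab = vocab,
                 params = params,
                 emb_config = emb_cfg, idcnn_config = idc_cfg,
                 mha_config = mha_cfg),
            class = "cner_model")
}

#' @export
print.cner_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<cner_model> d_model=", x$config$d_model, " filters=",
      x$config$filters, " heads=", x$config$heads,
      if (!x$config$use_mha) " (no MHA)", " | ", np, " parameters\n", sep = "")
  invisible(x)
}

mha_params_from_flat <- function(params, h) {
  list(Wq = lapply(seq_len(h), function(i) params[[paste0("wq", i)]]),
       Wk = lapply(seq_len(h), function(i) params[[paste0("wk", i)]]),
       Wv = lapply(seq_len(h), function(i) params[[paste0("wv", i)]]),
       Wo = params$wo)
}

# forward pass on one sentence of 0-based char ids; returns emissions and,
# when keep_cache, every intermediate needed for backprop
model_forward <- function(params, model, ids, dropmask = NULL,
                          keep_cache = FALSE) {
  cfg <- model$config
  n <- length(ids)
  E0 <- embed_sequence(ids, NULL, model$emb_config,
                       list(token = params$tok, segment = params$seg,
                            position = params$pos))
  E <- if (is.null(dropmask)) E0 else E0 * dropmask
  X <- sweep(E %*% params$win, 2L, params$bin, "+")
  # iterated dilated convolutions, shared parameters across iterations
  n_layers <- length(cfg$dilations)
  KS <- cfg$kernel_size
  Fh <- cfg$filters
  center <- (KS + 1L) %/% 2L
  kerns <- lapply(seq_len(n_layers), function(l) params[[paste0("conv_k", l)]])
  biases <- lapply(seq_len(n_layers), function(l) params[[paste0("conv_b", l)]])
  conv_in <- if (keep_cache) vector("list", cfg$iterations * n_layers)
  relu_pos <- if (keep_cache) vector("list", cfg$iterations * n_layers)
  h <- X
  li <- 0L
  for (it in seq_len(cfg$iterations)) {
    for (l in seq_len(n_layers)) {
      li <- li + 1L
      # concatenated shifted input: column block k holds x shifted by tap k
      xcat <- matrix(0, n, KS * Fh)
      for (k in seq_len(KS)) {
        off <- (k - center) * cfg$dilations[l]
        xcat[, ((k - 1L) * Fh + 1L):(k * Fh)] <- shift_rows(h, off)
      }
      z <- xcat %*% kerns[[l]]
      z <- z + rep(biases[[l]], each = n)
      if (keep_cache) {
        conv_in[[li]] <- xcat
        relu_pos[[li]] <- z > 0
      }
      h <- pmax(z, 0)
    }
  }
  Y <- h
  # multi-head self-attention
  if (cfg$use_mha) {
    dk <- cfg$filters %/% cfg$heads
    heads <- matrix(0, n, cfg$filters)
    att <- if (keep_cache) vector("list", cfg$heads)
    for (i in seq_len(cfg$heads)) {
      Q <- Y %*% params[[paste0("wq", i)]]
      K <- Y %*% params[[paste0("wk", i)]]
      V <- Y %*% params[[paste0("wv", i)]]
      S <- tcrossprod(Q, K) / sqrt(dk)
      A <- row_softmax(S)
      heads[, ((i - 1L) * dk + 1L):(i * dk)] <- A %*% V
      if (keep_cache) att[[i]] <- list(Q = Q, K = K, V = V, A = A)
    }
    M <- heads %*% params$wo
    if (cfg$residual) M <- M + Y
  } else {
    M <- Y
  }
  P <- sweep(M %*% params$wem, 2L, params$bem, "+")
  if (!keep_cache) return(list(P = P))
  list(P = P, cache = list(ids = ids, E0 = E0, E = E, dropmask = dropmask,
                           X = X, conv_in = conv_in, relu_pos = relu_pos,
                           Y = Y,
                           heads = if (cfg$use_mha) heads,
                           att = if (cfg$use_mha) att,
                           M = M))
}

# backprop from emission-score gradient dP to gradients of every parameter;
# returns a flat list aligned with `params` (missing entries = zero handled
# by caller via accumulate_grads)
model_backward <- function(params, model, cache, dP) {
  cfg <- model$config
  n <- length(cache$ids)
  g <- list()
  g$wem <- crossprod(cache$M, dP)
  g$bem <- colSums(dP)
  dM <- tcrossprod(dP, params$wem)
  if (cfg$use_mha) {
    dk <- cfg$filters %/% cfg$heads
    g$wo <- crossprod(cache$heads, dM)
    dheads <- tcrossprod(dM, params$wo)
    dY <- if (cfg$residual) dM else matrix(0, n, cfg$filters)
    for (i in seq_len(cfg$heads)) {
      a <- cache$att[[i]]
      dO <- dheads[, ((i - 1L) * dk + 1L):(i * dk), drop = FALSE]
      dA <- tcrossprod(dO, a$V)
      dV <- crossprod(a$A, dO)
      dS <- a$A * (dA - rowSums(dA * a$A))
      dS <- dS / sqrt(dk)
      dQ <- dS %*% a$K
      dK <- crossprod(dS, a$Q)
      g[[paste0("wq", i)]] <- crossprod(cache$Y, dQ)
      g[[paste0("wk", i)]] <- crossprod(cache$Y, dK)
      g[[paste0("wv", i)]] <- crossprod(cache$Y, dV)
      dY <- dY + tcrossprod(dQ, params[[paste0("wq", i)]]) +
        tcrossprod(dK, params[[paste0("wk", i)]]) +
        tcrossprod(dV, params[[paste0("wv", i)]])
    }
  } else {
    dY <- dM
  }
  # back through the iterated convolutions (shared parameters: accumulate)
  n_layers <- length(cfg$dilations)
  KS <- cfg$kernel_size
  Fh <- cfg$filters
  center <- (KS + 1L) %/% 2L
  kerns <- lapply(seq_len(n_layers), function(l) params[[paste0("conv_k", l)]])
  gk <- lapply(kerns, function(k) k * 0)
  gb <- lapply(seq_len(n_layers), function(l) numeric(Fh))
  dh <- dY
  for (it in rev(seq_len(cfg$iterations))) {
    for (l in rev(seq_len(n_layers))) {
      li <- (it - 1L) * n_layers + l
      dZ <- dh * cache$relu_pos[[li]]
      xcat <- cache$conv_in[[li]]
      gb[[l]] <- gb[[l]] + colSums(dZ)
      gk[[l]] <- gk[[l]] + crossprod(xcat, dZ)
      dxcat <- tcrossprod(dZ, kerns[[l]])
      dXin <- matrix(0, n, Fh)
      for (k in seq_len(KS)) {
        off <- (k - center) * cfg$dilations[l]
        dXin <- dXin +
          shift_rows(dxcat[, ((k - 1L) * Fh + 1L):(k * Fh), drop = FALSE],
                     -off)
      }
      dh <- dXin
    }
  }
  for (l in seq_len(n_layers)) {
    g[[paste0("conv_k", l)]] <- gk[[l]]
    g[[paste0("conv_b", l)]] <- gb[[l]]
  }
  dX <- dh
  g$win <- crossprod(cache$E, dX)
  g$bin <- colSums(dX)
  dE <- tcrossprod(dX, params$win)
  dE0 <- if (is.null(cache$dropmask)) dE else dE * cache$dropmask
  dtok <- matrix(0, nrow(params$tok), cfg$d_model)
  agg <- rowsum(dE0, group = cache$ids)
  dtok[as.integer(rownames(agg)) + 1L, ] <- agg
  dtok[PAD_ID + 1L, ] <- 0  # the padding row stays fixed at zero
  g$tok <- dtok
  dseg <- matrix(0, 2L, cfg$d_model)
  dseg[1L, ] <- colSums(dE0)   # single-sentence inputs use segment 0
  g$seg <- dseg
  if (cfg$position_mode == "learned") {
    dpos <- matrix(0, nrow(params$pos), cfg$d_model)
    dpos[seq_len(n), ] <- dE0
    g$pos <- dpos
  }
  g
}

zero_like <- function(params) lapply(params, function(p) p * 0)

sentences_to_ids <- function(sentences, vocab, schema, max_len) {
  lapply(sentences, function(s) {
    if (length(s$chars) > max_len) {
      stop("sentence of length ", length(s$chars), " exceeds max_len ",
           max_len, "; split it first with split_document()")
    }
    list(ids = chars_to_ids(s$chars, vocab),
         y = unname(schema$tag_index[s$tags]) + 1L)
  })
}

#' Mean loss and gradients over a batch of sentences
#'
#' Computes the mean CRF negative log-likelihood of the batch and its exact
#' gradient with respect to every model parameter by backpropagation. Used
#' by [train_model()] and directly useful for gradient checking.
#'
#' @param model A [build_model()] instance.
#' @param sentences List of [labeled_sentence()] objects.
#' @param params Parameter list (defaults to the model's own).
#' @param dropout Apply dropout (training mode); default `FALSE` so the
#'   computation is deterministic.
#' @return List with `loss` and `grads` (flat list aligned with `params`).
#' @export
model_batch_gradients <- function(model, sentences, params = model$params,
                                  dropout = FALSE) {
  enc <- sentences_to_ids(sentences, model$vocab, model$schema,
                          model$config$max_len)
  total <- zero_like(params)
  loss <- 0
  B <- length(enc)
  for (s in enc) {
    dm <- NULL
    if (dropout && model$config$dropout > 0) {
      keep <- 1 - model$config$dropout
      dm <- matrix(stats::rbinom(length(s$ids) * model$config$d_model, 1L,
                                 keep) / keep,
                   length(s$ids), model$config$d_model)
    }
    fw <- model_forward(params, model, s$ids, dropmask = dm,
                        keep_cache = TRUE)
    cg <- crf_gradients(fw$P, params$wcrf, s$y)
    if (!is.finite(cg$nll)) {
      stop("non-finite loss on a sentence of length ", length(s$ids),
           " (lr = ", model$config$learning_rate, ")")
    }
    loss <- loss + cg$nll
    g <- model_backward(params, model, fw$cache, cg$dP)
    g$wcrf <- cg$dW
    for (nm in names(g)) total[[nm]] <- total[[nm]] + g[[nm]]
  }
  list(loss = loss / B, grads = lapply(total, function(x) x / B))
}

#' Mean CRF negative log-likelihood of a batch
#'
#' Deterministic (no dropout) evaluation-mode loss; the objective minimized
#' by [train_model()].
#'
#' @inheritParams model_batch_gradients
#' @return Numeric scalar.
#' @export
model_batch_loss <- function(model, sentences, params = model$params) {
  enc <- sentences_to_ids(sentences, model$vocab, model$schema,
                          model$config$max_len)
  loss <- 0
  for (s in enc) {
    fw <- model_forward(params, model, s$ids)
    loss <- loss + neg_log_likelihood(fw$P, params$wcrf, s$y)
  }
  loss / length(enc)
}

#' Train a model by mini-batch maximum likelihood
#'
#' Minimizes the mean CRF negative log-likelihood with the configured
#' optimizer, evaluating strict entity-level P/R/F1 on the dev set after
#' each epoch and keeping the best-F1 parameters. Stops early when dev F1
#' has not improved for `patience` epochs. Fully reproducible given the
#' config seed on one thread.
#'
#' @param model A [build_model()] instance.
#' @param train_set,dev_set Lists of [labeled_sentence()] objects (`dev_set`
#'   may be `NULL`: no per-epoch evaluation or early stopping).
#' @param epochs,batch_size Optional overrides of the config values.
#' @param max_steps Optional cap on total gradient steps (for quick
#'   memorization runs); `Inf` by default.
#' @param verbose Print per-epoch progress.
#' @return The trained model, with a `report` element: a data frame of
#'   per-epoch loss, dev metrics and wall time, plus `best_epoch`.
#' @export
train_model <- function(model, train_set, dev_set = NULL, epochs = NULL,
                        batch_size = NULL, max_steps = Inf, verbose = FALSE) {
  if (!length(train_set)) stop("empty training set")
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  if (is.null(batch_size)) batch_size <- cfg$batch_size
  opt <- make_optimizer(cfg$optimizer, lr = cfg$learning_rate)
  params <- model$params
  n <- length(train_set)
  report <- data.frame(epoch = integer(), loss = numeric(),
                       dev_precision = numeric(), dev_recall = numeric(),
                       dev_f1 = numeric(), seconds = numeric())
  best_f1 <- -Inf; best_params <- params; best_epoch <- 0L
  stall <- 0L; steps <- 0L
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      t0 <- proc.time()[["elapsed"]]
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (b0 in seq(1L, n, by = batch_size)) {
        if (steps >= max_steps) break
        idx <- ord[b0:min(b0 + batch_size - 1L, n)]
        bg <- model_batch_gradients(model, train_set[idx], params,
                                    dropout = cfg$dropout > 0)
        params <- opt$step(params, bg$grads)
        ep_loss <- ep_loss + bg$loss; nb <- nb + 1L
        steps <- steps + 1L
      }
      if (nb == 0L) break
      ep_loss <- ep_loss / nb
      row <- data.frame(epoch = ep, loss = ep_loss, dev_precision = NA_real_,
                        dev_recall = NA_real_, dev_f1 = NA_real_,
                        seconds = proc.time()[["elapsed"]] - t0)
      if (!is.null(dev_set)) {
        m2 <- model; m2$params <- params
        pred <- predict(m2, dev_set)
        ev <- strict_match_eval(dev_set, pred, model$schema)
        row$dev_precision <- ev$overall$precision
        row$dev_recall <- ev$overall$recall
        row$dev_f1 <- ev$overall$f1
        if (ev$overall$f1 > best_f1) {
          best_f1 <- ev$overall$f1; best_params <- params; best_epoch <- ep
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
      } else {
        best_params <- params; best_epoch <- ep
      }
      report <- rbind(report, row)
      if (verbose) {
        cat(sprintf("epoch %3d  loss %8.4f  dev F1 %s  (%.1fs)\n", ep,
                    ep_loss,
                    if (is.na(row$dev_f1)) "-" else sprintf("%6.2f", row$dev_f1),
                    row$seconds))
      }
      if (!is.null(dev_set) && stall >= cfg$patience) break
      if (steps >= max_steps) break
    }
  })
  model$params <- best_params
  model$report <- list(epochs = report, best_epoch = best_epoch,
                       best_dev_f1 = if (is.finite(best_f1)) best_f1)
  model
}

#' Predict tags and entity mentions
#'
#' Runs the evaluation-mode forward pass (dropout disabled) and Viterbi
#' decoding on each sentence, then recovers entity mentions with the repair
#' decoding policy (predictions may be ill-formed when hard transition
#' constraints are disabled). Sentences are processed independently, so the
#' output does not depend on any batching.
#'
#' @param object A `cner_model`.
#' @param sentences List of [labeled_sentence()] objects (tags ignored).
#' @param ... Unused.
#' @return List, one element per sentence, each with `tags` (character
#'   labels) and `mentions` (an [entity_mentions()] data frame).
#' @export
predict.cner_model <- function(object, sentences, ...) {
  if (!length(sentences)) return(list())
  constraints <- if (object$config$constrained_decode) {
    bio_transition_mask(object$schema)
  }
  enc <- sentences_to_ids(sentences, object$vocab, object$schema,
                          object$config$max_len)
  lapply(enc, function(s) {
    fw <- model_forward(object$params, object, s$ids)
    vd <- viterbi_decode(fw$P, object$params$wcrf, constraints)
    tags <- object$schema$tags[vd$path]
    list(tags = tags,
         mentions = decode_tags(tags, object$schema, policy = "repair"))
  })
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a directory holding `model.json` (config, schema,
#' parameters) and `vocab.txt`, so a saved model reloads with no other
#' state.
#'
#' @param model A `cner_model`.
#' @param dir Checkpoint directory (created if missing).
#' @return `load_model` returns the restored `cner_model`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ser <- lapply(model$params, function(p) {
    list(dim = if (is.null(dim(p))) length(p) else dim(p), data = as.vector(p))
  })
  obj <- list(config = unclass(model$config), types = model$schema$types,
              params = ser)
  jsonlite::write_json(obj, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  write_vocabulary(model$vocab, file.path(dir, "vocab.txt"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  obj <- jsonlite::fromJSON(file.path(dir, "model.json"),
                            simplifyVector = TRUE)
  cfg <- do.call(model_config, obj$config[setdiff(names(obj$config), NULL)])
  schema <- tag_schema(obj$types)
  vocab <- read_vocabulary(file.path(dir, "vocab.txt"))
  model <- build_model(cfg, schema, vocab)
  for (nm in names(obj$params)) {
    p <- obj$params[[nm]]
    d <- as.integer(p$dim)
    model$params[[nm]] <- if (length(d) == 1L) as.numeric(p$data) else
      array(as.numeric(p$data), d)
  }
  model
}

#' Sweep the attention head count
#'
#' Trains one model per head count on the same corpus and reports dev F1 for
#' each, the standard experiment for choosing `h`.
#'
#' @param values Head counts to try (default `c(1, 2, 4, 8, 16)`).
#' @param train_set,dev_set Corpora.
#' @param config Base [model_config()] (its `heads` field is overridden;
#'   `filters` must be divisible by every value).
#' @param vocab Optional shared vocabulary (built from `train_set` when
#'   `NULL`).
#' @param schema A [tag_schema()].
#' @param verbose Print progress.
#' @return Data frame with columns `heads`, `dev_precision`, `dev_recall`,
#'   `dev_f1`, `best_epoch`.
#' @export
sweep_heads <- function(values = c(1L, 2L, 4L, 8L, 16L), train_set, dev_set,
                        config = model_config(), vocab = NULL,
                        schema = tag_schema(), verbose = FALSE) {
  if (is.null(vocab)) vocab <- build_vocabulary(train_set)
  rows <- lapply(values, function(h) {
    cfg <- config; cfg$heads <- as.integer(h)
    m <- build_model(cfg, schema, vocab)
    m <- train_model(m, train_set, dev_set, verbose = verbose)
    ep <- m$report$epochs
    best <- ep[which.max(ep$dev_f1), ]
    data.frame(heads = h, dev_precision = best$dev_precision,
               dev_recall = best$dev_recall, dev_f1 = best$dev_f1,
               best_epoch = m$report$best_epoch)
  })
  do.call(rbind, rows)
}

#' Compare optimizers on one corpus
#'
#' @param optimizers Character vector of optimizer names (see
#'   [make_optimizer()]).
#' @inheritParams sweep_heads
#' @return Data frame with one row per optimizer and dev metrics.
#' @export
compare_optimizers <- function(optimizers = c("adagrad", "rmsprop", "adam",
                                              "lookahead_adam", "radam"),
                               train_set, dev_set, config = model_config(),
                               vocab = NULL, schema = tag_schema(),
                               verbose = FALSE) {
  if (is.null(vocab)) vocab <- build_vocabulary(train_set)
  rows <- lapply(optimizers, function(op) {
    cfg <- config; cfg$optimizer <- op
    m <- build_model(cfg, schema, vocab)
    m <- train_model(m, train_set, dev_set, verbose = verbose)
    ep <- m$report$epochs
    best <- ep[which.max(ep$dev_f1), ]
    data.frame(optimizer = op, dev_precision = best$dev_precision,
               dev_recall = best$dev_recall, dev_f1 = best$dev_f1,
               best_epoch = m$report$best_epoch)
  })
  do.call(rbind, rows)
}
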