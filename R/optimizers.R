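# Adaptive-gradient optimizers over a flat named list of numeric arrays.
# Each optimizer is a closure with internal state; `step(params, grads)`
# returns the updated parameter list. Update rules follow the standard
# published forms (Adagrad, RMSprop, Adam, RAdam); Lookahead is a slow/fast
# weights wrapper around any inner optimizer.

#' Create an optimizer
#'
#' @param name One of `"adagrad"`, `"rmsprop"`, `"adam"`, `"radam"`,
#'   `"lookahead_adam"`.
#' @param lr Learning rate.
#' @param beta1,beta2 Adam/RAdam moment decay rates.
#' @param rho RMSprop decay rate.
#' @param eps Numerical stabilizer.
#' @param lookahead_k Lookahead synchronization period (fast steps per slow
#'   update).
#' @param lookahead_alpha Lookahead slow-weights step size.
#' @return An object of class `optimizer` with elements `name` and
#'   `step(params, grads)`.
#' @export
make_optimizer <- function(name = c("adam", "adagrad", "rmsprop", "radam",
                                    "lookahead_adam"),
                           lr = 1e-3, beta1 = 0.9, beta2 = 0.999, rho = 0.9,
                           eps = 1e-8, lookahead_k = 5L,
                           lookahead_alpha = 0.5) {
  name <- match.arg(name)
  inner <- switch(
    name,
    adagrad = adagrad_optimizer(lr, eps),
    rmsprop = rmsprop_optimizer(lr, rho, eps),
    adam = adam_optimizer(lr, beta1, beta2, eps),
    radam = radam_optimizer(lr, beta1, beta2, eps),
    lookahead_adam = lookahead_optimizer(
      adam_optimizer(lr, beta1, beta2, eps), lookahead_k, lookahead_alpha)
  )
  structure(list(name = name, step = inner), class = "optimizer")
}

adagrad_optimizer <- function(lr, eps) {
  acc <- NULL
  function(params, grads) {
    if (is.null(acc)) acc <<- lapply(params, function(p) p * 0)
    for (k in names(params)) {
      acc[[k]] <<- acc[[k]] + grads[[k]]^2
      params[[k]] <- params[[k]] - lr * grads[[k]] / (sqrt(acc[[k]]) + eps)
    }
    params
  }
}

rmsprop_optimizer <- function(lr, rho, eps) {
  acc <- NULL
  function(params, grads) {
    if (is.null(acc)) acc <<- lapply(params, function(p) p * 0)
    for (k in names(params)) {
      acc[[k]] <<- rho * acc[[k]] + (1 - rho) * grads[[k]]^2
      params[[k]] <- params[[k]] - lr * grads[[k]] / (sqrt(acc[[k]]) + eps)
    }
    params
  }
}

adam_optimizer <- function(lr, beta1, beta2, eps) {
  m <- NULL; v <- NULL; t <- 0L
  function(params, grads) {
    if (is.null(m)) {
      m <<- lapply(params, function(p) p * 0)
      v <<- lapply(params, function(p) p * 0)
    }
    t <<- t + 1L
    bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
    for (k in names(params)) {
      m[[k]] <<- beta1 * m[[k]] + (1 - beta1) * grads[[k]]
      v[[k]] <<- beta2 * v[[k]] + (1 - beta2) * grads[[k]]^2
      params[[k]] <- params[[k]] -
        lr * (m[[k]] / bc1) / (sqrt(v[[k]] / bc2) + eps)
    }
    params
  }
}

radam_optimizer <- function(lr, beta1, beta2, eps) {
  # rectified Adam: the adaptive term is used only once its variance is
  # tractable (rho_t > 4); earlier steps fall back to bias-corrected momentum
  m <- NULL; v <- NULL; t <- 0L
  rho_inf <- 2 / (1 - beta2) - 1
  function(params, grads) {
    if (is.null(m)) {
      m <<- lapply(params, function(p) p * 0)
      v <<- lapply(params, function(p) p * 0)
    }
    t <<- t + 1L
    bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
    rho_t <- rho_inf - 2 * t * beta2^t / bc2
    for (k in names(params)) {
      m[[k]] <<- beta1 * m[[k]] + (1 - beta1) * grads[[k]]
      v[[k]] <<- beta2 * v[[k]] + (1 - beta2) * grads[[k]]^2
      mhat <- m[[k]] / bc1
      if (rho_t > 4) {
        r_t <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                      ((rho_inf - 4) * (rho_inf - 2) * rho_t))
        params[[k]] <- params[[k]] -
          lr * r_t * mhat / (sqrt(v[[k]] / bc2) + eps)
      } else {
        params[[k]] <- params[[k]] - lr * mhat
      }
    }
    params
  }
}

lookahead_optimizer <- function(inner_step, k, alpha) {
  slow <- NULL; t <- 0L
  function(params, grads) {
    if (is.null(slow)) slow <<- params
    params <- inner_step(params, grads)
    t <<- t + 1L
    if (t %% k == 0L) {
      for (nm in names(params)) {
        slow[[nm]] <<- slow[[nm]] + alpha * (params[[nm]] - slow[[nm]])
      }
      params <- slow
    }
    params
  }
}
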