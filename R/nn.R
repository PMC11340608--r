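# Minimal dense neural-network core: linear / batch-norm / activation /
# dropout stages with exact manual gradients and an AdamW (decoupled weight
# decay) optimizer. Written in plain matrix algebra; problem sizes here are
# small enough that this is fast and keeps training bit-reproducible under a
# seed on one device.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

act_forward <- function(x, fun) {
  switch(fun,
    linear = x,
    relu = pmax(x, 0),
    sigmoid = 1 / (1 + exp(-x)),
    elu = ifelse(x > 0, x, exp(x) - 1),
    selu = SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(x) - 1)),
    abort(sprintf("Unknown activation '%s'.", fun))
  )
}

act_backward <- function(g, x, fun) {
  switch(fun,
    linear = g,
    relu = g * (x > 0),
    sigmoid = g * plogis(x) * (1 - plogis(x)),
    elu = g * ifelse(x > 0, 1, exp(x)),
    selu = g * SELU_LAMBDA * ifelse(x > 0, 1, SELU_ALPHA * exp(x))
  )
}

#' Configuration of a six-stage profile MLP
#'
#' The image-based-profile classifier is a six-stage fully connected network
#' with batch normalization at every hidden stage, dropout in the first two
#' stages, the activation sequence ELU, ReLU, ELU, ReLU, SELU and a linear
#' class head.
#'
#' @param layer_sizes Six integers: five hidden widths plus the output width
#'   (number of classes, or embedding size when used as a fusion trunk).
#' @param activations Six activation names among `"elu"`, `"relu"`,
#'   `"selu"`, `"linear"`.
#' @param dropout Six dropout rates in `[0, 1)`.
#' @param batch_norm Use batch normalization on hidden stages.
#' @return An `cvf_mlp_config` list.
#' @export
mlp_config <- function(layer_sizes = c(256, 128, 64, 64, 32, 10),
                       activations = c("elu", "relu", "elu", "relu", "selu",
                                       "linear"),
                       dropout = c(0.2, 0.2, 0, 0, 0, 0),
                       batch_norm = TRUE) {
  if (length(layer_sizes) != 6 || length(activations) != 6 ||
      length(dropout) != 6) {
    abort("A profile MLP has exactly six stages; supply six sizes, activations and dropout rates.",
          class = "cvf_config_error")
  }
  if (any(dropout < 0 | dropout >= 1)) {
    abort("Dropout rates must lie in [0, 1).", class = "cvf_config_error")
  }
  structure(list(layer_sizes = as.integer(layer_sizes),
                 activations = activations, dropout = dropout,
                 batch_norm = isTRUE(batch_norm)),
            class = "cvf_mlp_config")
}

# Build the internal net structure: a list of stages, each
# linear (+ optional batchnorm) + activation (+ optional dropout).
net_init <- function(input_dim, layer_sizes, activations, dropout,
                     batch_norm, seed = 1L) {
  n_stage <- length(layer_sizes)
  withr::with_seed(as.integer(seed), {
    params <- list()
    running <- list()
    dims_in <- c(input_dim, layer_sizes[-n_stage])
    for (i in seq_len(n_stage)) {
      fan_in <- dims_in[i]
      # He-style init, scaled for the mixed ELU/ReLU/SELU stack
      params[[sprintf("W%d", i)]] <-
        matrix(rnorm(fan_in * layer_sizes[i], 0, sqrt(2 / fan_in)),
               fan_in, layer_sizes[i])
      params[[sprintf("b%d", i)]] <- rep(0, layer_sizes[i])
      if (batch_norm && activations[i] != "linear") {
        params[[sprintf("g%d", i)]] <- rep(1, layer_sizes[i])
        params[[sprintf("e%d", i)]] <- rep(0, layer_sizes[i])
        running[[sprintf("mu%d", i)]] <- rep(0, layer_sizes[i])
        running[[sprintf("var%d", i)]] <- rep(1, layer_sizes[i])
      }
    }
    structure(list(input_dim = input_dim, layer_sizes = layer_sizes,
                   activations = activations, dropout = dropout,
                   batch_norm = batch_norm, params = params,
                   running = running),
              class = "cvf_net")
  })
}

BN_EPS <- 1e-5

net_forward <- function(net, x, train = FALSE) {
  x <- as.matrix(x)
  n_stage <- length(net$layer_sizes)
  cache <- vector("list", n_stage)
  running <- net$running
  for (i in seq_len(n_stage)) {
    st <- list()
    st$x_in <- x
    z <- x %*% net$params[[sprintf("W%d", i)]]
    z <- sweep(z, 2, net$params[[sprintf("b%d", i)]], "+")
    has_bn <- net$batch_norm && net$activations[i] != "linear"
    if (has_bn) {
      if (train) {
        mu <- colMeans(z)
        v <- colMeans(sweep(z, 2, mu)^2)
        running[[sprintf("mu%d", i)]] <-
          0.9 * running[[sprintf("mu%d", i)]] + 0.1 * mu
        running[[sprintf("var%d", i)]] <-
          0.9 * running[[sprintf("var%d", i)]] + 0.1 * v
      } else {
        mu <- running[[sprintf("mu%d", i)]]
        v <- running[[sprintf("var%d", i)]]
      }
      inv <- 1 / sqrt(v + BN_EPS)
      xhat <- sweep(sweep(z, 2, mu), 2, inv, "*")
      st$xhat <- xhat
      st$inv <- inv
      z <- sweep(sweep(xhat, 2, net$params[[sprintf("g%d", i)]], "*"),
                 2, net$params[[sprintf("e%d", i)]], "+")
    }
    st$pre_act <- z
    a <- act_forward(z, net$activations[i])
    if (train && net$dropout[i] > 0) {
      keep <- 1 - net$dropout[i]
      mask <- matrix(
        (runif(length(a)) < keep) / keep, nrow(a), ncol(a))
      st$mask <- mask
      a <- a * mask
    }
    cache[[i]] <- st
    x <- a
  }
  list(out = x, cache = cache, running = running)
}

net_backward <- function(net, cache, g) {
  n_stage <- length(net$layer_sizes)
  grads <- list()
  for (i in rev(seq_len(n_stage))) {
    st <- cache[[i]]
    if (!is.null(st$mask)) g <- g * st$mask
    g <- act_backward(g, st$pre_act, net$activations[i])
    has_bn <- net$batch_norm && net$activations[i] != "linear"
    if (has_bn) {
      xhat <- st$xhat
      grads[[sprintf("g%d", i)]] <- colSums(g * xhat)
      grads[[sprintf("e%d", i)]] <- colSums(g)
      gam <- net$params[[sprintf("g%d", i)]]
      dxhat <- sweep(g, 2, gam, "*")
      n <- nrow(g)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      g <- sweep(
        sweep(dxhat, 2, s1 / n) -
          xhat * matrix(s2 / n, n, length(s2), byrow = TRUE),
        2, st$inv, "*")
    }
    grads[[sprintf("W%d", i)]] <- t(st$x_in) %*% g
    grads[[sprintf("b%d", i)]] <- colSums(g)
    g <- g %*% t(net$params[[sprintf("W%d", i)]])
  }
  list(grads = grads, dx = g)
}

# Softmax cross-entropy: returns mean loss, probabilities and the gradient of
# the mean loss w.r.t. the logits.
softmax_ce <- function(logits, y_idx) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y_idx)], 1e-12)))
  g <- p
  g[cbind(seq_len(n), y_idx)] <- g[cbind(seq_len(n), y_idx)] - 1
  list(loss = loss, probs = p, grad = g / n)
}

# AdamW: adaptive moments with decoupled weight decay (decay applied to
# weight matrices only, never to biases or batch-norm parameters).
adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamw_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 1e-2) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    upd <- (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
    if (startsWith(nm, "W")) {
      params[[nm]] <- params[[nm]] - lr * (upd + weight_decay * params[[nm]])
    } else {
      params[[nm]] <- params[[nm]] - lr * upd
    }
  }
  list(params = params, state = state)
}

#' Build the image-based-profile MLP classifier
#'
#' Six fully connected stages with batch normalization, dropout in the first
#' two stages, the ELU/ReLU/ELU/ReLU/SELU activation sequence and a linear
#' class head.
#'
#' @param input_dim Number of input features (150 after Shapley selection).
#' @param n_classes Number of MOA classes (sets the head width).
#' @param cfg An [mlp_config()]; its sixth layer size is replaced by
#'   `n_classes`.
#' @param seed Integer seed for weight initialization.
#' @return A `cvf_net` ready for [train_mlp()].
#' @export
build_profile_mlp <- function(input_dim, n_classes = 10,
                              cfg = mlp_config(), seed = 1L) {
  sizes <- cfg$layer_sizes
  sizes[6] <- n_classes
  net_init(input_dim, sizes, cfg$activations, cfg$dropout, cfg$batch_norm,
           seed = seed)
}

#' Build the compound-structure MLP classifier
#'
#' Three ReLU hidden layers (1024/256/64 by default) over the 2048-bit
#' fingerprint input, dropout 0.5 on the first two stages, and a linear class
#' head.
#'
#' @param input_dim Fingerprint length (2048).
#' @param n_classes Number of MOA classes.
#' @param hidden Hidden widths.
#' @param dropout Dropout rate on the first two stages.
#' @param seed Integer seed.
#' @return A `cvf_net` ready for [train_mlp()].
#' @export
build_chem_mlp <- function(input_dim = 2048, n_classes = 10,
                           hidden = c(1024, 256, 64), dropout = 0.5,
                           seed = 1L) {
  sizes <- c(hidden, n_classes)
  net_init(input_dim, sizes,
           activations = c(rep("relu", length(hidden)), "linear"),
           dropout = c(dropout, dropout, rep(0, length(sizes) - 2)),
           batch_norm = FALSE, seed = seed)
}

#' Train a single-modality MLP classifier
#'
#' Minimizes softmax cross-entropy with AdamW. Deterministic for a fixed
#' seed.
#'
#' @param net A `cvf_net` from [build_profile_mlp()] or [build_chem_mlp()].
#' @param x Numeric matrix, rows = samples.
#' @param y Factor (or coercible) of class labels.
#' @param epochs,batch_size,lr,weight_decay Optimization settings.
#' @param x_val,y_val Optional validation split; when given, the parameters
#'   with the best validation macro-F1 are returned.
#' @param n_restarts Number of independently initialized training runs; the
#'   run with the best validation macro-F1 (or lowest final training loss
#'   without a validation split) is kept. Deterministic given `seed`.
#' @param seed Integer seed for shuffling and dropout.
#' @return A `cvf_mlp_model` with elements `net`, `classes` and `log`
#'   (per-epoch tibble).
#' @export
train_mlp <- function(net, x, y, epochs = 30, batch_size = 32, lr = 1e-3,
                      weight_decay = 1e-2, x_val = NULL, y_val = NULL,
                      n_restarts = 1L, seed = 1L) {
  if (n_restarts > 1) {
    runs <- lapply(seq_len(n_restarts), function(r) {
      net_r <- net_init(net$input_dim, net$layer_sizes, net$activations,
                        net$dropout, net$batch_norm,
                        seed = as.integer(seed) + (r - 1) * 1009L)
      train_mlp(net_r, x, y, epochs = epochs, batch_size = batch_size,
                lr = lr, weight_decay = weight_decay, x_val = x_val,
                y_val = y_val, n_restarts = 1L,
                seed = as.integer(seed) + (r - 1) * 1009L)
    })
    score <- vapply(runs, function(m) {
      if (!is.null(x_val)) max(c(-Inf, m$log$val_f1), na.rm = TRUE)
      else -utils::tail(m$log$train_loss, 1)
    }, numeric(1))
    return(runs[[which.max(score)]])
  }
  x <- as.matrix(x)
  y <- factor(y)
  classes <- levels(y)
  y_idx <- as.integer(y)
  opt <- adamw_init(net$params)
  log <- list()
  best <- list(f1 = -Inf, params = net$params, running = net$running)
  withr::with_seed(as.integer(seed), {
    for (ep in seq_len(max(epochs, 0))) {
      ord <- sample(nrow(x))
      losses <- c()
      for (start in seq(1, nrow(x), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, nrow(x))]
        fw <- net_forward(net, x[idx, , drop = FALSE], train = TRUE)
        net$running <- fw$running
        ce <- softmax_ce(fw$out, y_idx[idx])
        bw <- net_backward(net, fw$cache, ce$grad)
        st <- adamw_step(net$params, bw$grads, opt, lr = lr,
                         weight_decay = weight_decay)
        net$params <- st$params
        opt <- st$state
        losses <- c(losses, ce$loss)
      }
      row <- tibble(epoch = ep, train_loss = mean(losses),
                    val_f1 = NA_real_)
      if (!is.null(x_val)) {
        pv <- net_forward(net, as.matrix(x_val), train = FALSE)$out
        calls <- classes[max.col(pv, ties.method = "first")]
        row$val_f1 <- macro_f1(factor(calls, levels = classes),
                               factor(y_val, levels = classes))
        if (row$val_f1 >= best$f1) {
          best <- list(f1 = row$val_f1, params = net$params,
                       running = net$running)
        }
      }
      log[[ep]] <- row
    }
  })
  if (!is.null(x_val) && is.finite(best$f1)) {
    net$params <- best$params
    net$running <- best$running
  }
  structure(list(net = net, classes = classes,
                 log = if (length(log)) bind_rows(log) else
                   tibble(epoch = integer(), train_loss = numeric(),
                          val_f1 = numeric())),
            class = "cvf_mlp_model")
}

#' Predict class probabilities from a trained MLP
#'
#' @param object A `cvf_mlp_model`.
#' @param x Numeric matrix of inputs.
#' @param ... Unused.
#' @return Matrix of class probabilities (columns named by class).
#' @export
predict.cvf_mlp_model <- function(object, x, ...) {
  logits <- net_forward(object$net, as.matrix(x), train = FALSE)$out
  p <- softmax_ce(logits, rep(1L, nrow(logits)))$probs
  colnames(p) <- object$classes
  p
}
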