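# Three-modality fusion: the multi-modal outer arithmetic block (MOAB), a
# pluggable five-channel image encoder contract with a bundled tiny encoder,
# end-to-end training with AdamW, and field -> well -> compound prediction
# aggregation.

#' Multi-modal outer arithmetic block (MOAB) fusion of two vectors
#'
#' Appends 1 to each embedding (lengths `m + 1`, `n + 1`) and stacks the four
#' outer-arithmetic combinations — sum, difference, product and quotient — as
#' four `(m + 1) x (n + 1)` channels. The appended ones preserve each
#' embedding verbatim inside the product channel. Quotients guard the divisor
#' with `eps`.
#'
#' @param a,b Numeric embedding vectors.
#' @param eps Guard added to the divisor in the quotient channel.
#' @return Array of dimension `c(4, m + 1, n + 1)` with channel dimnames
#'   `sum`, `diff`, `prod`, `quot`.
#' @export
moab_fuse <- function(a, b, eps = 1e-6) {
  a1 <- c(as.numeric(a), 1)
  b1 <- c(as.numeric(b), 1)
  out <- array(0, c(4, length(a1), length(b1)),
               dimnames = list(c("sum", "diff", "prod", "quot"), NULL, NULL))
  out["sum", , ] <- outer(a1, b1, "+")
  out["diff", , ] <- outer(a1, b1, "-")
  out["prod", , ] <- outer(a1, b1)
  out["quot", , ] <- outer(a1, 1 / (b1 + eps))
  out
}

# Batched MOAB block with a learned 1x1 convolution over the four channels,
# ReLU, and global average pooling to `cout` features. Returns pooled
# activations plus the cache needed for the exact backward pass.
moab_block_forward <- function(A, B, W, bias, eps = 1e-6) {
  n <- nrow(A)
  cout <- ncol(W)
  pooled <- matrix(0, n, cout)
  cache <- vector("list", n)
  for (i in seq_len(n)) {
    a1 <- c(A[i, ], 1)
    b1 <- c(B[i, ], 1)
    r <- 1 / (b1 + eps)
    f <- rbind(as.vector(outer(a1, b1, "+")),
               as.vector(outer(a1, b1, "-")),
               as.vector(outer(a1, b1)),
               as.vector(outer(a1, r)))
    z <- crossprod(W, f) + bias       # cout x P
    h <- pmax(z, 0)
    pooled[i, ] <- rowMeans(h)
    cache[[i]] <- list(a1 = a1, b1 = b1, r = r, f = f, z = z)
  }
  list(out = pooled, cache = cache, eps = eps)
}

moab_block_backward <- function(fw, W, G) {
  n <- nrow(G)
  m <- length(fw$cache[[1]]$a1) - 1L
  k <- length(fw$cache[[1]]$b1) - 1L
  P <- (m + 1L) * (k + 1L)
  dW <- W * 0
  db <- rep(0, ncol(W))
  dA <- matrix(0, n, m)
  dB <- matrix(0, n, k)
  for (i in seq_len(n)) {
    st <- fw$cache[[i]]
    dz <- (st$z > 0) * (G[i, ] / P)   # cout x P (rowwise grad / pool size)
    dW <- dW + st$f %*% t(dz)
    db <- db + rowSums(dz)
    df <- W %*% dz                    # 4 x P
    dS <- matrix(df[1, ], m + 1L, k + 1L)
    dD <- matrix(df[2, ], m + 1L, k + 1L)
    dP <- matrix(df[3, ], m + 1L, k + 1L)
    dQ <- matrix(df[4, ], m + 1L, k + 1L)
    da1 <- rowSums(dS) + rowSums(dD) + dP %*% st$b1 + dQ %*% st$r
    db1 <- colSums(dS) - colSums(dD) + crossprod(dP, st$a1) -
      st$r^2 * crossprod(dQ, st$a1)
    dA[i, ] <- da1[seq_len(m)]
    dB[i, ] <- db1[seq_len(k)]
  }
  list(dW = dW, db = db, dA = dA, dB = dB)
}

#' Bundled tiny five-channel image encoder
#'
#' A lightweight convolutional test encoder that keeps the full fusion
#' pipeline runnable on a desk: a fixed average-pooling patch embedding
#' (each channel reduced to a `grid x grid` grid) followed by a learned
#' two-layer network producing the embedding. Production users register a
#' pretrained hierarchical windowed transformer behind the same contract
#' (a function from image batches to embedding matrices).
#'
#' @param embed_dim Output embedding size.
#' @param grid Patch grid side; input features are `5 * grid^2`.
#' @param hidden Hidden width.
#' @param seed Integer seed for weight initialization.
#' @return A `cvf_encoder` with fields `prep` (images -> pooled features) and
#'   `net` (a `cvf_net`).
#' @export
tiny_image_encoder <- function(embed_dim = 12, grid = 8, hidden = 32,
                               seed = 1L) {
  net <- net_init(5 * grid^2, c(hidden, embed_dim), c("relu", "linear"),
                  c(0, 0), batch_norm = FALSE, seed = seed)
  structure(list(grid = grid, embed_dim = embed_dim, net = net),
            class = "cvf_encoder")
}

#' Average-pool an image stack into patch features
#'
#' The fixed patch-embedding stage of the bundled tiny encoder: each channel
#' is mean-pooled onto a `grid x grid` grid and the five channel grids are
#' concatenated.
#'
#' @param image A [image_stack()].
#' @param grid Patch grid side.
#' @return Numeric vector of length `5 * grid^2`.
#' @export
pool_image_features <- function(image, grid = 8) {
  d <- dim(image$pixels)
  xb <- pmin(floor((seq_len(d[2]) - 1) / d[2] * grid) + 1, grid)
  yb <- pmin(floor((seq_len(d[3]) - 1) / d[3] * grid) + 1, grid)
  out <- numeric(5 * grid^2)
  k <- 0
  for (ch in seq_len(5)) {
    m <- rowsum(t(rowsum(image$pixels[ch, , ], xb)), yb)
    cnt <- tcrossprod(as.vector(table(yb)), as.vector(table(xb)))
    out[k + seq_len(grid^2)] <- as.vector(t(m / cnt))
    k <- k + grid^2
  }
  out
}

#' Encode a batch of images
#'
#' Applies an encoder satisfying the image-encoder contract to a list of
#' five-channel image stacks (evaluation mode).
#'
#' @param encoder A `cvf_encoder` (e.g. [tiny_image_encoder()]).
#' @param images List of [image_stack()] objects.
#' @return Matrix with one embedding row per image.
#' @export
image_encode <- function(encoder, images) {
  bad <- vapply(images, function(im) dim(im$pixels)[1] != 5L, logical(1))
  if (any(bad)) {
    abort("All images must have exactly five channels.",
          class = "cvf_format_error")
  }
  x <- t(vapply(images, pool_image_features, numeric(5 * encoder$grid^2),
                grid = encoder$grid))
  net_forward(encoder$net, x, train = FALSE)$out
}

#' Inflate a 3-channel patch-embedding kernel to five channels
#'
#' Adapts an RGB-pretrained patch-embedding weight to five-channel Cell
#' Painting input by appending two copies of the channel-mean kernel. On an
#' image whose five channels are identical the inflated kernel's response is
#' exactly `5/3` times the 3-channel response on the matching RGB image.
#'
#' @param w3 Matrix `3 x k` of per-channel kernel weights.
#' @param n_channels Target channel count (default 5).
#' @return Matrix `n_channels x k`.
#' @export
inflate_channel_kernel <- function(w3, n_channels = 5L) {
  stopifnot(nrow(w3) == 3)
  mean_k <- colMeans(w3)
  extra <- matrix(rep(mean_k, n_channels - 3L), ncol = ncol(w3), byrow = TRUE)
  rbind(w3, extra)
}

#' Fusion model configuration
#'
#' @param embed_dim Per-modality embedding size after projection.
#' @param fused_dim Output width of each MOAB block's learned convolution.
#' @param lr,epochs,batch_size AdamW optimization settings (repository
#'   defaults; tune per dataset).
#' @param weight_decay Decoupled weight decay (default `1e-2`).
#' @param dropout_ibp Dropout of the profile (IBP) trunk (default 0.2).
#' @param dropout_chem Dropout of the chemistry trunk (default 0.5).
#' @param prof_hidden,chem_hidden,img_hidden Trunk hidden widths.
#' @param seed Integer seed; training is deterministic given it.
#' @return A `cvf_fusion_config` list.
#' @export
fusion_config <- function(embed_dim = 12, fused_dim = 16, lr = 5e-3,
                          epochs = 10, batch_size = 8, weight_decay = 1e-2,
                          dropout_ibp = 0.2, dropout_chem = 0.5,
                          prof_hidden = c(64, 48, 32, 24, 16),
                          chem_hidden = c(128, 64), img_hidden = 32,
                          seed = 1L) {
  structure(list(embed_dim = embed_dim, fused_dim = fused_dim, lr = lr,
                 epochs = epochs, batch_size = batch_size,
                 weight_decay = weight_decay, dropout_ibp = dropout_ibp,
                 dropout_chem = dropout_chem, prof_hidden = prof_hidden,
                 chem_hidden = chem_hidden, img_hidden = img_hidden,
                 seed = as.integer(seed)),
            class = "cvf_fusion_config")
}

fusion_init <- function(d_img, d_prof, d_chem, n_classes, cfg) {
  e <- cfg$embed_dim
  withr::with_seed(cfg$seed, {
    img_net <- net_init(d_img, c(cfg$img_hidden, e), c("relu", "sigmoid"),
                        c(0, 0), FALSE, seed = string_seed(cfg$seed, "img"))
    prof_net <- net_init(
      d_prof, c(cfg$prof_hidden, e),
      c("elu", "relu", "elu", "relu", "selu", "sigmoid"),
      c(cfg$dropout_ibp, cfg$dropout_ibp, 0, 0, 0, 0), TRUE,
      seed = string_seed(cfg$seed, "prof"))
    chem_net <- net_init(
      d_chem, c(cfg$chem_hidden, e),
      c(rep("relu", length(cfg$chem_hidden)), "sigmoid"),
      c(cfg$dropout_chem, rep(0, length(cfg$chem_hidden))), FALSE,
      seed = string_seed(cfg$seed, "chem"))
    f <- cfg$fused_dim
    # the 1x1 convolution mixes the four outer-arithmetic channels, so its
    # fan-in is 4 regardless of embedding size
    W1 <- matrix(rnorm(4 * f, 0, sqrt(2 / 4)), 4, f)
    b1 <- rep(0, f)
    W2 <- matrix(rnorm(4 * f, 0, sqrt(2 / 4)), 4, f)
    b2 <- rep(0, f)
    Wh <- matrix(rnorm(f * n_classes, 0, sqrt(2 / f)), f, n_classes)
    bh <- rep(0, n_classes)
    list(img = img_net, prof = prof_net, chem = chem_net,
         W1 = W1, b1 = b1, W2 = W2, b2 = b2, Wh = Wh, bh = bh)
  })
}

fusion_forward <- function(mod, x_img, x_prof, x_chem, train = FALSE) {
  fi <- net_forward(mod$img, x_img, train = train)
  fp <- net_forward(mod$prof, x_prof, train = train)
  fc <- net_forward(mod$chem, x_chem, train = train)
  m1 <- moab_block_forward(fi$out, fp$out, mod$W1, mod$b1)
  m2 <- moab_block_forward(m1$out, fc$out, mod$W2, mod$b2)
  logits <- sweep(m2$out %*% mod$Wh, 2, mod$bh, "+")
  list(logits = logits, fi = fi, fp = fp, fc = fc, m1 = m1, m2 = m2)
}

#' Train the three-modality fusion classifier end to end
#'
#' Hierarchical pairwise MOAB fusion: the image and profile embeddings are
#' fused first, the result is fused with the chemistry embedding, and a
#' linear head produces class logits. The whole stack (three trunks, two
#' MOAB blocks, head) is trained jointly by minimizing cross-entropy with
#' AdamW and decoupled weight decay. Compound-level leakage between the
#' training and validation sets is a hard error.
#'
#' @param x_img Matrix of pooled image features (rows aligned with
#'   `x_prof`/`x_chem`), or a list of [image_stack()] plus `encoder_grid`.
#' @param x_prof Matrix of (min-max normalized, feature-selected) profile
#'   features.
#' @param x_chem Matrix of compound fingerprints.
#' @param y Class labels (factor or character), one per row.
#' @param compound Compound id per row (for the leakage check).
#' @param val_idx Integer indices of the validation rows; the checkpoint with
#'   the best validation macro-F1 is returned.
#' @param cfg A [fusion_config()].
#' @param n_restarts Number of independently initialized training runs; the
#'   run with the best validation macro-F1 (or lowest final training loss
#'   without a validation split) is kept. Deterministic given `cfg$seed`.
#' @return A `cvf_fusion_model` with elements `mod` (parameters), `classes`,
#'   `cfg` and per-epoch `log`.
#' @export
train_fusion <- function(x_img, x_prof, x_chem, y, compound = NULL,
                         val_idx = integer(), cfg = fusion_config(),
                         n_restarts = 1L) {
  if (n_restarts > 1) {
    runs <- lapply(seq_len(n_restarts), function(r) {
      cfg_r <- cfg
      cfg_r$seed <- cfg$seed + (r - 1) * 1009L
      train_fusion(x_img, x_prof, x_chem, y, compound = compound,
                   val_idx = val_idx, cfg = cfg_r, n_restarts = 1L)
    })
    score <- vapply(runs, function(m) {
      if (length(val_idx)) max(c(-Inf, m$log$val_f1), na.rm = TRUE)
      else -utils::tail(m$log$train_loss, 1)
    }, numeric(1))
    return(runs[[which.max(score)]])
  }
  x_img <- as.matrix(x_img)
  x_prof <- as.matrix(x_prof)
  x_chem <- as.matrix(x_chem)
  y <- factor(y)
  classes <- levels(y)
  y_idx <- as.integer(y)
  n <- nrow(x_img)
  stopifnot(nrow(x_prof) == n, nrow(x_chem) == n, length(y) == n)
  train_idx <- setdiff(seq_len(n), val_idx)
  if (!is.null(compound) && length(val_idx)) {
    shared <- intersect(unique(compound[train_idx]),
                        unique(compound[val_idx]))
    if (length(shared)) {
      abort(paste0("Compound leakage between train and validation: ",
                   paste(head(shared, 5), collapse = ", ")),
            class = "cvf_leakage_error")
    }
  }
  mod <- fusion_init(ncol(x_img), ncol(x_prof), ncol(x_chem),
                     length(classes), cfg)
  flat_names <- c("W1", "b1", "W2", "b2", "Wh", "bh")
  opt_nets <- list(img = adamw_init(mod$img$params),
                   prof = adamw_init(mod$prof$params),
                   chem = adamw_init(mod$chem$params))
  opt_flat <- adamw_init(mod[flat_names])
  log <- list()
  best <- list(f1 = -Inf, mod = mod)
  withr::with_seed(cfg$seed, {
    for (ep in seq_len(max(cfg$epochs, 0))) {
      ord <- sample(train_idx)
      losses <- c()
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
        fw <- fusion_forward(mod, x_img[idx, , drop = FALSE],
                             x_prof[idx, , drop = FALSE],
                             x_chem[idx, , drop = FALSE], train = TRUE)
        mod$img$running <- fw$fi$running
        mod$prof$running <- fw$fp$running
        mod$chem$running <- fw$fc$running
        ce <- softmax_ce(fw$logits, y_idx[idx])
        losses <- c(losses, ce$loss)
        # head
        gh <- ce$grad
        dWh <- t(fw$m2$out) %*% gh
        dbh <- colSums(gh)
        dh2 <- gh %*% t(mod$Wh)
        bw2 <- moab_block_backward(fw$m2, mod$W2, dh2)
        bw1 <- moab_block_backward(fw$m1, mod$W1, bw2$dA)
        gi <- net_backward(mod$img, fw$fi$cache, bw1$dA)$grads
        gp <- net_backward(mod$prof, fw$fp$cache, bw1$dB)$grads
        gc <- net_backward(mod$chem, fw$fc$cache, bw2$dB)$grads
        st <- adamw_step(mod$img$params, gi, opt_nets$img, lr = cfg$lr,
                         weight_decay = cfg$weight_decay)
        mod$img$params <- st$params; opt_nets$img <- st$state
        st <- adamw_step(mod$prof$params, gp, opt_nets$prof, lr = cfg$lr,
                         weight_decay = cfg$weight_decay)
        mod$prof$params <- st$params; opt_nets$prof <- st$state
        st <- adamw_step(mod$chem$params, gc, opt_nets$chem, lr = cfg$lr,
                         weight_decay = cfg$weight_decay)
        mod$chem$params <- st$params; opt_nets$chem <- st$state
        st <- adamw_step(mod[flat_names],
                         list(W1 = bw1$dW, b1 = bw1$db, W2 = bw2$dW,
                              b2 = bw2$db, Wh = dWh, bh = dbh),
                         opt_flat, lr = cfg$lr,
                         weight_decay = cfg$weight_decay)
        mod[flat_names] <- st$params; opt_flat <- st$state
      }
      row <- tibble(epoch = ep, train_loss = mean(losses), val_f1 = NA_real_)
      if (length(val_idx)) {
        pv <- fusion_forward(mod, x_img[val_idx, , drop = FALSE],
                             x_prof[val_idx, , drop = FALSE],
                             x_chem[val_idx, , drop = FALSE])$logits
        calls <- classes[max.col(pv, ties.method = "first")]
        row$val_f1 <- macro_f1(factor(calls, levels = classes),
                               factor(y[val_idx], levels = classes))
        if (row$val_f1 >= best$f1) best <- list(f1 = row$val_f1, mod = mod)
      }
      log[[ep]] <- row
    }
  })
  if (length(val_idx) && is.finite(best$f1)) mod <- best$mod
  structure(list(mod = mod, classes = classes, cfg = cfg,
                 log = if (length(log)) bind_rows(log) else
                   tibble(epoch = integer(), train_loss = numeric(),
                          val_f1 = numeric())),
            class = "cvf_fusion_model")
}

#' Predict class probabilities from a trained fusion model
#'
#' @param object A `cvf_fusion_model`.
#' @param x_img,x_prof,x_chem Aligned input matrices.
#' @param ... Unused.
#' @return Matrix of class probabilities.
#' @export
predict.cvf_fusion_model <- function(object, x_img, x_prof, x_chem, ...) {
  logits <- fusion_forward(object$mod, as.matrix(x_img), as.matrix(x_prof),
                           as.matrix(x_chem))$logits
  p <- softmax_ce(logits, rep(1L, nrow(logits)))$probs
  colnames(p) <- object$classes
  p
}

#' Build a prediction set
#'
#' A prediction set holds class-probability vectors at field, well or
#' compound granularity with the provenance links used for aggregation.
#'
#' @param probs Matrix of class probabilities (columns named by class).
#' @param level `"field"`, `"well"` or `"compound"`.
#' @param well_id,compound_id Provenance vectors (as applicable).
#' @param field_index Field indices (field level only).
#' @return A `cvf_predictions` tibble with probability columns prefixed
#'   `prob_`.
#' @export
prediction_set <- function(probs, level = c("field", "well", "compound"),
                           well_id = NULL, compound_id = NULL,
                           field_index = NULL) {
  level <- match.arg(level)
  probs <- as.matrix(probs)
  if (is.null(colnames(probs))) {
    abort("`probs` needs class names as column names.",
          class = "cvf_schema_error")
  }
  bad <- abs(rowSums(probs) - 1) > 1e-6 | apply(probs, 1, min) < 0
  if (any(bad)) {
    abort("Each probability row must be non-negative and sum to 1.",
          class = "cvf_validation_error")
  }
  tab <- tibble(.rows = nrow(probs))
  if (level != "compound") {
    if (is.null(well_id)) abort("`well_id` required below compound level.",
                                class = "cvf_schema_error")
    tab$well_id <- well_id
  }
  if (is.null(compound_id)) abort("`compound_id` is required.",
                                  class = "cvf_schema_error")
  tab$compound_id <- compound_id
  if (level == "field") {
    tab$field_index <- field_index %||% seq_len(nrow(probs))
  }
  pcols <- as_tibble(`colnames<-`(probs, paste0("prob_", colnames(probs))))
  out <- bind_cols(tab, pcols)
  structure(out, level = level, classes = colnames(probs),
            class = c("cvf_predictions", class(out)))
}

#' Aggregate predictions up the field -> well -> compound hierarchy
#'
#' Class-probability vectors are arithmetically averaged within each parent
#' (fields within a well, then wells within a compound), renormalized only if
#' numerically necessary. The compound-level argmax is the class call.
#'
#' @param preds A `cvf_predictions` at field or well level.
#' @param to Target level.
#' @return A `cvf_predictions` at the target level.
#' @export
aggregate_predictions <- function(preds, to = c("compound", "well")) {
  to <- match.arg(to)
  level <- attr(preds, "level")
  classes <- attr(preds, "classes")
  pcols <- paste0("prob_", classes)
  if (any(is.na(preds$compound_id))) {
    abort("Predictions with missing compound parent cannot be aggregated.",
          class = "cvf_validation_error")
  }
  if (level == "field") {
    well <- preds %>%
      group_by(.data$well_id, .data$compound_id) %>%
      summarise(across(dplyr::all_of(pcols), mean), .groups = "drop")
    wp <- as.matrix(well[pcols])
    wp <- wp / rowSums(wp)
    out <- prediction_set(`colnames<-`(wp, classes), "well",
                          well_id = well$well_id,
                          compound_id = well$compound_id)
    if (to == "well") return(out)
    preds <- out
    level <- "well"
  }
  if (level == "well" && to == "compound") {
    cpd <- preds %>%
      group_by(.data$compound_id) %>%
      summarise(across(dplyr::all_of(pcols), mean), .groups = "drop")
    cp <- as.matrix(cpd[pcols])
    cp <- cp / rowSums(cp)
    return(prediction_set(`colnames<-`(cp, classes), "compound",
                          compound_id = cpd$compound_id))
  }
  preds
}

#' Class calls from a compound-level prediction set
#'
#' @param preds A compound-level `cvf_predictions`.
#' @return Tibble `compound_id`, `call`.
#' @export
prediction_calls <- function(preds) {
  classes <- attr(preds, "classes")
  p <- as.matrix(preds[paste0("prob_", classes)])
  tibble(compound_id = preds$compound_id,
         call = classes[max.col(p, ties.method = "first")])
}
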