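# Trainable fusion variant: each model's embedding is linearly projected
# to a common width and treated as one token; a multi-head self-attention
# block mixes the n model tokens; mean-pooling over tokens yields the
# fused vector. Trained end-to-end with a temporary linear softmax head
# (cross-entropy, Adam); the head is discarded after training so the
# module remains an embedding generator, like concatenation.

#' Configure self-attention fusion
#'
#' @param n_heads Number of attention heads, one of 4, 8 or 12.
#' @param d_head Per-head width (default 64). The fused output width is
#'   `proj_dim = d_head * n_heads`, hence 256/512/768 at the default
#'   `d_head`; tests use smaller `d_head` for speed.
#' @param epochs Maximum training epochs (default 100).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Minibatch size (default 32).
#' @param patience Early-stopping patience, in epochs without validation
#'   accuracy improvement (default 10); ignored when no validation blocks
#'   are supplied.
#' @param seed Integer seed controlling initialisation and shuffling.
#' @param init `"random"` (scaled Gaussian) or `"identity"` (identity-like
#'   projections, useful for analytic checks).
#' @return An object of class `attention_fusion_config`.
#' @export
attention_fusion_config <- function(n_heads = 4L, d_head = 64L,
                                    epochs = 100L, learning_rate = 1e-3,
                                    batch_size = 32L, patience = 10L,
                                    seed = 1L,
                                    init = c("random", "identity")) {
  n_heads <- as.integer(n_heads)
  if (!n_heads %in% c(4L, 8L, 12L)) {
    stop("n_heads must be one of 4, 8, 12", call. = FALSE)
  }
  d_head <- as.integer(d_head)
  stopifnot(d_head >= 1L, epochs >= 0L, learning_rate > 0, batch_size >= 1L)
  structure(
    list(n_heads = n_heads, d_head = d_head,
         proj_dim = n_heads * d_head,
         epochs = as.integer(epochs), learning_rate = learning_rate,
         batch_size = as.integer(batch_size), patience = as.integer(patience),
         seed = as.integer(seed), init = match.arg(init)),
    class = "attention_fusion_config"
  )
}

identity_like <- function(nr, nc) {
  m <- matrix(0, nr, nc)
  k <- min(nr, nc)
  m[cbind(seq_len(k), seq_len(k))] <- 1
  m
}

init_attention_params <- function(dims, p, K, init) {
  rand <- function(nr, nc) matrix(rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
  make <- if (init == "identity") identity_like else rand
  list(
    W_in = lapply(dims, function(d) make(d, p)),
    b_in = lapply(dims, function(d) numeric(p)),
    Wq = make(p, p), Wk = make(p, p), Wv = make(p, p), Wo = make(p, p),
    Wc = rand(p, K), bc = numeric(K)
  )
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

head_cols <- function(h, d_head) seq.int((h - 1L) * d_head + 1L, h * d_head)

# Forward pass for one sample. x: list of per-model row vectors.
# Returns intermediates needed by the backward pass.
attn_forward <- function(x, par, n_heads, d_head) {
  n <- length(x)
  p <- ncol(par$Wq)
  T_ <- matrix(0, n, p)
  for (m in seq_len(n)) {
    T_[m, ] <- x[[m]] %*% par$W_in[[m]] + par$b_in[[m]]
  }
  Q <- T_ %*% par$Wq; K <- T_ %*% par$Wk; V <- T_ %*% par$Wv
  A <- vector("list", n_heads)
  O <- matrix(0, n, p)
  for (h in seq_len(n_heads)) {
    idx <- head_cols(h, d_head)
    S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) / sqrt(d_head)
    A[[h]] <- softmax_rows(S)
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  Y <- O %*% par$Wo
  z <- colMeans(Y)
  list(T_ = T_, Q = Q, K = K, V = V, A = A, O = O, z = z)
}

# Backward pass for one sample; dz is the gradient at the pooled vector.
# Accumulates parameter gradients into `grad` (an environment).
attn_backward <- function(x, fw, dz, par, grad, n_heads, d_head) {
  n <- nrow(fw$T_)
  p <- length(dz)
  dY <- matrix(rep(dz / n, each = n), n, p)
  grad$Wo <- grad$Wo + t(fw$O) %*% dY
  dO <- dY %*% t(par$Wo)
  dQ <- matrix(0, n, p); dK <- matrix(0, n, p); dV <- matrix(0, n, p)
  for (h in seq_len(n_heads)) {
    idx <- head_cols(h, d_head)
    A <- fw$A[[h]]
    dA <- dO[, idx, drop = FALSE] %*% t(fw$V[, idx, drop = FALSE])
    dV[, idx] <- t(A) %*% dO[, idx, drop = FALSE]
    dS <- A * (dA - rowSums(dA * A))
    dQ[, idx] <- (dS %*% fw$K[, idx, drop = FALSE]) / sqrt(d_head)
    dK[, idx] <- (t(dS) %*% fw$Q[, idx, drop = FALSE]) / sqrt(d_head)
  }
  grad$Wq <- grad$Wq + t(fw$T_) %*% dQ
  grad$Wk <- grad$Wk + t(fw$T_) %*% dK
  grad$Wv <- grad$Wv + t(fw$T_) %*% dV
  dT <- dQ %*% t(par$Wq) + dK %*% t(par$Wk) + dV %*% t(par$Wv)
  for (m in seq_len(n)) {
    grad$W_in[[m]] <- grad$W_in[[m]] + outer(as.vector(x[[m]]), dT[m, ])
    grad$b_in[[m]] <- grad$b_in[[m]] + dT[m, ]
  }
  invisible(NULL)
}

zero_grad <- function(par) {
  g <- new.env(parent = emptyenv())
  g$W_in <- lapply(par$W_in, function(w) w * 0)
  g$b_in <- lapply(par$b_in, function(b) b * 0)
  g$Wq <- par$Wq * 0; g$Wk <- par$Wk * 0; g$Wv <- par$Wv * 0
  g$Wo <- par$Wo * 0; g$Wc <- par$Wc * 0; g$bc <- par$bc * 0
  g
}

# Flatten parameters to a named list of arrays for the Adam update.
par_names <- function(par) {
  c(sprintf("W_in%d", seq_along(par$W_in)),
    sprintf("b_in%d", seq_along(par$b_in)),
    "Wq", "Wk", "Wv", "Wo", "Wc", "bc")
}
par_get <- function(par, nm) {
  if (grepl("^W_in", nm)) return(par$W_in[[as.integer(sub("W_in", "", nm))]])
  if (grepl("^b_in", nm)) return(par$b_in[[as.integer(sub("b_in", "", nm))]])
  par[[nm]]
}
par_set <- function(par, nm, value) {
  if (grepl("^W_in", nm)) {
    par$W_in[[as.integer(sub("W_in", "", nm))]] <- value
  } else if (grepl("^b_in", nm)) {
    par$b_in[[as.integer(sub("b_in", "", nm))]] <- value
  } else par[[nm]] <- value
  par
}

#' Fit a self-attention fusion model
#'
#' @param blocks Ordered list of training-split [embedding_set()] objects
#'   (aligned ids).
#' @param labels Integer vector of 0-based class indices for the training
#'   split; defaults to the labels carried by the first block. Multi-label
#'   tasks are not supported by this fusion strategy.
#' @param config An [attention_fusion_config()].
#' @param valid_blocks,valid_labels Optional validation blocks/labels for
#'   early stopping on validation accuracy.
#' @return An object of class `attention_fusion_model` holding the trained
#'   projections and attention weights (classification head discarded),
#'   plus the expected model names and dims.
#' @export
attention_fuse_fit <- function(blocks, labels = NULL, config,
                               valid_blocks = NULL, valid_labels = NULL) {
  stopifnot(inherits(config, "attention_fusion_config"), length(blocks) >= 1L)
  check_alignment(blocks)
  if (is.null(labels)) labels <- blocks[[1L]]$labels
  if (is.matrix(labels)) {
    stop("self-attention fusion supports single-label tasks only",
         call. = FALSE)
  }
  labels <- as.integer(labels)
  K <- max(2L, max(labels) + 1L)
  if (config$epochs > 0L && length(unique(labels)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  dims <- vapply(blocks, function(b) ncol(b$matrix), 0L)
  p <- config$proj_dim
  n_obs <- nrow(blocks[[1L]]$matrix)

  set.seed(config$seed)
  par <- init_attention_params(dims, p, K, config$init)
  model <- structure(
    list(params = par, config = config,
         models = vapply(blocks, function(b) b$model, ""), dims = dims),
    class = "attention_fusion_model"
  )
  if (config$epochs == 0L) return(model)

  # Adam state
  nms <- par_names(par)
  mom <- setNames(lapply(nms, function(nm) par_get(par, nm) * 0), nms)
  vel <- mom
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0

  rows <- function(bl, i) lapply(bl, function(b) b$matrix[i, , drop = FALSE])
  valid_acc <- function(m) {
    fe <- attention_fuse_apply(m, valid_blocks)
    pred <- attn_head_predict(fe$matrix, par$Wc, par$bc)
    mean(pred == as.integer(valid_labels))
  }
  if (!is.null(valid_blocks) && is.null(valid_labels)) {
    valid_labels <- valid_blocks[[1L]]$labels
  }

  best <- list(par = par, score = -Inf, stale = 0L)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n_obs)
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    epoch_loss <- 0
    for (batch in batches) {
      grad <- zero_grad(par)
      for (i in batch) {
        x <- rows(blocks, i)
        fw <- attn_forward(x, par, config$n_heads, config$d_head)
        logits <- as.vector(fw$z %*% par$Wc) + par$bc
        logits <- logits - max(logits)
        prob <- exp(logits) / sum(exp(logits))
        epoch_loss <- epoch_loss - log(max(prob[labels[i] + 1L], 1e-12))
        dlogit <- prob
        dlogit[labels[i] + 1L] <- dlogit[labels[i] + 1L] - 1
        grad$Wc <- grad$Wc + outer(fw$z, dlogit)
        grad$bc <- grad$bc + dlogit
        dz <- as.vector(par$Wc %*% dlogit)
        attn_backward(x, fw, dz, par, grad, config$n_heads, config$d_head)
      }
      t_step <- t_step + 1
      for (nm in nms) {
        g <- par_get(grad, nm) / length(batch)
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g^2
        m_hat <- mom[[nm]] / (1 - b1^t_step)
        v_hat <- vel[[nm]] / (1 - b2^t_step)
        par <- par_set(par, nm,
                       par_get(par, nm) -
                         config$learning_rate * m_hat / (sqrt(v_hat) + eps))
      }
    }
    if (!is.finite(epoch_loss)) {
      stop("attention fusion training diverged at epoch ", epoch,
           " (learning rate ", config$learning_rate, ")", call. = FALSE)
    }
    model$params <- par
    if (!is.null(valid_blocks)) {
      acc <- valid_acc(model)
      if (acc > best$score) {
        best <- list(par = par, score = acc, stale = 0L)
      } else {
        best$stale <- best$stale + 1L
        if (best$stale >= config$patience) break
      }
    }
  }
  if (!is.null(valid_blocks)) {
    model$params <- best$par
    model$valid_accuracy <- best$score
  }
  model
}

attn_head_predict <- function(Z, Wc, bc) {
  logits <- sweep(Z %*% Wc, 2L, bc, "+")
  max.col(logits, ties.method = "first") - 1L
}

#' Apply a fitted self-attention fusion model
#'
#' @param model An `attention_fusion_model` from [attention_fuse_fit()].
#' @param blocks Blocks for any split, matching the fitted models in name,
#'   dimensionality and order.
#' @return A `fused_embeddings` of width `proj_dim` with
#'   `strategy = "self_attention"` and an empty block layout (attention
#'   mixes models, so there are no recoverable sub-blocks).
#' @export
attention_fuse_apply <- function(model, blocks) {
  stopifnot(inherits(model, "attention_fusion_model"))
  names_in <- vapply(blocks, function(b) b$model, "")
  dims_in <- vapply(blocks, function(b) ncol(b$matrix), 0L)
  if (!identical(names_in, model$models) ||
      !identical(dims_in, model$dims)) {
    stop("blocks do not match the fitted fusion model: expected [",
         paste(model$models, collapse = ", "), "], got [",
         paste(names_in, collapse = ", "), "]", call. = FALSE)
  }
  check_alignment(blocks)
  n_obs <- nrow(blocks[[1L]]$matrix)
  cfg <- model$config
  Z <- matrix(0, n_obs, cfg$proj_dim)
  for (i in seq_len(n_obs)) {
    x <- lapply(blocks, function(b) b$matrix[i, , drop = FALSE])
    Z[i, ] <- attn_forward(x, model$params, cfg$n_heads, cfg$d_head)$z
  }
  structure(
    list(matrix = Z,
         blocks = data.frame(model = character(), offset = integer(),
                             dim = integer(), stringsAsFactors = FALSE),
         strategy = "self_attention",
         sample_ids = blocks[[1L]]$sample_ids,
         labels = blocks[[1L]]$labels),
    class = "fused_embeddings"
  )
}
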