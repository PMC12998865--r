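test_that("concatenation obeys the dimension algebra and preserves blocks", {
  # width additivity over random dims, sub-block recovery bitwise
  set.seed(21)
  for (rep in 1:10) {
    n_blocks <- sample(1:5, 1)
    dims <- sample(1:20, n_blocks, replace = TRUE)
    n <- sample(3:12, 1)
    blocks <- lapply(seq_len(n_blocks), function(i) {
      manual_block(matrix(rnorm(n * dims[i]), n, dims[i]),
                   model = sprintf("m%d", i))
    })
    fused <- concat_fuse(blocks)
    expect_identical(ncol(fused$matrix), sum(dims))
    expect_identical(fused$blocks$offset, cumsum(c(0L, dims[-n_blocks])))
    for (i in seq_len(n_blocks)) {
      expect_identical(fused_block(fused, sprintf("m%d", i)),
                       blocks[[i]]$matrix)
    }
  }
})

test_that("concatenation edge cases behave analytically", {
  # single block: identity
  b <- manual_block(matrix(1:6 / 2, 2, 3), "solo")
  expect_identical(concat_fuse(list(b))$matrix, b$matrix)

  # rows (1,2) + (3) -> (1,2,3)
  b1 <- manual_block(matrix(c(1, 2), 1, 2), "a", ids = "s1", labels = 0L)
  b2 <- manual_block(matrix(3, 1, 1), "b", ids = "s1", labels = 0L)
  fused <- concat_fuse(list(b1, b2))
  expect_identical(as.vector(fused$matrix), c(1, 2, 3))

  expect_error(concat_fuse(list()), "empty")

  # misaligned ids name the first mismatch
  b3 <- manual_block(matrix(0, 2, 2), "c", ids = c("s1", "s2"),
                     labels = c(0L, 1L))
  b4 <- manual_block(matrix(0, 2, 2), "d", ids = c("s1", "sX"),
                     labels = c(0L, 1L))
  expect_error(concat_fuse(list(b3, b4)), "not aligned.*'s2'")

  # no normalisation by default: values pass through untouched
  raw <- matrix(c(1000, 2000, 3000, 4000), 2, 2)
  expect_identical(concat_fuse(list(manual_block(raw, "big")))$matrix, raw)
  z <- concat_fuse(list(manual_block(raw, "big")), zscore_blocks = TRUE)
  expect_equal(colMeans(z$matrix), c(0, 0))
})

test_that("attention config enforces the head geometry", {
  expect_identical(attention_fusion_config(n_heads = 12, d_head = 64)$proj_dim,
                   768L)
  expect_identical(attention_fusion_config(n_heads = 4, d_head = 64)$proj_dim,
                   256L)
  expect_identical(attention_fusion_config(n_heads = 8, d_head = 64)$proj_dim,
                   512L)
  expect_error(attention_fusion_config(n_heads = 5), "4, 8, 12")
})

test_that("single-token attention with identity maps is the value projection", {
  set.seed(3)
  b <- manual_block(matrix(rnorm(40), 10, 4), "only")
  cfg <- attention_fusion_config(n_heads = 4, d_head = 2, epochs = 0,
                                 init = "identity", seed = 1)
  model <- attention_fuse_fit(list(b), config = cfg)
  out <- attention_fuse_apply(model, list(b))
  # identity-like projection embeds the 4 features into the first 4 of 8
  # columns; with one token the attention weight is exactly 1, so the
  # pooled output is the token itself
  expect_equal(out$matrix[, 1:4], b$matrix, tolerance = 1e-12)
  expect_equal(out$matrix[, 5:8], matrix(0, 10, 4), tolerance = 1e-12)
})

# Independent oracle: the attention formula computed directly, with no
# shared code with the implementation under test.
brute_force_attention <- function(xs, par, n_heads, d_head) {
  n <- length(xs)
  p <- n_heads * d_head
  T_ <- t(vapply(seq_len(n), function(m) {
    as.vector(xs[[m]] %*% par$W_in[[m]] + par$b_in[[m]])
  }, numeric(p)))
  O <- matrix(0, n, p)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * d_head + 1):(h * d_head)
    for (i in seq_len(n)) {
      # scores computed explicitly pairwise
      q_i <- as.vector(T_[i, ] %*% par$Wq)[idx]
      scores <- vapply(seq_len(n), function(j) {
        k_j <- as.vector(T_[j, ] %*% par$Wk)[idx]
        sum(q_i * k_j) / sqrt(d_head)
      }, 0)
      w <- exp(scores - max(scores))
      w <- w / sum(w)
      v <- t(vapply(seq_len(n), function(j) {
        as.vector(T_[j, ] %*% par$Wv)[idx]
      }, numeric(d_head)))
      O[i, idx] <- colSums(w * v)
    }
  }
  Y <- O %*% par$Wo
  colMeans(Y)
}

test_that("attention output matches a brute-force oracle on small instances", {
  set.seed(17)
  for (rep in 1:5) {
    n_tokens <- sample(2:3, 1)
    d_head <- 2L
    dims <- sample(2:4, n_tokens, replace = TRUE)
    blocks <- lapply(seq_len(n_tokens), function(i) {
      manual_block(matrix(rnorm(3 * dims[i]), 3, dims[i]),
                   model = sprintf("m%d", i))
    })
    cfg <- attention_fusion_config(n_heads = 4, d_head = d_head, epochs = 0,
                                   seed = rep)
    model <- attention_fuse_fit(blocks, config = cfg)
    out <- attention_fuse_apply(model, blocks)
    for (i in 1:3) {
      xs <- lapply(blocks, function(b) b$matrix[i, , drop = FALSE])
      expect_equal(out$matrix[i, ],
                   brute_force_attention(xs, model$params, 4L, d_head),
                   tolerance = 1e-6)
    }
  }
})

test_that("analytic gradients agree with numerical differentiation", {
  set.seed(5)
  blocks <- list(
    manual_block(matrix(rnorm(12), 4, 3), "a", labels = c(0L, 1L, 0L, 1L)),
    manual_block(matrix(rnorm(8), 4, 2), "b", labels = c(0L, 1L, 0L, 1L))
  )
  cfg <- attention_fusion_config(n_heads = 4, d_head = 2, epochs = 0, seed = 9)
  model <- attention_fuse_fit(blocks, labels = c(0L, 1L, 0L, 1L), config = cfg)
  par <- model$params
  labels <- c(0L, 1L, 0L, 1L)

  loss_of <- function(par) {
    total <- 0
    for (i in 1:4) {
      xs <- lapply(blocks, function(b) b$matrix[i, , drop = FALSE])
      fw <- embedfuse:::attn_forward(xs, par, 4L, 2L)
      logits <- as.vector(fw$z %*% par$Wc) + par$bc
      logits <- logits - max(logits)
      prob <- exp(logits) / sum(exp(logits))
      total <- total - log(prob[labels[i] + 1L])
    }
    total
  }

  # analytic gradient of the summed loss
  grad <- embedfuse:::zero_grad(par)
  for (i in 1:4) {
    xs <- lapply(blocks, function(b) b$matrix[i, , drop = FALSE])
    fw <- embedfuse:::attn_forward(xs, par, 4L, 2L)
    logits <- as.vector(fw$z %*% par$Wc) + par$bc
    logits <- logits - max(logits)
    prob <- exp(logits) / sum(exp(logits))
    dlogit <- prob
    dlogit[labels[i] + 1L] <- dlogit[labels[i] + 1L] - 1
    grad$Wc <- grad$Wc + outer(fw$z, dlogit)
    grad$bc <- grad$bc + dlogit
    dz <- as.vector(par$Wc %*% dlogit)
    embedfuse:::attn_backward(xs, fw, dz, par, grad, 4L, 2L)
  }

  eps <- 1e-6
  for (nm in c("Wq", "Wk", "Wv", "Wo", "Wc")) {
    M <- par[[nm]]
    for (probe_idx in list(c(1, 1), c(2, min(3, ncol(M))))) {
      pp <- par; pp[[nm]][probe_idx[1], probe_idx[2]] <- M[probe_idx[1], probe_idx[2]] + eps
      pm <- par; pm[[nm]][probe_idx[1], probe_idx[2]] <- M[probe_idx[1], probe_idx[2]] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      ana <- grad[[nm]][probe_idx[1], probe_idx[2]]
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
  # one projection weight too
  pp <- par; pp$W_in[[1]][1, 2] <- pp$W_in[[1]][1, 2] + eps
  pm <- par; pm$W_in[[1]][1, 2] <- pm$W_in[[1]][1, 2] - eps
  expect_equal(grad$W_in[[1]][1, 2],
               (loss_of(pp) - loss_of(pm)) / (2 * eps), tolerance = 1e-4)
})

test_that("fitted attention fusion is deterministic and order-checked", {
  ds <- tiny_dataset(seed = 13L, n_models = 2L, dims = c(6L, 6L),
                     signal = c(2, 1))
  reg <- registry_from_synthetic(ds)
  blocks <- blocks_for(reg, ds, c("synth01", "synth02"), "train")
  cfg <- attention_fusion_config(n_heads = 4, d_head = 2, epochs = 3,
                                 seed = 7)
  m1 <- attention_fuse_fit(blocks, config = cfg)
  m2 <- attention_fuse_fit(blocks, config = cfg)
  expect_identical(m1$params, m2$params)

  out1 <- attention_fuse_apply(m1, blocks)
  out2 <- attention_fuse_apply(m1, blocks)
  expect_identical(out1$matrix, out2$matrix)
  expect_identical(ncol(out1$matrix), 8L)
  expect_identical(nrow(out1$blocks), 0L)  # attention mixes models

  expect_error(attention_fuse_apply(m1, rev(blocks)),
               "do not match.*synth01")

  # multi-label tasks are not supported by this strategy
  ml <- tiny_dataset(seed = 14L, n_models = 2L, dims = c(4L, 4L),
                     signal = c(1, 1), n_classes = 3L,
                     task_type = "multilabel")
  mreg <- registry_from_synthetic(ml)
  expect_error(
    attention_fuse_fit(blocks_for(mreg, ml, c("synth01", "synth02"), "train"),
                       config = cfg),
    "single-label"
  )
})
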