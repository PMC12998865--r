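test_that("exhaustive enumeration yields every non-empty subset once", {
  for (n in 1:10) {
    subsets <- enumerate_subsets(n)
    expect_length(subsets, 2L^n - 1L)
    keys <- vapply(subsets, paste, "", collapse = ",")
    expect_identical(anyDuplicated(keys), 0L)
    # internal order of every subset follows registry order
    expect_true(all(vapply(subsets, function(s) all(diff(s) > 0), TRUE)))
  }
  expect_identical(
    lapply(enumerate_subsets(3), identity),
    list(1L, 2L, c(1L, 2L), 3L, c(1L, 3L), c(2L, 3L), 1:3)
  )
  expect_length(enumerate_subsets(1), 1L)
  expect_length(enumerate_subsets(9), 511L)
  expect_identical(enumerate_subsets(4, "singles_only"),
                   list(1L, 2L, 3L, 4L))
  expect_error(enumerate_subsets(0), "at least one")
})

test_that("search selects the winner by validation accuracy with dominance", {
  ds <- tiny_dataset(seed = 21L, n_models = 3L, dims = rep(6L, 3),
                     signal = c(2, 2, 0))
  reg <- registry_from_synthetic(ds)
  res <- run_search(reg, ds, seed = 2)
  expect_identical(res$n_evaluated, 7L)
  expect_identical(res$mode, "exhaustive")
  ok <- res$evaluations$status == "ok"
  expect_true(all(ok))
  expect_gte(res$selected_accuracy, max(res$evaluations$valid_accuracy))
  # fused dim of every evaluation obeys the dimension algebra
  expect_identical(res$evaluations$fused_dim, res$evaluations$size * 6L)
  # monotone benefit: the winner is at least as good as the best singleton
  singles <- res$evaluations$valid_accuracy[res$evaluations$size == 1L]
  expect_gte(res$selected_accuracy, max(singles))
})

test_that("ties break toward fewer models, then enumeration order", {
  # all three models are copies of one strongly separable block, so every
  # subset attains the same validation accuracy
  base <- generate_synthetic(synthetic_config(
    n_models = 1, dims = 6, n_classes = 2,
    n_per_split = c(train = 150, valid = 60, test = 40),
    signal_strengths = 4, noise_sd = 0.5, seed = 5
  ))
  block <- base$embeddings$synth01
  reg <- model_registry()
  for (nm in c("A", "B", "C")) {
    reg <- register_model(reg, model_spec(nm, 6L), local({
      b <- block
      function(split) b[[split$name]]
    }))
  }
  ds <- fusion_dataset("copies", "binary", 2L, base$splits)
  res <- run_search(reg, ds, seed = 1)
  accs <- res$evaluations$valid_accuracy
  expect_true(all(accs == accs[1L]))  # identical blocks, identical scores
  expect_identical(res$selected, "A")  # smallest subset, earliest enumerated
})

test_that("singles-only mode evaluates exactly the n singletons", {
  ds <- tiny_dataset(seed = 22L, n_models = 4L, dims = rep(5L, 4),
                     signal = c(2, 1, 0, 0))
  reg <- registry_from_synthetic(ds)
  res <- run_search(reg, ds, mode = "singles_only", seed = 3)
  expect_identical(res$n_evaluated, 4L)
  expect_true(all(res$evaluations$size == 1L))
  best <- which.max(res$evaluations$valid_accuracy)
  expect_identical(res$selected, res$evaluations$subset[best])
})

test_that("failed subset evaluations are recorded, not fatal", {
  ds <- tiny_dataset(seed = 23L, n_models = 2L, dims = c(4L, 4L),
                     signal = c(2, 0))
  reg <- registry_from_synthetic(ds)
  # second provider violates its declared width on the valid split only
  broken <- register_model(
    model_registry(),
    model_spec("synth01", 4L),
    local({
      b <- ds$embeddings$synth01
      function(split) b[[split$name]]
    })
  )
  broken <- register_model(
    broken, model_spec("bad", 4L),
    local({
      b <- ds$embeddings$synth02
      function(split) {
        if (split$name == "valid") b[[split$name]][, 1:3] else b[[split$name]]
      }
    })
  )
  res <- run_search(broken, ds, seed = 1)
  st <- res$evaluations$status
  expect_true(any(grepl("^failed", st)))
  expect_true(any(st == "ok"))
  expect_false(any(grepl("bad", res$selected)))
})

test_that("the fusion model reproduces search-time layout and embeddings", {
  ds <- tiny_dataset(seed = 24L)
  reg <- registry_from_synthetic(ds)
  ca <- embedding_cache()
  res <- run_search(reg, ds, seed = 4, cache = ca)
  fm <- build_fusion_model(res, reg)
  tr <- generate_embeddings(fm, ds, "train", ca)
  # identical to the fused train block used during search (same providers,
  # same order), bitwise
  direct <- concat_fuse(blocks_for(reg, ds, res$selected, "train"))
  expect_identical(tr$matrix, direct$matrix)
  te <- generate_embeddings(fm, ds, "test", ca)
  expect_identical(ncol(te$matrix), sum(fm$dims))

  expect_error(build_fusion_model(character(0), reg), "empty")
  expect_error(build_fusion_model(c("synth01", "ghost"), reg),
               "no longer registered.*ghost")
})

test_that("block offsets follow cumulative dims for a realistic model pool", {
  # two encoders with familiar widths: 512-d and 1408-d
  reg <- model_registry()
  reg <- register_model(reg, model_spec("CO", 512L),
                        function(split) matrix(0, length(split$ids), 512))
  reg <- register_model(reg, model_spec("CA", 1408L),
                        function(split) matrix(0, length(split$ids), 1408))
  split <- dataset_split("train", c("a", "b"), c(0L, 1L))
  fused <- concat_fuse(list(extract_embeddings(reg, "CO", split),
                            extract_embeddings(reg, "CA", split)))
  expect_identical(fused$blocks$model, c("CO", "CA"))
  expect_identical(fused$blocks$offset, c(0L, 512L))
  expect_identical(fused$blocks$dim, c(512L, 1408L))
  expect_identical(ncol(fused$matrix), 1920L)
})
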