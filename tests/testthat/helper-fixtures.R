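# Shared fixtures: small synthetic datasets and registries built in code.

tiny_dataset <- function(seed = 1L, n_models = 3L, dims = rep(6L, n_models),
                         signal = c(2, 2, 0)[seq_len(n_models)],
                         n_classes = 2L, task_type = "binary",
                         n = c(train = 150L, valid = 80L, test = 80L),
                         noise_sd = 3) {
  generate_synthetic(synthetic_config(
    n_models = n_models, dims = dims, n_classes = n_classes,
    n_per_split = n, signal_strengths = signal, noise_sd = noise_sd,
    task_type = task_type, seed = seed
  ))
}

# A registry whose providers count their invocations (for cache tests).
counting_registry <- function(dataset) {
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  config <- dataset$truth
  reg <- model_registry(version = sprintf("count-seed%d", config$seed))
  for (m in seq_len(config$n_models)) {
    name <- sprintf("synth%02d", m)
    provider <- local({
      blocks <- dataset$embeddings[[name]]
      function(split) {
        counter$n <- counter$n + 1L
        blocks[[split$name]]
      }
    })
    reg <- register_model(reg, model_spec(name, config$dims[m]), provider)
  }
  list(registry = reg, counter = counter)
}

blocks_for <- function(registry, dataset, models, split_name) {
  lapply(models, function(m) {
    extract_embeddings(registry, m, dataset$splits[[split_name]])
  })
}

# Hand-built embedding sets with explicit content.
manual_block <- function(mat, model, ids = sprintf("s%d", seq_len(nrow(mat))),
                         labels = rep(0L, nrow(mat)), split = "train") {
  embedding_set(mat, ids, labels, model, split)
}

# Python (with numpy) ships in the runtime image; used as an independent
# oracle for the NPY/NPZ container format.
python_bin <- function() Sys.which("python")
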