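#' Describe an embedding provider
#'
#' Registry metadata for one embedding model: its name, output
#' dimensionality and modality tag. Mirrors the kind of model pool used for
#' biomedical encoders (vision-language and unimodal vision transformers),
#' but carries no weights -- the actual computation lives in the provider
#' callable registered alongside the spec.
#'
#' @param name Unique identifier string.
#' @param dim Positive integer, the embedding dimensionality.
#' @param modality Free-text tag, e.g. `"histopathology"`, `"radiology"`,
#'   `"synthetic"`.
#' @param metadata Optional named list of descriptive strings
#'   (pre-training corpus, encoder family, ...).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, dim, modality = "unspecified", metadata = list()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("model name must be a non-empty string", call. = FALSE)
  }
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 1L) {
    stop("embedding dim must be a positive integer", call. = FALSE)
  }
  structure(
    list(name = name, dim = dim, modality = modality, metadata = metadata),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec '", x$name, "'> dim ", x$dim, ", modality ",
      x$modality, "\n", sep = "")
  invisible(x)
}

#' Create an empty model registry
#'
#' The registry keeps an ordered pool of [model_spec()] entries together
#' with their provider callables. Iteration order is insertion order and is
#' never re-sorted: this order is the canonical concatenation order used by
#' every fused representation, so results are reproducible by construction.
#'
#' @param version Free-form provider-pool version string; folded into cache
#'   content tags so stale cache entries are never silently reused.
#' @return An object of class `model_registry`.
#' @export
model_registry <- function(version = "1") {
  structure(
    list(specs = list(), providers = list(), version = as.character(version)),
    class = "model_registry"
  )
}

#' Register an embedding provider
#'
#' Appends a model to the end of the registry order. A provider is a
#' function taking one [dataset_split()] and returning either a numeric
#' matrix (rows in split order) or an [embedding_set()]. Providers must be
#' deterministic for a fixed seed; dimensionality is checked lazily at
#' extraction time so that cheap registration of many models stays cheap.
#'
#' @param registry A [model_registry()].
#' @param spec A [model_spec()].
#' @param provider Provider function for this model.
#' @return The updated registry (registries are immutable values).
#' @export
register_model <- function(registry, spec, provider) {
  stopifnot(inherits(registry, "model_registry"), inherits(spec, "model_spec"))
  if (spec$name %in% names(registry$specs)) {
    stop("model '", spec$name, "' is already registered", call. = FALSE)
  }
  if (!is.function(provider)) {
    stop("provider for '", spec$name, "' must be a function", call. = FALSE)
  }
  registry$specs[[spec$name]] <- spec
  registry$providers[[spec$name]] <- provider
  registry
}

#' Names of registered models, in concatenation order
#'
#' @param registry A [model_registry()].
#' @return Character vector of model names in registration order.
#' @export
registered_models <- function(registry) {
  stopifnot(inherits(registry, "model_registry"))
  names(registry$specs)
}

#' @export
print.model_registry <- function(x, ...) {
  cat("<model_registry> ", length(x$specs), " models\n", sep = "")
  for (s in x$specs) {
    cat("  ", format(s$name, width = 14), " dim ", format(s$dim, width = 5),
        "  ", s$modality, "\n", sep = "")
  }
  invisible(x)
}

get_spec <- function(registry, model_name) {
  spec <- registry$specs[[model_name]]
  if (is.null(spec)) {
    stop("model '", model_name, "' is not registered", call. = FALSE)
  }
  spec
}

#' Extract embeddings for one model on one split
#'
#' Invokes the registered provider and validates the contract: the returned
#' matrix must have one row per split sample (in split order) and exactly
#' `spec$dim` columns.
#'
#' @param registry A [model_registry()].
#' @param model_name Registered model name.
#' @param split A [dataset_split()].
#' @return An [embedding_set()].
#' @export
extract_embeddings <- function(registry, model_name, split) {
  spec <- get_spec(registry, model_name)
  stopifnot(inherits(split, "dataset_split"))
  if (n_samples(split) == 0L) {
    stop("split '", split$name, "' is empty", call. = FALSE)
  }
  out <- tryCatch(
    registry$providers[[model_name]](split),
    error = function(e) {
      stop("provider '", model_name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  mat <- if (inherits(out, "embedding_set")) out$matrix else out
  if (!is.matrix(mat)) {
    stop("provider '", model_name, "' did not return a matrix", call. = FALSE)
  }
  if (ncol(mat) != spec$dim) {
    stop("dimension mismatch for model '", model_name, "': expected ",
         spec$dim, " columns, provider returned ", ncol(mat), call. = FALSE)
  }
  if (nrow(mat) != n_samples(split)) {
    stop("row mismatch for model '", model_name, "': split has ",
         n_samples(split), " samples, provider returned ", nrow(mat),
         " rows", call. = FALSE)
  }
  embedding_set(mat, split$ids, split$labels, model_name, split$name)
}

#' Provider that flattens raw pixels
#'
#' A trivial baseline provider for image bundles: each sample's pixel array
#' is flattened to one feature vector and scaled to `[0, 1]` when it looks
#' like 8-bit image data. Useful as a weights-free reference encoder.
#'
#' @param scale Divide pixel values by this constant (default 255).
#' @return A provider function suitable for [register_model()].
#' @export
flatten_pixels_provider <- function(scale = 255) {
  function(split) {
    arr <- split$data
    if (is.null(arr)) {
      stop("split carries no raw data to flatten", call. = FALSE)
    }
    n <- dim(arr)[1L]
    mat <- matrix(as.numeric(arr), nrow = n) / scale
    mat
  }
}
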