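# On-disk embedding cache. Layout:
#   <root>/<dataset_id>/<model_name>/<split>.npy            array block
#   <root>/<dataset_id>/<model_name>/<split>.manifest.json  ids/labels/key
# The manifest makes a cached dataset self-describing, so downstream
# stages (search, tuning) can run from a cache directory alone.

#' Build a cache key
#'
#' @param model_name Registered model name.
#' @param dataset_id Dataset identifier.
#' @param split One of `"train"`, `"valid"`, `"test"`.
#' @param content_tag Short hash of provider version + dataset fingerprint;
#'   see [content_tag()].
#' @return An object of class `cache_key`.
#' @export
cache_key <- function(model_name, dataset_id, split, content_tag = "0") {
  split <- match.arg(split, c("train", "valid", "test"))
  structure(
    list(model_name = model_name, dataset_id = dataset_id, split = split,
         content_tag = content_tag),
    class = "cache_key"
  )
}

#' Content tag for a (provider, dataset) pair
#'
#' First 12 hex digits of an MD5 digest over the provider version and a
#' dataset fingerprint (id, split sizes). Folding the provider version into
#' the tag invalidates cached blocks when an encoder implementation
#' changes.
#'
#' @param provider_version Version string of the provider pool.
#' @param dataset A [fusion_dataset()] or a character fingerprint.
#' @return 12-character hex string.
#' @export
content_tag <- function(provider_version, dataset) {
  fp <- if (inherits(dataset, "fusion_dataset")) {
    paste(dataset$dataset_id,
          paste(vapply(dataset$splits, n_samples, 0L), collapse = ","),
          sep = "|")
  } else {
    as.character(dataset)
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(provider_version, fp, sep = "|"), tmp)
  substr(unname(tools::md5sum(tmp)), 1L, 12L)
}

#' Open an embedding cache rooted at a directory
#'
#' @param root Cache root directory; created if missing.
#' @param enabled If `FALSE`, [get_or_extract()] bypasses the cache and
#'   invokes the provider on every call.
#' @return An object of class `embedding_cache`.
#' @export
embedding_cache <- function(root = tempfile("embcache_"), enabled = TRUE) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  structure(list(root = root, enabled = isTRUE(enabled)),
            class = "embedding_cache")
}

cache_paths <- function(cache, key) {
  dir <- file.path(cache$root, key$dataset_id, key$model_name)
  list(dir = dir,
       npy = file.path(dir, paste0(key$split, ".npy")),
       manifest = file.path(dir, paste0(key$split, ".manifest.json")))
}

#' Persist an embedding set under a cache key
#'
#' The matrix is written in NPY format; sample ids, labels, dims and the
#' key fields go to a JSON manifest beside it. Storing the same key with
#' identical content is idempotent (same path, silently overwritten).
#'
#' @param cache An [embedding_cache()].
#' @param key A [cache_key()].
#' @param emb An [embedding_set()].
#' @return The path of the stored array, invisibly.
#' @export
cache_store <- function(cache, key, emb) {
  stopifnot(inherits(cache, "embedding_cache"), inherits(key, "cache_key"),
            inherits(emb, "embedding_set"))
  if (nrow(emb$matrix) == 0L) stop("refusing to cache an empty embedding set",
                                   call. = FALSE)
  p <- cache_paths(cache, key)
  dir.create(p$dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(p$dir)) {
    stop("cannot create cache directory ", p$dir, call. = FALSE)
  }
  write_npy(emb$matrix, p$npy)
  labels <- emb$labels
  manifest <- list(
    model_name = key$model_name, dataset_id = key$dataset_id,
    split = key$split, content_tag = key$content_tag,
    n_samples = nrow(emb$matrix), dim = ncol(emb$matrix),
    sample_ids = emb$sample_ids,
    label_kind = if (is.matrix(labels)) "multilabel" else "single",
    labels = if (is.matrix(labels)) {
      apply(labels, 1L, paste, collapse = ",")
    } else {
      as.integer(labels)
    }
  )
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA)
  invisible(p$npy)
}

#' Load an embedding set from the cache
#'
#' @param cache An [embedding_cache()].
#' @param key A [cache_key()].
#' @return The cached [embedding_set()], or `NULL` when the key is absent.
#'   A present-but-inconsistent entry (manifest/array mismatch, truncated
#'   array) raises an integrity error rather than returning `NULL`.
#' @export
cache_load <- function(cache, key) {
  p <- cache_paths(cache, key)
  if (!file.exists(p$npy) || !file.exists(p$manifest)) return(NULL)
  manifest <- jsonlite::read_json(p$manifest, simplifyVector = TRUE)
  mat <- tryCatch(read_npy(p$npy), error = function(e) {
    stop("cache integrity error for ", p$npy, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.matrix(mat)) mat <- matrix(mat, ncol = manifest$dim)
  if (nrow(mat) != manifest$n_samples || ncol(mat) != manifest$dim) {
    stop("cache integrity error for ", p$npy, ": array is ",
         nrow(mat), "x", ncol(mat), " but manifest says ",
         manifest$n_samples, "x", manifest$dim, call. = FALSE)
  }
  if (!identical(manifest$content_tag, key$content_tag)) {
    return(NULL)  # stale entry from a different provider/dataset version
  }
  labels <- if (identical(manifest$label_kind, "multilabel")) {
    do.call(rbind, lapply(strsplit(manifest$labels, ","), as.integer))
  } else {
    as.integer(manifest$labels)
  }
  embedding_set(mat, manifest$sample_ids, labels,
                manifest$model_name, manifest$split)
}

#' Fetch a block from the cache, extracting on miss
#'
#' On a hit the provider is not invoked; on a miss the block is extracted,
#' stored and returned. Over a process lifetime each key triggers at most
#' one provider invocation, which bounds provider work at
#' `n_models * n_splits` for an entire exhaustive search.
#'
#' @param cache An [embedding_cache()] (or `NULL` to disable caching).
#' @param registry A [model_registry()].
#' @param key A [cache_key()].
#' @param split The [dataset_split()] to extract from on a miss.
#' @return An [embedding_set()].
#' @export
get_or_extract <- function(cache, registry, key, split) {
  if (is.null(cache) || !cache$enabled) {
    return(extract_embeddings(registry, key$model_name, split))
  }
  hit <- cache_load(cache, key)
  if (!is.null(hit)) return(hit)
  emb <- extract_embeddings(registry, key$model_name, split)
  cache_store(cache, key, emb)
  emb
}

#' Write a whole dataset's embeddings into the cache layout
#'
#' Extracts every registered model on every split and stores the blocks,
#' so later stages can run from the cache directory alone.
#'
#' @param cache An [embedding_cache()].
#' @param registry A [model_registry()].
#' @param dataset A [fusion_dataset()].
#' @return The cache, invisibly.
#' @export
write_dataset_cache <- function(cache, registry, dataset) {
  tag <- content_tag(registry$version, dataset)
  for (model in registered_models(registry)) {
    for (split_name in names(dataset$splits)) {
      key <- cache_key(model, dataset$dataset_id, split_name, tag)
      get_or_extract(cache, registry, key, dataset$splits[[split_name]])
    }
  }
  invisible(cache)
}
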