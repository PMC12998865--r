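#' Construct a dataset split
#'
#' A split bundles the sample identifiers, the labels and (optionally) the
#' raw per-sample data that a provider consumes. Providers receive the whole
#' split object and own any preprocessing of `data`; the framework never
#' touches it.
#'
#' @param name Split name, one of `"train"`, `"valid"`, `"test"`.
#' @param ids Character vector of unique sample identifiers.
#' @param labels Integer vector of 0-based class indices (single-label
#'   tasks) or a 0/1 integer matrix with one column per label (multi-label
#'   tasks). Length/rows must match `ids`.
#' @param data Optional raw data for providers, e.g. an image array whose
#'   first dimension indexes samples.
#' @return An object of class `dataset_split`.
#' @export
dataset_split <- function(name, ids, labels, data = NULL) {
  name <- match.arg(name, c("train", "valid", "test"))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in split '", name, "'", call. = FALSE)
  }
  n_lab <- if (is.matrix(labels)) nrow(labels) else length(labels)
  if (n_lab != length(ids)) {
    stop("labels (", n_lab, ") and ids (", length(ids),
         ") disagree in split '", name, "'", call. = FALSE)
  }
  structure(
    list(name = name, ids = ids, labels = labels, data = data),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split '", x$name, "'> ", length(x$ids), " samples\n", sep = "")
  invisible(x)
}

n_samples <- function(split) length(split$ids)

#' Construct an embedding set
#'
#' One provider's embedding matrix for one dataset split, with the sample
#' identifiers and labels aligned row-for-row.
#'
#' @param matrix Numeric matrix, one row per sample.
#' @param sample_ids Character vector, one id per row.
#' @param labels Labels aligned with rows (vector or 0/1 matrix).
#' @param model Name of the producing model.
#' @param split Split name.
#' @return An object of class `embedding_set`.
#' @export
embedding_set <- function(matrix, sample_ids, labels, model, split) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("embeddings must be a numeric matrix", call. = FALSE)
  }
  sample_ids <- as.character(sample_ids)
  if (nrow(matrix) != length(sample_ids)) {
    stop("embedding rows (", nrow(matrix), ") and sample ids (",
         length(sample_ids), ") disagree for model '", model, "'",
         call. = FALSE)
  }
  structure(
    list(matrix = matrix, sample_ids = sample_ids, labels = labels,
         model = model, split = split),
    class = "embedding_set"
  )
}

#' @export
print.embedding_set <- function(x, ...) {
  cat("<embedding_set> model '", x$model, "', split '", x$split, "': ",
      nrow(x$matrix), " x ", ncol(x$matrix), "\n", sep = "")
  invisible(x)
}

#' @export
dim.embedding_set <- function(x) dim(x$matrix)

# Stop with the first mismatching id if two embedding sets are not aligned.
check_alignment <- function(blocks) {
  ref <- blocks[[1L]]$sample_ids
  for (b in blocks[-1L]) {
    if (length(b$sample_ids) != length(ref) || any(b$sample_ids != ref)) {
      bad <- if (length(b$sample_ids) != length(ref)) {
        ref[min(length(ref), length(b$sample_ids)) + 0L][1L]
      } else {
        ref[which(b$sample_ids != ref)[1L]]
      }
      stop("sample ids of model '", b$model,
           "' are not aligned with model '", blocks[[1L]]$model,
           "' (first mismatch at id '", bad, "')", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Assemble a dataset from splits
#'
#' @param dataset_id Identifier string used for caching.
#' @param task_type One of `"binary"`, `"multiclass"`, `"multilabel"`.
#' @param n_classes Number of classes (single-label) or labels (multi-label).
#' @param splits Named list of [dataset_split()] objects; must contain at
#'   least `train` and `valid`.
#' @return An object of class `fusion_dataset`.
#' @export
fusion_dataset <- function(dataset_id, task_type, n_classes, splits) {
  task_type <- match.arg(task_type, c("binary", "multiclass", "multilabel"))
  if (task_type == "binary" && n_classes != 2L) {
    stop("binary tasks require n_classes == 2", call. = FALSE)
  }
  stopifnot(is.list(splits), all(vapply(splits, inherits, TRUE, "dataset_split")))
  structure(
    list(dataset_id = dataset_id, task_type = task_type,
         n_classes = as.integer(n_classes), splits = splits),
    class = "fusion_dataset"
  )
}

#' @export
print.fusion_dataset <- function(x, ...) {
  cat("<fusion_dataset '", x$dataset_id, "'> ", x$task_type, ", ",
      x$n_classes, " classes; splits: ",
      paste(sprintf("%s=%d", names(x$splits),
                    vapply(x$splits, n_samples, 0L)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
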