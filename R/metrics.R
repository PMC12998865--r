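#' Classification accuracy
#'
#' Correct predictions over total predictions. For multi-label tasks
#' (matrix inputs) this is the per-label binary accuracy averaged over
#' labels, i.e. the fraction of correct individual label decisions.
#'
#' @param predictions Predicted class indices (vector) or 0/1 matrix
#'   (multi-label).
#' @param labels True labels, same shape as `predictions`.
#' @return Accuracy in `[0, 1]`.
#' @export
classification_accuracy <- function(predictions, labels) {
  if (length(predictions) == 0L) {
    stop("cannot compute accuracy of empty predictions", call. = FALSE)
  }
  if (is.matrix(labels) != is.matrix(predictions)) {
    stop("predictions and labels must both be vectors or both matrices",
         call. = FALSE)
  }
  if (is.matrix(labels)) {
    if (!all(dim(predictions) == dim(labels))) {
      stop("prediction/label shape mismatch", call. = FALSE)
    }
    return(mean(predictions == labels))
  }
  if (length(predictions) != length(labels)) {
    stop("prediction/label length mismatch", call. = FALSE)
  }
  mean(predictions == labels)
}

# Binary AUC by the rank (Mann-Whitney) construction: the probability that
# a random positive outscores a random negative, ties counting one half.
auc_binary <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC is undefined: only one class present", call. = FALSE)
  }
  r <- rank(scores)  # average ranks implement the 0.5 tie convention
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the ROC curve
#'
#' Binary AUC equals the normalised pairwise-comparison count
#' `(#(pos > neg) + 0.5 * #ties) / (n_pos * n_neg)`. Multi-class AUC is the
#' macro average of one-vs-rest AUCs; multi-label AUC is the macro average
#' of per-label AUCs.
#'
#' @param scores Binary: numeric vector of positive-class scores.
#'   Multi-class: matrix with one column per class. Multi-label: matrix
#'   with one column per label.
#' @param labels Binary: 0/1 vector. Multi-class: 0-based class indices.
#'   Multi-label: 0/1 matrix.
#' @param task_type One of `"binary"`, `"multiclass"`, `"multilabel"`.
#' @return AUC in `[0, 1]`; errors (rather than silently returning 0.5)
#'   when a class is absent.
#' @export
auc_roc <- function(scores, labels,
                    task_type = c("binary", "multiclass", "multilabel")) {
  task_type <- match.arg(task_type)
  switch(
    task_type,
    binary = auc_binary(as.numeric(scores), labels),
    multiclass = {
      stopifnot(is.matrix(scores))
      labels <- as.integer(labels)
      classes <- seq_len(ncol(scores)) - 1L
      present <- classes %in% labels
      if (!all(present)) {
        stop("AUC is undefined: class(es) ",
             paste(classes[!present], collapse = ", "),
             " absent from labels", call. = FALSE)
      }
      mean(vapply(classes, function(k) {
        auc_binary(scores[, k + 1L], as.integer(labels == k))
      }, 0))
    },
    multilabel = {
      stopifnot(is.matrix(scores), is.matrix(labels))
      mean(vapply(seq_len(ncol(labels)), function(j) {
        auc_binary(scores[, j], labels[, j])
      }, 0))
    }
  )
}

#' Balanced error
#'
#' One minus the mean of per-class recalls; insensitive to class imbalance
#' and the error measure used by corruption-robustness benchmarks. For
#' multi-label inputs, per-label binary balanced errors are averaged.
#'
#' @param predictions Predicted class indices (vector) or 0/1 matrix.
#' @param labels True labels, same shape.
#' @return Balanced error in `[0, 1]`.
#' @export
balanced_error <- function(predictions, labels) {
  if (is.matrix(labels)) {
    return(mean(vapply(seq_len(ncol(labels)), function(j) {
      balanced_error(predictions[, j], labels[, j])
    }, 0)))
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("balanced error needs every class present; labels contain only ",
         "class ", classes, call. = FALSE)
  }
  recalls <- vapply(classes, function(k) {
    mean(predictions[labels == k] == k)
  }, 0)
  1 - mean(recalls)
}

#' Number of corruption-severity conditions
#'
#' @param n_corruptions,n_severities Positive integers.
#' @return Their product, e.g. 11 corruptions x 5 severities = 55 pairs.
#' @export
count_corruption_pairs <- function(n_corruptions, n_severities) {
  stopifnot(n_corruptions >= 1L, n_severities >= 1L)
  as.integer(n_corruptions) * as.integer(n_severities)
}

#' Bundle per-corruption balanced errors for robustness scoring
#'
#' @param model_clean,ref_clean Balanced errors of the candidate model and
#'   of the reference model on the uncorrupted test set.
#' @param model_errors,ref_errors Matrices of balanced errors indexed by
#'   corruption (rows) and severity (columns); both models must cover the
#'   same conditions (11 x 5 in the standard benchmark).
#' @return An object of class `corruption_error_table`.
#' @export
corruption_error_table <- function(model_clean, ref_clean,
                                   model_errors, ref_errors) {
  stopifnot(is.matrix(model_errors), is.matrix(ref_errors))
  if (!all(dim(model_errors) == dim(ref_errors))) {
    stop("model and reference error matrices must have the same shape",
         call. = FALSE)
  }
  vals <- c(model_clean, ref_clean, model_errors, ref_errors)
  if (any(vals < 0 | vals > 1)) {
    stop("balanced errors must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(model_clean = model_clean, ref_clean = ref_clean,
         model_errors = model_errors, ref_errors = ref_errors),
    class = "corruption_error_table"
  )
}

#' Reference-normalised robustness scores
#'
#' For each corruption `c`, the severity-summed balanced errors of the
#' candidate model are divided by the reference model's; `BE` is the mean
#' of these per-corruption ratios (reference model = 1). `rBE` is the
#' analogous ratio of severity-summed error *increases* over the clean
#' error, and may legitimately be negative when the candidate's error
#' under corruption falls below its clean error while the reference's
#' rises. A `pair_mean` mode instead averages the 55 per-condition ratios
#' directly.
#'
#' @param table A [corruption_error_table()].
#' @param mode `"corruption_mean"` (severity-summed ratio per corruption,
#'   then mean over corruptions; the convention of the ImageNet-C family
#'   of benchmarks) or `"pair_mean"` (mean of per-condition ratios).
#' @param scale_100 Multiply both scores by 100 (reference = 100) instead
#'   of reporting raw ratios (reference = 1, the default).
#' @return A list with numeric scalars `BE` and `rBE`.
#' @export
robustness_scores <- function(table,
                              mode = c("corruption_mean", "pair_mean"),
                              scale_100 = FALSE) {
  stopifnot(inherits(table, "corruption_error_table"))
  mode <- match.arg(mode)
  me <- table$model_errors
  re <- table$ref_errors
  d_model <- me - table$model_clean
  d_ref <- re - table$ref_clean
  if (mode == "corruption_mean") {
    ref_sum <- rowSums(re)
    dref_sum <- rowSums(d_ref)
    if (any(ref_sum == 0)) {
      stop("zero reference error sum for corruption(s) ",
           paste(which(ref_sum == 0), collapse = ", "), call. = FALSE)
    }
    if (any(dref_sum == 0)) {
      stop("zero reference error increase for corruption(s) ",
           paste(which(dref_sum == 0), collapse = ", "), call. = FALSE)
    }
    be <- mean(rowSums(me) / ref_sum)
    rbe <- mean(rowSums(d_model) / dref_sum)
  } else {
    if (any(re == 0)) stop("zero reference error in table", call. = FALSE)
    if (any(d_ref == 0)) {
      stop("zero reference error increase in table", call. = FALSE)
    }
    be <- mean(me / re)
    rbe <- mean(d_model / d_ref)
  }
  s <- if (isTRUE(scale_100)) 100 else 1
  list(BE = be * s, rBE = rbe * s)
}

#' Read or write a corruption error table as CSV
#'
#' The file starts with a two-row clean-error block
#' (`clean,model,<value>` / `clean,ref,<value>`) followed by a standard
#' CSV body with columns `corruption,severity,model_error,ref_error`.
#'
#' @param table A [corruption_error_table()].
#' @param path File path.
#' @return `write_corruption_table()` returns `path` invisibly;
#'   `read_corruption_table()` returns a [corruption_error_table()].
#' @export
write_corruption_table <- function(table, path) {
  stopifnot(inherits(table, "corruption_error_table"))
  lines <- c(
    sprintf("clean,model,%.17g", table$model_clean),
    sprintf("clean,ref,%.17g", table$ref_clean),
    "corruption,severity,model_error,ref_error"
  )
  me <- table$model_errors
  re <- table$ref_errors
  for (c_ in seq_len(nrow(me))) {
    for (s_ in seq_len(ncol(me))) {
      lines <- c(lines, sprintf("%d,%d,%.17g,%.17g", c_, s_,
                                me[c_, s_], re[c_, s_]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_corruption_table
#' @export
read_corruption_table <- function(path) {
  lines <- readLines(path)
  clean <- strsplit(lines[1:2], ",")
  model_clean <- as.numeric(clean[[1L]][3L])
  ref_clean <- as.numeric(clean[[2L]][3L])
  body <- read.csv(textConnection(lines[-(1:2)]))
  n_c <- max(body$corruption)
  n_s <- max(body$severity)
  me <- matrix(NA_real_, n_c, n_s)
  re <- matrix(NA_real_, n_c, n_s)
  me[cbind(body$corruption, body$severity)] <- body$model_error
  re[cbind(body$corruption, body$severity)] <- body$ref_error
  if (anyNA(me) || anyNA(re)) {
    stop("corruption table is missing (corruption, severity) conditions",
         call. = FALSE)
  }
  corruption_error_table(model_clean, ref_clean, me, re)
}
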