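#' Fuse embedding blocks by concatenation
#'
#' Parameter-free fusion: given per-model embeddings `e_i` of width `d_i`,
#' the fused representation is `[e_1; e_2; ...; e_n]` along the feature
#' dimension, of total width `sum(d_i)`. Each model's features stay in an
#' isolated, contiguous sub-block (block order = registration order), so
#' no cross-model normalisation is applied and every input block can be
#' recovered exactly from its column range. An optional per-block z-scoring
#' flag exists for experimentation but defaults off: the downstream probe
#' is a tree ensemble, whose splits depend on feature ordering rather than
#' scale, so heterogeneous block scales are left untouched.
#'
#' @param blocks Ordered list of [embedding_set()] objects with identical
#'   sample ids in identical order.
#' @param zscore_blocks If `TRUE`, z-score each block's columns before
#'   concatenation (default `FALSE`).
#' @return An object of class `fused_embeddings` with fields `matrix`
#'   (`n x sum(d_i)`), `blocks` (data frame `model`, `offset`, `dim`, with
#'   0-based offsets partitioning the columns), `strategy = "concat"`,
#'   `sample_ids` and `labels`.
#' @export
concat_fuse <- function(blocks, zscore_blocks = FALSE) {
  if (length(blocks) == 0L) {
    stop("cannot fuse an empty sequence of blocks", call. = FALSE)
  }
  stopifnot(all(vapply(blocks, inherits, TRUE, "embedding_set")))
  check_alignment(blocks)
  mats <- lapply(blocks, function(b) {
    m <- b$matrix
    if (zscore_blocks) {
      m <- scale(m)
      m[is.nan(m)] <- 0  # constant columns
      attr(m, "scaled:center") <- NULL
      attr(m, "scaled:scale") <- NULL
    }
    m
  })
  dims <- vapply(mats, ncol, 0L)
  layout <- data.frame(
    model = vapply(blocks, function(b) b$model, ""),
    offset = cumsum(c(0L, dims[-length(dims)])),
    dim = dims,
    stringsAsFactors = FALSE
  )
  structure(
    list(matrix = do.call(cbind, mats), blocks = layout, strategy = "concat",
         sample_ids = blocks[[1L]]$sample_ids, labels = blocks[[1L]]$labels),
    class = "fused_embeddings"
  )
}

#' @export
print.fused_embeddings <- function(x, ...) {
  cat("<fused_embeddings> ", x$strategy, ": ", nrow(x$matrix), " x ",
      ncol(x$matrix), sep = "")
  if (nrow(x$blocks)) {
    cat(" [", paste(sprintf("%s:%d", x$blocks$model, x$blocks$dim),
                    collapse = " + "), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Extract one model's sub-block from a concatenation
#'
#' @param fused A `fused_embeddings` with strategy `"concat"`.
#' @param model Model name present in the block layout.
#' @return The model's original embedding matrix, bit-for-bit.
#' @export
fused_block <- function(fused, model) {
  stopifnot(inherits(fused, "fused_embeddings"))
  if (!identical(fused$strategy, "concat")) {
    stop("sub-block extraction is only defined for concatenation fusion",
         call. = FALSE)
  }
  i <- match(model, fused$blocks$model)
  if (is.na(i)) stop("no block for model '", model, "'", call. = FALSE)
  off <- fused$blocks$offset[i]
  fused$matrix[, seq.int(off + 1L, off + fused$blocks$dim[i]), drop = FALSE]
}
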