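# Minimal NPY (format version 1.0) reader/writer. NPY is the standard
# array container of the numerical-Python ecosystem; storing cache blocks
# in it keeps the on-disk cache language-portable and human-recoverable.
# Only what the cache and bundle reader need is implemented: little-endian
# float64/float32, int64/int32, uint8/int8, C or Fortran order, 1-4 dims.

npy_magic <- as.raw(c(0x93, charToRaw("NUMPY")))

npy_descr <- c(
  "<f8" = "double", "<f4" = "float", "<i8" = "int64", "<i4" = "integer",
  "|u1" = "uint8", "|i1" = "int8"
)

#' Write a numeric matrix or array to an NPY file
#'
#' Arrays are written as little-endian float64 in C (row-major) order,
#' readable by any NPY implementation.
#'
#' @param x Numeric matrix or array.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path) {
  if (is.null(dim(x))) dim(x) <- length(x)
  shape <- dim(x)
  shape_str <- if (length(shape) == 1L) {
    sprintf("(%d,)", shape)
  } else {
    sprintf("(%s)", paste(shape, collapse = ", "))
  }
  header <- sprintf(
    "{'descr': '<f8', 'fortran_order': False, 'shape': %s, }", shape_str)
  # total header block (magic 6 + version 2 + len 2 + header) padded to 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(npy_magic, con)
  writeBin(as.raw(c(1L, 0L)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  # C order: last axis fastest; R stores first axis fastest, so transpose
  perm <- rev(seq_along(dim(x)))
  writeBin(as.numeric(aperm(x, perm)), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read an NPY file
#'
#' @param path Path to a `.npy` file.
#' @return A numeric vector, matrix or array with the stored shape.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, npy_magic)) {
    stop("not an NPY file: ", path, call. = FALSE)
  }
  version <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(version[1L]) >= 2L) {
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
  }
  header <- readChar(con, hlen, useBytes = TRUE)
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s|,$", "", shape_str), ",")[[1L]])
  if (length(shape) == 0L) shape <- integer(0)
  n <- if (length(shape)) prod(shape) else 1L
  type <- npy_descr[descr]
  if (is.na(type)) {
    stop("unsupported NPY dtype '", descr, "' in ", path, call. = FALSE)
  }
  vals <- switch(
    type,
    double = readBin(con, "numeric", n, size = 8L, endian = "little"),
    float = readBin(con, "numeric", n, size = 4L, endian = "little"),
    int64 = {
      raw <- readBin(con, "raw", n * 8L)
      lo <- readBin(raw[rep(seq_len(n) * 8L - 7L, each = 4L) +
                          rep(0:3, n)], "integer", n, size = 4L,
                    endian = "little")
      hi <- readBin(raw[rep(seq_len(n) * 8L - 3L, each = 4L) +
                          rep(0:3, n)], "integer", n, size = 4L,
                    endian = "little")
      hi * 2^32 + ifelse(lo < 0, lo + 2^32, lo)
    },
    integer = readBin(con, "integer", n, size = 4L, endian = "little"),
    uint8 = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    int8 = as.numeric(readBin(con, "integer", n, size = 1L, signed = TRUE))
  )
  if (length(vals) != n) {
    stop("truncated NPY payload in ", path, ": expected ", n,
         " values, read ", length(vals), call. = FALSE)
  }
  if (length(shape) <= 1L) return(vals)
  if (fortran) {
    array(vals, dim = shape)
  } else {
    aperm(array(vals, dim = rev(shape)), rev(seq_along(shape)))
  }
}

#' Read a MedMNIST-style NPZ image bundle
#'
#' Expects a zip archive holding `train_images`, `train_labels`,
#' `val_images`, `val_labels`, `test_images`, `test_labels` as NPY members.
#' Labels may be integer class indices (single-label) or 0/1 multi-hot
#' matrices (multi-label); single-column label matrices are flattened.
#'
#' @param path Path to the `.npz` archive.
#' @param dataset_id Identifier for the resulting dataset (defaults to the
#'   file name without extension).
#' @return A [fusion_dataset()] whose splits carry the image arrays in
#'   `data` (first dimension indexes samples).
#' @export
read_npz_bundle <- function(path, dataset_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(dataset_id)) {
    dataset_id <- sub("\\.npz$", "", basename(path))
  }
  exdir <- tempfile("npz_")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  member <- function(key) {
    hit <- files[basename(files) %in% paste0(key, ".npy")]
    if (length(hit) != 1L) {
      stop("bundle is missing required key '", key, "'", call. = FALSE)
    }
    read_npy(hit)
  }
  splits <- list()
  key_of <- c(train = "train", valid = "val", test = "test")
  labels_train <- NULL
  for (split_name in names(key_of)) {
    imgs <- member(paste0(key_of[[split_name]], "_images"))
    labs <- member(paste0(key_of[[split_name]], "_labels"))
    if (is.matrix(labs) && ncol(labs) == 1L) labs <- as.vector(labs)
    labs <- if (is.matrix(labs)) {
      storage.mode(labs) <- "integer"; labs
    } else {
      as.integer(labs)
    }
    n <- dim(imgs)[1L]
    ids <- sprintf("%s_%06d", split_name, seq_len(n))
    splits[[split_name]] <- dataset_split(split_name, ids, labs, data = imgs)
    if (split_name == "train") labels_train <- labs
  }
  multilabel <- is.matrix(labels_train)
  n_classes <- if (multilabel) {
    ncol(labels_train)
  } else {
    length(unique(labels_train))
  }
  task <- if (multilabel) {
    "multilabel"
  } else if (n_classes == 2L) "binary" else "multiclass"
  fusion_dataset(dataset_id, task, n_classes, splits)
}

#' Read a CSV label table
#'
#' Single-label tables have header `sample_id,label`; multi-label tables
#' have `sample_id,l0,l1,...` with 0/1 entries.
#'
#' @param path CSV file path.
#' @return A list with `ids` (character) and `labels` (integer vector or
#'   0/1 integer matrix).
#' @export
read_label_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("label table must have a 'sample_id' column", call. = FALSE)
  }
  ids <- as.character(df$sample_id)
  value_cols <- setdiff(names(df), "sample_id")
  if (identical(value_cols, "label")) {
    labels <- as.integer(df$label)
  } else {
    labels <- as.matrix(df[value_cols])
    storage.mode(labels) <- "integer"
    if (any(!labels %in% c(0L, 1L))) {
      stop("multi-label table entries must be 0/1", call. = FALSE)
    }
  }
  list(ids = ids, labels = labels)
}
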