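#' Enumerate candidate model subsets
#'
#' Exhaustive mode yields every non-empty subset of the `n` registered
#' models exactly once (2^n - 1 subsets); `singles_only` yields the `n`
#' singletons (the "oracle-single" ablation). Within every subset, models
#' keep registry order -- the fixed concatenation order.
#'
#' @param n Number of registered models (>= 1).
#' @param mode `"exhaustive"` or `"singles_only"`.
#' @return List of integer index vectors into the registry order.
#' @export
enumerate_subsets <- function(n, mode = c("exhaustive", "singles_only")) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("need at least one model", call. = FALSE)
  if (mode == "singles_only") return(lapply(seq_len(n), identity))
  # bitmask enumeration: subset k contains model i iff bit i of k is set
  lapply(seq_len(2^n - 1L), function(k) {
    which(bitwAnd(k, 2^(seq_len(n) - 1L)) > 0L)
  })
}

#' Exhaustive model-subset search
#'
#' Evaluates every candidate subset: fetch the subset's blocks through the
#' cache, fuse by concatenation, fit the fixed-configuration probe on the
#' training split, and record validation accuracy. The winner is the
#' highest validation accuracy, with deterministic tie-breaking: fewer
#' models first, then earliest in enumeration order. Validation accuracy
#' is the only selection metric; AUC is reported downstream but never
#' drives selection.
#'
#' @param registry A [model_registry()].
#' @param dataset A [fusion_dataset()] with `train` and `valid` splits.
#' @param probe A [probe_config()]; the default is the fixed search
#'   probe (250 trees, learning rate 0.1, depth 6).
#' @param mode `"exhaustive"` or `"singles_only"`.
#' @param seed Probe seed used for every subset evaluation (one seed
#'   during search; run-averaging applies only at final evaluation).
#' @param cache An [embedding_cache()], or `NULL` to extract on the fly.
#' @param leaderboard_path Optional CSV path
#'   (`rank,subset,fused_dim,valid_accuracy,status`).
#' @return An object of class `search_result` with `evaluations` (data
#'   frame in enumeration order), `selected` (character vector of model
#'   names), `selected_accuracy`, `n_evaluated`, `mode` and `seed`.
#' @export
run_search <- function(registry, dataset, probe = probe_config(),
                       mode = c("exhaustive", "singles_only"), seed = 1L,
                       cache = NULL, leaderboard_path = NULL) {
  mode <- match.arg(mode)
  models <- registered_models(registry)
  if (length(models) == 0L) stop("registry is empty", call. = FALSE)
  if (!all(c("train", "valid") %in% names(dataset$splits))) {
    stop("dataset needs train and valid splits", call. = FALSE)
  }
  probe$seed <- as.integer(seed)
  tag <- content_tag(registry$version, dataset)
  fetch <- function(model, split_name) {
    get_or_extract(cache, registry,
                   cache_key(model, dataset$dataset_id, split_name, tag),
                   dataset$splits[[split_name]])
  }
  # fetch each block once up front; the exponential loop then only fuses.
  # A failing provider poisons only the subsets that contain it.
  safe_fetch <- function(model, split_name) {
    tryCatch(fetch(model, split_name), error = function(e) e)
  }
  blocks <- list(
    train = lapply(setNames(models, models), safe_fetch, split_name = "train"),
    valid = lapply(setNames(models, models), safe_fetch, split_name = "valid")
  )
  subsets <- enumerate_subsets(length(models), mode)
  evals <- data.frame(
    subset = vapply(subsets, function(s) paste(models[s], collapse = ","), ""),
    size = lengths(subsets),
    fused_dim = NA_integer_,
    valid_accuracy = NA_real_,
    status = "pending",
    stringsAsFactors = FALSE
  )
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    res <- tryCatch({
      for (b in c(blocks$train[s], blocks$valid[s])) {
        if (inherits(b, "error")) stop(conditionMessage(b))
      }
      tr <- concat_fuse(blocks$train[s])
      va <- concat_fuse(blocks$valid[s])
      fitted <- fit_probe(tr, config = probe,
                         task_type = dataset$task_type,
                         n_classes = dataset$n_classes)
      list(dim = ncol(tr$matrix), acc = probe_accuracy(fitted, va, va$labels))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      evals$status[i] <- paste0("failed: ", conditionMessage(res))
    } else {
      evals$fused_dim[i] <- res$dim
      evals$valid_accuracy[i] <- res$acc
      evals$status[i] <- "ok"
    }
  }
  ok <- which(evals$status == "ok")
  if (length(ok) == 0L) {
    stop("every subset evaluation failed; first failure: ",
         evals$status[1L], call. = FALSE)
  }
  # winner: max accuracy, ties -> smaller subset, then enumeration order
  ord <- ok[order(-evals$valid_accuracy[ok], evals$size[ok], ok)]
  winner <- ord[1L]
  result <- structure(
    list(evaluations = evals,
         selected = models[subsets[[winner]]],
         selected_accuracy = evals$valid_accuracy[winner],
         selected_dim = evals$fused_dim[winner],
         n_evaluated = length(subsets), mode = mode,
         seed = as.integer(seed), dataset_id = dataset$dataset_id,
         content_tag = tag),
    class = "search_result"
  )
  if (!is.null(leaderboard_path)) {
    lb <- evals[ord, c("subset", "fused_dim", "valid_accuracy", "status")]
    failed <- setdiff(seq_len(nrow(evals)), ok)
    if (length(failed)) {
      lb <- rbind(lb, evals[failed, c("subset", "fused_dim",
                                      "valid_accuracy", "status")])
    }
    lb <- cbind(rank = seq_len(nrow(lb)), lb)
    write.csv(lb, leaderboard_path, row.names = FALSE)
  }
  result
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result> ", x$mode, " over ", x$n_evaluated,
      " subsets; selected [", paste(x$selected, collapse = ", "),
      "] at validation accuracy ", sprintf("%.4f", x$selected_accuracy),
      "\n", sep = "")
  invisible(x)
}

#' Build the reusable embedding generator for a selected subset
#'
#' Packages the winning subset into a fusion model: applied to any split,
#' it extracts the selected models' blocks (through the cache) and fuses
#' them with the chosen strategy, yielding embeddings laid out exactly as
#' during search.
#'
#' @param result A `search_result` (or a character vector of model names).
#' @param registry The registry the search ran against.
#' @param strategy `"concat"` or `"self_attention"`.
#' @param attention An `attention_fusion_model` (required for
#'   `strategy = "self_attention"`).
#' @return An object of class `fusion_model`.
#' @export
build_fusion_model <- function(result, registry,
                               strategy = c("concat", "self_attention"),
                               attention = NULL) {
  strategy <- match.arg(strategy)
  selected <- if (inherits(result, "search_result")) result$selected else result
  if (length(selected) == 0L) stop("empty model selection", call. = FALSE)
  missing <- setdiff(selected, registered_models(registry))
  if (length(missing)) {
    stop("selected model(s) no longer registered: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (strategy == "self_attention" && is.null(attention)) {
    stop("self_attention strategy needs a fitted attention fusion model",
         call. = FALSE)
  }
  structure(
    list(selected = selected, registry = registry, strategy = strategy,
         attention = attention,
         dims = vapply(selected, function(m) get_spec(registry, m)$dim, 0L)),
    class = "fusion_model"
  )
}

#' @export
print.fusion_model <- function(x, ...) {
  cat("<fusion_model> ", x$strategy, " over [",
      paste(x$selected, collapse = ", "), "], output width ",
      if (x$strategy == "concat") sum(x$dims) else x$attention$config$proj_dim,
      "\n", sep = "")
  invisible(x)
}

#' Generate fused embeddings for a split
#'
#' @param model A `fusion_model` from [build_fusion_model()].
#' @param dataset The dataset whose split to embed.
#' @param split_name Split name.
#' @param cache Optional [embedding_cache()].
#' @return A `fused_embeddings`.
#' @export
generate_embeddings <- function(model, dataset, split_name, cache = NULL) {
  stopifnot(inherits(model, "fusion_model"))
  split <- dataset$splits[[split_name]]
  if (is.null(split)) stop("dataset has no split '", split_name, "'",
                           call. = FALSE)
  tag <- content_tag(model$registry$version, dataset)
  blocks <- lapply(model$selected, function(m) {
    get_or_extract(cache, model$registry,
                   cache_key(m, dataset$dataset_id, split_name, tag), split)
  })
  if (model$strategy == "concat") {
    concat_fuse(blocks)
  } else {
    attention_fuse_apply(model$attention, blocks)
  }
}
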