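# End-to-end orchestration: search -> fusion model -> tuning -> final
# test evaluation, with every artifact (leaderboard, trial log, metrics,
# resolved config) persisted so a run is reproducible from its output
# directory alone.

#' Configure an end-to-end run
#'
#' @param dataset_id Dataset identifier (must match the dataset passed to
#'   [run_workflow()]).
#' @param cache_root Cache directory; `NULL` disables caching.
#' @param mode Search mode, `"exhaustive"` or `"singles_only"`.
#' @param fusion Fusion settings: `list(strategy = "concat")` or
#'   `list(strategy = "self_attention", n_heads =, d_head =, epochs =, ...)`
#'   (extra entries are passed to [attention_fusion_config()]).
#' @param probe A [probe_config()] for the search phase.
#' @param tuner A [tuner_config()] for final-probe tuning.
#' @param n_final_runs Probe seeds averaged at final test evaluation
#'   (default 3).
#' @param seed Master seed for search, tuning and evaluation.
#' @param out_dir Output directory for run artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(dataset_id, cache_root = NULL,
                       mode = c("exhaustive", "singles_only"),
                       fusion = list(strategy = "concat"),
                       probe = probe_config(),
                       tuner = tuner_config(n_trials = 20L),
                       n_final_runs = 3L, seed = 1L,
                       out_dir = tempfile("run_")) {
  mode <- match.arg(mode)
  stopifnot(fusion$strategy %in% c("concat", "self_attention"))
  structure(
    list(dataset_id = dataset_id, cache_root = cache_root, mode = mode,
         fusion = fusion, probe = probe, tuner = tuner,
         n_final_runs = as.integer(n_final_runs), seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

config_as_yaml_list <- function(config) {
  list(
    dataset_id = config$dataset_id,
    cache_root = config$cache_root,
    mode = config$mode,
    fusion = config$fusion,
    probe = unclass(config$probe),
    tuner = list(n_trials = config$tuner$n_trials,
                 sampler = config$tuner$sampler,
                 seed = config$tuner$seed,
                 search_space = config$tuner$search_space),
    n_final_runs = config$n_final_runs,
    seed = config$seed
  )
}

#' Load a persisted run configuration
#'
#' @param path Path to a `config.resolved.yaml` written by
#'   [run_workflow()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  probe <- do.call(probe_config, y$probe)
  space <- lapply(y$tuner$search_space, function(p) {
    list(type = p$type, lo = p$lo, hi = p$hi)
  })
  run_config(
    dataset_id = y$dataset_id, cache_root = y$cache_root, mode = y$mode,
    fusion = y$fusion, probe = probe,
    tuner = tuner_config(n_trials = y$tuner$n_trials, search_space = space,
                         sampler = y$tuner$sampler, seed = y$tuner$seed),
    n_final_runs = y$n_final_runs, seed = y$seed
  )
}

stage_log <- function(dir, stage, ...) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste(..., collapse = " "))
  cat(line, "\n", file = file.path(dir, "run.log"), append = TRUE)
}

#' Run the full train/evaluate workflow
#'
#' Executes the six-stage pipeline: (1) take the dataset's splits; (2)
#' search model subsets on train/valid; (3) build the fusion model and
#' emit train/valid embeddings; (4) tune the final probe; (5) generate
#' test embeddings with the fusion model; (6) score the tuned probe on the
#' test split, averaging over `n_final_runs` probe seeds. Writes
#' `leaderboard.csv`, `trials.csv`, `metrics.json`, `config.resolved.yaml`
#' and `run.log` under `config$out_dir`; artifacts from completed stages
#' are retained even when a later stage fails.
#'
#' @param registry A [model_registry()].
#' @param dataset A [fusion_dataset()] with train/valid/test splits.
#' @param config A [run_config()].
#' @return An object of class `run_report`: the search result, fusion
#'   model, tuned configuration, test [score_probe()] report and stage
#'   status.
#' @export
run_workflow <- function(registry, dataset, config) {
  stopifnot(inherits(config, "run_config"))
  if (!identical(dataset$dataset_id, config$dataset_id)) {
    stop("config is for dataset '", config$dataset_id,
         "', got '", dataset$dataset_id, "'", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config_as_yaml_list(config),
                   file.path(config$out_dir, "config.resolved.yaml"))
  cache <- if (!is.null(config$cache_root)) {
    embedding_cache(config$cache_root)
  } else NULL
  stages <- character()
  report <- structure(
    list(config = config, stages = stages),
    class = "run_report"
  )
  run_stage <- function(stage, expr) {
    stage_log(config$out_dir, stage, "start")
    value <- tryCatch(expr, error = function(e) e)
    if (inherits(value, "error")) {
      stage_log(config$out_dir, stage, "FAILED:", conditionMessage(value))
      stop("stage '", stage, "' failed: ", conditionMessage(value),
           call. = FALSE)
    }
    stage_log(config$out_dir, stage, "done")
    value
  }

  search <- run_stage("search", run_search(
    registry, dataset, probe = config$probe, mode = config$mode,
    seed = config$seed, cache = cache,
    leaderboard_path = file.path(config$out_dir, "leaderboard.csv")
  ))
  report$search <- search
  stage_log(config$out_dir, "search",
            sprintf("selected=[%s] acc=%.4f",
                    paste(search$selected, collapse = ","),
                    search$selected_accuracy))

  strategy <- config$fusion$strategy
  attention <- NULL
  tag <- content_tag(registry$version, dataset)
  get_blocks <- function(split_name) {
    lapply(search$selected, function(m) {
      get_or_extract(cache, registry,
                     cache_key(m, dataset$dataset_id, split_name, tag),
                     dataset$splits[[split_name]])
    })
  }
  if (strategy == "self_attention") {
    attention <- run_stage("attention_fit", {
      extra <- config$fusion[setdiff(names(config$fusion), "strategy")]
      extra$seed <- config$seed
      acfg <- do.call(attention_fusion_config, extra)
      attention_fuse_fit(get_blocks("train"), config = acfg,
                         valid_blocks = get_blocks("valid"))
    })
  }
  fm <- run_stage("fusion_model",
                  build_fusion_model(search, registry, strategy = strategy,
                                     attention = attention))
  report$fusion_model <- fm
  train_emb <- run_stage("embed_train",
                         generate_embeddings(fm, dataset, "train", cache))
  valid_emb <- generate_embeddings(fm, dataset, "valid", cache)

  tuned <- run_stage("tune", {
    tn <- config$tuner
    tn$seed <- config$seed
    tune_probe(train_emb, valid_emb, tn,
               task_type = dataset$task_type, n_classes = dataset$n_classes,
               log_path = file.path(config$out_dir, "trials.csv"))
  })
  report$tuned <- tuned

  test_emb <- run_stage("embed_test",
                        generate_embeddings(fm, dataset, "test", cache))
  metrics <- run_stage("evaluate", {
    cfg <- tuned$best_config
    cfg$seed <- config$seed
    final_probe <- fit_probe(train_emb, config = cfg,
                             task_type = dataset$task_type,
                             n_classes = dataset$n_classes)
    score_probe(final_probe, test_emb, n_runs = config$n_final_runs,
                train = train_emb)
  })
  report$metrics <- metrics
  jsonlite::write_json(
    list(dataset_id = dataset$dataset_id,
         selected = search$selected,
         fused_dim = if (strategy == "concat") search$selected_dim
                     else attention$config$proj_dim,
         valid_accuracy = search$selected_accuracy,
         tuned_valid_accuracy = tuned$best_accuracy,
         test_accuracy = metrics$accuracy,
         test_auc = metrics$auc,
         per_seed = metrics$per_seed,
         n_runs = metrics$n_runs,
         seed = config$seed),
    file.path(config$out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  report$stages <- c("search", "fusion_model", "tune", "evaluate")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> dataset '", x$config$dataset_id, "'\n", sep = "")
  if (!is.null(x$search)) print(x$search)
  if (!is.null(x$metrics)) {
    cat(sprintf("  test accuracy %.4f, test AUC %.4f (%d runs)\n",
                x$metrics$accuracy, x$metrics$auc, x$metrics$n_runs))
  }
  invisible(x)
}

#' Summarise a run directory
#'
#' Prints the selected subset, fused width, validation/test metrics and
#' which stages completed; writes `summary.json` alongside the run
#' artifacts and flags stages whose outputs are missing (partial runs).
#'
#' @param run_dir A directory written by [run_workflow()].
#' @return The summary list, invisibly.
#' @export
report_run <- function(run_dir) {
  if (!dir.exists(run_dir)) {
    stop("no such run directory: ", run_dir, call. = FALSE)
  }
  have <- function(f) file.exists(file.path(run_dir, f))
  summary <- list(run_dir = run_dir,
                  stages_missing = character())
  if (have("leaderboard.csv")) {
    lb <- read.csv(file.path(run_dir, "leaderboard.csv"),
                   stringsAsFactors = FALSE)
    summary$selected <- lb$subset[1L]
    summary$fused_dim <- lb$fused_dim[1L]
    summary$valid_accuracy <- lb$valid_accuracy[1L]
  } else {
    summary$stages_missing <- c(summary$stages_missing, "search")
  }
  if (have("trials.csv")) {
    tr <- read.csv(file.path(run_dir, "trials.csv"), stringsAsFactors = FALSE)
    summary$n_trials <- nrow(tr)
    summary$tuned_valid_accuracy <- max(tr$valid_accuracy)
  } else {
    summary$stages_missing <- c(summary$stages_missing, "tune")
  }
  if (have("metrics.json")) {
    m <- jsonlite::read_json(file.path(run_dir, "metrics.json"),
                             simplifyVector = TRUE)
    summary$test_accuracy <- m$test_accuracy
    summary$test_auc <- m$test_auc
    summary$n_runs <- m$n_runs
  } else {
    summary$stages_missing <- c(summary$stages_missing, "evaluate")
  }
  cat("Run summary for ", run_dir, "\n", sep = "")
  if (!is.null(summary$selected)) {
    cat("  selected subset: ", summary$selected,
        " (fused width ", summary$fused_dim, ")\n", sep = "")
    cat(sprintf("  validation accuracy: %.4f\n", summary$valid_accuracy))
  }
  if (!is.null(summary$test_accuracy)) {
    cat(sprintf("  test accuracy: %.4f   test AUC: %.4f (%d runs)\n",
                summary$test_accuracy, summary$test_auc, summary$n_runs))
  }
  if (length(summary$stages_missing)) {
    cat("  missing stages: ",
        paste(summary$stages_missing, collapse = ", "), "\n", sep = "")
  }
  jsonlite::write_json(summary, file.path(run_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
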