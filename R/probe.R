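# Downstream probe: gradient-boosted trees on frozen fused embeddings.
# The search phase always uses one fixed configuration (250 trees,
# learning rate 0.1, depth 6) so that subset scores are comparable; a
# bounded hyperparameter tuner is applied only to the winning subset at
# final evaluation.

#' Probe configuration
#'
#' @param n_estimators Number of boosting rounds (default 250).
#' @param learning_rate Shrinkage (default 0.1).
#' @param max_depth Maximum tree depth (default 6).
#' @param min_child_weight,subsample,colsample_bytree,gamma,reg_alpha,reg_lambda
#'   Further boosting controls, exposed for the tuner; defaults are the
#'   library defaults.
#' @param seed Integer seed; with a single thread the probe is fully
#'   deterministic.
#' @return An object of class `probe_config`.
#' @export
probe_config <- function(n_estimators = 250L, learning_rate = 0.1,
                         max_depth = 6L, min_child_weight = 1,
                         subsample = 1, colsample_bytree = 1, gamma = 0,
                         reg_alpha = 0, reg_lambda = 1, seed = 1L) {
  structure(
    list(n_estimators = as.integer(n_estimators),
         learning_rate = learning_rate, max_depth = as.integer(max_depth),
         min_child_weight = min_child_weight, subsample = subsample,
         colsample_bytree = colsample_bytree, gamma = gamma,
         reg_alpha = reg_alpha, reg_lambda = reg_lambda,
         seed = as.integer(seed)),
    class = "probe_config"
  )
}

probe_matrix <- function(x) {
  if (inherits(x, "fused_embeddings")) x$matrix
  else if (inherits(x, "embedding_set")) x$matrix
  else as.matrix(x)
}

probe_labels <- function(x, labels) {
  if (!is.null(labels)) return(labels)
  if (is.list(x) && !is.null(x$labels)) return(x$labels)
  stop("no labels supplied and the embeddings carry none", call. = FALSE)
}

xgb_params <- function(config, objective, num_class = NULL) {
  p <- list(
    objective = objective, eta = config$learning_rate,
    max_depth = config$max_depth,
    min_child_weight = config$min_child_weight,
    subsample = config$subsample,
    colsample_bytree = config$colsample_bytree,
    gamma = config$gamma, alpha = config$reg_alpha,
    lambda = config$reg_lambda,
    nthread = 1L, seed = config$seed
  )
  if (!is.null(num_class)) p$num_class <- num_class
  p
}

#' Fit the probing classifier on fused embeddings
#'
#' Objective dispatch follows the task: multi-class probability objective
#' for >2 classes, binary logistic for 2, and an independent one-vs-rest
#' binary model per label for multi-label tasks.
#'
#' @param train Fused embeddings (or plain matrix) for the training split.
#' @param labels Training labels; defaults to those carried by `train`.
#' @param config A [probe_config()].
#' @param task_type Optional; inferred from the labels when `NULL`
#'   (matrix labels imply multi-label).
#' @param n_classes Optional; inferred from the labels when `NULL`.
#' @return An object of class `fitted_probe`.
#' @export
fit_probe <- function(train, labels = NULL, config = probe_config(),
                      task_type = NULL, n_classes = NULL) {
  X <- probe_matrix(train)
  y <- probe_labels(train, labels)
  if (is.null(task_type)) {
    task_type <- if (is.matrix(y)) {
      "multilabel"
    } else if (length(unique(y)) <= 2L) "binary" else "multiclass"
  }
  set.seed(config$seed)
  if (task_type == "multilabel") {
    stopifnot(is.matrix(y))
    if (is.null(n_classes)) n_classes <- ncol(y)
    boosters <- lapply(seq_len(ncol(y)), function(j) {
      yj <- y[, j]
      if (length(unique(yj)) < 2L) {
        stop("training labels for label ", j - 1L,
             " contain a single class", call. = FALSE)
      }
      xgboost::xgb.train(
        params = xgb_params(config, "binary:logistic"),
        data = xgboost::xgb.DMatrix(X, label = yj),
        nrounds = config$n_estimators, verbose = 0
      )
    })
  } else {
    y <- as.integer(y)
    if (is.null(n_classes)) n_classes <- max(y) + 1L
    if (length(unique(y)) < 2L) {
      stop("training labels contain a single class (class ", unique(y), ")",
           call. = FALSE)
    }
    boosters <- if (task_type == "binary") {
      list(xgboost::xgb.train(
        params = xgb_params(config, "binary:logistic"),
        data = xgboost::xgb.DMatrix(X, label = y),
        nrounds = config$n_estimators, verbose = 0
      ))
    } else {
      list(xgboost::xgb.train(
        params = xgb_params(config, "multi:softprob",
                            num_class = n_classes),
        data = xgboost::xgb.DMatrix(X, label = y),
        nrounds = config$n_estimators, verbose = 0
      ))
    }
  }
  structure(
    list(boosters = boosters, task_type = task_type,
         n_classes = as.integer(n_classes), config = config,
         n_features = ncol(X)),
    class = "fitted_probe"
  )
}

#' Per-class probability scores from a fitted probe
#'
#' @param object A `fitted_probe`.
#' @param newdata Fused embeddings or matrix.
#' @param ... Unused.
#' @return Binary: vector of positive-class probabilities. Multi-class:
#'   `n x K` probability matrix. Multi-label: `n x L` matrix of per-label
#'   probabilities.
#' @export
predict.fitted_probe <- function(object, newdata, ...) {
  X <- probe_matrix(newdata)
  if (ncol(X) != object$n_features) {
    stop("probe was fitted on ", object$n_features, " features, got ",
         ncol(X), call. = FALSE)
  }
  dm <- xgboost::xgb.DMatrix(X)
  switch(
    object$task_type,
    binary = as.numeric(predict(object$boosters[[1L]], dm)),
    multiclass = {
      p <- predict(object$boosters[[1L]], dm)
      if (is.matrix(p)) p else matrix(p, ncol = object$n_classes, byrow = TRUE)
    },
    multilabel = do.call(cbind, lapply(object$boosters, function(b) {
      as.numeric(predict(b, dm))
    }))
  )
}

#' Hard class predictions from a fitted probe
#'
#' @inheritParams predict.fitted_probe
#' @param threshold Decision threshold for binary and multi-label scores.
#' @return Class indices (vector) or 0/1 matrix (multi-label).
#' @export
predict_class <- function(object, newdata, threshold = 0.5) {
  scores <- predict(object, newdata)
  switch(
    object$task_type,
    binary = as.integer(scores >= threshold),
    multiclass = max.col(scores, ties.method = "first") - 1L,
    multilabel = {
      m <- (scores >= threshold) * 1L
      dimnames(m) <- NULL
      m
    }
  )
}

probe_accuracy <- function(probe, data, labels) {
  classification_accuracy(predict_class(probe, data), labels)
}

#' Score a fitted probe on a split
#'
#' Reports accuracy and AUC-ROC. When `n_runs > 1` the probe is refitted
#' with `n_runs` consecutive seeds on `train` and the report carries the
#' per-seed values together with their mean (the reported `accuracy` and
#' `auc`).
#'
#' @param probe A `fitted_probe`.
#' @param data Fused embeddings (or matrix) for the evaluation split.
#' @param labels Evaluation labels; defaults to those carried by `data`.
#' @param n_runs Number of probe seeds to average over (default 1).
#' @param train Training embeddings, required when `n_runs > 1`.
#' @return An object of class `metric_report`: `accuracy`, `auc`,
#'   `per_class_auc` (multi-class only), `per_seed` (data frame) and
#'   `n_runs`.
#' @export
score_probe <- function(probe, data, labels = NULL, n_runs = 1L,
                        train = NULL) {
  y <- probe_labels(data, labels)
  one_run <- function(p) {
    scores <- predict(p, data)
    acc <- classification_accuracy(predict_class(p, data), y)
    auc <- auc_roc(scores, y, p$task_type)
    per_class <- if (p$task_type == "multiclass") {
      vapply(seq_len(p$n_classes) - 1L, function(k) {
        auc_binary(scores[, k + 1L], as.integer(y == k))
      }, 0)
    } else NULL
    list(accuracy = acc, auc = auc, per_class_auc = per_class)
  }
  if (n_runs <= 1L) {
    r <- one_run(probe)
    return(structure(
      list(accuracy = r$accuracy, auc = r$auc,
           per_class_auc = r$per_class_auc,
           per_seed = data.frame(seed = probe$config$seed,
                                 accuracy = r$accuracy, auc = r$auc),
           n_runs = 1L),
      class = "metric_report"
    ))
  }
  if (is.null(train)) {
    stop("run-averaging needs the training embeddings to refit the probe",
         call. = FALSE)
  }
  seeds <- probe$config$seed + seq_len(n_runs) - 1L
  runs <- lapply(seeds, function(s) {
    cfg <- probe$config
    cfg$seed <- s
    p <- fit_probe(train, config = cfg, task_type = probe$task_type,
                   n_classes = probe$n_classes)
    one_run(p)
  })
  per_seed <- data.frame(
    seed = seeds,
    accuracy = vapply(runs, `[[`, 0, "accuracy"),
    auc = vapply(runs, `[[`, 0, "auc")
  )
  structure(
    list(accuracy = mean(per_seed$accuracy), auc = mean(per_seed$auc),
         per_class_auc = NULL, per_seed = per_seed,
         n_runs = as.integer(n_runs)),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> accuracy %.4f, AUC %.4f (%d run%s)\n",
              x$accuracy, x$auc, x$n_runs, if (x$n_runs > 1) "s" else ""))
  invisible(x)
}

default_search_space <- function() {
  list(
    n_estimators = list(type = "int", lo = 50, hi = 1000),
    learning_rate = list(type = "lognum", lo = 0.01, hi = 0.3),
    max_depth = list(type = "int", lo = 3, hi = 10),
    min_child_weight = list(type = "num", lo = 1, hi = 10),
    subsample = list(type = "num", lo = 0.5, hi = 1),
    colsample_bytree = list(type = "num", lo = 0.5, hi = 1),
    gamma = list(type = "num", lo = 0, hi = 5),
    reg_alpha = list(type = "num", lo = 0, hi = 5),
    reg_lambda = list(type = "num", lo = 0, hi = 5)
  )
}

#' Tuner configuration
#'
#' The default search space covers nine boosting hyperparameters with
#' conventional ranges; the objective is validation accuracy.
#'
#' @param n_trials Trial budget (default 100). Trial 0 always evaluates
#'   the default [probe_config()], so the tuned result can never fall
#'   below the default configuration's validation accuracy.
#' @param search_space Named list of parameter ranges, each
#'   `list(type = "int"|"num"|"lognum", lo =, hi =)`.
#' @param sampler `"random"`: independent uniform draws (log-uniform for
#'   `"lognum"` entries).
#' @param seed Integer seed; tuning is reproducible from it.
#' @return An object of class `tuner_config`.
#' @export
tuner_config <- function(n_trials = 100L, search_space = default_search_space(),
                         sampler = "random", seed = 1L) {
  if (length(search_space) == 0L) {
    stop("empty hyperparameter search space", call. = FALSE)
  }
  structure(
    list(n_trials = as.integer(n_trials), search_space = search_space,
         sampler = match.arg(sampler, "random"), seed = as.integer(seed)),
    class = "tuner_config"
  )
}

sample_trial <- function(space) {
  vals <- lapply(space, function(par) {
    switch(par$type,
           int = as.integer(round(runif(1L, par$lo, par$hi))),
           num = runif(1L, par$lo, par$hi),
           lognum = exp(runif(1L, log(par$lo), log(par$hi))),
           stop("unknown search-space type '", par$type, "'", call. = FALSE))
  })
  setNames(vals, names(space))
}

#' Tune the probe on a validation split
#'
#' Samples `n_trials` configurations (trial 0 is always the default probe
#' configuration), fits each on the training embeddings, scores validation
#' accuracy, and returns the argmax configuration with the full trial log.
#'
#' @param train Training fused embeddings (with labels).
#' @param valid Validation fused embeddings (with labels).
#' @param tuner A [tuner_config()].
#' @param task_type,n_classes Optional task overrides, as in [fit_probe()].
#' @param log_path Optional CSV path for the trial log
#'   (`trial,params_json,valid_accuracy`).
#' @return A list with `best_config` (a [probe_config()]), `best_accuracy`
#'   and `trials` (data frame `trial`, `params_json`, `valid_accuracy`).
#' @export
tune_probe <- function(train, valid, tuner = tuner_config(),
                       task_type = NULL, n_classes = NULL,
                       log_path = NULL) {
  stopifnot(inherits(tuner, "tuner_config"), tuner$n_trials >= 1L)
  set.seed(tuner$seed)
  configs <- vector("list", tuner$n_trials)
  configs[[1L]] <- probe_config(seed = tuner$seed)  # trial 0: defaults
  if (tuner$n_trials > 1L) {
    for (i in seq.int(2L, tuner$n_trials)) {
      draw <- sample_trial(tuner$search_space)
      cfg <- probe_config(seed = tuner$seed)
      cfg[names(draw)] <- draw
      configs[[i]] <- cfg
    }
  }
  y_valid <- probe_labels(valid, NULL)
  acc <- vapply(configs, function(cfg) {
    p <- fit_probe(train, config = cfg, task_type = task_type,
                   n_classes = n_classes)
    probe_accuracy(p, valid, y_valid)
  }, 0)
  trials <- data.frame(
    trial = seq_along(configs) - 1L,
    params_json = vapply(configs, function(cfg) {
      jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
    }, ""),
    valid_accuracy = acc,
    stringsAsFactors = FALSE
  )
  if (!is.null(log_path)) write.csv(trials, log_path, row.names = FALSE)
  best <- which.max(acc)  # ties: earliest trial, so defaults win ties
  list(best_config = configs[[best]], best_accuracy = acc[best],
       trials = trials)
}
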