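#' Describe a hyperparameter search space
#'
#' Each entry is one tunable parameter: `param_int(low, high)`,
#' `param_float(low, high, log = FALSE)` or `param_choice(values)`.
#'
#' @param ... Named parameter descriptors.
#' @return A `search_space`.
#' @export
search_space <- function(...) {
  space <- list(...)
  if (length(space) == 0L || is.null(names(space)) || any(names(space) == "")) {
    stop_pathpair("search space must be a named, non-empty set of parameters",
                  "pathpair_validation_error")
  }
  structure(space, class = "search_space")
}

#' @rdname search_space
#' @param low,high Bounds (inclusive).
#' @export
param_int <- function(low, high) {
  structure(list(type = "int", low = low, high = high), class = "param_spec")
}

#' @rdname search_space
#' @param log Sample on a log scale.
#' @export
param_float <- function(low, high, log = FALSE) {
  structure(list(type = "float", low = low, high = high, log = log),
            class = "param_spec")
}

#' @rdname search_space
#' @param values Candidate values.
#' @export
param_choice <- function(values) {
  structure(list(type = "choice", values = values), class = "param_spec")
}

sample_params <- function(space) {
  lapply(space, function(p) {
    switch(p$type,
           int = sample(seq(p$low, p$high), 1L),
           float = if (isTRUE(p$log)) {
             exp(stats::runif(1, log(p$low), log(p$high)))
           } else {
             stats::runif(1, p$low, p$high)
           },
           choice = p$values[[sample.int(length(p$values), 1L)]])
  })
}

running_median <- function(x) stats::median(x)

#' Hyperparameter tuning with median-rule pruning
#'
#' Random-search trials: each trial samples one configuration from the
#' space, then runs up to `cv_per_trial` sequential CV iterations. After
#' each step the trial's running median MCC is compared to the median of
#' completed trials' running medians at the same step; a trial below that
#' bar (after `n_warmup_steps`, once `n_startup_trials` trials have
#' completed) is pruned — it stops early without finishing its CV budget.
#' The objective is the median MCC across a trial's iterations; the best
#' trial's parameters are returned.
#'
#' @param kind Backend, `"gbt"` or `"mlp"`.
#' @param space A [search_space()] over that backend's hyperparameters.
#' @param ds A `pair_dataset`.
#' @param n_trials Number of tuning trials (protocol default 100).
#' @param cv_per_trial CV iterations per trial (protocol default 20).
#' @param plan A [split_plan()] for the within-trial splits.
#' @param store Optional [results_store()]; trials are persisted with
#'   JSON-serialized parameters.
#' @param sampler_seed Seed for parameter sampling; the whole procedure is
#'   deterministic given it.
#' @param n_startup_trials,n_warmup_steps Pruner controls.
#' @return A `tune_result`: `best_params`, `best_median_mcc`, `trials`
#'   data.frame.
#' @export
tune <- function(kind, space, ds, n_trials = 100L, cv_per_trial = 20L,
                 plan = split_plan(), store = NULL, sampler_seed = 1L,
                 n_startup_trials = 5L, n_warmup_steps = 5L) {
  stopifnot(inherits(space, "search_space"))
  param_sets <- with_seed(sampler_seed, {
    lapply(seq_len(n_trials), function(i) sample_params(space))
  })
  trial_rows <- list()
  step_medians <- list()   # per completed trial: running median at each step
  best <- NULL
  for (t in seq_len(n_trials)) {
    params <- param_sets[[t]]
    spec <- classifier_spec(kind, params, seed = sampler_seed + t)
    mccs <- numeric(0)
    pruned <- FALSE
    for (s in seq_len(cv_per_trial)) {
      it_plan <- split_plan(plan$test_fraction, plan$seed + (t - 1L) * cv_per_trial + s)
      sp <- stratified_split(ds, it_plan)
      train <- oversample_positives(sp$train)
      clf <- train_classifier(classifier_spec(kind, params, seed = it_plan$seed),
                              train)
      pred <- predict(clf, sp$test)
      mccs <- c(mccs, compute_metrics(pred$label, sp$test$label)$mcc)
      if (s >= n_warmup_steps && length(step_medians) >= n_startup_trials) {
        bar <- stats::median(vapply(step_medians, function(v) {
          v[min(s, length(v))]
        }, numeric(1)))
        if (stats::median(mccs) < bar) { pruned <- TRUE; break }
      }
    }
    med <- stats::median(mccs)
    if (!pruned) {
      step_medians[[length(step_medians) + 1L]] <-
        vapply(seq_along(mccs), function(s) stats::median(mccs[seq_len(s)]),
               numeric(1))
    }
    trial_rows[[t]] <- data.frame(trial_id = t,
                                  params = as.character(jsonlite::toJSON(
                                    params, auto_unbox = TRUE)),
                                  median_mcc = med, pruned = pruned,
                                  stringsAsFactors = FALSE)
    if (!is.null(store)) record_result(store, "trials", trial_rows[[t]])
    if (!pruned && (is.null(best) || med > best$median_mcc)) {
      best <- list(params = params, median_mcc = med, trial_id = t)
    }
  }
  if (is.null(best)) {
    stop_pathpair("every trial was pruned; no completed configuration",
                  "pathpair_tuning_error")
  }
  structure(list(best_params = best$params,
                 best_median_mcc = best$median_mcc,
                 best_trial = best$trial_id,
                 trials = do.call(rbind, trial_rows)),
            class = "tune_result")
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("<tune_result> %d trials (%d pruned); best median MCC %.4f (trial %d)\n",
              nrow(x$trials), sum(x$trials$pruned), x$best_median_mcc,
              x$best_trial))
  cat("  best params:", as.character(jsonlite::toJSON(x$best_params,
                                                      auto_unbox = TRUE)), "\n")
  invisible(x)
}
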