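#' Monte-Carlo cross-validation of a pair classifier
#'
#' Repeats, for `n_iterations` independent iterations: a stratified
#' train/test split (iteration `i` uses seed `plan$seed + i`, so results
#' are invariant to execution order), positive oversampling of the training
#' set only, model fitting, prediction on the untouched test set, and
#' metric computation — overall and per-pathway MCC (test rows grouped by
#' pathway category). A failing iteration is recorded and the remaining
#' iterations continue.
#'
#' @param spec A [classifier_spec()].
#' @param ds A `pair_dataset`.
#' @param n_iterations Number of CV iterations (>= 1).
#' @param plan A [split_plan()]; its seed is the base seed.
#' @param store Optional [results_store()]; when given, every metric is
#'   persisted to `cv_results` (and, for the gbt backend with
#'   `importance = TRUE`, raw/relative importances to `importance`).
#' @param feature_set Tag stored with results, e.g. `"non-encoded"`.
#' @param importance If `TRUE` and the backend is gbt, collect per-iteration
#'   raw gain importances.
#' @return A `cv_result`: list with per-iteration `metrics` (overall
#'   [compute_metrics()] output), `per_pathway` MCC maps, optional
#'   `importance` raw-score list, and `errors`.
#' @export
run_cv <- function(spec, ds, n_iterations, plan, store = NULL,
                   feature_set = "non-encoded", importance = FALSE) {
  stopifnot(n_iterations >= 1L)
  path_ids <- entry_ids(ds$pathways)
  metrics <- vector("list", n_iterations)
  per_pathway <- vector("list", n_iterations)
  imp_list <- if (importance && spec$kind == "gbt") vector("list", n_iterations)
  errors <- list()
  for (i in seq_len(n_iterations)) {
    res <- tryCatch({
      sp <- stratified_split(ds, split_plan(plan$test_fraction, plan$seed + i))
      train <- oversample_positives(sp$train)
      it_spec <- classifier_spec(spec$kind, spec$params, seed = spec$seed + i)
      clf <- train_classifier(it_spec, train)
      pred <- predict(clf, sp$test)
      overall <- compute_metrics(pred$label, sp$test$label)
      by_path <- vapply(seq_along(path_ids), function(j) {
        rows <- which(sp$test$path_idx == j)
        compute_metrics(pred$label[rows], sp$test$label[rows])$mcc
      }, numeric(1))
      names(by_path) <- path_ids
      imp <- if (!is.null(imp_list)) raw_feature_importance(clf)
      list(overall = overall, by_path = by_path, imp = imp)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- list(iteration = i,
                                            message = conditionMessage(res))
      next
    }
    metrics[[i]] <- res$overall
    per_pathway[[i]] <- res$by_path
    if (!is.null(imp_list)) imp_list[[i]] <- res$imp
    if (!is.null(store)) {
      for (mn in names(res$overall)) {
        record_result(store, "cv_results",
                      list(model_kind = spec$kind, feature_set = feature_set,
                           iteration = i, pathway = "overall",
                           metric_name = mn, value = res$overall[[mn]]))
      }
      record_result(store, "cv_results",
                    data.frame(model_kind = spec$kind, feature_set = feature_set,
                               iteration = i, pathway = path_ids,
                               metric_name = "mcc", value = res$by_path,
                               stringsAsFactors = FALSE))
      if (!is.null(imp_list)) {
        raw <- res$imp
        nz <- raw[raw > 0]
        rel <- if (length(nz)) exp(nz - max(nz)) / sum(exp(nz - max(nz))) else numeric()
        if (length(nz)) {
          record_result(store, "importance",
                        data.frame(feature_name = names(nz),
                                   entity_kind = sub("::.*$", "", names(nz)),
                                   iteration = i, raw_score = as.numeric(nz),
                                   relative_score = as.numeric(rel),
                                   stringsAsFactors = FALSE))
        }
      }
    }
  }
  structure(list(spec = spec, feature_set = feature_set, metrics = metrics,
                 per_pathway = per_pathway, importance = imp_list,
                 errors = errors, n_iterations = n_iterations),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  done <- !vapply(x$metrics, is.null, logical(1))
  mccs <- vapply(x$metrics[done], function(m) m$mcc, numeric(1))
  cat(sprintf("<cv_result> %s on %s features: %d/%d iterations completed\n",
              x$spec$kind, x$feature_set, sum(done), x$n_iterations))
  if (length(mccs)) {
    cat(sprintf("  test MCC: mean %.4f, sd %.4f, median %.4f\n",
                mean(mccs), stats::sd(mccs), stats::median(mccs)))
  }
  if (length(x$errors)) cat(sprintf("  %d failed iteration(s)\n", length(x$errors)))
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) {
  print(object)
  done <- !vapply(object$per_pathway, is.null, logical(1))
  if (any(done)) {
    pp <- do.call(rbind, object$per_pathway[done])
    cat("  per-pathway MCC (mean +/- sd):\n")
    for (p in colnames(pp)) {
      cat(sprintf("    %-45s %.4f +/- %.4f\n", p, mean(pp[, p]),
                  stats::sd(pp[, p])))
    }
  }
  invisible(object)
}

#' Mean and spread of the overall test MCC across CV iterations
#' @param cv A `cv_result`.
#' @return Named numeric vector with `mean`, `sd`, `median`, `n`.
#' @export
cv_mcc <- function(cv) {
  done <- !vapply(cv$metrics, is.null, logical(1))
  mccs <- vapply(cv$metrics[done], function(m) m$mcc, numeric(1))
  c(mean = mean(mccs), sd = stats::sd(mccs), median = stats::median(mccs),
    n = length(mccs))
}
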