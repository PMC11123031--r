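#' Create an empty results store
#'
#' A queryable store for everything the evaluation protocol produces:
#' per-iteration CV metrics, per-iteration feature importances, and
#' hyperparameter-tuning trials. It holds three tables with enforced
#' uniqueness keys and persists to a directory of CSV files, so results can
#' be summarized downstream without re-running any model.
#'
#' Tables:
#' \describe{
#'   \item{cv_results}{`model_kind, feature_set, iteration, pathway,
#'     metric_name, value` — unique on all of the first five. `pathway` is
#'     `"overall"` for whole-test-set metrics.}
#'   \item{importance}{`feature_name, entity_kind, iteration, raw_score,
#'     relative_score` with `relative_score` in \[0, 1\].}
#'   \item{trials}{`trial_id, params` (JSON-serialized), `median_mcc`,
#'     `pruned` flag.}
#' }
#'
#' @return A `results_store` (an environment holding the three tables).
#' @export
results_store <- function() {
  e <- new.env(parent = emptyenv())
  e$cv_results <- data.frame(model_kind = character(), feature_set = character(),
                             iteration = integer(), pathway = character(),
                             metric_name = character(), value = double(),
                             stringsAsFactors = FALSE)
  e$importance <- data.frame(feature_name = character(), entity_kind = character(),
                             iteration = integer(), raw_score = double(),
                             relative_score = double(), stringsAsFactors = FALSE)
  e$trials <- data.frame(trial_id = integer(), params = character(),
                         median_mcc = double(), pruned = logical(),
                         stringsAsFactors = FALSE)
  class(e) <- "results_store"
  e
}

#' @export
print.results_store <- function(x, ...) {
  cat(sprintf("<results_store> cv_results: %d rows; importance: %d rows; trials: %d rows\n",
              nrow(x$cv_results), nrow(x$importance), nrow(x$trials)))
  invisible(x)
}

store_key <- function(df) {
  do.call(paste, c(df[c("model_kind", "feature_set", "iteration",
                        "pathway", "metric_name")], sep = "\r"))
}

#' Persist a record in a results store
#'
#' @param store A [results_store()].
#' @param table One of `"cv_results"`, `"importance"`, `"trials"`.
#' @param record A one-row list/data.frame matching the table's schema.
#' @return Invisibly, the store.
#' @export
record_result <- function(store, table = c("cv_results", "importance", "trials"),
                          record) {
  table <- match.arg(table)
  stopifnot(inherits(store, "results_store"))
  record <- as.data.frame(record, stringsAsFactors = FALSE)
  need <- names(store[[table]])
  if (!all(need %in% names(record))) {
    stop_pathpair(sprintf("record for `%s` must have columns: %s",
                          table, paste(need, collapse = ", ")),
                  "pathpair_schema_error")
  }
  record <- record[need]
  if (table == "cv_results" && nrow(store$cv_results) > 0L) {
    if (any(store_key(record) %in% store_key(store$cv_results))) {
      stop_pathpair("duplicate (model_kind, feature_set, iteration, pathway, metric_name) key",
                    "pathpair_constraint_error")
    }
  }
  if (table == "importance" &&
      any(record$relative_score < 0 | record$relative_score > 1)) {
    stop_pathpair("relative_score must lie in [0, 1]", "pathpair_constraint_error")
  }
  store[[table]] <- rbind(store[[table]], record)
  invisible(store)
}

#' Summarize stored CV metrics
#'
#' Mean and standard deviation of a metric grouped by model, feature set and
#' pathway — the shape of a per-pathway performance report.
#'
#' @param store A [results_store()].
#' @param metric Metric name to summarize (default `"mcc"`).
#' @return A data.frame with columns `model_kind`, `feature_set`, `pathway`,
#'   `n`, `mean`, `sd`.
#' @export
store_summary <- function(store, metric = "mcc") {
  df <- store$cv_results[store$cv_results$metric_name == metric, , drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(model_kind = character(), feature_set = character(),
                      pathway = character(), n = integer(),
                      mean = double(), sd = double()))
  }
  agg <- stats::aggregate(value ~ model_kind + feature_set + pathway, df,
                          function(v) c(n = length(v), mean = mean(v),
                                        sd = stats::sd(v)))
  out <- cbind(agg[c("model_kind", "feature_set", "pathway")],
               as.data.frame(agg$value))
  out$n <- as.integer(out$n)
  out[order(out$model_kind, out$feature_set, out$pathway), , drop = FALSE]
}

#' Save / load a results store as a directory of CSV files
#'
#' @param store A [results_store()].
#' @param dir Directory path (created if needed).
#' @return `store_save` invisibly returns `dir`; `store_load` returns the
#'   reconstructed store.
#' @export
store_save <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in c("cv_results", "importance", "trials")) {
    utils::write.csv(store[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname store_save
#' @export
store_load <- function(dir) {
  store <- results_store()
  for (tb in c("cv_results", "importance", "trials")) {
    f <- file.path(dir, paste0(tb, ".csv"))
    if (file.exists(f)) {
      df <- utils::read.csv(f, stringsAsFactors = FALSE)
      if (nrow(df)) store[[tb]] <- df[names(store[[tb]])]
    }
  }
  store
}
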