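#' Specify a classifier backend
#'
#' One uniform contract over the two backends: gradient-boosted trees
#' (`"gbt"`, via xgboost) and a multilayer perceptron (`"mlp"`, a dense
#' network with ReLU hidden layers, sigmoid output, binary cross-entropy
#' on mini-batches and early stopping). Unspecified hyperparameters take
#' the defaults below — midpoints of the tuning search space.
#'
#' @param kind `"gbt"` or `"mlp"`.
#' @param params Named list of hyperparameters. gbt: `nrounds`, `max_depth`,
#'   `eta`, `subsample`, `colsample_bytree`, `min_child_weight`. mlp:
#'   `hidden` (integer vector of layer widths), `dropout`, `learning_rate`,
#'   `batch_size`, `epochs`, `patience`.
#' @param seed Integer seed; training is deterministic given it (single
#'   thread for gbt).
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("gbt", "mlp"), params = list(), seed = 1L) {
  kind <- match.arg(kind)
  defaults <- if (kind == "gbt") {
    list(nrounds = 100L, max_depth = 6L, eta = 0.1, subsample = 0.9,
         colsample_bytree = 0.9, min_child_weight = 1)
  } else {
    list(hidden = c(64L, 32L), dropout = 0, learning_rate = 5e-3,
         batch_size = 64L, epochs = 60L, patience = 8L)
  }
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop_pathpair(sprintf("unknown %s hyperparameter(s): %s", kind,
                          paste(unknown, collapse = ", ")),
                  "pathpair_validation_error")
  }
  defaults[names(params)] <- params
  structure(list(kind = kind, params = defaults, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train a metabolite-pathway pair classifier
#'
#' Fits the backend named by `spec` on the (typically oversampled)
#' training pairs. Class balancing is handled upstream by
#' [oversample_positives()], so neither backend re-weights its loss.
#'
#' @param spec A [classifier_spec()].
#' @param train A `pair_dataset` with both classes present.
#' @return A `pair_classifier` with `predict`, `print`, `summary` and
#'   [raw_feature_importance()] methods.
#' @export
train_classifier <- function(spec, train) {
  stopifnot(inherits(spec, "classifier_spec"), inherits(train, "pair_dataset"))
  if (length(train$label) == 0L) {
    stop_pathpair("empty training set", "pathpair_balance_error")
  }
  if (length(unique(train$label)) < 2L) {
    stop_pathpair("training set must contain both classes",
                  "pathpair_balance_error")
  }
  X <- pair_features(train)
  y <- train$label
  fitted <- if (spec$kind == "gbt") {
    p <- spec$params
    dtrain <- xgboost::xgb.DMatrix(X, label = y)
    with_seed(spec$seed,
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = p$max_depth, eta = p$eta,
                      subsample = p$subsample,
                      colsample_bytree = p$colsample_bytree,
                      min_child_weight = p$min_child_weight,
                      nthread = 1L, seed = spec$seed),
        data = dtrain, nrounds = p$nrounds, verbose = 0))
  } else {
    p <- spec$params
    nn_train(X, matrix(y, ncol = 1), hidden = p$hidden,
             activations_hidden = "relu", activation_out = "sigmoid",
             loss = "bce", epochs = p$epochs, batch_size = p$batch_size,
             learning_rate = p$learning_rate, dropout = p$dropout,
             val_fraction = 0.1, patience = p$patience, seed = spec$seed)
  }
  structure(list(kind = spec$kind, spec = spec, fit = fitted,
                 feature_names = train$feature_names,
                 n_train = length(y), n_pos = sum(y)),
            class = "pair_classifier")
}

#' @export
print.pair_classifier <- function(x, ...) {
  cat(sprintf("<pair_classifier> backend: %s; trained on %d pairs (%d positive)\n",
              x$kind, x$n_train, x$n_pos))
  cat(sprintf("  feature width: %d\n", length(x$feature_names)))
  invisible(x)
}

#' @export
summary.pair_classifier <- function(object, ...) {
  print(object)
  cat("  hyperparameters:\n")
  for (nm in names(object$spec$params)) {
    cat(sprintf("    %s = %s\n", nm,
                paste(object$spec$params[[nm]], collapse = ",")))
  }
  invisible(object)
}

#' Predict involvement scores and labels for pair rows
#'
#' @param object A `pair_classifier`.
#' @param newdata A `pair_dataset` (or numeric matrix) whose feature width
#'   and ordering match the training snapshot.
#' @param ... Unused.
#' @return A data.frame with `score` in \[0, 1\] and `label` in \{0, 1\}
#'   (`score >= 0.5`), one row per input row in input order.
#' @export
predict.pair_classifier <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "pair_dataset")) pair_features(newdata) else newdata
  if (ncol(X) != length(object$feature_names) ||
      (!is.null(colnames(X)) && !identical(colnames(X), object$feature_names))) {
    stop_pathpair("prediction input width/ordering does not match the training snapshot",
                  "pathpair_shape_error")
  }
  if (nrow(X) == 0L) {
    return(data.frame(score = double(), label = integer()))
  }
  score <- if (object$kind == "gbt") {
    as.numeric(predict(object$fit, xgboost::xgb.DMatrix(X)))
  } else {
    as.numeric(nn_predict(object$fit, X))
  }
  data.frame(score = score, label = as.integer(score >= 0.5))
}

#' Gain-based raw feature importance of a tree classifier
#'
#' Total loss reduction ("gain") contributed by splits on each feature,
#' defined only for the tree backend: a dense network has no per-feature
#' split gain. Features never used by any split score 0; every training
#' feature is present in the result exactly once.
#'
#' @param clf A `pair_classifier` with `kind == "gbt"`.
#' @return A named numeric vector of non-negative scores covering every
#'   training feature.
#' @export
raw_feature_importance <- function(clf) {
  stopifnot(inherits(clf, "pair_classifier"))
  if (clf$kind != "gbt") {
    stop_pathpair("feature importance is defined only for the gbt backend",
                  "pathpair_unsupported_model_error")
  }
  out <- stats::setNames(numeric(length(clf$feature_names)), clf$feature_names)
  imp <- tryCatch(xgboost::xgb.importance(model = clf$fit),
                  error = function(e) NULL)
  if (!is.null(imp) && nrow(imp)) {
    out[imp$Feature] <- imp$Gain
  }
  out
}
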