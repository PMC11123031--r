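#' Specify an autoencoder for feature compression
#'
#' The encoder compresses each feature vector to `floor(ratio * width)`
#' embedded features (one-tenth the width at the default ratio). The
#' architecture is a symmetric fully connected autoencoder with a single
#' nonlinear (sigmoid) encoding layer and a linear reconstruction layer,
#' trained with mean-squared-error loss on mini-batches, with early
#' stopping on a held-out fraction of rows.
#'
#' @param input_width Number of input features.
#' @param ratio Compression ratio in (0, 1); encoded width is
#'   `floor(ratio * input_width)` and must be >= 1. Default 0.1.
#' @param epochs,learning_rate,batch_size,patience Training controls.
#' @param val_fraction Fraction of rows held out for early stopping.
#' @param seed Integer seed; training is deterministic given it.
#' @return An `encoder_spec`.
#' @export
encoder_spec <- function(input_width, ratio = 0.1, epochs = 200L,
                         learning_rate = 1e-3, batch_size = 32L,
                         patience = 20L, val_fraction = 0.1, seed = 1L) {
  stopifnot(input_width >= 1, ratio > 0, ratio < 1)
  encoded <- floor(ratio * input_width)
  if (encoded < 1L) {
    stop_pathpair("encoded width floor(ratio * input_width) must be >= 1",
                  "pathpair_validation_error")
  }
  structure(list(input_width = as.integer(input_width), ratio = ratio,
                 encoded_width = as.integer(encoded),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "encoder_spec")
}

#' Encoded width implied by an input width and compression ratio
#'
#' @param input_width Number of input features.
#' @param ratio Compression ratio (default 0.1).
#' @return `floor(ratio * input_width)` as an integer.
#' @export
encoded_width <- function(input_width, ratio = 0.1) {
  as.integer(floor(ratio * input_width))
}

#' Train the autoencoder on combined metabolite and pathway rows
#'
#' Both matrices must share the identical (full, non-de-duplicated) column
#' set: the autoencoder expects its input to always be the same size, which
#' is why pathway features are de-duplicated only on the branch that feeds
#' the classifier directly. Rows are concatenated, min-max scaled per
#' column (the fitted `pre_ranges` are kept for later inputs), and the
#' network is fit to reconstruct its input. A second min-max scaling is
#' fit on the encoded training rows (`post_ranges`) so that final encoded
#' features lie in \[0, 1\].
#'
#' @param metabolites,pathways_full [feature_matrix()] objects with
#'   identical column names in identical order.
#' @param spec An [encoder_spec()]; its `input_width` must match.
#' @return A `trained_encoder`.
#' @export
train_autoencoder <- function(metabolites, pathways_full, spec) {
  stopifnot(inherits(metabolites, "feature_matrix"),
            inherits(pathways_full, "feature_matrix"),
            inherits(spec, "encoder_spec"))
  if (!identical(feature_names(metabolites), feature_names(pathways_full))) {
    stop_pathpair("metabolite and pathway matrices must share an identical column set",
                  "pathpair_shape_error")
  }
  if (ncol(metabolites$values) != spec$input_width) {
    stop_pathpair("spec input_width does not match the matrices",
                  "pathpair_shape_error")
  }
  combined <- rbind(metabolites$values, pathways_full$values)
  rownames(combined) <- make.unique(c(entry_ids(metabolites),
                                      entry_ids(pathways_full)))
  comb_fm <- feature_matrix(combined, metabolites$bond_level, "metabolite")
  scaled <- min_max_scale(comb_fm)
  X <- scaled$matrix$values
  fit <- nn_train(X, X, hidden = spec$encoded_width,
                  activations_hidden = "sigmoid", activation_out = "linear",
                  loss = "mse", epochs = spec$epochs,
                  batch_size = spec$batch_size,
                  learning_rate = spec$learning_rate,
                  val_fraction = spec$val_fraction, patience = spec$patience,
                  seed = spec$seed)
  enc_raw <- nn_predict(fit, X, upto_layer = 1L)
  colnames(enc_raw) <- paste0("enc_", seq_len(ncol(enc_raw)) - 1L)
  rownames(enc_raw) <- rownames(X)
  enc_fm <- feature_matrix(enc_raw, rep(0L, ncol(enc_raw)), "metabolite")
  post <- min_max_scale(enc_fm)
  structure(list(fit = fit, spec = spec,
                 columns = feature_names(metabolites),
                 pre_ranges = scaled$ranges, post_ranges = post$ranges,
                 history = fit$history),
            class = "trained_encoder")
}

#' @export
print.trained_encoder <- function(x, ...) {
  cat(sprintf("<trained_encoder> %d -> %d features (ratio %.3g), %d epochs trained\n",
              x$spec$input_width, x$spec$encoded_width, x$spec$ratio,
              length(x$history)))
  cat(sprintf("  reconstruction MSE: epoch 1 = %.4g, final = %.4g\n",
              x$history[1], x$history[length(x$history)]))
  invisible(x)
}

#' Encode a feature matrix with a trained autoencoder
#'
#' Applies the fitted pre-scaling (with clipping), the encoding layer, and
#' the fitted post-scaling (with clipping). Encoded features are named
#' `enc_0 .. enc_{k-1}`, carry bond level 0 as a placeholder, and are never
#' re-normalized downstream (proportion normalization applies to raw counts
#' only).
#'
#' @param enc A `trained_encoder`.
#' @param m A [feature_matrix()] whose columns match the training columns.
#' @return A [feature_matrix()] of shape `nrow(m) x encoded_width` with
#'   values in \[0, 1\] and the input's `entity_kind`.
#' @export
encode <- function(enc, m) {
  stopifnot(inherits(enc, "trained_encoder"), inherits(m, "feature_matrix"))
  if (!identical(feature_names(m), enc$columns)) {
    stop_pathpair("matrix columns do not match the encoder's training columns",
                  "pathpair_shape_error")
  }
  pre <- min_max_scale(m, enc$pre_ranges)
  Z <- nn_predict(enc$fit, pre$matrix$values, upto_layer = 1L)
  colnames(Z) <- paste0("enc_", seq_len(ncol(Z)) - 1L)
  rownames(Z) <- entry_ids(m)
  zfm <- feature_matrix(Z, rep(0L, ncol(Z)), m$entity_kind)
  min_max_scale(zfm, enc$post_ranges)$matrix
}
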