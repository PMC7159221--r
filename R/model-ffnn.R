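#' Fit the feed-forward network risk model
#'
#' Two fully-connected hidden layers (relu; widths 1024 and 256 by
#' default), a dropout layer (rate 0.3), and a 2-unit softmax output
#' trained with categorical cross-entropy and the ADAM optimizer at a
#' conservative learning rate of 0.0002, with early stopping on
#' validation loss. Dropout is disabled at inference so prediction is
#' deterministic.
#'
#' @param features Sparse feature matrix, records in rows
#'   ([build_code_features()]).
#' @param labels Binary outcome vector.
#' @param val_features,val_labels Validation split for early stopping.
#' @param hidden Two hidden-layer widths.
#' @param dropout Dropout rate after the second hidden layer.
#' @param learning_rate ADAM step size.
#' @param batch_size Minibatch size.
#' @param max_epochs,patience Early-stopping schedule.
#' @param seed Seed for initialization, batch order and dropout.
#' @return A `readmit_ffnn` model.
#' @export
fit_ffnn <- function(features, labels, val_features, val_labels,
                     hidden = c(1024, 256), dropout = 0.3,
                     learning_rate = 2e-4, batch_size = 256,
                     max_epochs = 50, patience = 5, seed = 1L) {
  n <- nrow(features)
  ord <- with_seed(derive_seed(seed, 11L), sample.int(n))
  fit <- mlp_fit_cpp(
    Matrix::t(features[ord, , drop = FALSE]), as.integer(labels)[ord],
    Matrix::t(val_features), as.integer(val_labels),
    as.integer(hidden[1]), as.integer(hidden[2]), dropout, learning_rate,
    as.integer(batch_size), as.integer(max_epochs), as.integer(patience),
    as.integer(seed)
  )
  structure(
    list(kind = "FFNN", weights = fit[c("W1", "b1", "W2", "b2", "W3", "b3")],
         train_loss = fit$train_loss, val_loss = fit$val_loss,
         best_epoch = fit$best_epoch,
         feature_names = colnames(features), hidden = hidden,
         dropout = dropout, seed = seed),
    class = c("readmit_ffnn", "readmit_model")
  )
}

#' @rdname predict.readmit_hlr
#' @export
predict.readmit_ffnn <- function(object, features, ...) {
  w <- object$weights
  p <- mlp_predict_cpp(Matrix::t(features), w$W1, w$b1, w$W2, w$b2,
                       w$W3, w$b3)
  clamp_prob(as.numeric(p))
}

#' @export
print.readmit_ffnn <- function(x, ...) {
  cat(sprintf(
    "<readmit_ffnn> %d features, hidden %s, best epoch %d\n",
    length(x$feature_names), paste(x$hidden, collapse = "->"), x$best_epoch
  ))
  invisible(x)
}
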