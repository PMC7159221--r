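#' Fit the gradient-boosted tree risk model
#'
#' XGBoost on binary code indicators (1 if the code is present, 0 if
#' absent) plus age and sex, with a deliberately conservative learning
#' rate (0.0002) and the number of boosting rounds chosen by early
#' stopping on validation log-loss. With such a small learning rate many
#' rounds are required; cap `n_rounds` to the compute available.
#'
#' @param features Sparse feature matrix ([build_code_features()]).
#' @param labels Binary outcome vector.
#' @param val_features,val_labels Validation split for early stopping.
#' @param learning_rate Boosting learning rate (default 0.0002).
#' @param n_rounds Maximum boosting rounds (default 20000; scale down
#'   for desk-scale runs). `0` returns a constant base-rate predictor.
#' @param early_stopping_rounds Stop when validation loss has not
#'   improved for this many rounds (default 100).
#' @param max_depth Tree depth (default 6).
#' @param seed Seed for the boosting RNG.
#' @return A `readmit_gbt` model.
#' @export
fit_gbt <- function(features, labels, val_features = NULL, val_labels = NULL,
                    learning_rate = 0.0002, n_rounds = 20000,
                    early_stopping_rounds = 100, max_depth = 6, seed = 1L) {
  if (is.null(dim(features)) || ncol(features) == 0L) {
    abort("`features` must be a non-empty matrix.",
          class = "readmitr_invalid_input")
  }
  base_rate <- mean(labels)
  if (n_rounds == 0L) {
    return(structure(
      list(kind = "GBT", booster = NULL, base_rate = base_rate,
           feature_names = colnames(features), best_iteration = 0L),
      class = c("readmit_gbt", "readmit_model")
    ))
  }
  dtrain <- xgboost::xgb.DMatrix(features, label = labels, nthread = 1)
  evals <- list()
  if (!is.null(val_features)) {
    evals <- list(val = xgboost::xgb.DMatrix(val_features, label = val_labels,
                                             nthread = 1))
  }
  booster <- xgboost::xgb.train(
    params = xgboost::xgb.params(
      objective = "binary:logistic", eta = learning_rate,
      max_depth = max_depth, tree_method = "hist",
      eval_metric = "logloss", nthread = 1, seed = seed
    ),
    data = dtrain, nrounds = n_rounds, evals = evals,
    early_stopping_rounds = if (length(evals)) early_stopping_rounds else NULL,
    verbose = 0
  )
  structure(
    list(kind = "GBT", booster = booster, base_rate = base_rate,
         feature_names = colnames(features),
         best_iteration = xgboost::xgb.attr(booster, "best_iteration")),
    class = c("readmit_gbt", "readmit_model")
  )
}

#' @rdname predict.readmit_hlr
#' @export
predict.readmit_gbt <- function(object, features, ...) {
  if (is.null(object$booster)) {
    return(clamp_prob(rep(object$base_rate, nrow(features))))
  }
  p <- predict(object$booster, xgboost::xgb.DMatrix(features, nthread = 1))
  clamp_prob(p)
}

#' @export
print.readmit_gbt <- function(x, ...) {
  cat(sprintf("<readmit_gbt> %d features, best iteration %s\n",
              length(x$feature_names),
              x$best_iteration %||% "none"))
  invisible(x)
}
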