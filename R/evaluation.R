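#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) pairs
#' in which the positive scores higher, with ties counted half.
#'
#' @param labels Binary outcome vector (both classes must be present).
#' @param scores Numeric risk scores.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' compute_auc(c(1, 0, 0, 1), c(0.9, 0.8, 0.3, 0.4))
compute_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("AUC undefined: both outcome classes must be present.",
          class = "readmitr_undefined_metric")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# hospital-stratified fold assignment (used by cv_auc_ci)
assign_folds <- function(hospital_ids, k, seed) {
  fold <- integer(length(hospital_ids))
  with_seed(derive_seed(seed, 21L), {
    for (h in unique(hospital_ids)) {
      idx <- which(hospital_ids == h)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(sample.int(k), length(idx))
    }
  })
  fold
}

#' Cross-validated AUC with a normal-theory confidence interval
#'
#' Splits the cohort into `k` hospital-stratified folds; each fold is
#' held out once while the model is refitted on the remainder and
#' scored on the held-out fold. The interval is
#' `mean +/- 1.96 * sd(folds) / sqrt(k)`. Folds that end up
#' single-class are skipped with a warning and `k` reduced in the
#' result.
#'
#' @param records Cohort records tibble (needs `hospital_id` and the
#'   outcome used by `trainer`).
#' @param trainer `function(train_records)` returning a fitted model.
#' @param scorer `function(model, test_records)` returning risk scores.
#' @param outcome Column name of the binary outcome (default
#'   `"unplanned_readmit"`).
#' @param k Number of folds (default 10).
#' @param seed Fold assignment seed.
#' @return An `auc_result`: list with `auc`, `ci_low`, `ci_high`,
#'   `per_fold`, `n_folds`.
#' @export
cv_auc_ci <- function(records, trainer, scorer,
                      outcome = "unplanned_readmit", k = 10, seed = 1L) {
  fold <- assign_folds(records$hospital_id, k, seed)
  per_fold <- numeric(0)
  for (f in seq_len(k)) {
    test <- records[fold == f, , drop = FALSE]
    train <- records[fold != f, , drop = FALSE]
    y <- test[[outcome]]
    if (length(unique(y)) < 2L) {
      warn(sprintf("fold %d has a single outcome class; skipped.", f))
      next
    }
    model <- trainer(train)
    per_fold <- c(per_fold, compute_auc(y, scorer(model, test)))
  }
  kk <- length(per_fold)
  m <- mean(per_fold)
  half <- if (kk > 1) 1.96 * sd(per_fold) / sqrt(kk) else 0
  structure(
    list(auc = m, ci_low = m - half, ci_high = m + half,
         per_fold = per_fold, n_folds = kk),
    class = "auc_result"
  )
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f, %.3f) from %d folds\n",
              x$auc, x$ci_low, x$ci_high, x$n_folds))
  invisible(x)
}

#' @rdname tidy.readmit_hlr
#' @export
tidy.auc_result <- function(x, ...) {
  tibble(fold = seq_along(x$per_fold), auc = x$per_fold)
}

#' @rdname tidy.readmit_hlr
#' @export
glance.auc_result <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
         n_folds = x$n_folds)
}
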