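#' Risk-standardized hospital rates by predictive margins
#'
#' The predictive margin of hospital h is the average predicted
#' readmission probability if every record in the cohort had been
#' admitted to hospital h (the model's hospital effect is forced to h
#' for all records). Only models with an explicit hospital effect
#' support this (hierarchical logistic regression, deep-set).
#'
#' @param model A fitted `readmit_hlr` or `readmit_deepset` model.
#' @param features Cohort features in the model's input format.
#' @param hospital_ids Hospitals to standardize (default: all hospitals
#'   known to the model).
#' @return An RSRR tibble: `hospital_id`, `rsrr`, `method`,
#'   `model_kind`.
#' @export
predictive_margin_rsrr <- function(model, features, hospital_ids = NULL) {
  UseMethod("predictive_margin_rsrr")
}

#' @export
predictive_margin_rsrr.default <- function(model, features,
                                           hospital_ids = NULL) {
  abort(sprintf(
    "model kind '%s' has no hospital effect; predictive margins are undefined.",
    model$kind %||% class(model)[1]
  ), class = "readmitr_unsupported_model")
}

#' @export
predictive_margin_rsrr.readmit_hlr <- function(model, features,
                                               hospital_ids = NULL) {
  hospital_ids <- hospital_ids %||% names(model$u)
  eta0 <- hlr_base_eta(model, features)
  rsrr <- vapply(hospital_ids, function(h) {
    mean(plogis(eta0 + model$u[[h]]))
  }, numeric(1))
  tibble(hospital_id = hospital_ids, rsrr = unname(rsrr),
         method = "predictive_margin", model_kind = model$kind)
}

#' @export
predictive_margin_rsrr.readmit_deepset <- function(model, features,
                                                   hospital_ids = NULL) {
  hospital_ids <- hospital_ids %||% model$hospital_levels
  eh <- model$eh[hospital_ids]
  rsrr <- deepset_margins_cpp(
    model$par, model$Edx, model$Eproc, features$Adx, features$Aproc,
    features$prin, features$hosp, features$age_z, features$female,
    as.numeric(eh)
  )
  tibble(hospital_id = hospital_ids, rsrr = as.numeric(rsrr),
         method = "predictive_margin", model_kind = model$kind)
}

#' Risk-standardized rates by the predicted-over-expected ratio
#'
#' The CMS-style standardization for the hierarchical model: for each
#' hospital, the mean prediction over its own records including its
#' random intercept (predicted), divided by the mean population-average
#' prediction over the same records (expected, u = 0), multiplied by
#' the overall unadjusted cohort readmission rate.
#'
#' @param model A fitted `readmit_hlr`.
#' @param features Cohort feature matrix.
#' @param hospital_ids Hospital of each cohort record.
#' @param labels Observed outcomes (for the unadjusted rate).
#' @return An RSRR tibble (`method = "predicted_over_expected"`).
#' @export
ratio_rsrr <- function(model, features, hospital_ids, labels) {
  if (!inherits(model, "readmit_hlr")) {
    abort("`ratio_rsrr()` is defined for hierarchical logistic models.",
          class = "readmitr_unsupported_model")
  }
  eta0 <- hlr_base_eta(model, features)
  overall <- mean(labels)
  hs <- intersect(names(model$u), unique(as.character(hospital_ids)))
  dropped <- setdiff(names(model$u), hs)
  if (length(dropped) > 0) {
    warn(sprintf("%d hospitals with no cohort records excluded.",
                 length(dropped)))
  }
  rsrr <- vapply(hs, function(h) {
    idx <- which(hospital_ids == h)
    predicted <- mean(plogis(eta0[idx] + model$u[[h]]))
    expected <- mean(plogis(eta0[idx]))
    (predicted / expected) * overall
  }, numeric(1))
  tibble(hospital_id = hs, rsrr = unname(rsrr),
         method = "predicted_over_expected", model_kind = model$kind)
}

#' Assign 20/60/20 performance groups
#'
#' Hospitals are ranked by risk-standardized rate (highest first by
#' default, so the "top 20%" are the hospitals with the highest
#' readmission rates); the top and bottom groups each take
#' `floor(0.2 N)` hospitals and the middle the remainder -- the only
#' rounding convention consistent with published 20/60/20 margins.
#' Ties break by hospital id (stable).
#'
#' @param rsrr An RSRR tibble from [predictive_margin_rsrr()] or
#'   [ratio_rsrr()].
#' @param highest_first Rank direction (default `TRUE`).
#' @return The tibble with a `group` factor
#'   (`top20`/`middle60`/`bottom20`).
#' @export
assign_groups <- function(rsrr, highest_first = TRUE) {
  n <- nrow(rsrr)
  if (n < 5L) {
    abort("need at least 5 hospitals to form 20/60/20 groups.",
          class = "readmitr_invalid_input")
  }
  key <- if (highest_first) -rsrr$rsrr else rsrr$rsrr
  ord <- order(key, rsrr$hospital_id, method = "radix")
  k <- floor(0.2 * n)
  group <- character(n)
  group[ord[seq_len(k)]] <- "top20"
  group[ord[seq.int(n - k + 1L, n)]] <- "bottom20"
  group[group == ""] <- "middle60"
  rsrr$group <- factor(group, levels = c("top20", "middle60", "bottom20"))
  rsrr
}

#' Cross-tabulate hospital groups under two models
#'
#' @param groups_a,groups_b RSRR tibbles with `group` columns from
#'   [assign_groups()] over the same hospital set (rows of the result
#'   are model A's groups, columns model B's).
#' @return A `reclassification_table`: 3x3 integer matrix with margin
#'   attributes.
#' @export
cross_tabulate <- function(groups_a, groups_b) {
  if (!setequal(groups_a$hospital_id, groups_b$hospital_id) ||
      nrow(groups_a) != nrow(groups_b)) {
    abort("the two group tables must cover the same hospitals.",
          class = "readmitr_invalid_input")
  }
  gb <- groups_b$group[match(groups_a$hospital_id, groups_b$hospital_id)]
  tab <- table(model_a = groups_a$group, model_b = gb)
  out <- matrix(as.integer(tab), 3, 3, dimnames = dimnames(tab))
  structure(out, class = c("reclassification_table", "matrix"),
            total = sum(out))
}

#' @export
print.reclassification_table <- function(x, ...) {
  m <- unclass(x)
  attr(m, "total") <- NULL
  full <- rbind(cbind(m, All = rowSums(m)),
                All = c(colSums(m), sum(m)))
  print(full)
  invisible(x)
}

#' Summarize reclassification between two models
#'
#' Reports each off-diagonal cell of a [cross_tabulate()] table as a
#' count and a percentage of all hospitals (rounded half-up to one
#' decimal), plus the total number reclassified.
#'
#' @param table A `reclassification_table`.
#' @return A tibble (`from`, `to`, `count`, `pct`) with attributes
#'   `total` (number of hospitals), `n_reclassified` and
#'   `pct_reclassified`.
#' @export
reclassification_summary <- function(table) {
  m <- unclass(table)
  attr(m, "total") <- NULL
  total <- sum(m)
  cells <- expand.grid(from = rownames(m), to = colnames(m),
                       stringsAsFactors = FALSE)
  cells <- cells[cells$from != cells$to, ]
  out <- tibble(
    from = cells$from, to = cells$to,
    count = as.integer(m[cbind(cells$from, cells$to)]),
    pct = round_half_up(100 * m[cbind(cells$from, cells$to)] / total, 1)
  )
  n_re <- sum(out$count)
  attr(out, "total") <- total
  attr(out, "n_reclassified") <- n_re
  attr(out, "pct_reclassified") <- round_half_up(100 * n_re / total, 1)
  out
}
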