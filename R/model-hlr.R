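#' Fit the hierarchical logistic regression risk model
#'
#' Logistic mixed model `logit p = X beta + u_hospital`, `u_h ~
#' Normal(0, sigma_u^2)`, fitted by Laplace-approximated maximum
#' likelihood via `lme4::glmer`. Returns fixed effects, the
#' random-effect SD and the posterior-mode hospital intercepts.
#'
#' @param features Numeric matrix of patient-level covariates
#'   (standardized age, female flag and 29 comorbidity indicators in the
#'   reference configuration).
#' @param hospital_ids Character/factor vector, one hospital per record.
#' @param labels Binary outcome vector.
#' @param fix_sigma_zero Fit an ordinary logistic regression with no
#'   hospital effect (used for degenerate or reference fits).
#' @return A `readmit_hlr` model.
#' @export
fit_hlr <- function(features, hospital_ids, labels, fix_sigma_zero = FALSE) {
  labels <- as.integer(labels)
  if (all(labels == 0L) || all(labels == 1L)) {
    abort("outcome is single-class; cannot fit.",
          class = "readmitr_invalid_input")
  }
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  }
  keep <- apply(features, 2, function(v) stats::var(v) > 0)
  X <- features[, keep, drop = FALSE]
  df <- data.frame(.y = labels, X, .hospital = as.character(hospital_ids),
                   check.names = FALSE)
  terms <- if (ncol(X) > 0) sprintf("`%s`", colnames(X)) else "1"

  if (fix_sigma_zero || length(unique(df$.hospital)) < 2L) {
    form <- stats::reformulate(terms, response = ".y")
    fit <- glm(form, data = df, family = binomial())
    beta <- coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    u <- setNames(rep(0, length(unique(df$.hospital))), unique(df$.hospital))
    sigma_u <- 0
    converged <- fit$converged
  } else {
    form <- stats::as.formula(paste(
      ".y ~", paste(terms, collapse = " + "), "+ (1 | .hospital)"
    ))
    fit <- lme4::glmer(
      form, data = df, family = binomial(), nAGQ = 1L,
      control = lme4::glmerControl(optimizer = "bobyqa",
                                   calc.derivs = FALSE)
    )
    beta <- lme4::fixef(fit)
    se <- sqrt(Matrix::diag(stats::vcov(fit)))
    re <- lme4::ranef(fit)$.hospital
    u <- setNames(re[["(Intercept)"]], rownames(re))
    sigma_u <- sqrt(as.numeric(lme4::VarCorr(fit)$.hospital[1]))
    converged <- length(fit@optinfo$conv$lme4) == 0
    if (!converged) {
      warn("glmer reported convergence issues; inspect `$messages`.")
    }
  }

  structure(
    list(kind = "HLR",
         beta = beta, se = se, u = u, sigma_u = sigma_u,
         features = colnames(X), all_features = colnames(features),
         n = nrow(X), loglik = as.numeric(stats::logLik(fit)),
         converged = converged,
         messages = if (inherits(fit, "glmerMod")) fit@optinfo$conv$lme4 else NULL),
    class = c("readmit_hlr", "readmit_model")
  )
}

# linear predictor without any hospital effect
hlr_base_eta <- function(object, features) {
  X <- as.matrix(features)[, object$features, drop = FALSE]
  drop(object$beta[1] + X %*% object$beta[-1])
}

#' Predict readmission probabilities
#'
#' All risk models share this contract: probabilities in (0, 1), with
#' the hospital effect taken from each record's own hospital
#' (`hospital = "actual"`), forced to a single hospital
#' (`force_hospital = "H0001"`), or set to the population average
#' (`hospital = "average"`: a zero random intercept for the hierarchical
#' model, the mean hospital embedding for the deep-set model). Models
#' without hospital effects ignore the hospital arguments.
#'
#' @param object A fitted readmitr model.
#' @param features Feature matrix matching the one used at fit time
#'   (deep-set models take the input list from
#'   [build_deepset_inputs()]).
#' @param hospital_ids Hospital of each record (for
#'   `hospital = "actual"`).
#' @param hospital `"actual"` or `"average"`.
#' @param force_hospital Hospital id whose effect is applied to every
#'   record; overrides `hospital`.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.readmit_hlr <- function(object, features, hospital_ids = NULL,
                                hospital = c("actual", "average"),
                                force_hospital = NULL, ...) {
  hospital <- match.arg(hospital)
  eta <- hlr_base_eta(object, features)
  if (!is.null(force_hospital)) {
    if (!force_hospital %in% names(object$u)) {
      abort(sprintf("hospital '%s' unknown to the model.", force_hospital),
            class = "readmitr_lookup_error")
    }
    eta <- eta + object$u[[force_hospital]]
  } else if (hospital == "actual") {
    if (is.null(hospital_ids)) {
      abort("`hospital_ids` needed for hospital = \"actual\".",
            class = "readmitr_invalid_input")
    }
    uh <- object$u[as.character(hospital_ids)]
    uh[is.na(uh)] <- 0
    eta <- eta + uh
  }
  unname(clamp_prob(plogis(eta)))
}

clamp_prob <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

#' @export
print.readmit_hlr <- function(x, ...) {
  cat(sprintf(
    "<readmit_hlr> %d features, %d hospitals, sigma_u = %.3f, n = %d\n",
    length(x$features), length(x$u), x$sigma_u, x$n
  ))
  invisible(x)
}

#' @rdname tidy.readmit_hlr
#' @export
glance.readmit_hlr <- function(x, ...) {
  tibble(sigma_u = x$sigma_u, n_hospitals = length(x$u), nobs = x$n,
         logLik = x$loglik, converged = x$converged)
}

#' Tidy a hierarchical logistic regression model
#'
#' `tidy()` returns the fixed effects (log-odds scale) with standard
#' errors; `glance()` returns model-level summaries.
#'
#' @param x A `readmit_hlr` model.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.readmit_hlr <- function(x, ...) {
  tibble(term = names(x$beta), estimate = as.numeric(x$beta),
         std.error = as.numeric(x$se),
         statistic = as.numeric(x$beta) / as.numeric(x$se))
}
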