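#' Fit the medical-code-embedding deep-set risk model
#'
#' Permutation-invariant classifier over the variable-length sets of
#' secondary diagnosis and procedure codes. Each code's pretrained
#' embedding passes through a shared encoder phi (dense + relu), the
#' encoded set is sum-pooled (so cardinality information is preserved
#' and the empty set pools to a zero vector), and a post-pool map rho
#' (dense + relu) produces the set representation. The head combines
#' the principal-diagnosis embedding, both set representations, a
#' learned 1-dimensional hospital embedding, age and sex through one
#' relu layer with dropout into a 2-unit softmax, trained like the
#' feed-forward model (ADAM at 0.0002, categorical cross-entropy, early
#' stopping). Code embeddings stay frozen.
#'
#' @param train_inputs,val_inputs Input lists from
#'   [build_deepset_inputs()].
#' @param dx_table,proc_table The embedding tables the inputs were
#'   built against.
#' @param hidden Width of phi and rho.
#' @param head_hidden Width of the head layer.
#' @inheritParams fit_ffnn
#' @return A `readmit_deepset` model.
#' @export
fit_deepset <- function(train_inputs, val_inputs, dx_table, proc_table,
                        hidden = 64, head_hidden = 64, dropout = 0.3,
                        learning_rate = 2e-4, batch_size = 256,
                        max_epochs = 50, patience = 5, seed = 1L) {
  Edx <- unname(dx_table$vectors)
  Eproc <- if (is.null(proc_table)) {
    matrix(0, 1, 2)
  } else {
    unname(proc_table$vectors)
  }
  if (is.null(proc_table) && nrow(train_inputs$Aproc) != 1L) {
    abort("procedure inputs present but no `proc_table` given.",
          class = "readmitr_invalid_input")
  }
  if (nrow(train_inputs$Adx) != nrow(Edx)) {
    abort("embedding dimension mismatch between inputs and `dx_table`.",
          class = "readmitr_invalid_input")
  }
  n <- length(train_inputs$y)
  ord <- with_seed(derive_seed(seed, 12L), sample.int(n))
  tr <- subset_deepset_inputs(train_inputs, ord)
  fit <- deepset_fit_cpp(
    Edx, Eproc, tr$Adx, tr$Aproc, tr$prin, tr$hosp, tr$age_z, tr$female,
    tr$y,
    val_inputs$Adx, val_inputs$Aproc, val_inputs$prin, val_inputs$hosp,
    val_inputs$age_z, val_inputs$female, val_inputs$y,
    length(train_inputs$hospital_levels), as.integer(hidden),
    as.integer(head_hidden), dropout, learning_rate,
    as.integer(batch_size), as.integer(max_epochs), as.integer(patience),
    as.integer(seed)
  )
  par <- fit[c("Wpd", "bpd", "Wpp", "bpp", "Wrd", "brd", "Wrp", "brp",
               "Whead", "bhead", "Wout", "bout", "eh")]
  structure(
    list(kind = "ME-DS", par = par, Edx = Edx, Eproc = Eproc,
         hospital_levels = train_inputs$hospital_levels,
         eh = setNames(as.numeric(par$eh), train_inputs$hospital_levels),
         train_loss = fit$train_loss, val_loss = fit$val_loss,
         best_epoch = fit$best_epoch, hidden = hidden, dropout = dropout,
         seed = seed),
    class = c("readmit_deepset", "readmit_model")
  )
}

#' @rdname predict.readmit_hlr
#' @export
predict.readmit_deepset <- function(object, features,
                                    hospital = c("actual", "average"),
                                    force_hospital = NULL, ...) {
  hospital <- match.arg(hospital)
  inputs <- features
  if (!is.null(force_hospital)) {
    if (!force_hospital %in% object$hospital_levels) {
      abort(sprintf("hospital '%s' unknown to the model.", force_hospital),
            class = "readmitr_lookup_error")
    }
    mode <- 1L
    value <- object$eh[[force_hospital]]
  } else if (hospital == "average") {
    mode <- 1L
    value <- mean(object$eh)
  } else {
    mode <- 0L
    value <- 0
  }
  p <- deepset_predict_cpp(object$par, object$Edx, object$Eproc,
                           inputs$Adx, inputs$Aproc, inputs$prin,
                           inputs$hosp, inputs$age_z, inputs$female,
                           mode, value)
  clamp_prob(as.numeric(p))
}

#' @export
print.readmit_deepset <- function(x, ...) {
  cat(sprintf(
    "<readmit_deepset> %d-d dx / %d-d proc embeddings, phi/rho width %d, %d hospitals, best epoch %d\n",
    ncol(x$Edx), ncol(x$Eproc), x$hidden, length(x$eh), x$best_epoch
  ))
  invisible(x)
}

#' @rdname tidy.readmit_hlr
#' @export
glance.readmit_deepset <- function(x, ...) {
  tibble(best_epoch = x$best_epoch,
         val_loss = x$val_loss[x$best_epoch],
         n_hospitals = length(x$eh), phi_width = x$hidden)
}

#' @rdname tidy.readmit_hlr
#' @export
tidy.readmit_deepset <- function(x, ...) {
  tibble(hospital_id = names(x$eh), embedding = as.numeric(x$eh))
}
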