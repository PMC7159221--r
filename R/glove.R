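#' GloVe weighted least-squares objective
#'
#' The embedding objective over nonzero co-occurrences:
#' `J = sum f(x_ij) * (w_i' wc_j + b_i + bc_j - log x_ij)^2` with the
#' saturating weight `f(x) = (x / x_max)^alpha` for `x < x_max`, else 1.
#' Returns the loss and its analytic gradients; used both for testing
#' the optimizer's gradients and for reporting.
#'
#' @param W,Wc Main and context vectors, `vocab x dim` matrices.
#' @param b,bc Main and context bias vectors.
#' @param i,j Integer vectors (1-based) of co-occurring pairs.
#' @param x Co-occurrence counts for each pair (> 0).
#' @param x_max,alpha Weighting-function parameters.
#' @return List with `loss`, `grad_W`, `grad_Wc`, `grad_b`, `grad_bc`.
#' @export
glove_objective <- function(W, Wc, b, bc, i, j, x, x_max = 100, alpha = 0.75) {
  f <- pmin(1, (x / x_max)^alpha)
  diff <- rowSums(W[i, , drop = FALSE] * Wc[j, , drop = FALSE]) +
    b[i] + bc[j] - log(x)
  loss <- sum(f * diff^2)
  g <- 2 * f * diff
  grad_W <- matrix(0, nrow(W), ncol(W))
  grad_Wc <- matrix(0, nrow(Wc), ncol(Wc))
  gW <- g * Wc[j, , drop = FALSE]
  gWc <- g * W[i, , drop = FALSE]
  for (d in seq_len(ncol(W))) {
    grad_W[, d] <- grad_W[, d] +
      as.numeric(tapply(gW[, d], factor(i, levels = seq_len(nrow(W))), sum,
                        default = 0))
    grad_Wc[, d] <- grad_Wc[, d] +
      as.numeric(tapply(gWc[, d], factor(j, levels = seq_len(nrow(Wc))), sum,
                        default = 0))
  }
  grad_b <- as.numeric(tapply(g, factor(i, levels = seq_len(nrow(W))), sum,
                              default = 0))
  grad_bc <- as.numeric(tapply(g, factor(j, levels = seq_len(nrow(Wc))), sum,
                               default = 0))
  list(loss = loss, grad_W = grad_W, grad_Wc = grad_Wc,
       grad_b = grad_b, grad_bc = grad_bc)
}

#' Fit GloVe embeddings from a co-occurrence matrix
#'
#' Minimizes the weighted least-squares objective (see
#' [glove_objective()]) by seeded stochastic gradient descent with
#' per-parameter adaptive (AdaGrad) learning rates over the nonzero
#' entries; each unordered pair is visited in both orientations per
#' epoch. The final embedding of a code is `w + wc` (main plus context
#' vector).
#'
#' @param cooc A `cooccurrence` object.
#' @param dim Embedding dimension (200 for diagnosis codes, 50 for
#'   procedure codes in the reference configuration).
#' @param x_max,alpha Weighting-function parameters (canonical defaults
#'   100 and 0.75).
#' @param learning_rate AdaGrad base step size.
#' @param n_epochs Training epochs.
#' @param seed Integer seed (initialization and visit order).
#' @return An `embedding_table`: list with `vectors` (matrix, one row
#'   per code), `loss` (per-epoch training loss), and the parameters.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   principal_dx = c("A", "B"), secondary_dx = list("B", "C"),
#'   procedures = list(character(0), character(0))
#' )
#' cooc <- count_cooccurrences(rec, c("A", "B", "C"))
#' emb <- fit_glove(cooc, dim = 4, n_epochs = 20, seed = 1)
#' dim(emb$vectors)
fit_glove <- function(cooc, dim, x_max = 100, alpha = 0.75,
                      learning_rate = 0.05, n_epochs = 25, seed = 1L) {
  if (dim < 1) abort("`dim` must be positive.", class = "readmitr_invalid_config")
  if (alpha <= 0 || alpha > 1) {
    abort("`alpha` must be in (0, 1].", class = "readmitr_invalid_config")
  }
  if (Matrix::nnzero(cooc$X) == 0L) {
    abort("co-occurrence matrix has no nonzero entries.",
          class = "readmitr_invalid_input")
  }
  Xt <- as(Matrix::triu(cooc$X), "TsparseMatrix")
  fit <- glove_fit_cpp(
    Xt@i, Xt@j, Xt@x, length(cooc$vocabulary), as.integer(dim),
    x_max, alpha, learning_rate, as.integer(n_epochs), as.integer(seed)
  )
  vectors <- fit$W + fit$Wc
  rownames(vectors) <- cooc$vocabulary
  structure(
    list(vectors = vectors, W = fit$W, Wc = fit$Wc, b = fit$b, bc = fit$bc,
         loss = as.numeric(fit$loss),
         params = list(dim = dim, x_max = x_max, alpha = alpha,
                       learning_rate = learning_rate, n_epochs = n_epochs,
                       seed = seed)),
    class = "embedding_table"
  )
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d codes x %d dims, final loss %.4g\n",
              nrow(x$vectors), ncol(x$vectors), utils::tail(x$loss, 1)))
  invisible(x)
}

#' Fit separate diagnosis and procedure embeddings
#'
#' One joint co-occurrence count feeds two GloVe fits restricted to the
#' diagnosis-diagnosis and procedure-procedure blocks, honoring the
#' different target dimensions.
#'
#' @param records Training records (exclude the test split).
#' @param dx_vocab,proc_vocab Vocabularies from [filter_rare_codes()].
#' @param dim_dx,dim_proc Embedding dimensions (defaults 200 and 50).
#' @param ... Passed to [fit_glove()].
#' @return List with elements `dx` and `proc` (embedding tables) and
#'   `cooccurrence` (the joint count matrix).
#' @export
fit_code_embeddings <- function(records, dx_vocab, proc_vocab,
                                dim_dx = 200, dim_proc = 50, ...) {
  cooc <- count_cooccurrences(records, c(dx_vocab, proc_vocab))
  dx <- fit_glove(subset_cooccurrence(cooc, dx_vocab), dim = dim_dx, ...)
  proc <- if (length(proc_vocab) > 0 &&
              Matrix::nnzero(subset_cooccurrence(cooc, proc_vocab)$X) > 0) {
    fit_glove(subset_cooccurrence(cooc, proc_vocab), dim = dim_proc, ...)
  } else {
    NULL
  }
  list(dx = dx, proc = proc, cooccurrence = cooc)
}

#' Look up the embedding vectors of one record
#'
#' Out-of-vocabulary codes are skipped (treated as absent); an
#' out-of-vocabulary principal diagnosis maps to a zero vector (with a
#' warning) or an error, per `on_missing_principal`.
#'
#' @param record One admission (a one-row tibble or a list with
#'   `principal_dx`, `secondary_dx`, `procedures`).
#' @param dx_table,proc_table Fitted [fit_glove()] tables.
#' @param on_missing_principal `"zero"` (default) or `"error"`.
#' @return List with `principal` (vector), `secondary` (matrix, one row
#'   per in-vocabulary code) and `procedures` (matrix).
#' @export
embed_record <- function(record, dx_table, proc_table,
                         on_missing_principal = c("zero", "error")) {
  on_missing_principal <- match.arg(on_missing_principal)
  prin <- unlist(record$principal_dx)[1]
  sec <- unlist(record$secondary_dx)
  proc <- unlist(record$procedures)

  lookup <- function(codes, table) {
    if (is.null(table) || length(codes) == 0) {
      return(matrix(0, 0, if (is.null(table)) 0L else ncol(table$vectors)))
    }
    hit <- codes[codes %in% rownames(table$vectors)]
    table$vectors[hit, , drop = FALSE]
  }

  if (prin %in% rownames(dx_table$vectors)) {
    principal <- dx_table$vectors[prin, ]
  } else if (on_missing_principal == "error") {
    abort(sprintf("principal diagnosis '%s' is out of vocabulary.", prin),
          class = "readmitr_oov_principal")
  } else {
    warn(sprintf("principal diagnosis '%s' out of vocabulary; using zero vector.",
                 prin))
    principal <- rep(0, ncol(dx_table$vectors))
  }
  list(principal = principal,
       secondary = lookup(sec, dx_table),
       procedures = lookup(proc, proc_table))
}

#' Write / read embeddings as TSV
#'
#' One line per code: the code then its vector entries.
#'
#' @param table An `embedding_table`.
#' @param path Output file.
#' @return `path` invisibly; `read_embeddings()` returns a reduced
#'   `embedding_table` (vectors only).
#' @export
write_embeddings <- function(table, path) {
  df <- data.frame(code = rownames(table$vectors),
                   table$vectors, check.names = FALSE)
  colnames(df) <- c("code", paste0("v", seq_len(ncol(table$vectors))))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  vectors <- as.matrix(df[, -1, drop = FALSE])
  rownames(vectors) <- df$code
  colnames(vectors) <- NULL
  structure(list(vectors = vectors, loss = NA_real_, params = list()),
            class = "embedding_table")
}
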