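#' Count record-level code co-occurrences
#'
#' Two codes co-occur when both appear in the same admission record
#' (principal and secondary diagnoses and procedures all participate).
#' Counting is presence-based: each unordered pair of distinct
#' in-vocabulary codes present in a record contributes exactly 1.
#'
#' @param records Admission tibble.
#' @param vocabulary Ordered character vector of codes to count over
#'   (codes outside it are ignored).
#' @return A `cooccurrence` object: list with `vocabulary` and `X`, a
#'   symmetric sparse matrix with zero diagonal, `X[i, j]` = number of
#'   records containing both codes.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   principal_dx = c("A", "A"), secondary_dx = list(c("B", "C"), "B"),
#'   procedures = list(character(0), character(0))
#' )
#' cooc <- count_cooccurrences(rec, c("A", "B", "C"))
#' cooc$X["A", "B"]
count_cooccurrences <- function(records, vocabulary) {
  if (length(vocabulary) == 0L) {
    abort("`vocabulary` must be non-empty.", class = "readmitr_invalid_input")
  }
  A <- record_code_matrix(records, vocabulary)
  X <- Matrix::t(A) %*% A
  Matrix::diag(X) <- 0
  X <- Matrix::drop0(X)
  dimnames(X) <- list(vocabulary, vocabulary)
  structure(list(vocabulary = vocabulary, X = X), class = "cooccurrence")
}

#' @export
print.cooccurrence <- function(x, ...) {
  cat(sprintf("<cooccurrence> %d codes, %d nonzero pairs\n",
              length(x$vocabulary), Matrix::nnzero(x$X) / 2))
  invisible(x)
}

# restrict a cooccurrence object to a code subset (e.g. the dx-dx block)
subset_cooccurrence <- function(cooc, codes) {
  keep <- intersect(cooc$vocabulary, codes)
  structure(
    list(vocabulary = keep, X = cooc$X[keep, keep, drop = FALSE]),
    class = "cooccurrence"
  )
}

#' Write / read a co-occurrence matrix as coordinate triplets
#'
#' Plain-text tab-separated `(code_i, code_j, count)` with one line per
#' unordered pair (upper triangle).
#'
#' @param cooc A `cooccurrence` object.
#' @param path Output file.
#' @return `path` invisibly; `read_cooccurrence()` returns the object.
#' @export
write_cooccurrence <- function(cooc, path) {
  Xt <- as(Matrix::triu(cooc$X), "TsparseMatrix")
  df <- data.frame(
    code_i = cooc$vocabulary[Xt@i + 1L],
    code_j = cooc$vocabulary[Xt@j + 1L],
    count = Xt@x
  )
  header <- paste0("# vocabulary: ", paste(cooc$vocabulary, collapse = " "))
  writeLines(header, path)
  suppressWarnings(write.table(
    df, path, sep = "\t", row.names = FALSE, col.names = TRUE,
    quote = FALSE, append = TRUE
  ))
  invisible(path)
}

#' @rdname write_cooccurrence
#' @export
read_cooccurrence <- function(path) {
  header <- readLines(path, n = 1L)
  vocab <- strsplit(sub("^# vocabulary: ", "", header), " ")[[1]]
  df <- read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  i <- match(df$code_i, vocab)
  j <- match(df$code_j, vocab)
  X <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = c(df$count, df$count),
    dims = c(length(vocab), length(vocab)),
    dimnames = list(vocab, vocab)
  )
  structure(list(vocabulary = vocab, X = X), class = "cooccurrence")
}
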