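# Co-occurrence counting and GloVe embedding fits.

test_that("co-occurrence counts follow the presence-based definition", {
  rec <- make_records("A", list(c("B", "C")))
  cooc <- count_cooccurrences(rec, c("A", "B", "C"))
  expect_equal(as.numeric(cooc$X["A", "B"]), 1)
  expect_equal(as.numeric(cooc$X["A", "C"]), 1)
  expect_equal(as.numeric(cooc$X["B", "C"]), 1)

  two <- make_records(c("A", "A"), list("B", "B"))
  cooc2 <- count_cooccurrences(two, c("A", "B"))
  expect_equal(as.numeric(cooc2$X["A", "B"]), 2)
  expect_error(count_cooccurrences(rec, character(0)),
               class = "readmitr_invalid_input")
})

test_that("co-occurrence matrix equals brute-force pair enumeration", {
  sim <- simulate_claims(tiny_config())
  adm <- sim$admissions[1:200, ]
  vocab <- sort(unique(unlist(c(adm$principal_dx, adm$secondary_dx,
                                adm$procedures))))
  cooc <- count_cooccurrences(adm, vocab)
  X <- matrix(0, length(vocab), length(vocab),
              dimnames = list(vocab, vocab))
  for (i in seq_len(nrow(adm))) {
    cs <- unique(c(adm$principal_dx[[i]], adm$secondary_dx[[i]],
                   adm$procedures[[i]]))
    cs <- intersect(cs, vocab)
    if (length(cs) >= 2) {
      pairs <- utils::combn(cs, 2)
      for (k in seq_len(ncol(pairs))) {
        a <- pairs[1, k]; b <- pairs[2, k]
        X[a, b] <- X[a, b] + 1
        X[b, a] <- X[b, a] + 1
      }
    }
  }
  expect_equal(as.matrix(cooc$X), X, ignore_attr = TRUE)
  # symmetry and zero diagonal
  expect_true(Matrix::isSymmetric(cooc$X))
  expect_true(all(Matrix::diag(cooc$X) == 0))
  expect_true(max(cooc$X) <= nrow(adm))
})

test_that("co-occurrence matrices round-trip through triplet text", {
  sim <- simulate_claims(tiny_config())
  cooc <- count_cooccurrences(sim$admissions[1:100, ],
                              sort(unique(unlist(sim$admissions$secondary_dx[1:100]))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cooccurrence(cooc, path)
  back <- read_cooccurrence(path)
  expect_equal(back$vocabulary, cooc$vocabulary)
  expect_equal(as.matrix(back$X), as.matrix(cooc$X))
})

test_that("analytic GloVe gradients match central finite differences", {
  set.seed(42)
  v <- 6L; d <- 3L
  W <- matrix(rnorm(v * d, sd = 0.3), v, d)
  Wc <- matrix(rnorm(v * d, sd = 0.3), v, d)
  b <- rnorm(v, sd = 0.2); bc <- rnorm(v, sd = 0.2)
  pairs <- utils::combn(v, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  x <- rpois(length(i), 20) + 1
  obj <- glove_objective(W, Wc, b, bc, i, j, x)
  eps <- 1e-6
  num_grad <- function(get, set) {
    th <- get()
    g <- numeric(length(th))
    for (k in seq_along(th)) {
      thp <- th; thp[k] <- th[k] + eps
      thm <- th; thm[k] <- th[k] - eps
      g[k] <- (set(thp)$loss - set(thm)$loss) / (2 * eps)
    }
    g
  }
  gW <- num_grad(function() W, function(th) {
    glove_objective(matrix(th, v, d), Wc, b, bc, i, j, x)
  })
  expect_equal(as.numeric(obj$grad_W), gW, tolerance = 1e-5)
  gb <- num_grad(function() b, function(th) {
    glove_objective(W, Wc, th, bc, i, j, x)
  })
  expect_equal(obj$grad_b, gb, tolerance = 1e-5)
  gWc <- num_grad(function() Wc, function(th) {
    glove_objective(W, matrix(th, v, d), b, bc, i, j, x)
  })
  expect_equal(as.numeric(obj$grad_Wc), gWc, tolerance = 1e-5)
})

test_that("a saturated two-code model drives the loss to ~0", {
  rec <- make_records("A", list("B"))
  cooc <- count_cooccurrences(rec, c("A", "B"))
  cooc$X["A", "B"] <- exp(1)
  cooc$X["B", "A"] <- exp(1)
  emb <- fit_glove(cooc, dim = 2, n_epochs = 400, learning_rate = 0.2,
                   seed = 2)
  expect_lt(utils::tail(emb$loss, 1), 1e-4)
})

test_that("training loss decreases from initialization and the objective is permutation-equivariant", {
  sim <- simulate_claims(tiny_config())
  vocab <- sort(unique(unlist(sim$admissions$secondary_dx[1:400])))
  cooc <- count_cooccurrences(sim$admissions[1:400, ], vocab)
  emb <- fit_glove(cooc, dim = 8, n_epochs = 10, seed = 3)
  expect_lt(utils::tail(emb$loss, 1), emb$loss[1])
  expect_true(all(is.finite(emb$vectors)))

  # loss is invariant under a simultaneous permutation of the vocabulary
  Xt <- as(Matrix::triu(cooc$X), "TsparseMatrix")
  i <- Xt@i + 1L; j <- Xt@j + 1L; x <- Xt@x
  v <- length(vocab)
  set.seed(9)
  W <- matrix(rnorm(v * 4), v, 4); Wc <- matrix(rnorm(v * 4), v, 4)
  b <- rnorm(v); bc <- rnorm(v)
  perm <- sample(v)
  l1 <- glove_objective(W, Wc, b, bc, i, j, x)$loss
  l2 <- glove_objective(W[order(perm), , drop = FALSE],
                        Wc[order(perm), , drop = FALSE],
                        b[order(perm)], bc[order(perm)],
                        perm[i], perm[j], x)$loss
  expect_equal(l1, l2)
})

test_that("block-structured co-occurrence yields within-block cosine separation", {
  # two 10-code blocks, dense within (count 50), zero between
  v <- 20L
  codes <- sprintf("C%02d", 1:v)
  block <- rep(1:2, each = 10)
  i <- integer(0); j <- integer(0)
  for (a in 1:(v - 1)) for (bb in (a + 1):v) {
    if (block[a] == block[bb]) { i <- c(i, a); j <- c(j, bb) }
  }
  X <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 50,
                            dims = c(v, v), dimnames = list(codes, codes))
  cooc <- structure(list(vocabulary = codes, X = X), class = "cooccurrence")
  emb <- fit_glove(cooc, dim = 8, n_epochs = 60, seed = 4)
  V <- emb$vectors / sqrt(rowSums(emb$vectors^2))
  S <- V %*% t(V)
  within <- S[outer(block, block, "==") & upper.tri(S)]
  between <- S[outer(block, block, "!=") & upper.tri(S)]
  expect_gt(mean(within) - mean(between), 0.3)
})

test_that("record embedding lookup handles OOV and empty sets", {
  rec <- make_records("A", list(c("B", "ZZZ")), list(character(0)))
  cooc <- count_cooccurrences(make_records(c("A", "B"), list("B", "A")),
                              c("A", "B"))
  emb <- fit_glove(cooc, dim = 3, n_epochs = 5, seed = 1)
  out <- embed_record(rec[1, ], emb, NULL)
  expect_equal(out$principal, emb$vectors["A", ])
  expect_equal(rownames(out$secondary), "B")
  expect_equal(nrow(out$procedures), 0L)

  # all codes OOV: zero principal vector plus warning
  oov <- make_records("QQ", list("ZZ"))
  expect_warning(res <- embed_record(oov[1, ], emb, NULL),
                 "out of vocabulary")
  expect_equal(res$principal, rep(0, 3), ignore_attr = TRUE)
  expect_equal(nrow(res$secondary), 0L)
  expect_error(embed_record(oov[1, ], emb, NULL,
                            on_missing_principal = "error"),
               class = "readmitr_oov_principal")
})

test_that("embeddings round-trip through TSV", {
  cooc <- count_cooccurrences(make_records(c("A", "B"), list("B", "A")),
                              c("A", "B"))
  emb <- fit_glove(cooc, dim = 4, n_epochs = 5, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_embeddings(emb, path)
  back <- read_embeddings(path)
  expect_equal(back$vectors, emb$vectors, tolerance = 1e-10)
})
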