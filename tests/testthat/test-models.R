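# The four risk models and the shared prediction contract.

# small cohort with features, reused across model tests
model_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_claims(tiny_config(n_hospitals = 30,
                                         hospital_size_log_mean = log(80)))
      ch <- build_cohort(sim)
      rec <- ch$records
      Xcode <- build_code_features(rec, ch$dx_vocab, ch$proc_vocab)
      Xhlr <- build_hlr_features(rec, synthetic_comorbidity_map(sim$universe))
      emb <- fit_code_embeddings(
        rec[rec$split != "test", ], ch$dx_vocab, ch$proc_vocab,
        dim_dx = 12, dim_proc = 6, n_epochs = 8, seed = 1
      )
      hosp_levels <- sort(unique(rec$hospital_id))
      ds <- build_deepset_inputs(rec, emb$dx, emb$proc, hosp_levels)
      cache <<- list(sim = sim, ch = ch, rec = rec, Xcode = Xcode,
                     Xhlr = Xhlr, emb = emb, ds = ds,
                     idx = split(seq_len(nrow(rec)), rec$split))
    }
    cache
  }
})

test_that("intercept-only logistic fit reproduces the empirical log-odds", {
  set.seed(1)
  y <- rbinom(400, 1, 0.3)
  X <- matrix(rnorm(400), ncol = 1, dimnames = list(NULL, "x"))
  X[] <- 0  # no information: intercept-only once constant column dropped
  m <- fit_hlr(X, rep("H1", 400), y, fix_sigma_zero = TRUE)
  expect_equal(unname(m$beta[1]), qlogis(mean(y)), tolerance = 1e-3)
  expect_equal(m$sigma_u, 0)
})

test_that("hlr predictions follow the logistic closed form", {
  # hand-computed 3-record example: beta = (-2, 1), x in {0, 1}, u = 0.5
  m <- structure(
    list(kind = "HLR", beta = c("(Intercept)" = -2, x = 1),
         u = c(H1 = 0.5, H2 = 0), sigma_u = 0.3, features = "x"),
    class = c("readmit_hlr", "readmit_model")
  )
  X <- matrix(c(0, 1, 1), ncol = 1, dimnames = list(NULL, "x"))
  p_actual <- predict(m, X, hospital_ids = c("H1", "H1", "H2"))
  expect_equal(p_actual, plogis(c(-1.5, -0.5, -1)), tolerance = 1e-12)
  # forced(h) vs population-average differ by exactly u_h on logit scale
  p_forced <- predict(m, X, force_hospital = "H1")
  p_avg <- predict(m, X, hospital = "average")
  expect_equal(qlogis(p_forced) - qlogis(p_avg), rep(0.5, 3),
               tolerance = 1e-12)
  # forced with u = 0 equals population-average
  expect_equal(predict(m, X, force_hospital = "H2"), p_avg,
               tolerance = 1e-12)
  expect_error(predict(m, X, force_hospital = "H9"),
               class = "readmitr_lookup_error")
})

test_that("hlr recovers a zero random-effect SD", {
  # n = 50,000 so the boundary estimate of sigma_u is sharp
  cfg <- tiny_config(sigma_hospital = 0, code_effect_sd = 0,
                     interaction_strength = 0, beta0 = qlogis(0.2),
                     n_hospitals = 50, hospital_size_log_mean = log(1000),
                     hospital_size_log_sd = 0, repeat_frac = 0)
  sim <- simulate_claims(cfg)
  adm <- sim$admissions
  X <- build_hlr_features(adm, synthetic_comorbidity_map(sim$universe),
                          cfg$age_mean, cfg$age_sd)
  m <- fit_hlr(X, adm$hospital_id, adm$readmit_30d)
  expect_lt(m$sigma_u, 0.05)
  est <- tidy(m)
  ba <- est[est$term == "age_z", ]
  expect_lt(abs(ba$estimate - cfg$beta_age), 1.96 * ba$std.error + 0.02)
})

test_that("hlr tidiers return well-formed tibbles", {
  fx <- model_fixture()
  idx <- fx$idx$train
  m <- fit_hlr(fx$Xhlr[idx, ], fx$rec$hospital_id[idx],
               fx$rec$unplanned_readmit[idx])
  td <- tidy(m)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$n_hospitals, length(unique(fx$rec$hospital_id)))
  expect_gte(gl$sigma_u, 0)
})

test_that("gbt with zero rounds predicts the base rate and capacity grows with rounds", {
  fx <- model_fixture()
  idx <- fx$idx$train
  y <- fx$rec$unplanned_readmit[idx]
  m0 <- fit_gbt(fx$Xcode[idx, ], y, n_rounds = 0)
  expect_equal(predict(m0, fx$Xcode[1:5, ]), rep(mean(y), 5),
               tolerance = 1e-12)

  # linearly separable toy data: validation AUC approaches 1
  n <- 600
  set.seed(3)
  x <- matrix(rnorm(2 * n), ncol = 2, dimnames = list(NULL, c("a", "b")))
  yy <- as.integer(x[, 1] > 0)
  xs <- methods::as(x, "CsparseMatrix")
  m1 <- fit_gbt(xs[1:400, ], yy[1:400], xs[401:600, ], yy[401:600],
                learning_rate = 0.3, n_rounds = 200,
                early_stopping_rounds = 50)
  expect_gt(compute_auc(yy[401:600], predict(m1, xs[401:600, ])), 0.98)
  expect_error(fit_gbt(matrix(numeric(0), 0, 0), integer(0)),
               class = "readmitr_invalid_input")
})

test_that("gbt beats chance on interaction-bearing synthetic data", {
  fx <- model_fixture()
  idx <- fx$idx
  y <- fx$rec$unplanned_readmit
  m <- fit_gbt(fx$Xcode[idx$train, ], y[idx$train],
               fx$Xcode[idx$validation, ], y[idx$validation],
               learning_rate = 0.05, n_rounds = 300,
               early_stopping_rounds = 50)
  auc <- compute_auc(y[idx$test], predict(m, fx$Xcode[idx$test, ]))
  expect_gte(auc, 0.55)
})

test_that("ffnn softmax output is a probability and inference is deterministic", {
  fx <- model_fixture()
  idx <- fx$idx
  y <- fx$rec$unplanned_readmit
  m <- fit_ffnn(fx$Xcode[idx$train, ], y[idx$train],
                fx$Xcode[idx$validation, ], y[idx$validation],
                hidden = c(32, 16), max_epochs = 4, seed = 5)
  p1 <- predict(m, fx$Xcode[idx$test, ])
  p2 <- predict(m, fx$Xcode[idx$test, ])
  expect_identical(p1, p2)          # dropout disabled at inference
  expect_true(all(p1 > 0 & p1 < 1)) # class probabilities sum to one
  # same seed refit reproduces the model
  m2 <- fit_ffnn(fx$Xcode[idx$train, ], y[idx$train],
                 fx$Xcode[idx$validation, ], y[idx$validation],
                 hidden = c(32, 16), max_epochs = 4, seed = 5)
  expect_equal(predict(m2, fx$Xcode[idx$test, ]), p1)
})

test_that("deep-set predictions are permutation-invariant and handle empty sets", {
  fx <- model_fixture()
  idx <- fx$idx
  m <- fit_deepset(subset_deepset_inputs(fx$ds, idx$train),
                   subset_deepset_inputs(fx$ds, idx$validation),
                   fx$emb$dx, fx$emb$proc, hidden = 16, head_hidden = 16,
                   max_epochs = 3, seed = 7)
  test_rec <- fx$rec[idx$test, ]
  p_ref <- predict(m, subset_deepset_inputs(fx$ds, idx$test))
  for (k in 1:5) {
    shuffled <- test_rec
    shuffled$secondary_dx <- lapply(shuffled$secondary_dx, sample)
    shuffled$procedures <- lapply(shuffled$procedures, sample)
    ds_s <- build_deepset_inputs(shuffled, fx$emb$dx, fx$emb$proc,
                                 fx$ds$hospital_levels)
    expect_lt(max(abs(predict(m, ds_s) - p_ref)), 1e-6)
  }
  # record with empty secondary and procedure sets: finite probability
  empty <- test_rec[1, ]
  empty$secondary_dx <- list(character(0))
  empty$procedures <- list(character(0))
  ds_e <- build_deepset_inputs(empty, fx$emb$dx, fx$emb$proc,
                               fx$ds$hospital_levels)
  pe <- predict(m, ds_e)
  expect_true(is.finite(pe) && pe > 0 && pe < 1)
  # forced-hospital and average modes work
  expect_length(predict(m, ds_e, hospital = "average"), 1L)
  expect_error(predict(m, ds_e, force_hospital = "NOPE"),
               class = "readmitr_lookup_error")
})
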