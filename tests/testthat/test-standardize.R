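# Risk standardization, quintile grouping, reclassification.

toy_hlr <- function(beta = c("(Intercept)" = -2, x = 1),
                    u = c(H1 = 0.5, H2 = -0.25)) {
  structure(
    list(kind = "HLR", beta = beta, u = u, sigma_u = sd(u),
         features = names(beta)[-1]),
    class = c("readmit_hlr", "readmit_model")
  )
}

test_that("predictive margins match brute-force enumeration", {
  m <- toy_hlr()
  X <- matrix(c(0, 1, 0.5), ncol = 1, dimnames = list(NULL, "x"))
  got <- predictive_margin_rsrr(m, X)
  # brute-force double loop over hospitals and records
  for (h in c("H1", "H2")) {
    manual <- mean(vapply(seq_len(nrow(X)), function(i) {
      plogis(-2 + X[i, 1] + m$u[[h]])
    }, numeric(1)))
    expect_equal(got$rsrr[got$hospital_id == h], manual, tolerance = 1e-12)
  }
})

test_that("margins collapse to the cohort mean when hospital effects vanish", {
  m <- toy_hlr(u = c(H1 = 0, H2 = 0, H3 = 0))
  X <- matrix(rnorm(20), ncol = 1, dimnames = list(NULL, "x"))
  got <- predictive_margin_rsrr(m, X)
  expect_equal(got$rsrr, rep(mean(plogis(-2 + X[, 1])), 3),
               tolerance = 1e-12)
})

test_that("margins are strictly increasing in the hospital intercept", {
  us <- seq(-1, 1, by = 0.25)
  m <- toy_hlr(u = setNames(us, sprintf("H%02d", seq_along(us))))
  X <- matrix(rnorm(50), ncol = 1, dimnames = list(NULL, "x"))
  got <- predictive_margin_rsrr(m, X)
  expect_true(all(diff(got$rsrr) > 0))
})

test_that("margins are unsupported for models without hospital effects", {
  gbt <- structure(list(kind = "GBT"), class = c("readmit_gbt", "readmit_model"))
  expect_error(predictive_margin_rsrr(gbt, NULL),
               class = "readmitr_unsupported_model")
})

test_that("ratio standardization matches a hand-computed example", {
  m <- toy_hlr()
  # 4 records: H1 has x = 0 and 1, H2 has x = 0 and 0.5
  X <- matrix(c(0, 1, 0, 0.5), ncol = 1, dimnames = list(NULL, "x"))
  hosp <- c("H1", "H1", "H2", "H2")
  y <- c(1, 0, 0, 1)
  got <- ratio_rsrr(m, X, hosp, y)
  overall <- 0.5
  pred_h1 <- mean(plogis(c(-2 + 0 + 0.5, -2 + 1 + 0.5)))
  exp_h1 <- mean(plogis(c(-2, -1)))
  expect_equal(got$rsrr[got$hospital_id == "H1"],
               pred_h1 / exp_h1 * overall, tolerance = 1e-12)
  pred_h2 <- mean(plogis(c(-2 - 0.25, -1.5 - 0.25)))
  exp_h2 <- mean(plogis(c(-2, -1.5)))
  expect_equal(got$rsrr[got$hospital_id == "H2"],
               pred_h2 / exp_h2 * overall, tolerance = 1e-12)
})

test_that("ratio standardization equals the unadjusted rate when u = 0", {
  m <- toy_hlr(u = c(H1 = 0, H2 = 0))
  X <- matrix(rnorm(10), ncol = 1, dimnames = list(NULL, "x"))
  hosp <- rep(c("H1", "H2"), 5)
  y <- rep(c(0, 1), 5)
  got <- ratio_rsrr(m, X, hosp, y)
  expect_equal(got$rsrr, rep(mean(y), 2), tolerance = 1e-12)
})

test_that("quintile groups follow the floor(0.2 N) convention", {
  sizes <- function(n) {
    rsrr <- tibble::tibble(
      hospital_id = sprintf("H%04d", 1:n), rsrr = seq(0, 1, length.out = n),
      method = "predictive_margin", model_kind = "HLR"
    )
    as.integer(table(assign_groups(rsrr)$group))
  }
  expect_equal(sizes(1118), c(223L, 672L, 223L))
  expect_equal(sizes(1708), c(341L, 1026L, 341L))
  expect_equal(sizes(1919), c(383L, 1153L, 383L))
  expect_equal(sizes(5), c(1L, 3L, 1L))
  expect_error(sizes(4), class = "readmitr_invalid_input")
})

test_that("top group takes the highest rates and ties break by hospital id", {
  rsrr <- tibble::tibble(
    hospital_id = c("H1", "H2", "H3", "H4", "H5"),
    rsrr = c(0.3, 0.1, 0.3, 0.05, 0.2),
    method = "predictive_margin", model_kind = "HLR"
  )
  g <- assign_groups(rsrr)
  expect_equal(as.character(g$group[g$hospital_id == "H1"]), "top20")
  expect_equal(as.character(g$group[g$hospital_id == "H4"]), "bottom20")
  low_first <- assign_groups(rsrr, highest_first = FALSE)
  expect_equal(as.character(low_first$group[low_first$hospital_id == "H4"]),
               "top20")
})

test_that("cross-tabulation counts, margins and degenerate cases", {
  n <- 10
  rsrr_a <- tibble::tibble(
    hospital_id = sprintf("H%02d", 1:n), rsrr = (1:n) / n,
    method = "predictive_margin", model_kind = "A"
  )
  rsrr_b <- rsrr_a
  rsrr_b$rsrr <- rev(rsrr_b$rsrr)   # reversed ranking
  ga <- assign_groups(rsrr_a)
  gb <- assign_groups(rsrr_b)
  tab <- cross_tabulate(ga, gb)
  # brute-force enumeration over the 10 hospitals
  brute <- table(ga$group, gb$group[match(ga$hospital_id, gb$hospital_id)])
  expect_equal(unclass(tab)[, ], matrix(as.integer(brute), 3, 3,
                                        dimnames = dimnames(tab)))
  # margins reproduce group sizes
  expect_equal(rowSums(tab), c(top20 = 2, middle60 = 6, bottom20 = 2))
  expect_equal(colSums(tab), c(top20 = 2, middle60 = 6, bottom20 = 2))

  # identical rankings give a diagonal table
  tab_id <- cross_tabulate(ga, ga)
  expect_equal(diag(unclass(tab_id)), c(top20 = 2, middle60 = 6, bottom20 = 2))
  expect_equal(sum(unclass(tab_id)) - sum(diag(unclass(tab_id))), 0)

  expect_error(cross_tabulate(ga, gb[1:5, ]),
               class = "readmitr_invalid_input")
})

test_that("reclassification summary reports half-up percentages of the total", {
  # the published AMI cross-tabulation as input
  m <- matrix(c(151L, 72L, 0L,
                72L, 563L, 37L,
                0L, 37L, 186L), 3, 3, byrow = TRUE,
              dimnames = list(c("top20", "middle60", "bottom20"),
                              c("top20", "middle60", "bottom20")))
  tab <- structure(m, class = c("reclassification_table", "matrix"),
                   total = sum(m))
  s <- reclassification_summary(tab)
  expect_equal(s$pct[s$from == "middle60" & s$to == "top20"], 6.4)
  expect_equal(s$pct[s$from == "middle60" & s$to == "bottom20"], 3.3)
  expect_equal(attr(s, "total"), 1118)
  expect_equal(attr(s, "n_reclassified"), sum(s$count))

  # diagonal table: all off-diagonal percentages 0.0
  d <- diag(c(2L, 6L, 2L))
  dimnames(d) <- dimnames(m)
  tab_d <- structure(d, class = c("reclassification_table", "matrix"),
                     total = 10L)
  expect_true(all(reclassification_summary(tab_d)$pct == 0))
})

test_that("margin conservation holds on random group assignments", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    rsrr_a <- tibble::tibble(
      hospital_id = sprintf("H%03d", 1:n), rsrr = runif(n),
      method = "predictive_margin", model_kind = "A"
    )
    rsrr_b <- rsrr_a
    rsrr_b$rsrr <- runif(n)
    ga <- assign_groups(rsrr_a)
    gb <- assign_groups(rsrr_b)
    tab <- cross_tabulate(ga, gb)
    k <- floor(0.2 * n)
    expect_equal(unname(rowSums(tab)), c(k, n - 2 * k, k))
    expect_equal(unname(colSums(tab)), c(k, n - 2 * k, k))
    expect_equal(sum(tab), n)
  }
})
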