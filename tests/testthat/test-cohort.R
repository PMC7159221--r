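# Cohort construction: exclusion cascade, first-admission selection,
# rare-code filtering, comorbidity mapping, stratified splits.

test_that("each exclusion rule removes exactly its marked record in a toy table", {
  # 10 records: four clean plus one per exclusion condition (applied in
  # the cascade order so each rule removes exactly one record); the last
  # record sits alone in an under-sized hospital
  rec <- make_records(
    principal = rep("D1", 10),
    secondary = rep(list(character(0)), 10),
    hospital_id = c(rep("H1", 9), "H2")
  )
  rec$length_of_stay[2] <- 0L
  rec$died[3] <- 1L
  rec$ama[4] <- 1L
  rec$admission_month[5] <- 12L
  rec$transfer_out[6] <- 1L
  rec$age[7] <- 12
  out <- apply_exclusions(rec, condition = "ami", min_hospital_size = 2L)
  expect_equal(out$log$n_removed, rep(1L, 7))
  expect_equal(out$records$admission_id, c("A001", "A008", "A009"))
  expect_equal(attr(out$log, "n_input") - sum(out$log$n_removed),
               attr(out$log, "n_final"))
})

test_that("zero length of stay is excluded only for the AMI cohort", {
  rec <- make_records("D1", list(character(0)))
  rec$length_of_stay <- 0L
  ami <- apply_exclusions(rec, "ami", min_hospital_size = 1L)
  hf <- apply_exclusions(rec, "hf", min_hospital_size = 1L)
  expect_equal(nrow(ami$records), 0L)
  expect_equal(nrow(hf$records), 1L)
  expect_false("zero_length_of_stay" %in% hf$log$rule)
  # cascade order is fixed
  expect_equal(ami$log$rule,
               c("zero_length_of_stay", "died_in_hospital",
                 "against_medical_advice", "december_discharge",
                 "transfer_to_acute_care", "age_under_18",
                 "hospital_under_10_admissions"))
})

test_that("empty input flows through the cascade with all-zero counts", {
  rec <- make_records(character(0), list())
  out <- apply_exclusions(rec, "ami")
  expect_equal(nrow(out$records), 0L)
  expect_true(all(out$log$n_removed == 0L))
})

test_that("principal-diagnosis inclusion restricts to the condition code set", {
  rec <- make_records(c("D1", "D2", "D1"), rep(list(character(0)), 3))
  out <- apply_exclusions(rec, "ami", principal_codes = "D1",
                          min_hospital_size = 1L)
  expect_equal(nrow(out$records), 2L)
  expect_equal(attr(out$log, "n_input"), 2L)
})

test_that("first-admission selection keeps the earliest record per patient", {
  rec <- make_records(rep("D1", 3), rep(list(character(0)), 3))
  rec$patient_id <- c("P1", "P1", "P2")
  rec$admission_month <- c(7L, 3L, 5L)
  out <- select_first_admission(rec)
  expect_equal(out$admission_month[out$patient_id == "P1"], 3L)
  # identity on unique patients
  uni <- make_records(c("D1", "D2"), rep(list(character(0)), 2))
  expect_identical(select_first_admission(uni), uni)
})

test_that("first-admission selection matches a group-by-minimum oracle", {
  sim <- simulate_claims(tiny_config())
  adm <- sim$admissions
  out <- select_first_admission(adm)
  # brute-force oracle: per patient, smallest month; ties by input order
  oracle <- vapply(split(seq_len(nrow(adm)), adm$patient_id), function(idx) {
    idx[which.min(adm$admission_month[idx])]
  }, integer(1))
  expect_setequal(out$admission_id, adm$admission_id[oracle])
  expect_equal(nrow(out), length(unique(adm$patient_id)))
})

test_that("rare-code filtering drops codes, never records", {
  rec <- make_records(
    principal = c("D1", "D1", "D1"),
    secondary = list(c("D2", "D9"), "D2", "D2"),
    procedures = list("P1", "P1", character(0))
  )
  out <- filter_rare_codes(rec, min_count = 2L)
  expect_equal(nrow(out$records), 3L)
  expect_setequal(out$dx_vocab, c("D1", "D2"))
  expect_setequal(out$proc_vocab, "P1")
  expect_false("D9" %in% unlist(out$records$secondary_dx))

  # min_count = 1 keeps everything
  all_kept <- filter_rare_codes(rec, min_count = 1L)
  expect_identical(all_kept$records$secondary_dx, rec$secondary_dx)
  expect_error(filter_rare_codes(rec, min_count = 0L),
               class = "readmitr_invalid_config")
})

test_that("code occurrence counting is per record, matching a brute-force counter", {
  sim <- simulate_claims(tiny_config())
  adm <- sim$admissions[1:150, ]
  out <- filter_rare_codes(adm, min_count = 10L)
  counts <- new.env()
  for (i in seq_len(nrow(adm))) {
    for (cd in unique(c(adm$principal_dx[[i]], adm$secondary_dx[[i]]))) {
      assign(cd, (mget(cd, counts, ifnotfound = 0))[[1]] + 1, counts)
    }
  }
  brute <- unlist(as.list(counts))
  expect_setequal(out$dx_vocab, names(brute)[brute >= 10])
})

test_that("comorbidity mapping is binary and matches a double loop", {
  map <- tibble::tibble(code = c("D1", "D2", "D3"), category = c(4L, 4L, 9L))
  rec <- make_records(
    principal = c("D9", "D9"),
    secondary = list(c("D1", "D2"), "D3")
  )
  m <- map_comorbidities(rec, map)
  expect_equal(dim(m), c(2L, 29L))
  expect_equal(unname(m[1, 4]), 1L)   # two codes, same category: still 1
  expect_equal(unname(m[2, 9]), 1L)
  expect_equal(sum(m), 2L)
  # unmapped record row is all zero
  none <- make_records("D9", list("D8"))
  expect_equal(sum(map_comorbidities(none, map)), 0L)

  # random map + records equals brute-force double loop
  sim <- simulate_claims(tiny_config())
  adm <- sim$admissions[1:80, ]
  smap <- synthetic_comorbidity_map(sim$universe)
  got <- map_comorbidities(adm, smap)
  for (i in seq_len(nrow(adm))) {
    expected <- integer(29)
    for (cd in adm$secondary_dx[[i]]) {
      k <- smap$category[smap$code == cd]
      if (length(k)) expected[k] <- 1L
    }
    expect_equal(unname(got[i, ]), expected)
  }
})

test_that("hospital-stratified split is a partition near 80/10/10", {
  rec <- make_records(rep("D1", 10), rep(list(character(0)), 10))
  out <- split_cohort(rec, seed = 4)
  expect_equal(as.integer(table(out$split)), c(8L, 1L, 1L))

  sim <- simulate_claims(tiny_config())
  adm <- split_cohort(sim$admissions, seed = 4)
  per_h <- table(adm$hospital_id, adm$split)
  for (h in rownames(per_h)) {
    m <- sum(per_h[h, ])
    expect_lt(max(abs(per_h[h, ] - c(0.8, 0.1, 0.1) * m)), 1)
  }
  # determinism and seed sensitivity
  again <- split_cohort(sim$admissions, seed = 4)
  expect_identical(adm$split, again$split)
  other <- split_cohort(sim$admissions, seed = 5)
  expect_false(identical(adm$split, other$split))
  expect_error(split_cohort(rec, proportions = c(0.5, 0.2, 0.2)),
               class = "readmitr_invalid_config")
})

test_that("build_cohort assembles outcome, vocabularies and split", {
  sim <- simulate_claims(tiny_config())
  ch <- build_cohort(sim)
  rec <- ch$records
  expect_s3_class(ch$exclusion_log, "exclusion_log")
  expect_false(any(duplicated(rec$patient_id)))
  expect_true(all(unlist(rec$secondary_dx) %in% ch$dx_vocab))
  expect_true(all(unlist(rec$procedures) %in% ch$proc_vocab))
  expect_equal(rec$unplanned_readmit,
               as.integer(rec$readmit_30d == 1 & rec$planned_readmit == 0))
  expect_true(all(table(rec$hospital_id) >= 10))
})
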