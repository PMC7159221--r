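#' Apply the cohort exclusion cascade
#'
#' Restricts a raw admission table to the condition cohort and applies
#' the exclusion rules sequentially, each to the survivors of the
#' previous rule: zero length of stay (AMI cohorts only), in-hospital
#' death, discharge against medical advice, December discharge (no
#' 30-day follow-up window), transfer to another acute-care hospital,
#' age under 18, and hospitals left with fewer than 10 admissions.
#'
#' @param raw Admission tibble (e.g. `simulate_claims()$admissions`).
#' @param condition `"ami"`, `"hf"` or `"pna"`. Zero length of stay is
#'   excluded only for `"ami"`.
#' @param principal_codes Character vector of principal-diagnosis codes
#'   defining the cohort; records whose `principal_dx` is outside this
#'   set are dropped before the cascade. `NULL` keeps all records.
#' @param min_hospital_size Hospitals with fewer remaining admissions
#'   are dropped (default 10).
#' @return A list with `records` (the surviving tibble) and `log`, an
#'   ordered `exclusion_log` tibble of `(rule, n_removed)` with
#'   attributes `n_input` (post-inclusion count) and `n_final`.
#' @export
apply_exclusions <- function(raw, condition = c("ami", "hf", "pna"),
                             principal_codes = NULL,
                             min_hospital_size = 10L) {
  condition <- match.arg(condition)
  rec <- raw
  if (!is.null(principal_codes)) {
    rec <- rec[rec$principal_dx %in% principal_codes, , drop = FALSE]
  }
  n_input <- nrow(rec)

  rules <- list()
  drop_rule <- function(rec, rule, keep) {
    rules[[length(rules) + 1L]] <<- tibble(rule = rule,
                                           n_removed = sum(!keep))
    rec[keep, , drop = FALSE]
  }

  if (condition == "ami") {
    rec <- drop_rule(rec, "zero_length_of_stay", rec$length_of_stay > 0)
  }
  rec <- drop_rule(rec, "died_in_hospital", rec$died == 0)
  rec <- drop_rule(rec, "against_medical_advice", rec$ama == 0)
  rec <- drop_rule(rec, "december_discharge", rec$admission_month != 12L)
  rec <- drop_rule(rec, "transfer_to_acute_care", rec$transfer_out == 0)
  rec <- drop_rule(rec, "age_under_18", rec$age >= 18)
  hosp_n <- table(rec$hospital_id)
  small <- names(hosp_n)[hosp_n < min_hospital_size]
  rec <- drop_rule(rec, "hospital_under_10_admissions",
                   !(rec$hospital_id %in% small))

  log <- dplyr::bind_rows(rules)
  attr(log, "n_input") <- n_input
  attr(log, "n_final") <- nrow(rec)
  class(log) <- c("exclusion_log", class(log))
  list(records = rec, log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat(sprintf("<exclusion_log> %d -> %d records\n",
              attr(x, "n_input"), attr(x, "n_final")))
  NextMethod()
}

#' Keep each patient's first admission
#'
#' Orders a patient's admissions by `admission_month` (stable input
#' order breaks ties) and keeps the earliest.
#'
#' @param records Admission tibble with `patient_id`, `admission_month`.
#' @return The filtered tibble, one row per patient, original order.
#' @export
select_first_admission <- function(records) {
  if (nrow(records) == 0L) return(records)
  ord <- order(records$patient_id, records$admission_month,
               seq_len(nrow(records)), method = "radix")
  first <- ord[!duplicated(records$patient_id[ord])]
  records[sort(first), , drop = FALSE]
}

#' Restrict code lists to sufficiently frequent codes
#'
#' Counts code occurrences (once per record containing the code) over a
#' reference corpus and removes codes seen fewer than `min_count` times
#' from every record's code lists. Records themselves are never removed.
#'
#' @param records Admission tibble to filter.
#' @param reference Corpus over which occurrence counts are taken
#'   (defaults to `records`; pass the full raw table to mirror counting
#'   over the whole database).
#' @param min_count Minimum occurrence count (default 10).
#' @return A list with `records` (filtered), `dx_vocab`, `proc_vocab`.
#' @export
filter_rare_codes <- function(records, reference = records, min_count = 10L) {
  if (min_count < 1L) {
    abort("`min_count` must be >= 1.", class = "readmitr_invalid_config")
  }
  count_codes <- function(lists) {
    tab <- table(unlist(lists, use.names = FALSE))
    tab
  }
  dx_tab <- count_codes(c(
    lapply(seq_len(nrow(reference)), function(i) {
      unique(c(reference$principal_dx[[i]], reference$secondary_dx[[i]]))
    })
  ))
  proc_tab <- count_codes(lapply(reference$procedures, unique))
  dx_vocab <- sort(names(dx_tab)[dx_tab >= min_count])
  proc_vocab <- sort(names(proc_tab)[proc_tab >= min_count])

  records$secondary_dx <- lapply(records$secondary_dx,
                                 function(v) v[v %in% dx_vocab])
  records$procedures <- lapply(records$procedures,
                               function(v) v[v %in% proc_vocab])
  list(records = records, dx_vocab = dx_vocab, proc_vocab = proc_vocab)
}

#' Binary comorbidity feature matrix
#'
#' Maps each record's diagnosis codes through a comorbidity map (a
#' two-column table: `code`, `category` with categories 1..29) and
#' returns the n x 29 binary indicator matrix: entry (i, k) is 1 iff any
#' mapped diagnosis code of record i falls in category k. Unmapped codes
#' contribute nothing; repeated hits stay binary.
#'
#' @param records Admission tibble.
#' @param map Data frame with columns `code` and `category` (integer
#'   1..29; at most one category per code).
#' @param include_principal Include the principal diagnosis code
#'   (default `FALSE`: secondary codes record the comorbidities).
#' @return Integer matrix `n_records x 29` with column names `cm_01` ..
#'   `cm_29`.
#' @export
map_comorbidities <- function(records, map, include_principal = FALSE) {
  if (anyDuplicated(map$code) > 0L) {
    abort("`map` must assign at most one category per code.",
          class = "readmitr_invalid_config")
  }
  n <- nrow(records)
  out <- matrix(0L, n, 29L,
                dimnames = list(NULL, sprintf("cm_%02d", 1:29)))
  cat_of <- setNames(as.integer(map$category), map$code)
  for (i in seq_len(n)) {
    cs <- records$secondary_dx[[i]]
    if (include_principal) cs <- c(records$principal_dx[[i]], cs)
    ks <- unique(cat_of[cs])
    ks <- ks[!is.na(ks)]
    out[i, ks] <- 1L
  }
  out
}

#' Simplified comorbidity map for synthetic code universes
#'
#' Builds a pluggable comorbidity map from a synthetic code universe:
#' the more prevalent diagnosis codes (top `coverage` fraction by
#' prevalence) are assigned to one of 29 categories by their latent
#' cluster (`(cluster - 1) %% 29 + 1`), emulating how established
#' comorbidity indices cover frequent, clinically grouped codes while
#' leaving rare codes unmapped. Real comorbidity tables in the same
#' two-column format can be dropped in instead.
#'
#' @param universe A `code_universe`.
#' @param coverage Fraction of diagnosis codes (by prevalence rank) that
#'   receive a category (default 0.3).
#' @return Tibble with `code`, `category`.
#' @export
synthetic_comorbidity_map <- function(universe, coverage = 0.3) {
  dx <- universe$codes[universe$codes$type == "dx", ]
  dx <- dx[order(-dx$prevalence), ]
  keep <- head(dx, ceiling(coverage * nrow(dx)))
  tibble(code = keep$code,
         category = ((keep$cluster - 1L) %% 29L) + 1L)
}

#' Hospital-stratified train/validation/test split
#'
#' Within each hospital, records are shuffled (seeded) and allocated to
#' the three sets by largest-remainder rounding of the target
#' proportions, so per-hospital counts deviate from the exact
#' proportions by less than one record.
#'
#' @param records Admission tibble with `hospital_id`.
#' @param proportions Length-3 numeric summing to 1 (train, validation,
#'   test); default `c(0.8, 0.1, 0.1)`.
#' @param seed Integer seed for the within-hospital shuffles.
#' @return `records` with a `split` factor column
#'   (`train`/`validation`/`test`).
#' @export
split_cohort <- function(records, proportions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(proportions) != 3L || abs(sum(proportions) - 1) > 1e-8) {
    abort("`proportions` must be three numbers summing to 1.",
          class = "readmitr_invalid_config")
  }
  labels <- c("train", "validation", "test")
  split <- character(nrow(records))
  with_seed(derive_seed(seed, 101L), {
    for (h in unique(records$hospital_id)) {
      idx <- which(records$hospital_id == h)
      idx <- idx[sample.int(length(idx))]
      m <- length(idx)
      base <- floor(proportions * m)
      rem <- proportions * m - base
      extra <- m - sum(base)
      if (extra > 0L) {
        base[order(-rem)[seq_len(extra)]] <- base[order(-rem)[seq_len(extra)]] + 1L
      }
      split[idx] <- rep(labels, base)
    }
  })
  records$split <- factor(split, levels = labels)
  records
}

#' Build an analysis cohort from raw admissions
#'
#' Runs the full cohort pipeline: exclusion cascade,
#' first-admission-per-patient selection, rare-code filtering (counts
#' taken over the full raw table), the unplanned-readmission outcome
#' (`readmit_30d` and not `planned_readmit`), and the hospital-stratified
#' 80/10/10 split.
#'
#' @param sim A `claims_sim`, or a list with `admissions` and `universe`.
#' @param condition Cohort condition label (defaults to the generator
#'   profile when available).
#' @param min_code_count Rare-code threshold (default 10).
#' @param proportions Split proportions, see [split_cohort()].
#' @param seed Seed for the split.
#' @return A `cohort` list: `records` (with `split` and
#'   `unplanned_readmit`), `dx_vocab`, `proc_vocab`, `exclusion_log`,
#'   `condition`.
#' @export
#' @examples
#' sim <- simulate_claims(generator_config(
#'   n_hospitals = 12, hospital_size_log_mean = log(40), seed = 2
#' ))
#' ch <- build_cohort(sim)
#' table(ch$records$split)
build_cohort <- function(sim, condition = NULL, min_code_count = 10L,
                         proportions = c(0.8, 0.1, 0.1), seed = 1L) {
  condition <- condition %||% sim$config$profile %||% "ami"
  principal_codes <- sim$universe$principal_codes %||% NULL
  excl <- apply_exclusions(sim$admissions, condition = condition,
                           principal_codes = principal_codes)
  rec <- select_first_admission(excl$records)
  filt <- filter_rare_codes(rec, reference = sim$admissions,
                            min_count = min_code_count)
  rec <- filt$records
  rec$unplanned_readmit <- as.integer(
    rec$readmit_30d == 1L & rec$planned_readmit == 0L
  )
  rec <- split_cohort(rec, proportions = proportions, seed = seed)
  structure(
    list(records = rec, dx_vocab = filt$dx_vocab,
         proc_vocab = filt$proc_vocab, exclusion_log = excl$log,
         condition = condition),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %s: %d records, %d hospitals, %d dx + %d proc codes\n",
    x$condition, nrow(x$records), length(unique(x$records$hospital_id)),
    length(x$dx_vocab), length(x$proc_vocab)
  ))
  cat(sprintf("  unplanned 30-day readmission rate: %.3f\n",
              mean(x$records$unplanned_readmit)))
  invisible(x)
}

#' Serialize an exclusion log as JSON
#'
#' @param log An `exclusion_log`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(log, path) {
  jsonlite::write_json(
    list(n_input = attr(log, "n_input"),
         rules = as.data.frame(log),
         n_final = attr(log, "n_final")),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
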