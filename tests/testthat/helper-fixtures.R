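# Shared fixtures: small generator configs and hand-built record tables.

tiny_config <- function(...) {
  defaults <- list(
    n_hospitals = 15, hospital_size_log_mean = log(40),
    hospital_size_log_sd = 0.4, n_dx_codes = 120, n_proc_codes = 40,
    n_clusters = 6, seed = 11
  )
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

# a moderately sized simulation reused by several test files (memoised)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_claims(generator_config(seed = 202))
    }
    cache
  }
})

# minimal record tibble from explicit code lists
make_records <- function(principal, secondary, procedures = NULL,
                         hospital_id = NULL, ...) {
  n <- length(principal)
  procedures <- procedures %||% rep(list(character(0)), n)
  tibble::tibble(
    admission_id = sprintf("A%03d", seq_len(n)),
    patient_id = sprintf("P%03d", seq_len(n)),
    hospital_id = hospital_id %||% rep("H1", n),
    age = rep(70, n), female = rep(0L, n), admission_month = rep(5L, n),
    length_of_stay = rep(3L, n), died = 0L, ama = 0L, transfer_out = 0L,
    principal_dx = principal, secondary_dx = secondary,
    procedures = procedures, ...
  )
}

# brute-force AUC by pair enumeration (independent oracle)
auc_bruteforce <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
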