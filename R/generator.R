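#' Configuration for the synthetic claims generator
#'
#' Builds the parameter set that drives the synthetic admission-record
#' generator. The generator emulates the statistical structure of an
#' all-payer readmission database: hospital clustering of outcomes
#' (log-odds random intercepts), extremely skewed marginal code prevalence
#' (power law, the most frequent diagnosis code reaching ~75% prevalence),
#' variable-length diagnosis/procedure code sets with condition-specific
#' moments, latent disease-cluster co-occurrence structure, and a
#' readmission-generating model with nonlinear (pairwise) code
#' interactions.
#'
#' @param profile Cohort profile: `"ami"` (acute myocardial infarction),
#'   `"hf"` (heart failure) or `"pna"` (pneumonia). Sets age mean/SD,
#'   female fraction, secondary-diagnosis and procedure count moments, and
#'   the baseline readmission rate the intercept is calibrated to.
#' @param n_hospitals Number of hospitals.
#' @param hospital_size_log_mean,hospital_size_log_sd Log-normal
#'   parameters for hospital admission volumes.
#' @param sigma_hospital SD of the hospital log-odds random intercepts.
#' @param n_dx_codes,n_proc_codes Vocabulary sizes for diagnosis and
#'   procedure codes.
#' @param n_clusters Number of latent disease clusters codes belong to.
#' @param zipf_exponent Exponent of the power-law marginal code
#'   prevalence (rank^-zipf_exponent).
#' @param max_prevalence Marginal prevalence of the most frequent code
#'   (the power law is rescaled so rank 1 attains this).
#' @param cluster_tilt Multiplicative weight boost for codes in a
#'   record's active clusters during code sampling; each record activates
#'   1-2 clusters, which induces block co-occurrence structure.
#' @param beta0 Baseline log-odds of readmission. `NULL` (default)
#'   calibrates the intercept at generation time so the marginal
#'   readmission rate matches the profile target (12.0% AMI, 17.7% HF,
#'   14.3% PNA); an explicit value is used as-is.
#' @param beta_age,beta_sex Log-odds coefficients for standardized age
#'   and female sex.
#' @param code_effect_sd Marginal SD of per-code log-odds effects.
#' @param cluster_effect_frac Fraction of the code-effect variance shared
#'   within a cluster (effects are cluster mean + code-level noise; the
#'   marginal law stays Normal(0, code_effect_sd^2)). Shared cluster risk
#'   is what lets co-occurrence embeddings generalize to rare codes.
#' @param interaction_strength Magnitude of within-cluster pairwise code
#'   interaction effects on the log-odds scale. Each cluster draws one
#'   synergy sign shared by its interacting pairs, so the nonlinearity is
#'   coherent at the disease-family level. Zero disables interactions.
#' @param n_interactions Number of interacting code pairs (spread over
#'   clusters, members drawn prevalence-weighted within cluster).
#' @param exclusion_rates Named list of probabilities exercising the
#'   cohort exclusion rules: `died`, `ama`, `transfer`, `zero_los`,
#'   `december` (probability of a December discharge), `minor_age`
#'   (fraction of records with age < 18).
#' @param repeat_frac Fraction of patients with 2-4 admissions (exercises
#'   first-admission selection).
#' @param planned_frac Fraction of readmissions flagged as planned.
#' @param seed Integer seed; every generator stage derives its stream
#'   from it.
#'
#' @return A `generator_config` list.
#' @export
#' @examples
#' cfg <- generator_config(n_hospitals = 20, seed = 1)
#' cfg$age_mean
generator_config <- function(profile = c("ami", "hf", "pna"),
                             n_hospitals = 300,
                             hospital_size_log_mean = log(150),
                             hospital_size_log_sd = 0.6,
                             sigma_hospital = 0.3,
                             n_dx_codes = 1500,
                             n_proc_codes = 500,
                             n_clusters = 20,
                             zipf_exponent = 1.3,
                             max_prevalence = 0.75,
                             cluster_tilt = 8,
                             beta0 = NULL,
                             beta_age = 0.25,
                             beta_sex = 0.15,
                             code_effect_sd = 0.3,
                             cluster_effect_frac = 0.75,
                             interaction_strength = 0.5,
                             n_interactions = 200,
                             exclusion_rates = list(),
                             repeat_frac = 0.10,
                             planned_frac = 0.05,
                             seed = 1L) {
  profile <- match.arg(profile)

  # Condition profiles: age mean/SD and female fraction from the cohort
  # summaries; secondary-dx and procedure count moments (negative binomial,
  # truncated at 29 / 15); target marginal readmission rate.
  profiles <- list(
    ami = list(age_mean = 66.8, age_sd = 13.7, female_frac = 0.376,
               dx_mean = 12.4, dx_sd = 6.1, proc_mean = 5.6, proc_sd = 3.3,
               target_rate = 0.120),
    hf  = list(age_mean = 72.5, age_sd = 14.2, female_frac = 0.489,
               dx_mean = 15.1, dx_sd = 5.5, proc_mean = 1.1, proc_sd = 1.9,
               target_rate = 0.177),
    pna = list(age_mean = 69.2, age_sd = 16.8, female_frac = 0.518,
               dx_mean = 12.7, dx_sd = 5.8, proc_mean = 0.7, proc_sd = 1.5,
               target_rate = 0.143)
  )
  prof <- profiles[[profile]]

  rates <- list(died = 0.05, ama = 0.012, transfer = 0.02, zero_los = 0.015,
                december = 1 / 12, minor_age = 0.002)
  rates[names(exclusion_rates)] <- exclusion_rates

  cfg <- c(
    list(profile = profile),
    prof,
    list(
      n_hospitals = n_hospitals,
      hospital_size_log_mean = hospital_size_log_mean,
      hospital_size_log_sd = hospital_size_log_sd,
      sigma_hospital = sigma_hospital,
      n_dx_codes = n_dx_codes,
      n_proc_codes = n_proc_codes,
      n_clusters = n_clusters,
      zipf_exponent = zipf_exponent,
      max_prevalence = max_prevalence,
      cluster_tilt = cluster_tilt,
      beta0 = beta0,
      beta_age = beta_age,
      beta_sex = beta_sex,
      code_effect_sd = code_effect_sd,
      cluster_effect_frac = cluster_effect_frac,
      interaction_strength = interaction_strength,
      n_interactions = n_interactions,
      exclusion_rates = rates,
      repeat_frac = repeat_frac,
      planned_frac = planned_frac,
      seed = as.integer(seed)
    )
  )
  class(cfg) <- c("generator_config", "list")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot_count(cfg$n_hospitals, "n_hospitals")
  stopifnot_count(cfg$n_dx_codes, "n_dx_codes")
  stopifnot_count(cfg$n_proc_codes, "n_proc_codes")
  stopifnot_count(cfg$n_clusters, "n_clusters")
  if (cfg$zipf_exponent <= 0) {
    abort("`zipf_exponent` must be > 0.", class = "readmitr_invalid_config")
  }
  if (cfg$sigma_hospital < 0) {
    abort("`sigma_hospital` must be >= 0.", class = "readmitr_invalid_config")
  }
  if (cfg$n_clusters > cfg$n_dx_codes) {
    abort("`n_clusters` cannot exceed `n_dx_codes`.",
          class = "readmitr_invalid_config")
  }
  stopifnot_scalar_prob(cfg$max_prevalence, "max_prevalence")
  for (nm in names(cfg$exclusion_rates)) {
    stopifnot_scalar_prob(cfg$exclusion_rates[[nm]],
                          paste0("exclusion_rates$", nm))
  }
  stopifnot_scalar_prob(cfg$repeat_frac, "repeat_frac")
  stopifnot_scalar_prob(cfg$planned_frac, "planned_frac")
  invisible(cfg)
}

#' Generate the hospital table
#'
#' Draws hospital volumes from a log-normal (rounded, floored at 1) and
#' hospital-specific log-odds intercepts `u` i.i.d. Normal(0,
#' sigma_hospital^2).
#'
#' @param config A [generator_config()].
#' @return A tibble with `hospital_id`, `n_admissions`, `u`.
#' @export
generate_hospitals <- function(config) {
  validate_generator_config(config)
  with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_hospitals
    sizes <- pmax(1L, as.integer(round(rlnorm(
      n, config$hospital_size_log_mean, config$hospital_size_log_sd
    ))))
    u <- rnorm(n, 0, config$sigma_hospital)
    tibble(
      hospital_id = sprintf("H%04d", seq_len(n)),
      n_admissions = sizes,
      u = u
    )
  })
}

#' Generate the synthetic code universe
#'
#' Creates diagnosis and procedure code vocabularies with power-law
#' marginal prevalences (rank^-zipf_exponent rescaled so rank 1 attains
#' `max_prevalence`), a round-robin partition of codes into latent
#' disease clusters, per-code log-odds effects (marginally Normal(0,
#' code_effect_sd^2), with a within-cluster shared component), and
#' within-cluster pairwise interaction effects of magnitude
#' `interaction_strength` (random sign), placed among the more prevalent
#' codes of each cluster so the pairs actually co-occur.
#'
#' @param config A [generator_config()].
#' @return A `code_universe` list with tibbles `codes` (code, type,
#'   cluster, prevalence, effect), `interactions` (code_a, code_b,
#'   effect) and the principal-diagnosis condition code set.
#' @export
generate_code_universe <- function(config) {
  validate_generator_config(config)
  with_seed(derive_seed(config$seed, 2L), {
    zipf_prev <- function(n) {
      config$max_prevalence * seq_len(n)^(-config$zipf_exponent)
    }
    dx_codes <- sprintf("D%04d", seq_len(config$n_dx_codes))
    proc_codes <- sprintf("P%04d", seq_len(config$n_proc_codes))
    codes <- tibble(
      code = c(dx_codes, proc_codes),
      type = rep(c("dx", "proc"), c(config$n_dx_codes, config$n_proc_codes)),
      rank = c(seq_len(config$n_dx_codes), seq_len(config$n_proc_codes)),
      prevalence = c(zipf_prev(config$n_dx_codes),
                     zipf_prev(config$n_proc_codes))
    )
    # round-robin by prevalence rank: every cluster spans the prevalence range
    codes$cluster <- ((codes$rank - 1L) %% config$n_clusters) + 1L

    sdv <- config$code_effect_sd
    frac <- config$cluster_effect_frac
    cluster_base <- rnorm(config$n_clusters, 0, sdv * sqrt(frac))
    codes$effect <- cluster_base[codes$cluster] +
      rnorm(nrow(codes), 0, sdv * sqrt(1 - frac))
    # center effects (prevalence-weighted, per code type) so the expected
    # per-record effect sum is ~0 in every universe; keeps the marginal
    # readmission rate stable across seeds so the calibrated intercept holds
    for (ty in c("dx", "proc")) {
      sel <- codes$type == ty
      codes$effect[sel] <- codes$effect[sel] -
        stats::weighted.mean(codes$effect[sel], codes$prevalence[sel])
    }

    # condition set: the most frequent diagnosis codes of cluster 1 act as
    # the principal-diagnosis codes defining the cohort
    dx <- codes[codes$type == "dx", ]
    cluster1 <- dx[dx$cluster == 1L, ]
    principal_codes <- head(cluster1$code[order(cluster1$rank)], 5L)

    interactions <- tibble(code_a = character(), code_b = character(),
                           effect = double())
    if (config$interaction_strength > 0 && config$n_interactions > 0) {
      # one synergy sign per cluster: codes of a disease family compound
      # risk coherently, so the nonlinearity lives at the cluster level
      # (recoverable from co-occurrence structure) rather than in
      # arbitrary code pairs
      cluster_sign <- sample(c(-1, 1), config$n_clusters, replace = TRUE)
      picks <- vector("list", config$n_interactions)
      for (k in seq_len(config$n_interactions)) {
        cl <- ((k - 1L) %% config$n_clusters) + 1L
        pool <- dx[dx$cluster == cl, ]
        # prevalence-weighted pair: frequent pairs carry most of the
        # nonlinear signal, rarer ones reward models that share strength
        pair <- sample(pool$code, 2L, prob = pool$prevalence)
        picks[[k]] <- tibble(
          code_a = min(pair), code_b = max(pair),
          effect = cluster_sign[cl] * config$interaction_strength
        )
      }
      interactions <- dplyr::distinct(
        dplyr::bind_rows(picks), .data$code_a, .data$code_b,
        .keep_all = TRUE
      )
    }

    structure(
      list(codes = codes[, c("code", "type", "cluster", "prevalence", "effect")],
           interactions = interactions,
           principal_codes = principal_codes),
      class = "code_universe"
    )
  })
}

#' @export
print.code_universe <- function(x, ...) {
  n_dx <- sum(x$codes$type == "dx")
  n_proc <- sum(x$codes$type == "proc")
  cat(sprintf(
    "<code_universe> %d dx + %d proc codes, %d clusters, %d interacting pairs\n",
    n_dx, n_proc, length(unique(x$codes$cluster)), nrow(x$interactions)
  ))
  invisible(x)
}

# negative binomial size parameter from mean/sd; falls back to Poisson when
# the target is not overdispersed
rcount <- function(n, mean, sd) {
  if (sd^2 > mean) {
    size <- mean^2 / (sd^2 - mean)
    rnbinom(n, size = size, mu = mean)
  } else {
    rpois(n, mean)
  }
}

#' Generate raw admission records
#'
#' Draws one row per admission for every hospital in `hospitals`:
#' demographics from the active cohort profile, variable-length secondary
#' diagnosis (<= 29) and procedure (<= 15) code sets sampled from a
#' cluster-tilted prevalence distribution (each record activates 1-2
#' latent clusters), a principal diagnosis from the condition code set,
#' discharge disposition flags and months driven by `exclusion_rates`,
#' and repeat admissions for a fraction of patients.
#'
#' @param config A [generator_config()].
#' @param hospitals Output of [generate_hospitals()].
#' @param universe Output of [generate_code_universe()].
#' @return A tibble of admission records (no outcome yet); see
#'   [generate_outcomes()].
#' @export
generate_admissions <- function(config, hospitals, universe) {
  validate_generator_config(config)
  if (!is.data.frame(hospitals) || nrow(hospitals) == 0L) {
    abort("`hospitals` must be a non-empty hospital table.",
          class = "readmitr_invalid_input")
  }
  with_seed(derive_seed(config$seed, 3L), {
    rates <- config$exclusion_rates

    # --- patients: a fraction have 2-4 admissions, within one hospital ---
    slots <- hospitals$n_admissions
    pat_hosp_l <- vector("list", length(slots))
    pat_k_l <- vector("list", length(slots))
    for (h in seq_along(slots)) {
      m <- slots[h]
      k <- ifelse(runif(m) < config$repeat_frac,
                  sample(2:4, m, replace = TRUE), 1L)
      cum <- cumsum(k)
      np <- which(cum >= m)[1]
      k <- k[seq_len(np)]
      k[np] <- k[np] - (cum[np] - m)
      pat_hosp_l[[h]] <- rep.int(h, np)
      pat_k_l[[h]] <- as.integer(k)
    }
    pat_hosp <- unlist(pat_hosp_l, use.names = FALSE)
    pat_k <- unlist(pat_k_l, use.names = FALSE)
    n_pat <- length(pat_k)
    n <- sum(pat_k)

    # patient-level attributes
    p_age <- rnorm(n_pat, config$age_mean, config$age_sd)
    p_age <- pmax(p_age, 18)
    minors <- runif(n_pat) < rates$minor_age
    p_age[minors] <- runif(sum(minors), 1, 17.5)
    p_female <- as.integer(runif(n_pat) < config$female_frac)

    rec_pat <- rep(seq_len(n_pat), pat_k)
    rec_hosp <- rep(pat_hosp, pat_k)

    # admission month: December probability from the exclusion rates, the
    # remaining mass uniform over Jan-Nov
    month_probs <- c(rep((1 - rates$december) / 11, 11), rates$december)
    admission_month <- sample.int(12L, n, replace = TRUE, prob = month_probs)

    length_of_stay <- 1L + rpois(n, 4)
    length_of_stay[runif(n) < rates$zero_los] <- 0L
    died <- as.integer(runif(n) < rates$died)
    ama <- as.integer(runif(n) < rates$ama)
    transfer_out <- as.integer(runif(n) < rates$transfer)

    # --- code sampling -------------------------------------------------
    codes <- universe$codes
    dx <- codes[codes$type == "dx", ]
    pr <- codes[codes$type == "proc", ]
    n_cl <- config$n_clusters
    tilt <- config$cluster_tilt

    dx_n <- pmin(rcount(n, config$dx_mean, config$dx_sd), 29L)
    proc_n <- pmin(rcount(n, config$proc_mean, config$proc_sd), 15L)

    # active clusters per record: 1 or 2
    two <- runif(n) < 0.5
    cl1 <- sample.int(n_cl, n, replace = TRUE)
    cl2 <- ifelse(two, sample.int(n_cl, n, replace = TRUE), cl1)

    principal_dx <- sample(
      universe$principal_codes, n, replace = TRUE,
      prob = dx$prevalence[match(universe$principal_codes, dx$code)]
    )
    prin_idx <- match(principal_dx, dx$code)

    # weight matrix per cluster: column k = weights with cluster k tilted
    w_dx <- outer(dx$prevalence,
                  rep(1, n_cl)) * (1 + (tilt - 1) *
                  outer(dx$cluster, seq_len(n_cl), "=="))
    w_pr <- outer(pr$prevalence,
                  rep(1, n_cl)) * (1 + (tilt - 1) *
                  outer(pr$cluster, seq_len(n_cl), "=="))

    secondary_dx <- vector("list", n)
    procedures <- vector("list", n)
    for (i in seq_len(n)) {
      w <- w_dx[, cl1[i]] + w_dx[, cl2[i]]
      w[prin_idx[i]] <- 0
      k <- dx_n[i]
      secondary_dx[[i]] <- if (k > 0L) {
        dx$code[sample.int(nrow(dx), k, prob = w)]
      } else {
        character(0)
      }
      kp <- proc_n[i]
      procedures[[i]] <- if (kp > 0L) {
        wp <- w_pr[, cl1[i]] + w_pr[, cl2[i]]
        pr$code[sample.int(nrow(pr), kp, prob = wp)]
      } else {
        character(0)
      }
    }

    tibble(
      admission_id = sprintf("A%07d", seq_len(n)),
      patient_id = sprintf("%s-P%06d", hospitals$hospital_id[rec_hosp], rec_pat),
      hospital_id = hospitals$hospital_id[rec_hosp],
      age = p_age[rec_pat],
      female = p_female[rec_pat],
      admission_month = admission_month,
      length_of_stay = length_of_stay,
      died = died,
      ama = ama,
      transfer_out = transfer_out,
      principal_dx = principal_dx,
      secondary_dx = secondary_dx,
      procedures = procedures
    )
  })
}

# sparse record x code indicator matrix over `codes` (character vector);
# includes principal + secondary + procedures by default
record_code_matrix <- function(records, codes,
                               include = c("principal", "secondary", "procedures")) {
  n <- nrow(records)
  idx_i <- integer(0)
  idx_j <- integer(0)
  per_record <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- character(0)
    if ("principal" %in% include) cs <- c(cs, records$principal_dx[[i]])
    if ("secondary" %in% include) cs <- c(cs, records$secondary_dx[[i]])
    if ("procedures" %in% include) cs <- c(cs, records$procedures[[i]])
    per_record[[i]] <- unique(match(cs, codes))
  }
  lens <- vapply(per_record, function(x) sum(!is.na(x)), integer(1))
  idx_j <- unlist(lapply(per_record, function(x) x[!is.na(x)]), use.names = FALSE)
  idx_i <- rep(seq_len(n), lens)
  Matrix::sparseMatrix(i = idx_i, j = idx_j, x = 1,
                       dims = c(n, length(codes)))
}

#' Attach ground-truth readmission probabilities and sampled labels
#'
#' The readmission-generating model is a logistic model on standardized
#' age, sex, additive per-code effects, within-cluster pairwise code
#' interactions and the hospital random intercept:
#' `logit(p) = beta0 + beta_age * z_age + beta_sex * female +
#' sum(effects) + sum(interactions) + u_hospital`. Labels are Bernoulli
#' draws from `true_p`; a fraction of readmissions is flagged planned.
#'
#' @param admissions Output of [generate_admissions()].
#' @param hospitals,universe,config Matching generator objects.
#' @return `admissions` with `true_p`, `readmit_30d`, `planned_readmit`.
#' @export
generate_outcomes <- function(admissions, hospitals, universe, config) {
  validate_generator_config(config)
  if (!all(admissions$hospital_id %in% hospitals$hospital_id)) {
    abort("every `hospital_id` must have an intercept in `hospitals`.",
          class = "readmitr_invalid_input")
  }
  with_seed(derive_seed(config$seed, 4L), {
    codes <- universe$codes
    A <- record_code_matrix(admissions, codes$code)
    eff <- as.numeric(A %*% codes$effect)

    inter <- 0
    if (nrow(universe$interactions) > 0) {
      ia <- match(universe$interactions$code_a, codes$code)
      ib <- match(universe$interactions$code_b, codes$code)
      inter <- as.numeric(
        (A[, ia, drop = FALSE] * A[, ib, drop = FALSE]) %*%
          universe$interactions$effect
      )
    }

    z_age <- (admissions$age - config$age_mean) / config$age_sd
    u <- hospitals$u[match(admissions$hospital_id, hospitals$hospital_id)]
    rest <- config$beta_age * z_age + config$beta_sex * admissions$female +
      eff + inter + u
    # with beta0 = NULL the intercept is calibrated on this universe so the
    # marginal readmission rate hits the profile target
    beta0 <- config$beta0 %||% stats::uniroot(
      function(b) mean(plogis(b + rest)) - config$target_rate,
      interval = c(-12, 6), extendInt = "yes"
    )$root
    eta <- beta0 + rest
    true_p <- plogis(eta)

    readmit <- rbinom(nrow(admissions), 1L, true_p)
    planned <- integer(nrow(admissions))
    planned[readmit == 1L] <-
      as.integer(runif(sum(readmit)) < config$planned_frac)

    admissions$true_p <- true_p
    admissions$readmit_30d <- readmit
    admissions$planned_readmit <- planned
    attr(admissions, "beta0_used") <- beta0
    admissions
  })
}

#' Run the full synthetic claims generator
#'
#' Convenience wrapper: hospitals, code universe, admissions and
#' outcomes, all derived from `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A `claims_sim` list with `admissions`, `hospitals`,
#'   `universe`, `config`.
#' @export
#' @examples
#' sim <- simulate_claims(generator_config(
#'   n_hospitals = 10, hospital_size_log_mean = log(30), seed = 1
#' ))
#' nrow(sim$admissions)
simulate_claims <- function(config) {
  hospitals <- generate_hospitals(config)
  universe <- generate_code_universe(config)
  admissions <- generate_admissions(config, hospitals, universe)
  admissions <- generate_outcomes(admissions, hospitals, universe, config)
  structure(
    list(admissions = admissions, hospitals = hospitals,
         universe = universe, config = config),
    class = "claims_sim"
  )
}

#' @export
print.claims_sim <- function(x, ...) {
  cat(sprintf(
    "<claims_sim> %d admissions, %d hospitals, profile '%s', seed %d\n",
    nrow(x$admissions), nrow(x$hospitals), x$config$profile, x$config$seed
  ))
  invisible(x)
}

#' Write / read a claims table as CSV
#'
#' The admission table is written with code list-columns flattened to
#' space-separated strings; ground-truth columns (`true_p`, hospital `u`)
#' go to a separate `truth.csv` sidecar so that model-fitting code cannot
#' accidentally consume them.
#'
#' @param sim A `claims_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_claims <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  adm <- sim$admissions
  flat <- adm[setdiff(names(adm), c("secondary_dx", "procedures", "true_p"))]
  flat$secondary_dx <- vapply(adm$secondary_dx, paste, character(1),
                              collapse = " ")
  flat$procedures <- vapply(adm$procedures, paste, character(1),
                            collapse = " ")
  write.csv(flat, file.path(dir, "admissions.csv"), row.names = FALSE)
  write.csv(sim$hospitals[c("hospital_id", "n_admissions")],
            file.path(dir, "hospitals.csv"), row.names = FALSE)
  truth <- data.frame(admission_id = adm$admission_id, true_p = adm$true_p)
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  write.csv(data.frame(hospital_id = sim$hospitals$hospital_id,
                       u = sim$hospitals$u),
            file.path(dir, "truth_hospitals.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_claims
#' @export
read_claims <- function(dir) {
  flat <- read.csv(file.path(dir, "admissions.csv"),
                   stringsAsFactors = FALSE)
  split_codes <- function(x) {
    lapply(strsplit(x, " ", fixed = TRUE),
           function(v) v[nzchar(v)])
  }
  flat$secondary_dx <- split_codes(flat$secondary_dx)
  flat$procedures <- split_codes(flat$procedures)
  as_tibble(flat)
}
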