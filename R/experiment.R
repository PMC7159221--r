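#' Configuration for an end-to-end experiment
#'
#' Bundles the generator settings and the model/embedding
#' hyperparameters for [run_experiment()]. The defaults are desk-scale:
#' ~50k admissions, a 2,000-code vocabulary (1,500 diagnosis + 500
#' procedure), 50-d diagnosis / 25-d procedure embeddings and reduced
#' network widths, sized so the full four-model comparison runs on one
#' CPU in minutes (see the methods vignette).
#'
#' @param gen A [generator_config()].
#' @param dim_dx,dim_proc Embedding dimensions.
#' @param glove_epochs GloVe training epochs.
#' @param ffnn_hidden Feed-forward hidden widths.
#' @param ds_hidden,ds_head_hidden Deep-set phi/rho and head widths.
#' @param gbt_rounds,gbt_early_stop Boosting round cap and early
#'   stopping.
#' @param max_epochs,patience,batch_size Network training schedule.
#' @param n_model_seeds Number of seeded training replicates for the
#'   stochastic trainers.
#' @param min_code_count Rare-code threshold.
#' @param age_min Optional minimum age (e.g. 65 for the elderly
#'   sensitivity analysis); `NULL` keeps all adults.
#' @param seed Master seed for split, embeddings and model seeds.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(gen = generator_config(),
                              dim_dx = 50, dim_proc = 25,
                              glove_epochs = 40,
                              ffnn_hidden = c(256, 64),
                              ds_hidden = 64, ds_head_hidden = 64,
                              gbt_rounds = 20000, gbt_early_stop = 200,
                              max_epochs = 100, patience = 10,
                              batch_size = 256,
                              n_model_seeds = 5,
                              min_code_count = 10,
                              age_min = NULL,
                              seed = 1L) {
  structure(
    list(gen = gen, dim_dx = dim_dx, dim_proc = dim_proc,
         glove_epochs = glove_epochs, ffnn_hidden = ffnn_hidden,
         ds_hidden = ds_hidden, ds_head_hidden = ds_head_hidden,
         gbt_rounds = gbt_rounds, gbt_early_stop = gbt_early_stop,
         max_epochs = max_epochs, patience = patience,
         batch_size = batch_size, n_model_seeds = n_model_seeds,
         min_code_count = min_code_count, age_min = age_min,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Run the full readmission-modelling experiment
#'
#' Generate synthetic claims, build the cohort, fit embeddings on the
#' non-test records, train the four risk models, evaluate test-set AUC
#' (the stochastic network trainers are refitted under
#' `n_model_seeds` seeds; the hierarchical and boosted models are
#' deterministic given the data and fitted once), compute
#' predictive-margin risk-standardized rates for the hierarchical and
#' deep-set models over the whole cohort, assign 20/60/20 groups and
#' cross-tabulate them, and compare margin standardization against the
#' predicted-over-expected ratio for the hierarchical model.
#'
#' @param config An [experiment_config()].
#' @param sim Optionally, a pre-generated `claims_sim` matching
#'   `config$gen` (avoids regenerating when the caller already has one).
#' @param quiet Suppress progress messages.
#' @return An `experiment_report` list; see Details.
#' @export
run_experiment <- function(config = experiment_config(), sim = NULL,
                           quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed

  say("generating synthetic claims (seed %d) ...", config$gen$seed)
  sim <- sim %||% simulate_claims(config$gen)
  cohort <- build_cohort(sim, min_code_count = config$min_code_count,
                         seed = derive_seed(seed, 1L))
  rec <- cohort$records
  if (!is.null(config$age_min)) {
    rec <- rec[rec$age >= config$age_min, , drop = FALSE]
  }
  is_train <- rec$split == "train"
  is_val <- rec$split == "validation"
  is_test <- rec$split == "test"
  y <- rec$unplanned_readmit
  say("cohort: %d records (%d train / %d val / %d test), rate %.3f",
      nrow(rec), sum(is_train), sum(is_val), sum(is_test), mean(y))

  age_center <- mean(rec$age[is_train])
  age_scale <- sd(rec$age[is_train])

  say("fitting GloVe embeddings (%d-d dx, %d-d proc) ...",
      config$dim_dx, config$dim_proc)
  emb <- fit_code_embeddings(
    rec[!is_test, , drop = FALSE], cohort$dx_vocab, cohort$proc_vocab,
    dim_dx = config$dim_dx, dim_proc = config$dim_proc,
    n_epochs = config$glove_epochs, seed = derive_seed(seed, 2L)
  )

  Xcode <- build_code_features(rec, cohort$dx_vocab, cohort$proc_vocab,
                               age_center, age_scale)
  cm_map <- synthetic_comorbidity_map(sim$universe)
  Xhlr <- build_hlr_features(rec, cm_map, age_center, age_scale)
  hosp_levels <- sort(unique(rec$hospital_id))
  ds_inputs <- build_deepset_inputs(rec, emb$dx, emb$proc, hosp_levels,
                                    age_center, age_scale)

  idx_tr <- which(is_train)
  idx_va <- which(is_val)
  idx_te <- which(is_test)

  aucs <- list()
  add_auc <- function(model_kind, seed_used, scores) {
    aucs[[length(aucs) + 1L]] <<- tibble(
      model = model_kind, seed = seed_used,
      auc = compute_auc(y[idx_te], scores)
    )
  }

  say("fitting hierarchical logistic regression ...")
  hlr <- fit_hlr(Xhlr[idx_tr, , drop = FALSE], rec$hospital_id[idx_tr],
                 y[idx_tr])
  add_auc("HLR", NA_integer_,
          predict(hlr, Xhlr[idx_te, , drop = FALSE],
                  hospital_ids = rec$hospital_id[idx_te]))

  say("fitting gradient-boosted trees (<= %d rounds) ...",
      config$gbt_rounds)
  gbt <- fit_gbt(Xcode[idx_tr, , drop = FALSE], y[idx_tr],
                 Xcode[idx_va, , drop = FALSE], y[idx_va],
                 n_rounds = config$gbt_rounds,
                 early_stopping_rounds = config$gbt_early_stop,
                 seed = derive_seed(seed, 3L))
  add_auc("GBT", NA_integer_, predict(gbt, Xcode[idx_te, , drop = FALSE]))

  meds_fits <- list()
  for (s in seq_len(config$n_model_seeds)) {
    ms <- derive_seed(seed, 40L + s)
    say("network replicate %d/%d (seed %d) ...", s,
        config$n_model_seeds, ms)
    ffnn <- fit_ffnn(Xcode[idx_tr, , drop = FALSE], y[idx_tr],
                     Xcode[idx_va, , drop = FALSE], y[idx_va],
                     hidden = config$ffnn_hidden,
                     batch_size = config$batch_size,
                     max_epochs = config$max_epochs,
                     patience = config$patience, seed = ms)
    add_auc("FFNN", ms, predict(ffnn, Xcode[idx_te, , drop = FALSE]))

    meds <- fit_deepset(subset_deepset_inputs(ds_inputs, idx_tr),
                        subset_deepset_inputs(ds_inputs, idx_va),
                        emb$dx, emb$proc,
                        hidden = config$ds_hidden,
                        head_hidden = config$ds_head_hidden,
                        batch_size = config$batch_size,
                        max_epochs = config$max_epochs,
                        patience = config$patience, seed = ms)
    meds_fits[[s]] <- meds
    add_auc("ME-DS", ms,
            predict(meds, subset_deepset_inputs(ds_inputs, idx_te)))
  }

  auc_tbl <- dplyr::bind_rows(aucs)
  auc_summary <- auc_tbl |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_auc = mean(.data$auc), n_fits = dplyr::n(),
                     .groups = "drop")

  # risk standardization with the deep-set replicate that validated best
  best_meds <- meds_fits[[which.min(vapply(
    meds_fits, function(m) m$val_loss[m$best_epoch], numeric(1)
  ))]]

  say("computing risk-standardized rates ...")
  rsrr_hlr <- assign_groups(predictive_margin_rsrr(hlr, Xhlr))
  rsrr_meds <- assign_groups(predictive_margin_rsrr(best_meds, ds_inputs))
  common <- intersect(rsrr_hlr$hospital_id, rsrr_meds$hospital_id)
  reclass <- cross_tabulate(
    assign_groups(rsrr_meds[rsrr_meds$hospital_id %in% common, ]),
    assign_groups(rsrr_hlr[rsrr_hlr$hospital_id %in% common, ])
  )
  rsrr_ratio <- ratio_rsrr(hlr, Xhlr, rec$hospital_id, y)
  both <- dplyr::inner_join(
    rsrr_hlr[c("hospital_id", "rsrr")], rsrr_ratio[c("hospital_id", "rsrr")],
    by = "hospital_id", suffix = c("_margin", "_ratio")
  )
  # degenerate (constant) rsrr vectors can arise in toy runs; report NA
  ratio_margin_spearman <- suppressWarnings(
    stats::cor(both$rsrr_margin, both$rsrr_ratio, method = "spearman")
  )

  structure(
    list(
      auc = auc_tbl, auc_summary = auc_summary,
      rsrr = dplyr::bind_rows(rsrr_hlr, rsrr_meds),
      rsrr_ratio = rsrr_ratio,
      ratio_margin_spearman = ratio_margin_spearman,
      reclassification = reclass,
      reclass_summary = reclassification_summary(reclass),
      cohort_summary = tibble(
        n_records = nrow(rec),
        n_hospitals = length(unique(rec$hospital_id)),
        readmission_rate = mean(y),
        n_dx_codes = length(cohort$dx_vocab),
        n_proc_codes = length(cohort$proc_vocab)
      ),
      exclusion_log = cohort$exclusion_log,
      models = list(hlr = hlr, gbt = gbt, meds = best_meds),
      config = config
    ),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("== readmission experiment report ==\n")
  cat(sprintf("cohort: %d records, %d hospitals, rate %.3f\n",
              x$cohort_summary$n_records, x$cohort_summary$n_hospitals,
              x$cohort_summary$readmission_rate))
  cat("\ntest-set AUC (mean over fits):\n")
  print(as.data.frame(x$auc_summary), row.names = FALSE)
  cat(sprintf("\nmargin vs ratio standardization, Spearman rho: %.3f\n",
              x$ratio_margin_spearman))
  cat("\nreclassification (rows ME-DS, cols HLR):\n")
  print(x$reclassification)
  invisible(x)
}

#' Write an experiment report to disk
#'
#' JSON (machine-readable: AUCs, RSRR tables, reclassification counts,
#' configuration) plus a Markdown summary; histogram bin data for the
#' RSRR distributions is included for exact re-plotting.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hist_data <- report$rsrr |>
    dplyr::group_by(.data$model_kind) |>
    dplyr::group_modify(~ rsrr_histogram(.x)) |>
    dplyr::ungroup()
  payload <- list(
    auc = report$auc, auc_summary = report$auc_summary,
    rsrr = report$rsrr,
    ratio_margin_spearman = report$ratio_margin_spearman,
    reclassification = as.data.frame(unclass(report$reclassification)),
    reclass_summary = report$reclass_summary,
    cohort_summary = report$cohort_summary,
    rsrr_histograms = hist_data,
    config = report$config[setdiff(names(report$config), "gen")],
    generator = unclass(report$config$gen)
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  md <- c(
    "# Readmission experiment report", "",
    sprintf("- records: %d; hospitals: %d; unplanned readmission rate: %.3f",
            report$cohort_summary$n_records,
            report$cohort_summary$n_hospitals,
            report$cohort_summary$readmission_rate),
    "", "## Test-set AUC", "",
    knit_simple_table(report$auc_summary),
    "", "## Reclassification (rows ME-DS, cols HLR)", "",
    knit_simple_table(as.data.frame(unclass(report$reclassification))),
    "",
    sprintf("Margin vs ratio standardization Spearman rho: %.3f",
            report$ratio_margin_spearman)
  )
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

# minimal markdown table without extra dependencies
knit_simple_table <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(round(v, 4)))
  header <- paste0("| ", paste(colnames(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

#' Histogram bins for an RSRR distribution
#'
#' @param rsrr An RSRR tibble (or any data frame with an `rsrr`
#'   column).
#' @param bins Number of bins.
#' @return Tibble with `bin_left`, `bin_right`, `count`.
#' @export
rsrr_histogram <- function(rsrr, bins = 30) {
  h <- graphics::hist(rsrr$rsrr, breaks = bins, plot = FALSE)
  tibble(bin_left = h$breaks[-length(h$breaks)],
         bin_right = h$breaks[-1], count = h$counts)
}
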