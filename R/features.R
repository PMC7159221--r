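# Feature construction shared by the risk models.

#' Dummy-coded code feature matrix
#'
#' Sparse record-by-feature matrix: one binary indicator per vocabulary
#' code (1 if present in the record's principal/secondary diagnoses or
#' procedures, 0 if absent) plus standardized age and the female flag.
#'
#' @param records Admission tibble.
#' @param dx_vocab,proc_vocab Code vocabularies.
#' @param age_center,age_scale Standardization constants for age; fix
#'   them from the training split and reuse at prediction time.
#' @return A `dgCMatrix` with named columns.
#' @export
build_code_features <- function(records, dx_vocab, proc_vocab,
                                age_center = 65, age_scale = 15) {
  A <- record_code_matrix(records, c(dx_vocab, proc_vocab))
  colnames(A) <- c(dx_vocab, proc_vocab)
  extra <- Matrix::Matrix(
    cbind(age_z = (records$age - age_center) / age_scale,
          female = records$female),
    sparse = TRUE
  )
  out <- cbind(A, extra)
  methods::as(out, "CsparseMatrix")
}

#' Regression feature matrix for the hierarchical model
#'
#' Standardized age, female flag and the 29 binary comorbidity
#' indicators from [map_comorbidities()].
#'
#' @inheritParams build_code_features
#' @param map Comorbidity map (see [map_comorbidities()]).
#' @return Dense numeric matrix with named columns.
#' @export
build_hlr_features <- function(records, map, age_center = 65, age_scale = 15) {
  cm <- map_comorbidities(records, map)
  cbind(age_z = (records$age - age_center) / age_scale,
        female = records$female, cm)
}

#' Structured inputs for the deep-set model
#'
#' Converts records into the containers the deep-set network consumes:
#' sparse code-by-record indicator matrices for secondary diagnoses and
#' procedures, the principal-diagnosis row index into the diagnosis
#' embedding table (0 when out of vocabulary, which the network treats
#' as a zero vector), hospital index, standardized age, sex and label.
#'
#' @param records Admission tibble.
#' @param dx_table,proc_table Fitted embedding tables ([fit_glove()]).
#' @param hospital_levels Character vector fixing the hospital index
#'   space (training hospitals).
#' @inheritParams build_code_features
#' @return List of model inputs.
#' @export
build_deepset_inputs <- function(records, dx_table, proc_table,
                                 hospital_levels,
                                 age_center = 65, age_scale = 15) {
  dx_vocab <- rownames(dx_table$vectors)
  proc_vocab <- if (is.null(proc_table)) character(0) else rownames(proc_table$vectors)
  n <- nrow(records)
  Adx <- Matrix::t(record_code_matrix(records, dx_vocab, include = "secondary"))
  Aproc <- if (length(proc_vocab) > 0) {
    Matrix::t(record_code_matrix(records, proc_vocab, include = "procedures"))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(1L, n))
  }
  prin <- match(records$principal_dx, dx_vocab)
  prin[is.na(prin)] <- 0L
  hosp <- match(records$hospital_id, hospital_levels)
  if (anyNA(hosp)) {
    abort("records reference hospitals outside `hospital_levels`.",
          class = "readmitr_lookup_error")
  }
  label <- records$unplanned_readmit %||% rep(0L, n)
  list(
    Adx = Adx, Aproc = Aproc, prin = as.integer(prin),
    hosp = as.integer(hosp),
    age_z = (records$age - age_center) / age_scale,
    female = as.numeric(records$female),
    y = as.integer(label),
    hospital_levels = hospital_levels
  )
}

# subset deep-set inputs by record index
subset_deepset_inputs <- function(inputs, idx) {
  list(
    Adx = inputs$Adx[, idx, drop = FALSE],
    Aproc = inputs$Aproc[, idx, drop = FALSE],
    prin = inputs$prin[idx], hosp = inputs$hosp[idx],
    age_z = inputs$age_z[idx], female = inputs$female[idx],
    y = inputs$y[idx], hospital_levels = inputs$hospital_levels
  )
}
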