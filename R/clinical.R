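#' The eleven mFI-11 comorbidity items
#'
#' Canonical column names for the 11-item modified Frailty Index: diabetes
#' mellitus; congestive heart failure; hypertension; myocardial infarction;
#' percutaneous coronary intervention / prior cardiac surgery / angina;
#' peripheral vascular disease; chronic or acute respiratory disease;
#' impaired sensorium; TIA or CVA; CVA with neurological deficit; and
#' dependent functional status (ADL).
#'
#' @return Character vector of length 11.
#' @export
mfi11_items <- function() {
  c(
    "diabetes", "chf", "hypertension", "mi", "pci_angina", "pvd",
    "respiratory", "impaired_sensorium", "tia_cva", "cva_deficit",
    "adl_dependent"
  )
}

#' Score the modified Frailty Index (mFI-11)
#'
#' Each comorbidity contributes one binary point; subjects are stratified
#' into low (`score <= cut - 1` ... i.e. "0-2") and high (">=3") frailty
#' strata at the conventional cut of 3. Missing items are an error: the
#' instrument is a complete count, no imputation is performed.
#'
#' @param data A data frame with one logical (or 0/1) column per item.
#' @param items Item column names (default [mfi11_items()]).
#' @param cut Stratum threshold (default 3: strata "0-2" vs ">=3").
#' @return `data` with `mfi11_score` (integer) and `mfi11_stratum`
#'   (factor `"0-2"` / `">=3"`) appended.
#' @export
mfi11_score <- function(data, items = mfi11_items(), cut = 3) {
  missing_cols <- setdiff(items, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing mFI-11 item(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  vals <- data[items]
  bad <- vapply(vals, function(v) {
    anyNA(v) || !all(v %in% c(0, 1, TRUE, FALSE))
  }, logical(1))
  if (any(bad)) {
    abort(sprintf("non-binary or missing values in item(s): %s.",
                  paste(items[bad], collapse = ", ")))
  }
  score <- as.integer(Reduce(`+`, lapply(vals, as.numeric)))
  lo <- sprintf("0-%d", cut - 1)
  hi <- sprintf(">=%d", cut)
  dplyr::mutate(
    as_tibble(data),
    mfi11_score = score,
    mfi11_stratum = factor(ifelse(score >= cut, hi, lo), levels = c(lo, hi))
  )
}

#' Classify drainage responders by the MCID rule
#'
#' A subject is a Responder when the best available inpatient-domain
#' improvement (gait, balance or cognition) is at least
#' `inpatient_threshold` percent AND the patient/caregiver-reported
#' functional improvement is at least `functional_threshold` percent; both
#' boundaries inclusive. Missing inpatient domains are allowed as long as
#' at least one is observed; a missing functional report is an error.
#'
#' @param data A data frame of per-subject outcome changes (percent).
#' @param inpatient Columns holding inpatient-domain improvements.
#' @param functional Column holding the reported functional improvement.
#' @param inpatient_threshold,functional_threshold MCID thresholds
#'   (percent; defaults 10 and 20).
#' @return `data` with a `responder` factor
#'   (`"Responder"` / `"Non-Responder"`) appended.
#' @export
classify_responder <- function(data,
                               inpatient = c("gait_improvement_pct",
                                             "balance_improvement_pct",
                                             "cognitive_improvement_pct"),
                               functional = "functional_improvement_pct",
                               inpatient_threshold = 10,
                               functional_threshold = 20) {
  present <- intersect(inpatient, names(data))
  if (length(present) == 0L) {
    abort("no inpatient-domain columns present.")
  }
  if (!functional %in% names(data)) {
    abort(sprintf("functional report column '%s' is missing.", functional))
  }
  inp <- as.matrix(data[present])
  if (any(rowSums(!is.na(inp)) == 0L)) {
    abort("at least one inpatient domain must be observed for every subject.")
  }
  fn <- data[[functional]]
  if (anyNA(fn)) abort("functional report contains missing values.")
  best <- apply(inp, 1, max, na.rm = TRUE)
  resp <- best >= inpatient_threshold & fn >= functional_threshold
  dplyr::mutate(
    as_tibble(data),
    responder = factor(ifelse(resp, "Responder", "Non-Responder"),
                       levels = c("Responder", "Non-Responder"))
  )
}
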