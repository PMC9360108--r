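# Pharmacometric rectangular datasets: one row per dose or observation,
# NONMEM-style column dialect (ID, TIME, AMT, DV, EVID, MDV; optional SS, II,
# ADDL, REGIMEN, BLQ), comma-separated with a header. TIME is hours since
# each subject's first dose; time-after-dose is derived, never stored
# authoritatively.

.required_cols <- c("ID", "TIME", "AMT", "DV", "EVID")

#' Construct and validate a PK dataset
#'
#' @param records data frame with columns `ID`, `TIME`, `AMT`, `DV`, `EVID`
#'   (1 dose / 0 observation) and optionally `MDV`, `SS`, `II`, `ADDL`,
#'   `REGIMEN`, `BLQ`. Dose rows must have `AMT > 0` and missing `DV`;
#'   observation rows `AMT = 0` and a `DV` value (unless `MDV = 1`).
#' @param covariates optional data frame of subject-level covariates with an
#'   `ID` column (one row per subject).
#' @param loq lower limit of quantification (mg/L); 0.01 mg/L corresponds to
#'   the 10 ug/L assay limit.
#' @return Object of class `pk_data`.
#' @export
pk_data <- function(records, covariates = NULL, loq = 0.01) {
  records <- as.data.frame(records)
  miss <- setdiff(.required_cols, names(records))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!"MDV" %in% names(records))
    records$MDV <- ifelse(records$EVID == 1, 1L, ifelse(is.na(records$DV), 1L, 0L))
  for (col in c("TIME", "AMT", "DV", "II"))
    if (col %in% names(records)) records[[col]] <- as.numeric(records[[col]])
  for (col in c("EVID", "MDV", "SS", "ADDL"))
    if (col %in% names(records)) records[[col]] <- as.integer(records[[col]])
  records <- records[order(records$ID, records$TIME, -records$EVID), ]
  rownames(records) <- NULL
  bad <- character()
  if (any(records$TIME < 0)) bad <- c(bad, "negative TIME")
  if (any(records$AMT < 0)) bad <- c(bad, "negative AMT")
  if (!all(records$EVID %in% c(0L, 1L))) bad <- c(bad, "EVID must be 0 or 1")
  dose <- records$EVID == 1
  if (any(dose & records$AMT == 0)) bad <- c(bad, "dose row with AMT = 0")
  if (any(dose & !is.na(records$DV))) bad <- c(bad, "dose row with a DV value")
  obs <- !dose
  if (any(obs & records$AMT != 0)) bad <- c(bad, "observation row with AMT != 0")
  if (any(obs & records$MDV == 0 & is.na(records$DV)))
    bad <- c(bad, "non-missing observation without DV")
  if (length(bad)) stop("invalid PK records: ", paste(bad, collapse = "; "))
  for (id in unique(records$ID)) {
    ri <- records[records$ID == id, ]
    if (!any(ri$EVID == 1)) stop("subject ", id, " has no dose record")
    if (any(ri$EVID == 0 & ri$TIME < min(ri$TIME[ri$EVID == 1])))
      stop("subject ", id, " has an observation before any dose")
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (!"ID" %in% names(covariates)) stop("covariates need an ID column")
    if (anyDuplicated(covariates$ID)) stop("one covariate row per subject")
  }
  structure(list(records = records, covariates = covariates, loq = loq),
            class = "pk_data")
}

#' @export
print.pk_data <- function(x, ...) {
  r <- x$records
  cat(sprintf("PK dataset: %d subjects, %d observations, %d dose records (LOQ %g mg/L)\n",
              length(unique(r$ID)), sum(r$EVID == 0 & r$MDV == 0),
              sum(r$EVID == 1), x$loq))
  invisible(x)
}

#' Read a PK dataset from CSV
#'
#' @param path CSV file with the NONMEM-style columns described in
#'   [pk_data()]. `ADDL`/`II` dose rows are expanded into individual doses.
#' @param loq lower limit of quantification (mg/L).
#' @param covariates_path optional CSV of subject covariates (`ID` column).
#' @return A validated [pk_data()] object.
#' @export
read_pkdata <- function(path, loq = 0.01, covariates_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.required_cols, names(rec))
  if (length(miss))
    stop("dataset format error; missing columns: ", paste(miss, collapse = ", "))
  if (all(c("ADDL", "II") %in% names(rec))) rec <- expand_addl(rec)
  covs <- if (!is.null(covariates_path))
    utils::read.csv(covariates_path, stringsAsFactors = FALSE) else NULL
  pk_data(rec, covariates = covs, loq = loq)
}

# expand ADDL/II shorthand (ADDL extra doses at interval II) into explicit rows
expand_addl <- function(rec) {
  idx <- which(rec$EVID == 1 & !is.na(rec$ADDL) & rec$ADDL > 0 &
                 !is.na(rec$II) & rec$II > 0)
  if (!length(idx)) return(rec)
  extra <- do.call(rbind, lapply(idx, function(i) {
    k <- seq_len(rec$ADDL[i])
    out <- rec[rep(i, length(k)), ]
    out$TIME <- rec$TIME[i] + k * rec$II[i]
    out$ADDL <- 0
    out
  }))
  rec$ADDL[idx] <- 0
  rbind(rec, extra)
}

#' Write a PK dataset to CSV
#'
#' Numeric fields are written with 17 significant digits so that
#' `read_pkdata(write_pkdata(ds))` reproduces every double bit-exactly.
#'
#' @param ds a [pk_data()] object.
#' @param path output CSV path.
#' @param covariates_path optional path for the covariate table.
#' @return `path`, invisibly.
#' @export
write_pkdata <- function(ds, path, covariates_path = NULL) {
  fmt <- function(df) {
    for (j in names(df))
      if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    df[df == "nan" | df == "NA"] <- NA
    df
  }
  utils::write.csv(fmt(ds$records), path, row.names = FALSE, na = "")
  if (!is.null(covariates_path) && !is.null(ds$covariates))
    utils::write.csv(fmt(ds$covariates), covariates_path, row.names = FALSE, na = "")
  invisible(path)
}

#' Remove observations below the limit of quantification
#'
#' Observations with `DV < loq` are removed (the exclusion approach; a
#' below-LOQ likelihood contribution is deliberately not used). Dose rows are
#' never touched.
#'
#' @param ds a [pk_data()].
#' @param loq override for the dataset's LOQ (mg/L).
#' @return List with `data` (filtered [pk_data()]) and `n_excluded`.
#' @export
filter_blq <- function(ds, loq = ds$loq) {
  r <- ds$records
  drop <- r$EVID == 0 & !is.na(r$DV) & r$DV < loq
  out <- ds
  out$records <- r[!drop, ]
  rownames(out$records) <- NULL
  list(data = out, n_excluded = sum(drop))
}

#' Remove one subject from a dataset
#'
#' @param ds a [pk_data()].
#' @param subject_id subject to remove (must exist).
#' @return The reduced [pk_data()].
#' @export
exclude_subject <- function(ds, subject_id) {
  if (!subject_id %in% ds$records$ID)
    stop("unknown subject: ", subject_id)
  ds$records <- ds$records[ds$records$ID != subject_id, ]
  rownames(ds$records) <- NULL
  if (!is.null(ds$covariates))
    ds$covariates <- ds$covariates[ds$covariates$ID != subject_id, ]
  ds
}

#' Time after most recent dose
#'
#' @param ds a [pk_data()].
#' @return Numeric vector, one entry per record: hours since the most recent
#'   dose at or before the record's time (`NA` before the first dose).
#' @export
compute_tad <- function(ds) {
  r <- ds$records
  tad <- rep(NA_real_, nrow(r))
  for (id in unique(r$ID)) {
    i <- which(r$ID == id)
    dt <- r$TIME[i][r$EVID[i] == 1]
    for (k in i) {
      prev <- dt[dt <= r$TIME[k]]
      if (length(prev)) tad[k] <- r$TIME[k] - max(prev)
    }
  }
  tad
}

# observations only (EVID 0, MDV 0)
obs_records <- function(ds) {
  r <- ds$records
  r[r$EVID == 0 & r$MDV == 0, ]
}
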