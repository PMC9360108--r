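# Application of a fixed population model to steady-state patient data:
# MAP Bayesian individual estimation, prediction errors, dosing-interval
# filtering and the clearance comparison.

#' MAP Bayesian application of a population model to patient data
#'
#' Estimates each patient's random effects by maximum a posteriori (MAP)
#' estimation with the population parameters held fixed (no population
#' update), computes individual predictions for every observation, and
#' derives the individual Bayesian clearance
#' \eqn{CL_{bayes} = CL_{pop} e^{\hat\eta_{CL}}}. Steady state is realised
#' by superposition of doses at the recorded interval until the trough
#' converges. Prediction errors follow
#' \eqn{PE_{DV} = (IPRED - DV)/DV \times 100} and
#' \eqn{PE_{CL} = (CL_{pop} - CL_{bayes})/CL_{bayes} \times 100}.
#'
#' @param ds patient [pk_data()] with steady-state dose rows (`SS`/`II`).
#' @param model fixed population [poppk_model()].
#' @return List of class `map_result`: `observations` (ID, TIME, TAD, DV,
#'   IPRED, PE_DV), `patients` (ID, CL_pop, CL_bayesian, PE_CL and the eta
#'   estimates), `cl_pop`.
#' @export
map_apply <- function(ds, model) {
  ebe <- ebe_estimate(ds, model)
  subjects <- prep_subjects(ds)
  tad <- compute_tad(ds)
  obs_idx <- ds$records$EVID == 0 & ds$records$MDV == 0
  obs <- ebe$ipred
  obs$TAD <- tad[obs_idx]
  obs$PE_DV <- prediction_error_dv(obs$IPRED, obs$DV)
  cl_pop_i <- vapply(subjects, function(s)
    ind_theta(model, NULL, s$covariates)[["cl"]], 0)
  eta_cl <- if ("cl" %in% colnames(ebe$eta)) ebe$eta[, "cl"] else
    rep(0, nrow(ebe$eta))
  patients <- data.frame(ID = vapply(subjects, `[[`, ds$records$ID[1], "id"),
                         CL_pop = cl_pop_i,
                         CL_bayesian = cl_pop_i * exp(eta_cl))
  patients$PE_CL <- prediction_error_cl(patients$CL_pop, patients$CL_bayesian)
  patients <- cbind(patients, ebe$eta)
  rownames(patients) <- NULL
  structure(list(observations = obs[, c("ID", "TIME", "TAD", "DV", "IPRED", "PE_DV")],
                 patients = patients, cl_pop = model$theta$cl),
            class = "map_result")
}

#' Concentration prediction error (percent)
#'
#' \eqn{PE_{DV} = (IPRED - DV)/DV \times 100}; overprediction is positive.
#'
#' @param ipred individual prediction (mg/L).
#' @param dv observed concentration (mg/L), positive.
#' @return Percent prediction error (vectorised).
#' @export
prediction_error_dv <- function(ipred, dv) {
  if (any(dv <= 0, na.rm = TRUE)) stop("dv must be positive")
  (ipred - dv) / dv * 100
}

#' Clearance prediction error (percent)
#'
#' \eqn{PE_{CL} = (CL_{pop} - CL_{bayes})/CL_{bayes} \times 100}; positive
#' when the individual (Bayesian) clearance is below the population value.
#'
#' @param cl_pop population clearance (L/h).
#' @param cl_bayesian MAP individual clearance (L/h), positive.
#' @return Percent prediction error (vectorised).
#' @export
prediction_error_cl <- function(cl_pop, cl_bayesian) {
  if (any(cl_bayesian <= 0, na.rm = TRUE)) stop("cl_bayesian must be positive")
  (cl_pop - cl_bayesian) / cl_bayesian * 100
}

#' Bias and precision of prediction errors
#'
#' Bias is the median prediction error; precision is the median absolute
#' prediction error. The two are computed independently (the median of
#' absolute values is not bounded below by the absolute median).
#'
#' @param pe numeric vector of prediction errors (percent); `NA`s dropped.
#' @return List: `bias`, `precision`, `n`.
#' @export
bias_precision <- function(pe) {
  pe <- pe[!is.na(pe)]
  if (!length(pe)) stop("no prediction errors supplied")
  list(bias = stats::median(pe), precision = stats::median(abs(pe)),
       n = length(pe))
}

#' Restrict observations to the prescribed dosing interval
#'
#' Keeps observations whose time after the most recent recorded dose does
#' not exceed the prescribed interval: 24 h for once-daily and 12 h for
#' twice-daily regimens (taken from the `REGIMEN` column, or from the dose
#' rows' `II` when no regimen label is present). Rows with an unknown
#' regimen are excluded and counted.
#'
#' @param ds patient [pk_data()].
#' @return List: `data` (filtered [pk_data()]), `n_kept`, `n_excluded`.
#' @export
interval_filter <- function(ds) {
  r <- ds$records
  tad <- compute_tad(ds)
  tau <- rep(NA_real_, nrow(r))
  if ("REGIMEN" %in% names(r))
    tau <- vapply(as.character(r$REGIMEN), regimen_tau, 0)
  if ("II" %in% names(r)) {
    for (id in unique(r$ID)) {
      i <- r$ID == id
      ii <- r$II[i & r$EVID == 1]
      ii <- ii[!is.na(ii)]
      if (length(ii) && any(is.na(tau[i]))) tau[i & is.na(tau)] <- ii[1]
    }
  }
  obs <- r$EVID == 0 & r$MDV == 0
  keep <- !obs | (!is.na(tau) & tad <= tau)
  out <- ds
  out$records <- r[keep, ]
  rownames(out$records) <- NULL
  list(data = out, n_kept = sum(obs & keep), n_excluded = sum(obs & !keep))
}

#' Compare clearance between two groups (Mann-Whitney U)
#'
#' Two-sided Wilcoxon rank-sum test; exact for small samples without ties,
#' normal approximation with tie correction otherwise (the default
#' behaviour of [stats::wilcox.test()]).
#'
#' @param cl_a,cl_b clearance values (L/h) of the two groups.
#' @return List: `p`, `statistic` (U), `median_a`, `median_b`.
#' @export
compare_cl_groups <- function(cl_a, cl_b) {
  if (!length(cl_a) || !length(cl_b)) stop("both groups must be non-empty")
  w <- suppressWarnings(stats::wilcox.test(cl_a, cl_b, alternative = "two.sided"))
  list(p = w$p.value, statistic = unname(w$statistic),
       median_a = stats::median(cl_a), median_b = stats::median(cl_b))
}
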