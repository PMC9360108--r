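# Non-compartmental analysis of single-dose concentration profiles and the
# comparison of empirical Bayes (model-based) individual estimates with NCA.

#' Non-compartmental analysis of one profile
#'
#' Cmax/tmax are read off the observed points (ties broken to the earliest
#' time). The AUC uses the trapezoid rule, by default linear on rising and
#' logarithmic on falling segments. The terminal slope \eqn{\lambda_z} is
#' estimated by log-linear regression over the last 3 to 6 quantifiable
#' points strictly after tmax, choosing the point count with the best
#' adjusted R-squared. The extrapolated tail is \eqn{C_{last}/\lambda_z};
#' CL = dose/AUC(0-inf) and Vz = CL/\eqn{\lambda_z}. When no positive
#' terminal slope can be estimated, the extrapolation-dependent quantities
#' are reported as `NA`.
#'
#' @param times sampling times (h), sorted ascending.
#' @param concs concentrations (mg/L).
#' @param dose administered dose (mg).
#' @param method `"lin_up_log_down"` (default) or `"linear"` trapezoid.
#' @param auc_to upper end of the truncated AUC window (h), default 72.
#' @param add_t0_zero prepend a zero concentration at time 0 when the first
#'   sample is later (appropriate for single oral doses, where the
#'   concentration at dosing is zero; used by [nca_cohort()]).
#' @return List of class `nca_profile`: `cmax`, `tmax`, `auc_0_t`
#'   (0 to `auc_to`), `auc_0_inf`, `lambda_z`, `cl`, `vz`,
#'   `n_lambda_points`.
#' @export
nca_profile <- function(times, concs, dose, method = c("lin_up_log_down", "linear"),
                        auc_to = 72, add_t0_zero = FALSE) {
  method <- match.arg(method)
  if (length(times) != length(concs)) stop("times and concs must align")
  if (is.unsorted(times)) stop("times must be sorted")
  if (sum(concs > 0) < 3) stop("need at least 3 positive concentrations")
  if (add_t0_zero && times[1] > 0) {
    times <- c(0, times)
    concs <- c(0, concs)
  }
  imax <- which.max(concs)          # which.max takes the earliest maximum
  cmax <- concs[imax]
  tmax <- times[imax]
  keep <- times <= auc_to
  auc_0_t <- trapz_auc(times[keep], concs[keep], method)
  # terminal slope: last 3-6 positive points strictly after tmax
  term <- which(times > tmax & concs > 0)
  lambda_z <- NA_real_; n_pts <- NA_integer_; best_r2 <- -Inf
  for (k in 3:6) {
    if (length(term) < k) break
    idx <- utils::tail(term, k)
    fit <- stats::lm(log(concs[idx]) ~ times[idx])
    slope <- -stats::coef(fit)[[2]]
    if (slope <= 1e-8) next   # no genuine decline
    r2 <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.finite(r2) && r2 > best_r2) {
      best_r2 <- r2; lambda_z <- slope; n_pts <- k
    }
  }
  auc_0_inf <- cl <- vz <- NA_real_
  if (is.finite(lambda_z) && lambda_z > 0) {
    clast <- concs[max(which(concs > 0))]
    tlast <- times[max(which(concs > 0))]
    auc_all <- trapz_auc(times, concs, method)
    auc_0_inf <- auc_all + clast / lambda_z
    if (tlast < auc_to) auc_0_t <- auc_all  # window extends past data
    cl <- dose / auc_0_inf
    vz <- cl / lambda_z
  }
  structure(list(cmax = cmax, tmax = tmax, auc_0_t = auc_0_t,
                 auc_0_inf = auc_0_inf, lambda_z = lambda_z,
                 cl = cl, vz = vz, n_lambda_points = n_pts),
            class = "nca_profile")
}

# trapezoid AUC; log interpolation on strictly decreasing positive segments
trapz_auc <- function(t, c, method = "lin_up_log_down") {
  if (length(t) < 2) return(0)
  dt <- diff(t)
  c1 <- c[-length(c)]
  c2 <- c[-1]
  lin <- dt * (c1 + c2) / 2
  if (method == "lin_up_log_down") {
    dn <- c2 < c1 & c2 > 0 & c1 > 0
    lin[dn] <- dt[dn] * (c1[dn] - c2[dn]) / log(c1[dn] / c2[dn])
  }
  sum(lin)
}

#' Geometric summary statistics
#'
#' Geometric mean \eqn{\bar x_G = \exp(\mathrm{mean}(\log x))} and geometric
#' relative standard deviation
#' \eqn{RSD_G = \sqrt{\exp(SD(\log x)^2) - 1}} (reported as a percentage),
#' plus the median and interquartile range.
#'
#' @param values positive numeric vector (`NA`s dropped).
#' @return List: `geo_mean`, `geo_rsd_percent`, `median`, `iqr` (named
#'   25\%/75\% quantiles), `n`.
#' @export
geometric_stats <- function(values) {
  values <- values[!is.na(values)]
  if (any(values <= 0)) stop("geometric statistics require positive values")
  lx <- log(values)
  s <- if (length(values) > 1) stats::sd(lx) else 0
  list(geo_mean = exp(mean(lx)),
       geo_rsd_percent = 100 * sqrt(exp(s^2) - 1),
       median = stats::median(values),
       iqr = stats::quantile(values, c(0.25, 0.75), names = TRUE),
       n = length(values))
}

#' NCA over every subject of a single-dose dataset
#'
#' @param ds a [pk_data()] of single-dose profiles.
#' @param dose dose (mg); taken from each subject's dose record by default.
#' @param ... passed to [nca_profile()].
#' @return Data frame, one row per subject: `ID`, `cmax`, `tmax`,
#'   `auc_0_t`, `auc_0_inf`, `lambda_z`, `cl`, `vz`, `n_lambda_points`.
#' @export
nca_cohort <- function(ds, dose = NULL, ...) {
  subs <- prep_subjects(ds)
  rows <- lapply(subs, function(s) {
    d <- if (is.null(dose)) sum(s$dose_amt) else dose
    ord <- order(s$times)
    p <- nca_profile(s$times[ord], s$dv[ord], d, add_t0_zero = TRUE, ...)
    data.frame(ID = s$id, cmax = p$cmax, tmax = p$tmax, auc_0_t = p$auc_0_t,
               auc_0_inf = p$auc_0_inf, lambda_z = p$lambda_z, cl = p$cl,
               vz = p$vz, n_lambda_points = p$n_lambda_points)
  })
  do.call(rbind, rows)
}

#' Model-based individual PK metrics from empirical Bayes estimates
#'
#' Per-subject exposure metrics computed from the individual (EBE)
#' parameters of a fitted model: clearance `cl` and distribution volume
#' `vd` (central plus peripheral) directly from the individual parameters;
#' `cmax`, `tmax` and truncated `auc_0_t` from the individual predicted
#' curve evaluated on a dense grid (0.01 h near the absorption peak).
#'
#' @param fit a [fit_poppk()] result on single-dose data.
#' @param dose dose (mg) for the profile; default from the data.
#' @param auc_to truncation time (h) for the AUC, default 72.
#' @param grid_end end of the fine grid used for the Cmax search (h).
#' @return Data frame, one row per subject: `ID`, `cl`, `vd`, `cmax`,
#'   `tmax`, `auc_0_t`.
#' @export
ebe_pk_metrics <- function(fit, dose = NULL, auc_to = 72, grid_end = 12) {
  model <- fit$model
  grid <- c(seq(0.01, grid_end, by = 0.01), seq(grid_end + 0.05, auc_to, by = 0.05))
  rows <- lapply(seq_along(fit$subjects), function(i) {
    s <- fit$subjects[[i]]
    eta <- fit$eta[i, ]
    th <- ind_theta(model, eta, s$covariates)
    d <- if (is.null(dose)) sum(s$dose_amt) else dose
    conc <- conc_dose_events(model$structure, th, 0, d, grid)
    imax <- which.max(conc)
    data.frame(ID = s$id, cl = th[["cl"]],
               vd = th[["v1"]] + if ("v2" %in% names(th)) th[["v2"]] else 0,
               cmax = conc[imax], tmax = grid[imax],
               auc_0_t = trapz_auc(grid, conc))
  })
  do.call(rbind, rows)
}

#' Compare model-based (EBE) and non-compartmental individual estimates
#'
#' Builds the standard comparison table: geometric mean and geometric RSD
#' per approach for log-normally distributed metrics (AUC, Cmax, Vd, CL)
#' with a paired t-test on the log scale, and median/IQR for tmax with a
#' paired Wilcoxon signed-rank test (or paired t-test).
#'
#' @param ebe_table data frame from [ebe_pk_metrics()].
#' @param nca_table data frame from [nca_cohort()].
#' @param metrics named character vector mapping metric label to the pair of
#'   column names `c(ebe_col, nca_col)`; defaults cover AUC(0-72), Cmax, Vd
#'   and CL.
#' @param tmax_test `"signed_rank"` or `"t"`.
#' @return Data frame: metric, n, EBE and NCA summaries, p-value.
#' @export
compare_ebe_nca <- function(ebe_table, nca_table,
                            metrics = list(auc_0_72 = c("auc_0_t", "auc_0_t"),
                                           cmax = c("cmax", "cmax"),
                                           vd = c("vd", "vz"),
                                           cl = c("cl", "cl")),
                            tmax_test = c("signed_rank", "t")) {
  tmax_test <- match.arg(tmax_test)
  if (!setequal(ebe_table$ID, nca_table$ID))
    stop("subject mismatch between the EBE and NCA tables")
  nca_table <- nca_table[match(ebe_table$ID, nca_table$ID), ]
  out <- lapply(names(metrics), function(mname) {
    cols <- metrics[[mname]]
    x <- ebe_table[[cols[1]]]
    y <- nca_table[[cols[2]]]
    ok <- !is.na(x) & !is.na(y)
    gx <- geometric_stats(x[ok])
    gy <- geometric_stats(y[ok])
    p <- if (sd(log(x[ok]) - log(y[ok])) == 0) 1
         else stats::t.test(log(x[ok]), log(y[ok]), paired = TRUE)$p.value
    data.frame(metric = mname, n = sum(ok),
               ebe_geo_mean = gx$geo_mean, ebe_geo_rsd = gx$geo_rsd_percent,
               nca_geo_mean = gy$geo_mean, nca_geo_rsd = gy$geo_rsd_percent,
               p_value = p)
  })
  out <- do.call(rbind, out)
  # tmax compared on the original scale
  x <- ebe_table$tmax; y <- nca_table$tmax
  ok <- !is.na(x) & !is.na(y)
  p_tmax <- if (all(x[ok] == y[ok])) 1
    else if (tmax_test == "signed_rank")
      stats::wilcox.test(x[ok], y[ok], paired = TRUE, exact = FALSE)$p.value
    else stats::t.test(x[ok], y[ok], paired = TRUE)$p.value
  out <- rbind(out, data.frame(metric = "tmax", n = sum(ok),
    ebe_geo_mean = stats::median(x[ok]), ebe_geo_rsd = NA,
    nca_geo_mean = stats::median(y[ok]), nca_geo_rsd = NA, p_value = p_tmax))
  out
}
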