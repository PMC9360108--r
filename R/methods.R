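# S3 methods for fitted population models.

#' @export
print.poppk_fit <- function(x, ...) {
  cat("Population PK fit (FOCE-I)\n")
  cat(sprintf("  subjects: %d, observations: %d\n", length(x$subjects),
              sum(vapply(x$subjects, `[[`, 0L, "n_obs"))))
  cat(sprintf("  OFV: %.4f  (converged: %s)\n", x$ofv, x$converged))
  th <- unlist(x$model$theta)
  cat("  theta:", paste(sprintf("%s=%.4g", names(th), th), collapse = ", "), "\n")
  if (!is.null(x$model$iiv)) {
    cvs <- omega_to_cv(diag(x$model$iiv$omega))
    cat("  IIV CV%:", paste(sprintf("%s=%.1f", names(cvs), cvs), collapse = ", "), "\n")
  }
  er <- x$model$error
  cat("  error:", er$kind,
      if (!is.null(er$sigma_add)) sprintf("add=%.4g", er$sigma_add),
      if (!is.null(er$sigma_prop)) sprintf("prop=%.1f%%", 100 * er$sigma_prop), "\n")
  invisible(x)
}

#' Summarise a population PK fit
#'
#' Estimate table shaped like a standard popPK report: structural
#' parameters, IIV as CV percent, residual error, with RSEs when
#' [covariance_step()] has been run, plus OFV, AIC and shrinkage.
#'
#' @param object a [fit_poppk()] result.
#' @param ... unused.
#' @return Object of class `summary.poppk_fit` (list with `table`, `ofv`,
#'   `aic`, `npar`, `shrinkage`, `converged`, `covariance_ok`).
#' @export
summary.poppk_fit <- function(object, ...) {
  nat <- natural_par(object$model, object$packing)
  npar <- length(object$par)
  tab <- data.frame(parameter = names(nat), estimate = unname(nat))
  # report lognormal IIV SDs as CV%
  is_om <- grepl("^omega_", tab$parameter)
  tab$cv_percent <- NA_real_
  if (object$model$eta_link == "exp")
    tab$cv_percent[is_om] <- omega_to_cv(tab$estimate[is_om]^2)
  if (!is.null(object$se)) {
    tab$se <- unname(object$se[tab$parameter])
    tab$rse_percent <- unname(object$rse[tab$parameter])
  }
  structure(list(table = tab, ofv = object$ofv, aic = aic(object$ofv, npar),
                 npar = npar, shrinkage = object$shrinkage,
                 converged = object$converged,
                 covariance_ok = object$covariance_ok),
            class = "summary.poppk_fit")
}

#' @export
print.summary.poppk_fit <- function(x, ...) {
  cat(sprintf("OFV %.4f | AIC %.4f | %d parameters | converged: %s\n",
              x$ofv, x$aic, x$npar, x$converged))
  if (!is.na(x$covariance_ok))
    cat(sprintf("covariance step: %s\n",
                if (isTRUE(x$covariance_ok)) "ok" else "FAILED"))
  print(x$table, digits = 4, row.names = FALSE)
  if (length(x$shrinkage))
    cat("eta shrinkage (%):",
        paste(sprintf("%s=%.1f", names(x$shrinkage), x$shrinkage),
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.poppk_fit <- function(object, ...) {
  natural_par(object$model, object$packing)
}

#' @export
logLik.poppk_fit <- function(object, ...) {
  structure(-object$ofv / 2, df = length(object$par),
            nobs = sum(vapply(object$subjects, `[[`, 0L, "n_obs")),
            class = "logLik")
}

#' @export
vcov.poppk_fit <- function(object, ...) {
  if (is.null(object$cov_natural))
    stop("run covariance_step() first")
  object$cov_natural
}

#' Predictions from a fitted population model
#'
#' @param object a [fit_poppk()] result.
#' @param newdata optional [pk_data()]; defaults to the fitting data.
#' @param type `"ipred"` (individual, at the conditional eta mode) or
#'   `"pred"` (population, eta = 0).
#' @param ... unused.
#' @return Data frame `ID`, `TIME`, `DV`, and the requested prediction.
#' @export
predict.poppk_fit <- function(object, newdata = NULL,
                              type = c("ipred", "pred"), ...) {
  type <- match.arg(type)
  model <- object$model
  if (is.null(newdata)) {
    g <- gof_table(object)
    return(g[, c("ID", "TIME", "DV", if (type == "ipred") "IPRED" else "PRED")])
  }
  if (type == "ipred") {
    e <- ebe_estimate(newdata, model)
    return(e$ipred)
  }
  subjects <- prep_subjects(newdata)
  n_eta <- if (!is.null(model$iiv)) nrow(model$iiv$omega) else 0
  eta0 <- stats::setNames(numeric(n_eta),
                          if (n_eta) rownames(model$iiv$omega))
  do.call(rbind, lapply(subjects, function(s) {
    th <- ind_theta(model, eta0, s$covariates)
    data.frame(ID = s$id, TIME = s$times, DV = s$dv,
               PRED = pred_subject(model, th, s))
  }))
}

#' @export
residuals.poppk_fit <- function(object, type = c("cwres", "iwres", "response"), ...) {
  type <- match.arg(type)
  g <- gof_table(object)
  switch(type, cwres = g$CWRES, iwres = g$IWRES, response = g$DV - g$IPRED)
}

#' Simulate datasets from a fitted population model
#'
#' Draws new random effects and residual errors at the design (subjects,
#' dosing, sampling times) of the fitting data.
#'
#' @param object a [fit_poppk()] result.
#' @param nsim number of datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return List of `nsim` [pk_data()] objects.
#' @export
simulate.poppk_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ds <- object$data
  obs_idx <- ds$records$EVID == 0 & ds$records$MDV == 0
  lapply(seq_len(nsim), function(k) {
    dv <- unlist(simulate_dv(object$model, object$subjects))
    out <- ds
    out$records$DV[obs_idx] <- dv
    out
  })
}

#' Goodness-of-fit plots
#'
#' Standard 2 x 2 panel: observations versus individual and population
#' predictions, conditional weighted residuals versus population
#' predictions and versus time.
#'
#' @param x a [fit_poppk()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.poppk_fit <- function(x, ...) {
  g <- gof_table(x)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  lim <- range(c(g$DV, g$IPRED, g$PRED), na.rm = TRUE)
  graphics::plot(g$IPRED, g$DV, xlab = "Individual prediction (mg/L)",
                 ylab = "Observed (mg/L)", xlim = lim, ylim = lim, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(g$PRED, g$DV, xlab = "Population prediction (mg/L)",
                 ylab = "Observed (mg/L)", xlim = lim, ylim = lim, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(g$PRED, g$CWRES, xlab = "Population prediction (mg/L)",
                 ylab = "CWRES", ...)
  graphics::abline(h = 0, lty = 2)
  graphics::plot(g$TIME, g$CWRES, xlab = "Time after dose (h)",
                 ylab = "CWRES", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Plot a visual predictive check
#'
#' @param x a [vpc()] result.
#' @param log_y log-scale concentration axis.
#' @param ... passed to [graphics::plot()].
#' @export
plot.poppk_vpc <- function(x, log_y = FALSE, ...) {
  pcts <- sort(unique(x$percentile))
  xs <- sort(unique(x$bin_mid))
  graphics::plot(range(xs), range(c(x$sim_lo, x$sim_hi, x$observed)),
                 type = "n", xlab = "Time (h)", ylab = "Concentration (mg/L)",
                 log = if (log_y) "y" else "", ...)
  for (p in pcts) {
    xi <- x[x$percentile == p, ]
    xi <- xi[order(xi$bin_mid), ]
    graphics::polygon(c(xi$bin_mid, rev(xi$bin_mid)),
                      c(xi$sim_lo, rev(xi$sim_hi)),
                      col = grDevices::adjustcolor("grey60", 0.4), border = NA)
    graphics::lines(xi$bin_mid, xi$observed, lwd = 2,
                    lty = if (p == 50) 1 else 2)
  }
  invisible(x)
}
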