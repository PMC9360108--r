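# Internal model evaluation: visual predictive check, nonparametric
# bootstrap, goodness-of-fit tables.

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets at the design of the observed data
#' and compares the observed percentiles per time bin with the simulation
#' envelope of the same statistics. Binning is by exact scheduled sampling
#' time by default (appropriate for protocolised designs); `bins` may give
#' numeric bin edges for irregular data, and empty bins are merged with
#' their left neighbour.
#'
#' @param fit a [fit_poppk()] result (or a list with `model` and `subjects`).
#' @param n_sim number of simulated replicates (default 1000).
#' @param percentiles observed statistics to check (default 5/50/95).
#' @param ci envelope coverage across simulations (default 95 percent).
#' @param bins `NULL` for exact-time bins, or numeric bin edges.
#' @param seed RNG seed.
#' @return Data frame of class `poppk_vpc`: one row per bin x percentile
#'   with `bin_mid`, `n_obs`, `percentile`, `observed`, `sim_lo`,
#'   `sim_median`, `sim_hi`.
#' @export
vpc <- function(fit, n_sim = 1000, percentiles = c(5, 50, 95), ci = 95,
                bins = NULL, seed = 1) {
  subjects <- fit$subjects
  model <- fit$model
  times <- unlist(lapply(subjects, `[[`, "times"))
  dv <- unlist(lapply(subjects, `[[`, "dv"))
  if (is.null(bins)) {
    bin_id <- match(times, sort(unique(times)))
    bin_mid <- sort(unique(times))
  } else {
    bin_id <- findInterval(times, bins, rightmost.closed = TRUE)
    keep <- tabulate(bin_id, nbins = length(bins) - 1) > 0
    # merge empty bins leftwards by re-labelling
    lab <- cumsum(keep)
    bin_id <- pmax(lab[pmax(bin_id, 1)], 1)
    bin_mid <- vapply(split(times, bin_id), stats::median, 0)
  }
  nb <- length(unique(bin_id))
  probs <- percentiles / 100
  obs_stat <- t(vapply(split(dv, bin_id),
                       function(x) stats::quantile(x, probs, names = FALSE),
                       numeric(length(probs))))
  set.seed(seed)
  sims <- array(NA_real_, c(nb, length(probs), n_sim))
  for (s in seq_len(n_sim)) {
    sdv <- unlist(simulate_dv(model, subjects))
    sims[, , s] <- t(vapply(split(sdv, bin_id),
                            function(x) stats::quantile(x, probs, names = FALSE),
                            numeric(length(probs))))
  }
  alpha <- (1 - ci / 100) / 2
  rows <- list()
  n_per_bin <- tabulate(bin_id)
  for (b in seq_len(nb)) for (p in seq_along(probs)) {
    env <- stats::quantile(sims[b, p, ], c(alpha, 0.5, 1 - alpha), names = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      bin_mid = bin_mid[b], n_obs = n_per_bin[b], percentile = percentiles[p],
      observed = obs_stat[b, p], sim_lo = env[1], sim_median = env[2],
      sim_hi = env[3])
  }
  out <- do.call(rbind, rows)
  class(out) <- c("poppk_vpc", class(out))
  out
}

#' Nonparametric bootstrap of a population fit
#'
#' Resamples subjects with replacement to the original cohort size, refits
#' each replicate starting from the base estimates, and summarises the
#' replicate estimates by median and a central confidence interval.
#' Replicates that error, fail to converge, or (optionally) fail the
#' covariance step are excluded from the summaries but counted in the
#' success rate.
#'
#' @param fit a [fit_poppk()] result.
#' @param n_rep number of bootstrap replicates (default 1000).
#' @param seed RNG seed (resampling is reproducible; replicate `r` uses a
#'   sub-seed derived deterministically from `seed`).
#' @param ci confidence level (default 95 percent).
#' @param check_covariance also require a successful covariance step.
#' @param control a [poppk_control()] for the refits.
#' @return List of class `poppk_boot`: `summary` (data frame with estimate,
#'   median and CI per parameter), `estimates` (replicate x parameter
#'   matrix), `success_rate` (percent), `n_rep`.
#' @export
bootstrap_poppk <- function(fit, n_rep = 1000, seed = 1, ci = 95,
                            check_covariance = FALSE,
                            control = fit$control) {
  ds <- fit$data
  ids <- unique(ds$records$ID)
  n <- length(ids)
  base <- natural_par(fit$model, fit$packing)
  est <- matrix(NA_real_, n_rep, length(base),
                dimnames = list(NULL, names(base)))
  ok <- logical(n_rep)
  set.seed(seed)
  draw <- matrix(sample(ids, n_rep * n, replace = TRUE), n_rep, n)
  for (r in seq_len(n_rep)) {
    take <- draw[r, ]
    recs <- do.call(rbind, lapply(seq_along(take), function(j) {
      ri <- ds$records[ds$records$ID == take[j], ]
      ri$ID <- j
      ri
    }))
    covs <- if (!is.null(ds$covariates)) {
      ci2 <- ds$covariates[match(take, ds$covariates$ID), ]
      ci2$ID <- seq_along(take)
      ci2
    } else NULL
    bds <- pk_data(recs, covariates = covs, loq = ds$loq)
    f <- tryCatch(fit_poppk(bds, fit$model, control = control),
                  error = function(e) NULL)
    good <- !is.null(f) && f$converged
    if (good && check_covariance) {
      f <- covariance_step(f)
      good <- isTRUE(f$covariance_ok)
    }
    if (good) {
      est[r, ] <- natural_par(f$model, f$packing)
      ok[r] <- TRUE
    }
  }
  alpha <- (1 - ci / 100) / 2
  qs <- apply(est[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.5, alpha, 1 - alpha), na.rm = TRUE)
  summary <- data.frame(parameter = names(base), estimate = unname(base),
                        boot_median = qs[1, ], ci_lo = qs[2, ], ci_hi = qs[3, ],
                        row.names = NULL)
  if (mean(ok) < 0.5)
    warning("bootstrap success rate below 50%; summaries may be unreliable")
  structure(list(summary = summary, estimates = est[ok, , drop = FALSE],
                 success_rate = 100 * mean(ok), n_rep = n_rep),
            class = "poppk_boot")
}

#' @export
print.poppk_boot <- function(x, ...) {
  cat(sprintf("Bootstrap: %d replicates, %.1f%% successful\n",
              x$n_rep, x$success_rate))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Goodness-of-fit table
#'
#' One row per observation with the observed value, the population
#' prediction (eta = 0), the individual prediction (eta at the conditional
#' mode), the conditional weighted residual and the individual weighted
#' residual.
#'
#' @param fit a [fit_poppk()] result.
#' @return Data frame: `ID`, `TIME`, `DV`, `PRED`, `IPRED`, `CWRES`,
#'   `IWRES`.
#' @export
gof_table <- function(fit) {
  model <- fit$model
  rows <- lapply(seq_along(fit$subjects), function(i) {
    s <- fit$subjects[[i]]
    ps <- fit$details$per_subject[[i]]
    th0 <- ind_theta(model, stats::setNames(numeric(ncol(fit$eta)),
                                            colnames(fit$eta)), s$covariates)
    pred <- pred_subject(model, th0, s)
    v <- pmax(residual_variance(ps$f, model$error), .v_floor)
    data.frame(ID = s$id, TIME = s$times, DV = s$dv, PRED = pred,
               IPRED = ps$f, CWRES = ps$cwres, IWRES = (s$dv - ps$f) / sqrt(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
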