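# Nonlinear mixed-effects estimation by first-order conditional estimation
# with interaction (FOCE-I).
#
# For subject i with observations y_i, random effects eta ~ N(0, Omega) and
# conditional mode eta_hat, the marginal -2 log-likelihood is approximated by
# linearising f around eta_hat:
#   OFV_i = log|C_i| + r_i' C_i^{-1} r_i,
#   C_i = J_i Omega J_i' + diag(v_i),  r_i = y_i - f_i(eta_hat) + J_i eta_hat,
# with J_i = df/deta at eta_hat and v_i the residual variance evaluated at
# f_i(eta_hat) ("interaction"). The n log(2pi) constant is excluded
# throughout, so only OFV differences are meaningful (AIC = OFV + 2p).

# ---- data preparation --------------------------------------------------

# split a pk_data into per-subject lists used by the estimation engine
prep_subjects <- function(ds, model = NULL) {
  r <- ds$records
  ids <- unique(r$ID)
  covs <- ds$covariates
  lapply(ids, function(id) {
    ri <- r[r$ID == id, ]
    oi <- ri[ri$EVID == 0 & ri$MDV == 0, ]
    di <- ri[ri$EVID == 1, ]
    ss <- if ("SS" %in% names(di)) !is.na(di$SS) & di$SS == 1 else rep(FALSE, nrow(di))
    ii <- if ("II" %in% names(di)) di$II else rep(NA_real_, nrow(di))
    cv <- if (!is.null(covs) && id %in% covs$ID)
      as.list(covs[covs$ID == id, , drop = FALSE]) else NULL
    list(id = id, times = oi$TIME, dv = oi$DV,
         dose_t = di$TIME, dose_amt = di$AMT, ss = ss, ii = ii,
         covariates = cv, n_obs = nrow(oi))
  })
}

# individual parameter vector: typical values -> covariate links -> eta
ind_theta <- function(model, eta, covariates = NULL) {
  th <- unlist(model$theta)
  for (ln in model$covariate_links) {
    x <- covariates[[ln$covariate]]
    if (is.null(x)) stop("covariate '", ln$covariate, "' missing for a subject")
    th[ln$parameter] <- th[ln$parameter] * link_multiplier(ln, x)
  }
  if (length(eta)) {
    if (model$eta_link == "exp") {
      th[names(eta)] <- th[names(eta)] * exp(eta)
    } else {
      th[names(eta)] <- th[names(eta)] + eta
    }
  }
  th
}

# prediction for one subject at given individual parameters
pred_subject <- function(model, th, subj) {
  if (!is.null(model$predict_fun)) return(model$predict_fun(th, subj))
  struct <- model$structure
  dt <- subj$dose_t
  da <- subj$dose_amt
  if (any(subj$ss)) {
    thl <- as.list(th)
    keep <- !subj$ss
    dt2 <- dt[keep]; da2 <- da[keep]
    for (j in which(subj$ss)) {
      K <- n_doses_for_ss(struct, thl, subj$ii[j])
      dt2 <- c(dt2, subj$dose_t[j] - (seq_len(K) - 1) * subj$ii[j])
      da2 <- c(da2, rep(subj$dose_amt[j], K))
    }
    dt <- dt2; da <- da2
  }
  conc_dose_events(struct, th, dt, da, subj$times)
}

.v_floor <- 1e-12

# ---- individual (MAP) objective ---------------------------------------

# fast per-subject prediction closure: th0 already carries covariate
# multipliers; eta enters via the model's eta link
make_subject_fn <- function(model, subj, th0, eta_names) {
  ei <- match(eta_names, names(th0))
  exp_link <- model$eta_link == "exp"
  apply_eta <- function(eta) {
    th <- th0
    if (length(ei))
      th[ei] <- if (exp_link) th[ei] * exp(eta) else th[ei] + eta
    th
  }
  if (!is.null(model$predict_fun)) {
    function(eta) model$predict_fun(apply_eta(eta), subj)
  } else if (!any(subj$ss)) {
    struct <- model$structure
    dt <- subj$dose_t; da <- subj$dose_amt; tm <- subj$times
    function(eta) conc_dose_events(struct, apply_eta(eta), dt, da, tm)
  } else {
    function(eta) pred_subject(model, apply_eta(eta), subj)
  }
}

# residual-variance closure (avoids re-dispatching on the error kind)
make_var_fn <- function(error) {
  sa2 <- if (!is.null(error$sigma_add)) error$sigma_add^2 else 0
  sp2 <- if (!is.null(error$sigma_prop)) error$sigma_prop^2 else 0
  function(f) {
    v <- sa2 + sp2 * f * f
    v[is.na(v) | v < .v_floor] <- .v_floor
    v
  }
}

inner_objective <- function(eta, subj, model, omega_inv, eta_names, log_det_omega) {
  names(eta) <- eta_names
  th <- ind_theta(model, eta, subj$covariates)
  f <- pred_subject(model, th, subj)
  v <- pmax(residual_variance(f, model$error), .v_floor)
  sum(log(v) + (subj$dv - f)^2 / v) +
    drop(eta %*% omega_inv %*% eta) + log_det_omega
}

#' Joint individual objective for MAP estimation
#'
#' The criterion minimised by the empirical Bayes (MAP) step for a single
#' subject: extended-least-squares data term plus the normal prior on
#' \eqn{\eta},
#' \deqn{\sum_j [\log v_j + (y_j - f_j(\eta))^2 / v_j]
#'       + \eta' \Omega^{-1} \eta + \log|\Omega|.}
#'
#' @param ds a [pk_data()] containing exactly one subject.
#' @param model a [poppk_model()] with IIV.
#' @param eta named numeric vector of random effects (names = IIV parameters).
#' @return Scalar objective value.
#' @export
individual_joint_objective <- function(ds, model, eta) {
  subj <- prep_subjects(ds)[[1]]
  omega <- model$iiv$omega
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch)) stop("omega is singular or not positive definite")
  inner_objective(as.numeric(eta)[match(rownames(omega), names(eta))], subj,
                  model, chol2inv(ch), rownames(omega), 2 * sum(log(diag(ch))))
}

# FOCE-I contribution of one subject; returns value and linearisation pieces.
# `dual = TRUE` searches the conditional mode from both the zero vector and
# the warm start and keeps the deeper mode (the conditional objective can be
# multimodal, e.g. through exchange between the absorption and transit
# rates); `dual = FALSE` trusts the warm chain.
foce_subject <- function(subj, fn, var_fn, omega, omega_inv, n_eta,
                         start = NULL, inner_reltol = 1e-12, dual = TRUE) {
  if (n_eta == 0) {
    f <- fn(numeric(0))
    v <- var_fn(f)
    res <- subj$dv - f
    ofv <- sum(log(v) + res^2 / v)
    return(list(ofv = if (is.finite(ofv)) ofv else 1e10, eta = numeric(0),
                f = f, cwres = res / sqrt(v), converged = TRUE))
  }
  dv <- subj$dv
  obj <- function(eta) {
    f <- fn(eta)
    v <- var_fn(f)
    val <- sum(log(v) + (dv - f)^2 / v) + sum(eta * (omega_inv %*% eta))
    if (!is.finite(val)) 1e10 else val
  }
  zero <- numeric(n_eta)
  if (!is.null(start) && !all(is.finite(start))) start <- NULL
  if (subj$n_obs == 0) {
    eta <- numeric(n_eta)
    conv <- TRUE
  } else {
    solve_from <- function(p)
      stats::optim(p, obj, method = "BFGS",
                   control = list(reltol = inner_reltol, maxit = 200,
                                  ndeps = rep(1e-6, n_eta)))
    warm_ok <- !is.null(start) && sum(abs(start - zero)) > 1e-8
    if (dual || !warm_ok) {
      o <- solve_from(zero)
      if (warm_ok) {
        o2 <- solve_from(start)
        if (o2$value < o$value) o <- o2
      }
    } else {
      o <- solve_from(start)
    }
    eta <- o$par
    conv <- o$convergence == 0
  }
  f <- fn(eta)
  # Jacobian df/deta at the mode, central differences, relative step 1e-4
  J <- matrix(0, subj$n_obs, n_eta)
  for (k in seq_len(n_eta)) {
    h <- 1e-4 * max(1, abs(eta[k]))
    ep <- eta; ep[k] <- eta[k] + h
    en <- eta; en[k] <- eta[k] - h
    J[, k] <- (fn(ep) - fn(en)) / (2 * h)
  }
  v <- var_fn(f)
  C <- J %*% omega %*% t(J) + diag(v, nrow = subj$n_obs)
  U <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(U))
    return(list(ofv = 1e10, eta = eta, f = f, cwres = rep(NA_real_, subj$n_obs),
                converged = FALSE))
  r <- dv - f + drop(J %*% eta)
  z <- backsolve(U, r, transpose = TRUE)
  ofv <- 2 * sum(log(diag(U))) + sum(z^2)
  list(ofv = if (is.finite(ofv)) ofv else 1e10, eta = eta, f = f, J = J,
       cwres = z, converged = conv)
}

foce_details <- function(subjects, model, eta_start = NULL,
                         inner_reltol = 1e-12, dual = TRUE) {
  if (!is.null(model$iiv)) {
    omega_full <- model$iiv$omega
    active <- diag(omega_full) > 1e-12
    omega <- omega_full[active, active, drop = FALSE]
    eta_names <- rownames(omega_full)[active]
  } else {
    omega <- matrix(0, 0, 0)
    eta_names <- character(0)
  }
  omega_inv <- NULL
  if (length(eta_names)) {
    ch <- tryCatch(chol(omega), error = function(e) NULL)
    if (is.null(ch)) return(list(ofv = 1e10, ok = FALSE))
    omega_inv <- chol2inv(ch)
  }
  var_fn <- make_var_fn(model$error)
  out <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    subj <- subjects[[i]]
    th0 <- ind_theta(model, NULL, subj$covariates)
    fn <- make_subject_fn(model, subj, th0, eta_names)
    st <- if (!is.null(eta_start)) eta_start[[i]] else NULL
    if (!is.null(st) && length(st) != length(eta_names)) st <- NULL
    out[[i]] <- foce_subject(subj, fn, var_fn, omega, omega_inv,
                             length(eta_names), start = st,
                             inner_reltol = inner_reltol, dual = dual)
  }
  for (i in seq_along(out)) names(out[[i]]$eta) <- eta_names
  list(ofv = sum(vapply(out, `[[`, 0, "ofv")), per_subject = out,
       eta_names = eta_names, ok = TRUE)
}

#' FOCE-I objective function value
#'
#' The population objective: sum over subjects of the linearised -2 log
#' marginal likelihood at each subject's conditional \eqn{\eta} mode,
#' excluding the \eqn{n\log(2\pi)} constant. Additive over subjects and
#' invariant to subject ordering.
#'
#' @param ds a [pk_data()].
#' @param model a [poppk_model()].
#' @return Scalar OFV.
#' @export
foce_ofv <- function(ds, model) {
  foce_details(prep_subjects(ds), model)$ofv
}

#' Empirical Bayes (MAP) estimates with fixed population parameters
#'
#' Maximum a posteriori \eqn{\hat\eta} per subject given fixed population
#' parameters (no population update), with individual predictions evaluated
#' at \eqn{\hat\eta}.
#'
#' @param ds a [pk_data()].
#' @param model a [poppk_model()] with IIV.
#' @return List: `eta` (subjects x eta matrix), `ipred` (per-observation
#'   data frame with `ID`, `TIME`, `DV`, `IPRED`), `converged` (per subject).
#' @export
ebe_estimate <- function(ds, model) {
  subjects <- prep_subjects(ds)
  det <- foce_details(subjects, model)
  if (!det$ok) stop("omega is singular; cannot compute EBEs")
  eta <- do.call(rbind, lapply(det$per_subject, `[[`, "eta"))
  rownames(eta) <- vapply(subjects, function(s) as.character(s$id), "")
  colnames(eta) <- det$eta_names
  ipred <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    data.frame(ID = rep(s$id, length(s$times)), TIME = s$times, DV = s$dv,
               IPRED = det$per_subject[[i]]$f)
  }))
  list(eta = eta, ipred = ipred,
       converged = vapply(det$per_subject, `[[`, TRUE, "converged"))
}

# ---- outer estimation ---------------------------------------------------

#' Control settings for population fitting
#'
#' @param maxit maximum outer quasi-Newton iterations.
#' @param reltol outer relative convergence tolerance.
#' @param grad_step relative step for the outer central-difference gradient.
#' @param inner_reltol convergence tolerance of the inner \eqn{\eta} search.
#' @param n_starts number of starts; starts beyond the first jitter the
#'   transformed initial parameters with SD `jitter_sd` under seeds derived
#'   from `seed`.
#' @param jitter_sd SD of the multi-start jitter (transformed scale).
#' @param seed base seed for multi-start jitter.
#' @param restarts maximum BFGS restart rounds from the incumbent optimum
#'   (guards against premature line-search stalls); restarting stops once a
#'   round improves the OFV by less than `restart_tol`.
#' @param restart_tol OFV improvement below which restarting stops.
#' @param trace print outer progress every `trace` evaluations (0 = silent).
#' @return List of control settings.
#' @export
poppk_control <- function(maxit = 150, reltol = 1e-9, grad_step = 1e-4,
                          inner_reltol = 1e-12, n_starts = 1,
                          jitter_sd = 0.2, seed = 1, restarts = 2,
                          restart_tol = 0.5, trace = 0) {
  list(maxit = maxit, reltol = reltol, grad_step = grad_step,
       inner_reltol = inner_reltol, n_starts = n_starts,
       jitter_sd = jitter_sd, seed = seed, restarts = restarts,
       restart_tol = restart_tol, trace = trace)
}

# ---- parameter packing --------------------------------------------------
# Transformed ("packed") vector: log(theta) for estimated structural
# parameters, log-Cholesky entries per omega block, log(sigma), and
# form-specific transforms for covariate-effect coefficients.

make_packing <- function(model, estimate) {
  omega <- if (!is.null(model$iiv)) model$iiv$omega else NULL
  eta_names <- rownames(omega)
  blocks <- list()
  if (!is.null(omega)) {
    in_block <- character(0)
    for (b in model$iiv$blocks) {
      blocks <- c(blocks, list(b))
      in_block <- c(in_block, b)
    }
    for (nm in setdiff(eta_names, in_block)) blocks <- c(blocks, list(nm))
  }
  sig <- c(if (!is.null(model$error$sigma_add)) "sigma_add",
           if (!is.null(model$error$sigma_prop)) "sigma_prop")
  links <- model$covariate_links
  est_links <- which(vapply(links, function(l) !isTRUE(l$fixed), TRUE))
  list(estimate = estimate, blocks = blocks, eta_names = eta_names,
       sigma = sig, est_links = est_links)
}

pack_par <- function(model, pk) {
  p <- log(unlist(model$theta[pk$estimate]))
  names(p) <- pk$estimate
  omega <- if (!is.null(model$iiv)) model$iiv$omega else NULL
  for (b in pk$blocks) {
    if (length(b) == 1) {
      p <- c(p, stats::setNames(0.5 * log(omega[b, b]), paste0("omega.", b)))
    } else {
      L <- t(chol(omega[b, b]))
      p <- c(p, stats::setNames(
        c(log(L[1, 1]), L[2, 1], log(L[2, 2])),
        paste0("omchol.", paste(b, collapse = "_"), ".", 1:3)))
    }
  }
  for (s in pk$sigma)
    p <- c(p, stats::setNames(log(model$error[[s]]), s))
  for (i in pk$est_links) {
    ln <- model$covariate_links[[i]]
    tc <- ln$theta_cov
    if (ln$form == "proportional_shift") tc <- log1p(tc)
    p <- c(p, stats::setNames(tc, paste0("beta.", ln$covariate, ".",
                                         ln$parameter,
                                         if (length(tc) > 1) seq_along(tc) else "")))
  }
  p
}

unpack_par <- function(par, model, pk) {
  i <- 0
  take <- function(n) { out <- unname(par[i + seq_len(n)]); i <<- i + n; out }
  th <- model$theta
  for (nm in pk$estimate) th[[nm]] <- exp(take(1))
  if (!is.null(model$iiv)) {
    omega <- model$iiv$omega
    for (b in pk$blocks) {
      if (length(b) == 1) {
        omega[b, b] <- exp(2 * take(1))
      } else {
        v <- take(3)
        L <- matrix(c(exp(v[1]), v[2], 0, exp(v[3])), 2, 2)
        omega[b, b] <- L %*% t(L)
      }
    }
    model$iiv$omega <- omega
  }
  for (s in pk$sigma) model$error[[s]] <- exp(take(1))
  for (j in pk$est_links) {
    ln <- model$covariate_links[[j]]
    tc <- take(length(ln$theta_cov))
    if (ln$form == "proportional_shift") tc <- expm1(tc)
    model$covariate_links[[j]]$theta_cov <- unname(tc)
  }
  model$theta <- th
  model
}

# natural-scale report vector (for SE/RSE via the delta method)
natural_par <- function(model, pk) {
  out <- unlist(model$theta[pk$estimate])
  if (!is.null(model$iiv)) {
    omega <- model$iiv$omega
    for (b in pk$blocks) {
      if (length(b) == 1) {
        out <- c(out, stats::setNames(sqrt(omega[b, b]), paste0("omega_", b)))
      } else {
        s1 <- sqrt(omega[b[1], b[1]]); s2 <- sqrt(omega[b[2], b[2]])
        out <- c(out, stats::setNames(
          c(s1, s2, omega[b[1], b[2]] / (s1 * s2)),
          c(paste0("omega_", b), paste0("corr_", paste(b, collapse = "_")))))
      }
    }
  }
  for (s in pk$sigma) out <- c(out, stats::setNames(model$error[[s]], s))
  for (j in pk$est_links) {
    ln <- model$covariate_links[[j]]
    out <- c(out, stats::setNames(ln$theta_cov,
      paste0("beta_", ln$covariate, "_", ln$parameter,
             if (length(ln$theta_cov) > 1) seq_along(ln$theta_cov) else "")))
  }
  out
}

#' Fit a population pharmacokinetic model by FOCE-I
#'
#' Maximises the FOCE-with-interaction approximate marginal likelihood over
#' fixed effects, random-effect (co)variances and residual-error parameters.
#' All variance parameters are estimated on unconstrained transformed scales
#' (log for SDs and structural parameters, log-Cholesky for omega blocks), so
#' estimates are positive by construction. Empirical Bayes estimates and
#' shrinkage are computed at the optimum.
#'
#' @param ds a [pk_data()].
#' @param model a [poppk_model()] providing the structure and initial values.
#' @param init optional named list overriding initial typical values.
#' @param estimate character vector of structural parameters to estimate
#'   (default: all in `model$theta`).
#' @param control a [poppk_control()].
#' @return Object of class `poppk_fit` with components `model` (estimates),
#'   `ofv`, `eta` (EBE matrix), `shrinkage`, `converged`, `start_ofvs`,
#'   `n_ofv_evals`, and the data/packing needed by [covariance_step()],
#'   [cwres()] and the evaluation tools.
#' @seealso [covariance_step()], [shrinkage()], [cwres()], [vpc()],
#'   [bootstrap_poppk()]
#' @export
fit_poppk <- function(ds, model, init = NULL, estimate = NULL,
                      control = poppk_control()) {
  if (!is.null(init)) for (nm in names(init)) model$theta[[nm]] <- init[[nm]]
  if (is.null(estimate)) estimate <- names(model$theta)
  pk <- make_packing(model, estimate)
  subjects <- prep_subjects(ds, model)
  warm <- new.env(parent = emptyenv())
  warm$eta <- NULL
  # the OFV is mildly history-dependent through the warm-started inner
  # search, so the incumbent best point is tracked explicitly and the final
  # answer is taken from it rather than trusting the optimizer's bookkeeping
  incumbent <- new.env(parent = emptyenv())
  incumbent$ofv <- Inf
  n_evals <- 0L
  objfun <- function(par) {
    n_evals <<- n_evals + 1L
    m <- unpack_par(par, model, pk)
    # resynchronise the warm chains against the zero-start mode periodically;
    # in between, follow the warm chain (cheap and smooth)
    det <- foce_details(subjects, m, eta_start = warm$eta,
                        inner_reltol = control$inner_reltol,
                        dual = is.null(warm$eta) || n_evals %% 10L == 0L)
    if (!det$ok) return(1e10)
    warm$eta <- lapply(det$per_subject, `[[`, "eta")
    if (det$ofv < incumbent$ofv) {
      incumbent$ofv <- det$ofv
      incumbent$par <- par
      incumbent$eta <- warm$eta
    }
    if (control$trace > 0 && n_evals %% control$trace == 0)
      message(sprintf("  eval %d: OFV %.4f", n_evals, det$ofv))
    last$par <- par
    last$value <- det$ofv
    det$ofv
  }
  last <- new.env(parent = emptyenv())
  last$par <- NULL
  # forward-difference gradient, reusing the objective value the optimizer
  # just computed at the expansion point
  gradfun <- function(par) {
    f0 <- if (!is.null(last$par) && identical(last$par, par)) last$value
          else objfun(par)
    g <- numeric(length(par))
    for (k in seq_along(par)) {
      h <- control$grad_step * max(1, abs(par[k]))
      pp <- par; pp[k] <- par[k] + h
      g[k] <- (objfun(pp) - f0) / h
    }
    g
  }
  p0 <- pack_par(model, pk)
  starts <- list(p0)
  if (control$n_starts > 1) {
    for (s in 2:control$n_starts) {
      set.seed(control$seed + 977L * s)
      starts[[s]] <- p0 + stats::rnorm(length(p0), 0, control$jitter_sd)
    }
  }
  best <- NULL
  start_ofvs <- numeric(0)
  run_bfgs <- function(p) stats::optim(p, objfun, gr = gradfun,
                                       method = "BFGS",
                                       control = list(maxit = control$maxit,
                                                      reltol = control$reltol))
  converged <- TRUE
  for (s in seq_along(starts)) {
    warm$eta <- NULL
    incumbent$ofv <- Inf   # each start keeps its own incumbent
    incumbent$par <- NULL
    incumbent$eta <- NULL
    o <- run_bfgs(starts[[s]])
    conv_s <- o$convergence == 0
    for (r in seq_len(control$restarts)) {
      # continue from the incumbent best; escapes line-search stalls and
      # any drift of the optimizer away from the best visited point
      prev <- incumbent$ofv
      warm$eta <- incumbent$eta
      o <- run_bfgs(incumbent$par)
      conv_s <- o$convergence == 0
      if (prev - incumbent$ofv < control$restart_tol) break
    }
    start_ofvs <- c(start_ofvs, incumbent$ofv)
    if (is.null(best) || incumbent$ofv < best$value) {
      best <- list(par = incumbent$par, value = incumbent$ofv,
                   eta = incumbent$eta)
      converged <- conv_s
    }
  }
  final_model <- unpack_par(best$par, model, pk)
  det <- foce_details(subjects, final_model, eta_start = best$eta,
                      inner_reltol = control$inner_reltol)
  eta <- if (length(det$eta_names))
    matrix(unlist(lapply(det$per_subject, `[[`, "eta")),
           nrow = length(subjects), byrow = TRUE,
           dimnames = list(vapply(subjects, function(s) as.character(s$id), ""),
                           det$eta_names))
  else matrix(0, length(subjects), 0)
  fit <- structure(list(
    model = final_model, data = ds, subjects = subjects, packing = pk,
    par = best$par, ofv = det$ofv, eta = eta, details = det,
    converged = converged, start_ofvs = start_ofvs,
    n_ofv_evals = n_evals, control = control,
    se = NULL, rse = NULL, covariance_ok = NA), class = "poppk_fit")
  fit$shrinkage <- shrinkage(fit)
  fit
}

#' Parameter standard errors from the objective-function curvature
#'
#' Computes the covariance of the estimates as twice the inverse Hessian of
#' the OFV at the optimum (finite differences on the transformed scale) and
#' propagates it to the natural scale by the delta method. When the Hessian
#' is not positive definite the covariance step is flagged as failed
#' (`covariance_ok = FALSE`), mirroring the practice of rejecting candidate
#' models whose covariance step does not complete.
#'
#' @param fit a [fit_poppk()] result.
#' @param h relative finite-difference step.
#' @return The fit with `se`, `rse` (percent) and `covariance_ok` filled in.
#' @export
covariance_step <- function(fit, h = 1e-3) {
  pk <- fit$packing
  subjects <- fit$subjects
  base_model <- fit$model
  # repack from the final model so the expansion point is the optimum
  par <- pack_par(base_model, pk)
  ofv_at <- function(p) {
    det <- foce_details(subjects, unpack_par(p, base_model, pk),
                        inner_reltol = fit$control$inner_reltol)
    if (!det$ok) return(1e10)
    det$ofv
  }
  n <- length(par)
  hh <- h * pmax(1, abs(par))
  f0 <- ofv_at(par)
  H <- matrix(0, n, n)
  fp <- fm <- numeric(n)
  for (k in seq_len(n)) {
    pp <- par; pp[k] <- par[k] + hh[k]
    pm <- par; pm[k] <- par[k] - hh[k]
    fp[k] <- ofv_at(pp); fm[k] <- ofv_at(pm)
    H[k, k] <- (fp[k] + fm[k] - 2 * f0) / hh[k]^2
  }
  for (k in seq_len(n - 1)) for (l in (k + 1):n) {
    ppp <- par; ppp[k] <- par[k] + hh[k]; ppp[l] <- par[l] + hh[l]
    pmm <- par; pmm[k] <- par[k] - hh[k]; pmm[l] <- par[l] - hh[l]
    H[k, l] <- H[l, k] <-
      (ofv_at(ppp) + ofv_at(pmm) - fp[k] - fm[k] - fp[l] - fm[l] + 2 * f0) /
      (2 * hh[k] * hh[l])
  }
  ok <- !inherits(tryCatch(chol(H), error = function(e) e), "error")
  fit$covariance_ok <- ok
  if (!ok) return(fit)
  cov_par <- 2 * chol2inv(chol(H))
  # delta method to the natural report scale
  nat0 <- natural_par(base_model, pk)
  G <- matrix(0, length(nat0), n)
  for (k in seq_len(n)) {
    pp <- par; pp[k] <- par[k] + hh[k]
    pm <- par; pm[k] <- par[k] - hh[k]
    G[, k] <- (natural_par(unpack_par(pp, base_model, pk), pk) -
               natural_par(unpack_par(pm, base_model, pk), pk)) / (2 * hh[k])
  }
  v <- diag(G %*% cov_par %*% t(G))
  if (any(v < 0)) { fit$covariance_ok <- FALSE; return(fit) }
  fit$se <- stats::setNames(sqrt(v), names(nat0))
  fit$rse <- 100 * fit$se / abs(nat0)
  fit$cov_natural <- G %*% cov_par %*% t(G)
  fit
}

#' Eta shrinkage
#'
#' \eqn{100 (1 - SD(\hat\eta_k)/\omega_k)} per random effect. High shrinkage
#' means the individual estimates collapse toward the population mean and the
#' empirical Bayes estimates carry little individual information.
#'
#' @param fit a [fit_poppk()] result (or any list with `eta` and `model`).
#' @return Named vector of shrinkage percentages (`NA` where \eqn{\omega = 0}
#'   or fewer than two subjects).
#' @export
shrinkage <- function(fit) {
  eta <- fit$eta
  if (is.null(eta) || ncol(eta) == 0) return(stats::setNames(numeric(0), character(0)))
  om <- sqrt(diag(fit$model$iiv$omega))[colnames(eta)]
  out <- rep(NA_real_, ncol(eta))
  names(out) <- colnames(eta)
  if (nrow(eta) >= 2) {
    sde <- apply(eta, 2, stats::sd)
    ok <- om > 0
    out[ok] <- 100 * (1 - sde[ok] / om[ok])
  }
  out
}

#' Conditional weighted residuals
#'
#' FOCE-linearised residuals
#' \eqn{CWRES_i = L_i^{-1}(y_i - f_i(\hat\eta) + J_i\hat\eta)} with
#' \eqn{L_i L_i' = J_i \Omega J_i' + diag(v_i)}; approximately standard
#' normal under the true model.
#'
#' @param fit a [fit_poppk()] result.
#' @return Numeric vector, one residual per observation (data order).
#' @export
cwres <- function(fit) {
  unlist(lapply(fit$details$per_subject, `[[`, "cwres"), use.names = FALSE)
}
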