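# Structural (deterministic) concentration models.
#
# All disposition systems are linear mammillary compartment models with
# first-order elimination from the central compartment; all parameters are
# apparent (scaled by oral bioavailability F, which is not identifiable with
# oral-only data and therefore never appears as its own symbol). Units are
# fixed package-wide: mg (dose), h (time), mg/L (concentration), L/h
# (clearances), L (volumes).

# Gauss-Legendre nodes/weights on [-1, 1] via Golub-Welsch; cached.
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  if (n == 1) {
    gl <- list(x = 0, w = 2)
  } else {
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    gl <- list(x = e$values, w = 2 * e$vectors[1, ]^2)
  }
  .gl_cache[[key]] <- gl
  gl
}

.absorption_kinds <- c("first_order", "first_order_lag", "zero_order_lag",
                       "double_peak", "double_peak_1ka", "transit")

#' Define a structural pharmacokinetic model
#'
#' A structural model combines a number of disposition compartments with an
#' absorption hypothesis. The candidate ladder mirrors standard practice for
#' delayed oral absorption: plain first-order absorption, first-order with a
#' lag time, zero-order (constant-rate) input with a lag time, a double-peak
#' model splitting the dose over two parallel first-order paths (optionally
#' sharing one rate constant), and a transit-compartment model in which the
#' dose passes through a chain of `n_transit` hypothetical compartments
#' (continuous, via the gamma function) with mean transit time `mtt` before
#' first-order absorption at rate `ka`.
#'
#' @param n_cpt number of disposition compartments (1, 2 or 3).
#' @param absorption one of `"first_order"`, `"first_order_lag"`,
#'   `"zero_order_lag"`, `"double_peak"`, `"double_peak_1ka"`, `"transit"`.
#' @return An object of class `pk_structure` listing the structural
#'   parameters the model requires.
#' @examples
#' pk_structure(2, "transit")
#' @export
pk_structure <- function(n_cpt = 2, absorption = "transit") {
  if (!n_cpt %in% 1:3) stop("n_cpt must be 1, 2 or 3")
  absorption <- match.arg(absorption, .absorption_kinds)
  disp <- switch(n_cpt, c("cl", "v1"), c("cl", "v1", "q", "v2"),
                 c("cl", "v1", "q", "v2", "q3", "v3"))
  abs_par <- switch(absorption,
    first_order = "ka",
    first_order_lag = c("ka", "alag"),
    zero_order_lag = c("d_zero", "alag"),
    double_peak = c("frac1", "ka", "alag", "ka2", "alag2"),
    double_peak_1ka = c("frac1", "ka", "alag", "alag2"),
    transit = c("ka", "mtt", "n_transit"))
  structure(list(n_cpt = n_cpt, absorption = absorption,
                 parameters = c(disp, abs_par)),
            class = "pk_structure")
}

#' @export
print.pk_structure <- function(x, ...) {
  cat(sprintf("Structural PK model: %d-compartment disposition, %s absorption\n",
              x$n_cpt, gsub("_", "-", x$absorption)))
  cat("  parameters:", paste(x$parameters, collapse = ", "), "\n")
  invisible(x)
}

#' Define a dosing regimen
#'
#' @param times dose times (h), strictly increasing.
#' @param amounts dose amounts (mg), positive; recycled to `length(times)`.
#' @param tau dosing interval (h) for repeated/steady-state dosing, or `NA`.
#' @param label free-text regimen label (e.g. `"400qd"`).
#' @return An object of class `pk_regimen`.
#' @export
pk_regimen <- function(times = 0, amounts = 400, tau = NA_real_, label = "") {
  amounts <- rep_len(amounts, length(times))
  if (any(amounts < 0)) stop("dose amounts must be nonnegative")
  if (is.unsorted(times, strictly = TRUE)) stop("dose times must be strictly increasing")
  structure(list(times = as.numeric(times), amounts = as.numeric(amounts),
                 tau = tau, label = label),
            class = "pk_regimen")
}

#' Transit-compartment drug input rate
#'
#' Rate of drug arrival in the absorption depot after passage through a chain
#' of transit compartments:
#' \deqn{r(t) = D \, k_{tr} (k_{tr} t)^N e^{-k_{tr} t} / \Gamma(N+1),\quad
#'       k_{tr} = (N+1)/MTT,}
#' i.e. a gamma(\eqn{N+1}, \eqn{k_{tr}}) density scaled by the dose. The
#' gamma function is evaluated through the log-gamma so the number of transit
#' compartments \eqn{N} may be any nonnegative real. The rate integrates to
#' the dose over \eqn{[0, \infty)}.
#'
#' @param t time since dose (h), nonnegative (vectorised).
#' @param dose dose amount (mg).
#' @param mtt mean transit time (h), positive.
#' @param n_transit number of transit compartments, nonnegative real.
#' @return Input rate (mg/h) at each `t`.
#' @export
transit_input_rate <- function(t, dose, mtt, n_transit) {
  if (any(t < 0)) stop("t must be nonnegative")
  if (mtt <= 0) stop("mtt must be positive")
  if (n_transit < 0) stop("n_transit must be nonnegative")
  ktr <- (n_transit + 1) / mtt
  dose * stats::dgamma(t, shape = n_transit + 1, rate = ktr)
}

# amount-in-central exponential modes for a unit bolus into the central
# compartment: A_c(t) = sum_i r_i exp(-lambda_i t), sum r_i = 1
disposition_modes <- function(theta, n_cpt) {
  k10 <- theta[["cl"]] / theta[["v1"]]
  if (n_cpt == 1) return(list(lambda = k10, r = 1))
  if (n_cpt == 2) {
    k12 <- theta[["q"]] / theta[["v1"]]
    k21 <- theta[["q"]] / theta[["v2"]]
    s <- k10 + k12 + k21
    disc2 <- s^2 - 4 * k10 * k21
    if (disc2 < 1e-14 * s^2) {  # repeated-root guard
      k21 <- k21 * (1 + 1e-7)
      s <- k10 + k12 + k21
      disc2 <- s^2 - 4 * k10 * k21
    }
    disc <- sqrt(max(disc2, 0))
    alpha <- (s + disc) / 2
    beta <- (s - disc) / 2
    return(list(lambda = c(alpha, beta),
                r = c((alpha - k21) / (alpha - beta), (k21 - beta) / (alpha - beta))))
  }
  k12 <- theta[["q"]] / theta[["v1"]]
  k21 <- theta[["q"]] / theta[["v2"]]
  k13 <- theta[["q3"]] / theta[["v1"]]
  k31 <- theta[["q3"]] / theta[["v3"]]
  A <- matrix(c(-(k10 + k12 + k13), k21, k31,
                k12, -k21, 0,
                k13, 0, -k31), 3, 3, byrow = TRUE)
  e <- eigen(A)
  Vi <- solve(e$vectors)
  list(lambda = -Re(e$values), r = Re(e$vectors[1, ] * Vi[, 1]))
}

# modes of the amount-in-central response to a unit dose placed in a
# first-order depot (rate ka): Bateman-type convolution of exp(-ka t)
oral_modes <- function(modes, ka) {
  lam <- modes$lambda
  coll <- abs(ka - lam) < 1e-9 * (ka + lam)
  if (any(coll)) ka <- ka * (1 + 1e-8)
  cc <- modes$r * ka / (ka - lam)
  list(lambda = c(lam, ka), c = c(cc, -sum(cc)))
}

# single-dose concentration for closed-form absorption models (everything
# except transit), unit-ready for multiple doses via superposition
conc_closed_form <- function(struct, theta, dose_t, dose_amt, times) {
  dm <- disposition_modes(theta, struct$n_cpt)
  v1 <- theta[["v1"]]
  out <- numeric(length(times))
  first_order_path <- function(D, ka, alag, t0) {
    om <- oral_modes(dm, ka)
    tt <- times - t0 - alag
    pos <- tt > 0
    if (!any(pos)) return(numeric(length(times)))
    a <- numeric(length(times))
    for (m in seq_along(om$lambda))
      a[pos] <- a[pos] + om$c[m] * exp(-om$lambda[m] * tt[pos])
    D * a / v1
  }
  for (d in seq_along(dose_t)) {
    D <- dose_amt[d]
    t0 <- dose_t[d]
    out <- out + switch(struct$absorption,
      first_order = first_order_path(D, theta[["ka"]], 0, t0),
      first_order_lag = first_order_path(D, theta[["ka"]], theta[["alag"]], t0),
      double_peak = first_order_path(D * theta[["frac1"]], theta[["ka"]],
                                     theta[["alag"]], t0) +
        first_order_path(D * (1 - theta[["frac1"]]), theta[["ka2"]],
                         theta[["alag2"]], t0),
      double_peak_1ka = first_order_path(D * theta[["frac1"]], theta[["ka"]],
                                         theta[["alag"]], t0) +
        first_order_path(D * (1 - theta[["frac1"]]), theta[["ka"]],
                         theta[["alag2"]], t0),
      zero_order_lag = {
        dz <- theta[["d_zero"]]
        R0 <- D / dz
        ts <- times - t0 - theta[["alag"]]
        pos <- ts > 0
        a <- numeric(length(times))
        for (m in seq_along(dm$lambda)) {
          lam <- dm$lambda[m]
          up <- pmin(ts[pos], dz)
          a[pos] <- a[pos] + dm$r[m] / lam *
            (exp(-lam * (ts[pos] - up)) - exp(-lam * ts[pos]))
        }
        R0 * a / v1
      },
      stop("unsupported absorption kind"))
  }
  pmax(out, 0)
}

# dispatch: concentration for arbitrary dose events (times/amounts vectors);
# non-finite parameters (reachable through unconstrained optimizer trials)
# yield NaN predictions, which the estimation layer converts to a penalty
conc_dose_events <- function(struct, theta, dose_t, dose_amt, times) {
  pv <- unlist(theta[setdiff(struct$parameters, "n_transit")], use.names = FALSE)
  nt <- if ("n_transit" %in% struct$parameters) theta[["n_transit"]] else 0
  if (!all(is.finite(pv)) || any(pv <= 0) || !is.finite(nt) || nt < 0)
    return(rep(NaN, length(times)))
  if (struct$absorption == "transit") {
    if (struct$n_cpt == 3) stop("transit absorption supports 1- or 2-compartment disposition")
    gl <- gauss_legendre(40L)
    q <- if (struct$n_cpt == 2) theta[["q"]] else 0
    v2 <- if (struct$n_cpt == 2) theta[["v2"]] else 0
    conc_transit_cpp(times, dose_t, dose_amt,
                     theta[["cl"]], theta[["v1"]], q, v2,
                     theta[["ka"]], theta[["mtt"]], theta[["n_transit"]],
                     gl$x, gl$w)
  } else {
    conc_closed_form(struct, theta, dose_t, dose_amt, times)
  }
}

check_theta <- function(struct, theta) {
  missing <- setdiff(struct$parameters, names(theta))
  if (length(missing))
    stop("incomplete theta for this structure; missing: ",
         paste(missing, collapse = ", "))
  pos <- setdiff(struct$parameters, "n_transit")
  if (any(unlist(theta[pos]) <= 0))
    stop("structural parameters must be positive")
  if ("n_transit" %in% struct$parameters && theta[["n_transit"]] < 0)
    stop("n_transit must be nonnegative")
  if ("frac1" %in% struct$parameters &&
      (theta[["frac1"]] <= 0 || theta[["frac1"]] >= 1))
    stop("frac1 must lie in (0, 1)")
  invisible(TRUE)
}

#' Predict concentrations from a structural model
#'
#' Deterministic concentration-time prediction for a given parameter vector
#' and dosing regimen. Disposition is handled analytically through the
#' exponential modes of the linear compartment system; closed-form solutions
#' are used for first-order, lagged, zero-order and double-peak absorption,
#' and adaptive-free Gauss-Legendre convolution of the gamma-density transit
#' input for the transit model. Solutions are linear in dose and obey
#' superposition.
#'
#' @param struct a [pk_structure()].
#' @param theta named list/vector of structural parameters (see
#'   `struct$parameters`).
#' @param regimen a [pk_regimen()].
#' @param times observation times (h since first dose), nonnegative.
#' @return Numeric vector of concentrations (mg/L).
#' @export
predict_conc <- function(struct, theta, regimen, times) {
  theta <- as.list(theta)
  check_theta(struct, theta)
  if (any(times < 0)) stop("times must be nonnegative")
  conc_dose_events(struct, theta, regimen$times, regimen$amounts, times)
}

# number of superposed doses needed for the trough to converge within rtol
n_doses_for_ss <- function(struct, theta, tau, rtol = 0.001) {
  pv <- unlist(theta[struct$parameters], use.names = FALSE)
  if (!all(is.finite(pv))) return(5L)   # prediction will be NaN anyway
  lam_min <- min(disposition_modes(as.list(theta), struct$n_cpt)$lambda)
  k <- ceiling(-log(rtol) / (lam_min * tau)) + 2L
  min(max(k, 5L), 1000L)
}

#' Steady-state concentration profile over one dosing interval
#'
#' Superposes identical doses given every `tau` hours until the trough
#' concentration changes by less than `rtol` (default 0.1\%) between
#' successive intervals, and returns the concentration at times within (or
#' beyond) one interval after the last dose. Times may exceed `tau` to
#' describe samples drawn after a skipped or delayed dose.
#'
#' @param struct a [pk_structure()].
#' @param theta named structural parameters.
#' @param dose dose amount (mg) given each interval.
#' @param tau dosing interval (h), positive.
#' @param times times after the last dose (h) at which to evaluate.
#' @param rtol relative trough convergence tolerance.
#' @return Concentrations (mg/L) at `times`.
#' @export
steady_state_profile <- function(struct, theta, dose, tau, times, rtol = 0.001) {
  theta <- as.list(theta)
  check_theta(struct, theta)
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  K <- n_doses_for_ss(struct, theta, tau, rtol)
  dose_t <- -(seq_len(K) - 1) * tau   # doses at 0, -tau, -2 tau, ...
  conc_dose_events(struct, theta, dose_t, rep(dose, K), times)
}

#' Secondary parameters of the two-compartment transit model
#'
#' Standard two-compartment algebra: hybrid rate constants \eqn{\alpha} and
#' \eqn{\beta} satisfy \eqn{\alpha\beta = k_{10}k_{21}} and
#' \eqn{\alpha+\beta = k_{10}+k_{12}+k_{21}}; the terminal half-life is
#' \eqn{\ln 2/\beta}; the transit rate constant is
#' \eqn{k_{tr} = (N+1)/MTT}; the apparent steady-state volume is
#' \eqn{V_1 + V_2}.
#'
#' @param theta named parameters including `cl`, `v1`, `q`, `v2` and, when
#'   present, `mtt` and `n_transit`.
#' @return Named list: `ktr` (1/h, when transit parameters present), `alpha`,
#'   `beta` (1/h), `t_half_terminal` (h), `vss` (L).
#' @export
secondary_parameters <- function(theta) {
  theta <- as.list(theta)
  need <- c("cl", "v1", "q", "v2")
  if (!all(need %in% names(theta)))
    stop("secondary_parameters requires two-compartment parameters (cl, v1, q, v2)")
  if (any(c("q3", "v3") %in% names(theta)))
    stop("three-compartment models are not supported here")
  dm <- disposition_modes(theta, 2)
  out <- list(alpha = max(dm$lambda), beta = min(dm$lambda))
  out$t_half_terminal <- log(2) / out$beta
  out$vss <- theta[["v1"]] + theta[["v2"]]
  if (all(c("mtt", "n_transit") %in% names(theta)))
    out$ktr <- (theta[["n_transit"]] + 1) / theta[["mtt"]]
  out
}
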