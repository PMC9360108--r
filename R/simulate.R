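# Synthetic cohort generators. The healthy-volunteer design emulates a
# single-dose 400 mg rich-sampling bioequivalence-style study (26 subjects,
# 17 samples from 0.5 to 72 h, dense through the absorption peak); the
# patient design emulates steady-state therapeutic drug monitoring in GIST
# patients on 200-600 mg daily regimens with mostly trough sampling.

#' Canonical rich sampling schedule for the healthy cohort
#'
#' 0.5-12 h dense (14 points, 0.5 h steps through the absorption peak) plus
#' 24, 48 and 72 h: 17 samples, inside the 16-19-sample range of the design
#' being emulated.
#'
#' @return Numeric vector of sampling times (h).
#' @export
default_schedule <- function() {
  c(0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5, 6, 8, 10, 12, 24, 48, 72)
}

#' Default allele frequencies for the genotype simulator
#'
#' Plausible European allele frequencies for the genotyped panel. These are
#' placeholders chosen for realism of the simulated cohorts; they are not
#' estimates from any specific study population.
#'
#' @return Named list: locus -> named numeric vector of allele frequencies
#'   (summing to 1).
#' @export
default_allele_freqs <- function() {
  list(
    CYP3A4 = c("*1" = 0.96, "*20" = 0.01, "*22" = 0.03),
    CYP3A5 = c("*1" = 0.08, "*3" = 0.92),
    CYP2C9 = c("*1" = 0.81, "*2" = 0.12, "*3" = 0.07),
    CYP2C19 = c("*1" = 0.63, "*2" = 0.15, "*17" = 0.22),
    CYP2C8 = c("*1" = 0.84, "*3" = 0.11, "*4" = 0.05),
    CYP2B6_G516T = c("G" = 0.75, "T" = 0.25),
    CYP2D6 = c("*1" = 0.73, "*3" = 0.02, "*4" = 0.18, "*5" = 0.04, "*9" = 0.03),
    ABCB1_C3435T = c("C" = 0.48, "T" = 0.52))
}

# truncated lognormal draw with given median and log-SD
rlnorm_trunc <- function(n, median, sdlog, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n, log(median), sdlog)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Simulate subject covariates
#'
#' Demographics are drawn from truncated lognormal distributions matching
#' the medians and ranges of the emulated healthy cohort (median age 23.0 y,
#' weight 69.5 kg, BMI 22.5 kg/m2, BSA 1.86 m2; 18 males to 8 females).
#' Height is implied by weight and BMI, BSA by the Mosteller formula.
#' Diplotypes are drawn under Hardy-Weinberg proportions per locus.
#'
#' @param n number of subjects.
#' @param seed RNG seed.
#' @param allele_freqs as [default_allele_freqs()].
#' @param prop_male proportion of males (default 18/26).
#' @return Data frame: `ID`, `SEX`, `AGE`, `WT`, `BMI`, `BSA` plus one
#'   diplotype column per locus.
#' @export
simulate_covariates <- function(n, seed = 1, allele_freqs = default_allele_freqs(),
                                prop_male = 18 / 26) {
  for (locus in names(allele_freqs)) {
    f <- allele_freqs[[locus]]
    if (abs(sum(f) - 1) > 1e-8)
      stop("allele frequencies for ", locus, " must sum to 1")
  }
  set.seed(seed)
  wt <- rlnorm_trunc(n, 69.5, 0.14, 52, 96)
  bmi <- rlnorm_trunc(n, 22.5, 0.10, 20, 30)
  age <- rlnorm_trunc(n, 23.0, 0.10, 19.7, 31.0)
  ht <- sqrt(wt / bmi)                      # m
  bsa <- sqrt(ht * 100 * wt / 3600)         # Mosteller
  sex <- ifelse(stats::runif(n) < prop_male, "M", "F")
  out <- data.frame(ID = seq_len(n), SEX = sex, AGE = age, WT = wt,
                    BMI = bmi, BSA = bsa, stringsAsFactors = FALSE)
  for (locus in names(allele_freqs)) {
    f <- allele_freqs[[locus]]
    a1 <- sample(names(f), n, replace = TRUE, prob = f)
    a2 <- sample(names(f), n, replace = TRUE, prob = f)
    snp <- all(nchar(names(f)) == 1)
    out[[locus]] <- vapply(seq_len(n), function(i) {
      al <- sort(c(a1[i], a2[i]))
      if (snp) paste0(al, collapse = "") else paste(al, collapse = "/")
    }, "")
  }
  out
}

# draw a matrix of etas (n x n_eta) from the model's omega
draw_etas <- function(model, n) {
  if (is.null(model$iiv)) return(matrix(0, n, 0))
  omega <- model$iiv$omega
  L <- chol(omega)
  z <- matrix(stats::rnorm(n * ncol(omega)), n)
  eta <- z %*% L
  colnames(eta) <- rownames(omega)
  eta
}

add_residual_error <- function(f, error) {
  n <- length(f)
  dv <- f
  if (!is.null(error$sigma_prop)) dv <- dv * (1 + stats::rnorm(n, 0, error$sigma_prop))
  if (!is.null(error$sigma_add)) dv <- dv + stats::rnorm(n, 0, error$sigma_add)
  dv
}

#' Simulate the healthy-volunteer cohort
#'
#' Each subject receives a single oral dose; individual parameters are
#' \eqn{TV e^\eta} with \eqn{\eta \sim N(0, \Omega)} (covariate links in
#' `model`, if any, are applied to the typical values first), concentrations
#' follow the structural model, and observations add residual error
#' according to the model's error specification.
#'
#' @param n number of subjects (default 26).
#' @param model generating [poppk_model()] (default [reference_model()]).
#' @param schedule sampling times (h), default [default_schedule()].
#' @param dose dose (mg), default 400.
#' @param seed RNG seed.
#' @param covariates optional covariate data frame (default simulated via
#'   [simulate_covariates()] with a seed derived from `seed`).
#' @param loq dataset LOQ (mg/L).
#' @return A [pk_data()]; the generating etas and model are attached as
#'   `attr(ds, "sim")`.
#' @export
simulate_healthy_cohort <- function(n = 26, model = reference_model(),
                                    schedule = default_schedule(), dose = 400,
                                    seed = 1, covariates = NULL, loq = 0.01) {
  if (is.null(covariates)) covariates <- simulate_covariates(n, seed = seed + 211L)
  set.seed(seed)
  eta <- draw_etas(model, n)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    covs <- as.list(covariates[i, , drop = FALSE])
    th <- ind_theta(model, eta[i, ], covs)
    f <- conc_dose_events(model$structure, th, 0, dose, schedule)
    dv <- add_residual_error(f, model$error)
    recs[[i]] <- data.frame(
      ID = i, TIME = c(0, schedule), AMT = c(dose, rep(0, length(schedule))),
      DV = c(NA, dv), EVID = c(1L, rep(0L, length(schedule))),
      MDV = c(1L, rep(0L, length(schedule))),
      REGIMEN = "single-400", stringsAsFactors = FALSE)
  }
  ds <- pk_data(do.call(rbind, recs), covariates = covariates, loq = loq)
  attr(ds, "sim") <- list(eta = eta, model = model, dose = dose,
                          schedule = schedule, seed = seed)
  ds
}

.regimen_defs <- list(
  "200qd" = list(dose = 200, tau = 24), "300qd" = list(dose = 300, tau = 24),
  "400qd" = list(dose = 400, tau = 24), "600qd" = list(dose = 600, tau = 24),
  "400bid" = list(dose = 400, tau = 12))

regimen_tau <- function(label) {
  d <- .regimen_defs[[label]]
  if (is.null(d)) NA_real_ else d$tau
}

#' Simulate the steady-state patient cohort
#'
#' Patients on chronic oral dosing (200/300/400/600 mg once daily or 400 mg
#' twice daily), sampled mostly at trough: recorded times-after-dose scatter
#' around the dosing interval tau on a lognormal scale (`tad_sdlog`), so a
#' fraction of the samples exceeds the prescribed interval, as in outpatient
#' monitoring. Patient clearance is scaled by `cl_scale` relative to the
#' healthy typical value (default 0.75, matching the lower clearance
#' reported in GIST patients: 13.2 x 0.75 = 9.9 L/h). A `noncompliance_rate`
#' fraction of observations is simulated after an unrecorded skipped dose
#' (true concentration from one extra interval of decay) while the recorded
#' dosing history still claims regular dosing.
#'
#' @param n number of patients (default 40).
#' @param model healthy-population [poppk_model()] (default
#'   [reference_model()]); `cl_scale` is applied to its typical clearance to
#'   form the patient truth.
#' @param cl_scale clearance multiplier for the patient population.
#' @param regimen_mix named probabilities over
#'   `c("200qd","300qd","400qd","600qd","400bid")`; must sum to 1.
#' @param n_obs_range inclusive range of observations per patient.
#' @param tad_sdlog lognormal SD of recorded time-after-dose around tau
#'   (0 puts every sample exactly at tau).
#' @param noncompliance_rate fraction of observations following a skipped
#'   dose.
#' @param seed RNG seed.
#' @param loq dataset LOQ (mg/L).
#' @return A [pk_data()] with steady-state dose rows (`SS = 1`, `II` = tau)
#'   and trough observations; generation truth in `attr(ds, "sim")`.
#' @export
simulate_patient_cohort <- function(n = 40, model = reference_model(),
                                    cl_scale = 0.75,
                                    regimen_mix = c("200qd" = 0.05, "300qd" = 0.075,
                                                    "400qd" = 0.75, "600qd" = 0.05,
                                                    "400bid" = 0.075),
                                    n_obs_range = c(3, 6), tad_sdlog = 0.5,
                                    noncompliance_rate = 0.05, seed = 1,
                                    loq = 0.01) {
  if (abs(sum(regimen_mix) - 1) > 1e-8) stop("regimen_mix must sum to 1")
  truth <- model
  truth$theta$cl <- truth$theta$cl * cl_scale
  set.seed(seed)
  eta <- draw_etas(truth, n)
  reg <- sample(names(regimen_mix), n, replace = TRUE, prob = regimen_mix)
  recs <- vector("list", n)
  nonc <- vector("list", n)
  for (i in seq_len(n)) {
    th <- ind_theta(truth, eta[i, ], NULL)
    def <- .regimen_defs[[reg[i]]]
    k <- sample(seq(n_obs_range[1], n_obs_range[2]), 1)
    tad <- if (tad_sdlog > 0) def$tau * stats::rlnorm(k, 0, tad_sdlog)
           else rep(def$tau, k)
    tad <- sort(round(tad, 2))
    skip <- stats::runif(k) < noncompliance_rate
    true_tad <- tad + ifelse(skip, def$tau, 0)
    f <- steady_state_profile(truth$structure, th, def$dose, def$tau, true_tad)
    dv <- add_residual_error(f, truth$error)
    recs[[i]] <- data.frame(
      ID = i, TIME = c(0, tad), AMT = c(def$dose, rep(0, k)),
      DV = c(NA, dv), EVID = c(1L, rep(0L, k)), MDV = c(1L, rep(0L, k)),
      SS = c(1L, rep(0L, k)), II = c(def$tau, rep(NA, k)),
      REGIMEN = reg[i], stringsAsFactors = FALSE)
    nonc[[i]] <- skip
  }
  ds <- pk_data(do.call(rbind, recs), loq = loq)
  attr(ds, "sim") <- list(eta = eta, model = truth, regimen = reg,
                          cl_scale = cl_scale, skipped = nonc, seed = seed)
  ds
}

#' Rebuild a simulated cohort with a covariate effect in the truth
#'
#' Positive-control generator for the covariate scan: the individual
#' parameters of an existing simulated dataset are regenerated with `link`
#' applied to the typical values before the (unchanged) etas, and the
#' concentrations and residual errors are re-simulated.
#'
#' @param ds a dataset from [simulate_healthy_cohort()].
#' @param link a [covariate_link()]; its covariate must be present in
#'   `ds$covariates`.
#' @param seed RNG seed for the new residual errors.
#' @return A new [pk_data()] with the effect built into the truth.
#' @export
inject_covariate_effect <- function(ds, link, seed = 1) {
  sim <- attr(ds, "sim")
  if (is.null(sim)) stop("ds must come from simulate_healthy_cohort()")
  model <- sim$model
  model$covariate_links <- c(model$covariate_links, list(link))
  set.seed(seed)
  r <- ds$records
  for (i in seq_len(nrow(sim$eta))) {
    id <- unique(r$ID)[i]
    covs <- as.list(ds$covariates[ds$covariates$ID == id, , drop = FALSE])
    th <- ind_theta(model, sim$eta[i, ], covs)
    obs <- which(r$ID == id & r$EVID == 0)
    f <- conc_dose_events(model$structure, th, 0, sim$dose, r$TIME[obs])
    r$DV[obs] <- add_residual_error(f, model$error)
  }
  out <- pk_data(r, covariates = ds$covariates, loq = ds$loq)
  attr(out, "sim") <- c(sim, list(injected_link = link))
  out
}

#' Simulate individual exposure metrics from a population model
#'
#' Draws `n` subjects from the model's IIV distribution, computes each
#' subject's noise-free concentration curve after a single oral dose on a
#' dense grid (0.01 h steps through the absorption peak), and returns the
#' individual exposure metrics: truncated AUC (linear trapezoid on the
#' dense grid), Cmax, tmax, clearance and total apparent distribution
#' volume. Cohort geometric summaries of these metrics follow via
#' [geometric_stats()].
#'
#' @param n number of simulated subjects.
#' @param model a [poppk_model()] (default [reference_model()]).
#' @param dose single oral dose (mg).
#' @param seed RNG seed.
#' @param auc_to AUC truncation time (h), default 72.
#' @param grid_end end of the 0.01-h grid for the Cmax search (h).
#' @return Data frame: `cl`, `vd`, `cmax`, `tmax`, `auc_0_t` per subject.
#' @export
simulate_pk_metrics <- function(n, model = reference_model(), dose = 400,
                                seed = 1, auc_to = 72, grid_end = 12) {
  set.seed(seed)
  eta <- draw_etas(model, n)
  grid <- c(seq(0.01, grid_end, by = 0.01),
            seq(grid_end + 0.05, auc_to, by = 0.05))
  out <- matrix(NA_real_, n, 5,
                dimnames = list(NULL, c("cl", "vd", "cmax", "tmax", "auc_0_t")))
  for (i in seq_len(n)) {
    th <- ind_theta(model, eta[i, ], NULL)
    conc <- conc_dose_events(model$structure, th, 0, dose, grid)
    imax <- which.max(conc)
    out[i, ] <- c(th[["cl"]],
                  th[["v1"]] + if ("v2" %in% names(th)) th[["v2"]] else 0,
                  conc[imax], grid[imax], trapz_auc(grid, conc))
  }
  as.data.frame(out)
}

# simulate replacement DVs at the design of prepared subjects (used by VPC
# and the simulate() method); returns a list of DV vectors per subject
simulate_dv <- function(model, subjects) {
  eta <- draw_etas(model, length(subjects))
  lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    th <- ind_theta(model, eta[i, ], s$covariates)
    add_residual_error(pred_subject(model, th, s), model$error)
  })
}
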