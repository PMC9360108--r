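# Shared fixtures: small, fast models and cohorts built in code.

# one-compartment oral model with IIV on CL only; fits in seconds
small_1cpt_model <- function(error = error_spec("proportional", sigma_prop = 0.1),
                             cv_cl = 25) {
  poppk_model(pk_structure(1, "first_order"),
              theta = list(cl = 10, v1 = 100, ka = 1.5),
              iiv = iiv_spec(cv_percent = c(cl = cv_cl)),
              error = error)
}

small_schedule <- c(1, 2, 4, 8, 24)

sim_small_cohort <- function(n = 16, model = small_1cpt_model(), seed = 1,
                             schedule = small_schedule) {
  simulate_healthy_cohort(n = n, model = model, schedule = schedule,
                          dose = 400, seed = seed)
}

fast_ctrl <- function(...) poppk_control(maxit = 80, reltol = 1e-8, ...)

# additive linear-Gaussian verification model: f(eta) = theta + eta
linear_gaussian_model <- function(theta = 10, omega_sd = 2, sigma = 1.5) {
  poppk_model(structure = NULL, theta = list(base = theta),
              iiv = iiv_spec(sd = c(base = omega_sd)),
              error = error_spec("additive", sigma_add = sigma),
              predict_fun = function(th, s) rep(th[["base"]], length(s$times)),
              eta_link = "additive")
}

# dataset for the linear-Gaussian model: k observations per subject
sim_linear_data <- function(n_subj = 8, k = 4, theta = 10, omega_sd = 2,
                            sigma = 1.5, seed = 7) {
  set.seed(seed)
  recs <- do.call(rbind, lapply(seq_len(n_subj), function(i) {
    y <- theta + stats::rnorm(1, 0, omega_sd) + stats::rnorm(k, 0, sigma)
    data.frame(ID = i, TIME = c(0, seq_len(k)), AMT = c(1, rep(0, k)),
               DV = c(NA, y), EVID = c(1L, rep(0L, k)),
               MDV = c(1L, rep(0L, k)))
  }))
  pk_data(recs)
}

# exact -2 log marginal likelihood (excluding n log 2pi) for the
# linear-Gaussian model: y_i ~ N(theta 1, omega^2 11' + sigma^2 I)
exact_linear_m2ll <- function(ds, theta, omega_sd, sigma) {
  total <- 0
  r <- ds$records
  for (id in unique(r$ID)) {
    y <- r$DV[r$ID == id & r$EVID == 0]
    n <- length(y)
    C <- matrix(omega_sd^2, n, n) + diag(sigma^2, n)
    total <- total + as.numeric(determinant(C)$modulus) +
      drop((y - theta) %*% solve(C) %*% (y - theta))
  }
  total
}

# tiny three-row CSV used by the IO tests
write_toy_csv <- function(path) {
  writeLines(c("ID,TIME,AMT,DV,EVID",
               "1,0,400,,1",
               "1,1,0,1.2,0",
               "1,2,0,0.8,0"), path)
  path
}
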