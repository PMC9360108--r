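test_that("residual variance follows the error model", {
  expect_equal(residual_variance(5, error_spec("additive", sigma_add = 0.01)),
               1e-4)
  # proportional: sd = sigma * prediction
  v <- residual_variance(2, error_spec("proportional", sigma_prop = 0.136))
  expect_equal(sqrt(v), 0.272)
  comb <- error_spec("combined", sigma_add = 0.05, sigma_prop = 0.1)
  expect_equal(residual_variance(0, comb), 0.05^2)
  expect_true(all(residual_variance(c(0, 1, 10), comb) >= 0.05^2))
})

test_that("individual joint objective has the Gaussian-posterior minimiser", {
  # linear model f(eta) = theta + eta with additive error: the MAP criterion
  # is quadratic with closed-form minimiser
  #   eta_hat = (sum y - n theta) / (n + sigma^2 / omega^2)
  m <- linear_gaussian_model(theta = 10, omega_sd = 2, sigma = 1.5)
  ds <- sim_linear_data(n_subj = 1, k = 5, seed = 3)
  y <- ds$records$DV[ds$records$EVID == 0]
  n <- length(y)
  eta_hat_exact <- sum(y - 10) / (n + 1.5^2 / 2^2)
  e <- ebe_estimate(ds, m)
  expect_equal(unname(e$eta[1, "base"]), eta_hat_exact, tolerance = 1e-8)
  # the objective at the minimiser is below neighbouring etas
  f0 <- individual_joint_objective(ds, m, c(base = eta_hat_exact))
  expect_lt(f0, individual_joint_objective(ds, m, c(base = eta_hat_exact + 0.1)))
  expect_lt(f0, individual_joint_objective(ds, m, c(base = eta_hat_exact - 0.1)))
})

test_that("prior mode and flat-prior limits of the MAP estimate", {
  ds <- sim_linear_data(n_subj = 1, k = 5, seed = 3)
  y <- ds$records$DV[ds$records$EVID == 0]
  # huge residual variance: the prior dominates and eta_hat -> 0
  m_noisy <- linear_gaussian_model(omega_sd = 2, sigma = 1e4)
  expect_lt(abs(ebe_estimate(ds, m_noisy)$eta[1, "base"]), 1e-4)
  # flat prior: eta_hat -> least squares (mean residual)
  m_flat <- linear_gaussian_model(omega_sd = 1e4, sigma = 1.5)
  expect_equal(unname(ebe_estimate(ds, m_flat)$eta[1, "base"]),
               mean(y) - 10, tolerance = 1e-4)
})

test_that("EBEs recover the generating etas from noise-free rich data", {
  m <- reference_model()
  sched <- default_schedule()
  set.seed(5)
  eta0 <- c(cl = 0.2, v1 = 0.15, ka = -0.4, mtt = 0.3)
  th <- unlist(m$theta)
  th[names(eta0)] <- th[names(eta0)] * exp(eta0)
  conc <- transitpk:::conc_dose_events(m$structure, th, 0, 400, sched)
  recs <- data.frame(ID = 1, TIME = c(0, sched), AMT = c(400, rep(0, 17)),
                     DV = c(NA, conc), EVID = c(1L, rep(0L, 17)))
  m$error <- error_spec("proportional", sigma_prop = 0.001)  # tiny noise
  e <- ebe_estimate(pk_data(recs), m)
  expect_lt(sqrt(sum((e$eta[1, ] - eta0)^2)), 1e-3)
  expect_equal(e$ipred$IPRED, conc, tolerance = 1e-4)
})

test_that("FOCE-I equals the exact marginal likelihood for linear-Gaussian models", {
  m <- linear_gaussian_model(theta = 10, omega_sd = 2, sigma = 1.5)
  ds <- sim_linear_data(n_subj = 8, k = 4, seed = 7)
  expect_equal(foce_ofv(ds, m), exact_linear_m2ll(ds, 10, 2, 1.5),
               tolerance = 1e-6)
})

test_that("OFV is additive over subjects and order-invariant", {
  m <- small_1cpt_model()
  ds <- sim_small_cohort(n = 6, seed = 12)
  ofv <- foce_ofv(ds, m)
  # duplicate every subject under new IDs: OFV doubles exactly
  r2 <- ds$records
  r2$ID <- r2$ID + 100
  dup <- pk_data(rbind(ds$records, r2))
  expect_equal(foce_ofv(dup, m), 2 * ofv, tolerance = 1e-10)
  # reversing subject order leaves the OFV unchanged
  rev_recs <- ds$records[order(-ds$records$ID, ds$records$TIME), ]
  expect_equal(foce_ofv(pk_data(rev_recs), m), ofv, tolerance = 1e-10)
})

test_that("omega -> 0 reduces FOCE to extended least squares", {
  m <- small_1cpt_model()
  ds <- sim_small_cohort(n = 5, seed = 13)
  m_zero <- m
  m_zero$iiv <- iiv_spec(sd = c(cl = 1e-8))
  m_els <- m
  m_els$iiv <- NULL
  expect_equal(foce_ofv(ds, m_zero), foce_ofv(ds, m_els), tolerance = 1e-4)
})

test_that("population fitting recovers a small model and is self-consistent", {
  truth <- small_1cpt_model()
  ds <- sim_small_cohort(n = 16, seed = 21)
  fit <- fit_poppk(ds, truth, control = fast_ctrl())
  expect_true(fit$converged)
  # refit cannot be beaten by the truth by more than a trivial margin
  expect_lte(fit$ofv, foce_ofv(ds, truth) + 0.01)
  expect_equal(fit$model$theta$cl, 10, tolerance = 0.15)
  expect_equal(fit$model$theta$v1, 100, tolerance = 0.15)
  # two jittered starts agree on the optimum
  fit2 <- fit_poppk(ds, truth,
                    control = poppk_control(maxit = 80, reltol = 1e-8,
                                            n_starts = 2, jitter_sd = 0.15,
                                            seed = 4))
  expect_lt(abs(min(fit2$start_ofvs) - fit$ofv), 0.1)
})

test_that("covariance step matches the closed-form SE on a fixed-effects model", {
  # y = theta + eps: SE(theta_hat) = sigma / sqrt(n)
  set.seed(31)
  n <- 60
  y <- stats::rnorm(n, 10, 1.5)
  recs <- data.frame(ID = 1, TIME = c(0, seq_len(n)), AMT = c(1, rep(0, n)),
                     DV = c(NA, y), EVID = c(1L, rep(0L, n)))
  m <- poppk_model(structure = NULL, theta = list(base = 10), iiv = NULL,
                   error = error_spec("additive", sigma_add = 1.5),
                   predict_fun = function(th, s) rep(th[["base"]], length(s$times)))
  fit <- fit_poppk(pk_data(recs), m, control = fast_ctrl())
  fit <- covariance_step(fit)
  expect_true(fit$covariance_ok)
  sigma_hat <- fit$model$error$sigma_add
  expect_equal(unname(fit$se["base"]), sigma_hat / sqrt(n), tolerance = 0.01)
})

test_that("covariance step flags an unidentifiable parameter", {
  # a covariate effect on a covariate that never varies has zero information
  truth <- small_1cpt_model()
  ds <- sim_small_cohort(n = 8, seed = 22)
  ds$covariates$CONST <- 1
  m <- truth
  m$covariate_links <- list(covariate_link("cl", "CONST", "linear",
                                           reference = 1))
  fit <- fit_poppk(ds, m, control = fast_ctrl())
  fit <- covariance_step(fit)
  expect_false(fit$covariance_ok)
})

test_that("shrinkage reflects how informative the data are", {
  fit_like <- list(eta = matrix(0, 10, 1, dimnames = list(NULL, "cl")),
                   model = small_1cpt_model())
  # all conditional modes at zero: complete shrinkage
  expect_equal(unname(shrinkage(fit_like)["cl"]), 100)
  # SD(eta_hat) = omega: no shrinkage
  om <- sqrt(fit_like$model$iiv$omega["cl", "cl"])
  set.seed(41)
  e <- stats::rnorm(200)
  fit_like$eta <- matrix(om * e / stats::sd(e), ncol = 1,
                         dimnames = list(NULL, "cl"))
  expect_equal(unname(shrinkage(fit_like)["cl"]), 0, tolerance = 1e-8)
})

test_that("CWRES are standard normal under the generating model", {
  m <- reference_model()
  ds <- simulate_healthy_cohort(n = 26, seed = 61)
  det <- transitpk:::foce_details(transitpk:::prep_subjects(ds), m)
  cw <- unlist(lapply(det$per_subject, `[[`, "cwres"))
  expect_equal(length(cw), sum(ds$records$EVID == 0))
  expect_gt(mean(cw), -0.1); expect_lt(mean(cw), 0.1)
  expect_gt(stats::var(cw), 0.8); expect_lt(stats::var(cw), 1.2)
})

test_that("omega = 0 reduces CWRES to classical weighted residuals", {
  truth <- small_1cpt_model()
  ds <- sim_small_cohort(n = 4, seed = 62)
  m <- truth
  m$iiv <- iiv_spec(sd = c(cl = 1e-9))
  det <- transitpk:::foce_details(transitpk:::prep_subjects(ds), m)
  # compare against classical weighted residuals (y - f)/sd at eta ~ 0
  subs <- transitpk:::prep_subjects(ds)
  for (i in seq_along(subs)) {
    f <- det$per_subject[[i]]$f
    wres <- (subs[[i]]$dv - f) / sqrt(residual_variance(f, m$error))
    expect_equal(as.numeric(det$per_subject[[i]]$cwres), wres, tolerance = 1e-4)
  }
})

test_that("CWRES of noise-free data at eta = 0 vanish", {
  m <- small_1cpt_model()
  sched <- small_schedule
  conc <- predict_conc(m$structure, m$theta, pk_regimen(0, 400), sched)
  recs <- data.frame(ID = 1:2, each = 1)
  recs <- do.call(rbind, lapply(1:2, function(i)
    data.frame(ID = i, TIME = c(0, sched), AMT = c(400, rep(0, 5)),
               DV = c(NA, conc), EVID = c(1L, rep(0L, 5)))))
  det <- transitpk:::foce_details(transitpk:::prep_subjects(pk_data(recs)), m)
  expect_true(all(abs(unlist(lapply(det$per_subject, `[[`, "cwres"))) < 1e-3))
})
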