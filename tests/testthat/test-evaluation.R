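test_that("VPC reproduces degenerate cases and is seed-stable", {
  truth <- small_1cpt_model()
  ds <- sim_small_cohort(n = 12, seed = 51)
  fit_like <- structure(list(model = truth,
                             subjects = transitpk:::prep_subjects(ds),
                             data = ds), class = "poppk_fit")
  # n_sim = 1: the envelope collapses onto the single simulated statistic
  v1 <- vpc(fit_like, n_sim = 1, seed = 2)
  expect_equal(v1$sim_lo, v1$sim_hi)
  expect_equal(v1$sim_lo, v1$sim_median)
  # fixed seed: bit-identical output
  v2 <- vpc(fit_like, n_sim = 25, seed = 3)
  v3 <- vpc(fit_like, n_sim = 25, seed = 3)
  expect_identical(v2, v3)
  # constant observations: observed percentiles all equal that constant
  dsc <- ds
  dsc$records$DV[dsc$records$EVID == 0] <- 1.7
  fit_c <- structure(list(model = truth,
                          subjects = transitpk:::prep_subjects(dsc),
                          data = dsc), class = "poppk_fit")
  vc <- vpc(fit_c, n_sim = 5, seed = 4)
  expect_true(all(vc$observed == 1.7))
})

test_that("VPC of self-simulated data is calibrated", {
  truth <- small_1cpt_model()
  ds <- sim_small_cohort(n = 20, seed = 52)
  fit_like <- structure(list(model = truth,
                             subjects = transitpk:::prep_subjects(ds),
                             data = ds), class = "poppk_fit")
  inside <- total <- 0
  for (s in 1:3) {
    v <- vpc(fit_like, n_sim = 150, seed = 100 + s)
    inside <- inside + sum(v$observed >= v$sim_lo & v$observed <= v$sim_hi)
    total <- total + nrow(v)
  }
  # nominal coverage ~95%; require at least 80% across replicates
  expect_gte(inside / total, 0.8)
})

test_that("bootstrap is reproducible and degenerate on identical subjects", {
  truth <- small_1cpt_model()
  # cohort of identical subjects: every resample is the same dataset
  conc <- predict_conc(truth$structure, truth$theta, pk_regimen(0, 400),
                       small_schedule)
  recs <- do.call(rbind, lapply(1:6, function(i)
    data.frame(ID = i, TIME = c(0, small_schedule),
               AMT = c(400, rep(0, 5)), DV = c(NA, conc * 1.05),
               EVID = c(1L, rep(0L, 5)))))
  ds_same <- pk_data(recs)
  fit <- fit_poppk(ds_same, truth, control = fast_ctrl())
  b <- bootstrap_poppk(fit, n_rep = 4, seed = 5, control = fast_ctrl())
  expect_equal(b$success_rate, 100)
  expect_equal(b$summary$ci_lo, b$summary$ci_hi, tolerance = 1e-6)
  # replicate refits re-polish from the optimum; agreement to optimizer noise
  expect_equal(b$summary$boot_median, b$summary$estimate, tolerance = 1e-3)
  # fixed seed gives identical resampling
  ds <- sim_small_cohort(n = 8, seed = 53)
  fit2 <- fit_poppk(ds, truth, control = fast_ctrl())
  b1 <- bootstrap_poppk(fit2, n_rep = 3, seed = 11, control = fast_ctrl())
  b2 <- bootstrap_poppk(fit2, n_rep = 3, seed = 11, control = fast_ctrl())
  expect_identical(b1$estimates, b2$estimates)
})

test_that("goodness-of-fit table has one calibrated row per observation", {
  truth <- small_1cpt_model()
  ds <- sim_small_cohort(n = 16, seed = 54)
  fit <- fit_poppk(ds, truth, control = fast_ctrl())
  g <- gof_table(fit)
  expect_equal(nrow(g), sum(ds$records$EVID == 0))
  expect_named(g, c("ID", "TIME", "DV", "PRED", "IPRED", "CWRES", "IWRES"))
  # regression of observations on individual predictions is near identity
  slope <- stats::coef(stats::lm(DV ~ IPRED, data = g))[[2]]
  expect_equal(slope, 1, tolerance = 0.05)
  # noise-free data at eta = 0 (additive error, where the conditional mode
  # sits exactly at zero): DV = PRED = IPRED
  m_add <- small_1cpt_model(error = error_spec("additive", sigma_add = 0.05))
  conc <- predict_conc(m_add$structure, m_add$theta, pk_regimen(0, 400),
                       small_schedule)
  recs <- data.frame(ID = 1, TIME = c(0, small_schedule),
                     AMT = c(400, rep(0, 5)), DV = c(NA, conc),
                     EVID = c(1L, rep(0L, 5)))
  det_fit <- structure(list(model = m_add,
                            subjects = transitpk:::prep_subjects(pk_data(recs)),
                            details = transitpk:::foce_details(
                              transitpk:::prep_subjects(pk_data(recs)), m_add),
                            eta = matrix(0, 1, 1, dimnames = list("1", "cl"))),
                       class = "poppk_fit")
  g0 <- gof_table(det_fit)
  expect_equal(g0$DV, g0$IPRED, tolerance = 1e-6)
  expect_equal(g0$DV, g0$PRED, tolerance = 1e-6)
})

test_that("fit methods expose the usual modelling interface", {
  truth <- small_1cpt_model()
  ds <- sim_small_cohort(n = 10, seed = 55)
  fit <- fit_poppk(ds, truth, control = fast_ctrl())
  expect_output(print(fit), "OFV")
  s <- summary(fit)
  expect_s3_class(s, "summary.poppk_fit")
  expect_equal(s$aic, aic(fit$ofv, length(fit$par)))
  expect_true(all(c("cl", "v1", "ka", "omega_cl", "sigma_prop") %in%
                    names(coef(fit))))
  expect_equal(as.numeric(stats::logLik(fit)), -fit$ofv / 2)
  expect_equal(stats::AIC(fit), fit$ofv + 2 * length(fit$par))
  pr <- predict(fit, type = "pred")
  expect_equal(nrow(pr), sum(ds$records$EVID == 0))
  expect_length(residuals(fit, type = "cwres"), nrow(pr))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "pk_data")
  expect_false(identical(sims[[1]]$records$DV, sims[[2]]$records$DV))
})
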