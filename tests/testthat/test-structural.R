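# Reference typical values used throughout: CL/F 13.2, V1/F 172, Q/F 3.75,
# V2/F 43.6 L, Ka 1.22 1/h, MTT 0.537 h, N 3.62.
ref_theta <- reference_model()$theta

test_that("transit input rate is a scaled gamma density", {
  expect_equal(transit_input_rate(0, 400, 0.537, 3.62), 0)   # (ktr t)^N = 0
  expect_error(transit_input_rate(-1, 400, 0.537, 3.62), "nonnegative")
  expect_error(transit_input_rate(1, 400, 0, 3.62), "positive")
  # integrates to the dose (adaptive quadrature oracle)
  int <- stats::integrate(function(s) transit_input_rate(s, 400, 0.537, 3.62),
                          0, 200, rel.tol = 1e-10)$value
  expect_equal(int, 400, tolerance = 1e-6)
  # mode of the rate at N MTT / (N + 1)
  tstar <- stats::optimize(function(s) transit_input_rate(s, 400, 0.537, 3.62),
                           c(0, 5), maximum = TRUE)$maximum
  expect_equal(tstar, 3.62 * 0.537 / 4.62, tolerance = 1e-4)
})

test_that("transit concentration matches an independent ODE solution", {
  skip_if_not_installed("deSolve")
  st <- pk_structure(2, "transit")
  times <- c(0.5, 1, 2, 3, 4, 6, 8, 12, 24, 48, 72)
  rhs <- function(t, y, p) {
    r <- transit_input_rate(t, 400, p$mtt, p$n_transit)
    k10 <- p$cl / p$v1; k12 <- p$q / p$v1; k21 <- p$q / p$v2
    list(c(r - p$ka * y[1],
           p$ka * y[1] - (k10 + k12) * y[2] + k21 * y[3],
           k12 * y[2] - k21 * y[3],
           k10 * y[2]))
  }
  sol <- deSolve::ode(c(0, 0, 0, 0), c(0, times), rhs, ref_theta,
                      rtol = 1e-10, atol = 1e-12)
  ode_conc <- sol[-1, 3] / ref_theta$v1
  pkg_conc <- predict_conc(st, ref_theta, pk_regimen(0, 400), times)
  expect_equal(pkg_conc, unname(ode_conc), tolerance = 1e-7)
  # mass balance on the ODE state: compartments + eliminated = input so far
  absorbed <- 400 * stats::pgamma(sol[-1, 1], ref_theta$n_transit + 1,
                                  rate = (ref_theta$n_transit + 1) / ref_theta$mtt)
  expect_equal(rowSums(sol[-1, 2:5]), unname(absorbed), tolerance = 1e-6)
})

test_that("closed-form absorption models match the ODE oracle", {
  skip_if_not_installed("deSolve")
  times <- c(0.5, 1, 2, 4, 8, 12, 24, 48)
  th_f <- list(cl = 13.2, v1 = 172, q = 3.75, v2 = 43.6, ka = 1.22)
  rhs <- function(t, y, p) {
    k10 <- p$cl / p$v1; k12 <- p$q / p$v1; k21 <- p$q / p$v2
    list(c(-p$ka * y[1], p$ka * y[1] - (k10 + k12) * y[2] + k21 * y[3],
           k12 * y[2] - k21 * y[3]))
  }
  sol <- deSolve::ode(c(400, 0, 0), c(0, times), rhs, th_f,
                      rtol = 1e-11, atol = 1e-12)
  c_first <- predict_conc(pk_structure(2, "first_order"), th_f,
                          pk_regimen(0, 400), times)
  expect_equal(c_first, unname(sol[-1, 3] / 172), tolerance = 1e-8)

  th_z <- list(cl = 13.2, v1 = 172, q = 3.75, v2 = 43.6, d_zero = 2, alag = 0.5)
  rhs0 <- function(t, y, p) {
    k10 <- p$cl / p$v1; k12 <- p$q / p$v1; k21 <- p$q / p$v2
    r <- if (t > 0.5 && t < 2.5) 200 else 0
    list(c(r - (k10 + k12) * y[1] + k21 * y[2], k12 * y[1] - k21 * y[2]))
  }
  solz <- deSolve::ode(c(0, 0), c(0, times), rhs0, th_z,
                       rtol = 1e-11, atol = 1e-13)
  c_zero <- predict_conc(pk_structure(2, "zero_order_lag"), th_z,
                         pk_regimen(0, 400), times)
  expect_equal(c_zero, unname(solz[-1, 2] / 172), tolerance = 1e-4)
})

test_that("dose linearity and superposition hold", {
  st <- pk_structure(2, "transit")
  times <- c(1, 2, 4, 8, 24, 72)
  c400 <- predict_conc(st, ref_theta, pk_regimen(0, 400), times)
  # two simultaneous 200 mg doses equal one 400 mg dose
  c2x200 <- transitpk:::conc_dose_events(st, ref_theta, c(0, 0), c(200, 200), times)
  expect_equal(c400, c2x200)
  # doubling the dose doubles the curve
  c800 <- predict_conc(st, ref_theta, pk_regimen(0, 800), times)
  expect_equal(c800, 2 * c400)
  # zero-amount regimen produces zero concentration everywhere
  c0 <- predict_conc(st, ref_theta, pk_regimen(0, 0), times)
  expect_equal(c0, rep(0, length(times)))
  # C(0) = 0 for oral dosing
  expect_equal(predict_conc(st, ref_theta, pk_regimen(0, 400), 0), 0)
})

test_that("incomplete theta is a configuration error", {
  st <- pk_structure(2, "transit")
  expect_error(predict_conc(st, list(cl = 13.2, v1 = 172), pk_regimen(0, 400), 1),
               "incomplete theta")
  expect_error(predict_conc(st, replace(ref_theta, "cl", -1),
                            pk_regimen(0, 400), 1), "positive")
})

test_that("transit model degenerates to first-order absorption", {
  # N = 0 and MTT -> 0: the transit chain vanishes
  th_t <- list(cl = 13.2, v1 = 172, q = 3.75, v2 = 43.6, ka = 1.22,
               mtt = 1e-4, n_transit = 0)
  th_f <- list(cl = 13.2, v1 = 172, q = 3.75, v2 = 43.6, ka = 1.22)
  times <- c(0.5, 1, 2, 4, 8, 24)
  c_t <- predict_conc(pk_structure(2, "transit"), th_t, pk_regimen(0, 400), times)
  c_f <- predict_conc(pk_structure(2, "first_order"), th_f, pk_regimen(0, 400), times)
  expect_equal(c_t, c_f, tolerance = 1e-3)
})

test_that("typical-value peak falls at about three hours", {
  grid <- seq(0.01, 12, by = 0.01)
  conc <- predict_conc(pk_structure(2, "transit"), ref_theta,
                       pk_regimen(0, 400), grid)
  tmax <- grid[which.max(conc)]
  expect_gte(tmax, 2.5)
  expect_lte(tmax, 3.5)
})

test_that("steady state matches long superposition and accumulates", {
  m <- reference_model()
  ss <- steady_state_profile(m$structure, m$theta, 400, 24, c(12, 24))
  brute <- transitpk:::conc_dose_events(m$structure, m$theta,
                                        -(0:29) * 24, rep(400, 30), c(12, 24))
  expect_equal(ss, brute, tolerance = 1e-3)
  # trough above the single-dose concentration at t = tau
  single <- predict_conc(m$structure, m$theta, pk_regimen(0, 400), 24)
  expect_gt(ss[2], single)
  # linear in dose
  ss2 <- steady_state_profile(m$structure, m$theta, 800, 24, c(12, 24))
  expect_equal(ss2, 2 * ss)
  expect_error(steady_state_profile(m$structure, m$theta, 400, -1, 12),
               "tau must be positive")
})

test_that("secondary parameters satisfy the two-compartment identities", {
  sp <- secondary_parameters(ref_theta)
  expect_equal(sp$ktr, 4.62 / 0.537, tolerance = 1e-10)
  expect_equal(sp$vss, 215.6)
  set.seed(11)
  for (i in 1:10) {
    th <- list(cl = stats::runif(1, 2, 30), v1 = stats::runif(1, 20, 300),
               q = stats::runif(1, 0.5, 20), v2 = stats::runif(1, 10, 200))
    sp <- secondary_parameters(th)
    k10 <- th$cl / th$v1; k12 <- th$q / th$v1; k21 <- th$q / th$v2
    expect_equal(sp$alpha * sp$beta, k10 * k21, tolerance = 1e-10)
    expect_equal(sp$alpha + sp$beta, k10 + k12 + k21, tolerance = 1e-10)
    # eigenvalues of the disposition rate matrix
    A <- matrix(c(-(k10 + k12), k21, k12, -k21), 2, 2, byrow = TRUE)
    ev <- sort(-eigen(A, only.values = TRUE)$values)
    expect_equal(c(sp$beta, sp$alpha), ev, tolerance = 1e-10)
  }
  # q -> 0: beta -> 0 and alpha -> k10
  sp0 <- secondary_parameters(list(cl = 13.2, v1 = 172, q = 1e-9, v2 = 43.6))
  expect_lt(sp0$beta, 1e-9)
  expect_equal(sp0$alpha, 13.2 / 172, tolerance = 1e-6)
  expect_error(secondary_parameters(list(cl = 1, v1 = 10)), "two-compartment")
})
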