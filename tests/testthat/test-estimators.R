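test_that("realized growth rate inverts exponential growth", {
  expect_equal(growth_rate_realized(1e2, 1e2 * exp(2), 2), 1)
  expect_equal(growth_rate_realized(1e5, 1e5, 5), 0)
  expect_equal(growth_rate_realized(2e5, 2e5 * exp(3), 3), 1)
  expect_error(growth_rate_realized(0, 10, 1), "positive")
})

test_that("p0_mle is the transconjugant-free fraction", {
  expect_identical(p0_mle(84, 84), 1)
  expect_identical(p0_mle(0, 84), 0)
  expect_identical(p0_mle(42, 84), 0.5)
  expect_error(p0_mle(1, 0), "n_total")
})

test_that("assay observations enforce density bookkeeping", {
  expect_error(assay_observation(t_tilde = 2, Dt = 10, Rt = 10, Tt = 1,
                                 Nt = 100), "1%")
  obs <- assay_observation(t_tilde = 2, D0 = 10, R0 = 20)
  expect_equal(obs$N0, 30)
})

test_that("SIM estimate is exact and time-invariant under identical rates", {
  tr <- ode_solve(det_params(), det_inoculum(), seq(0, 8, by = 1))
  vals <- vapply(2:9, function(k) {
    sim_estimate(assay_observation(
      t_tilde = tr$time[k], N0 = tr$N[1], Dt = tr$D[k], Rt = tr$R[k],
      Tt = tr$T[k], Nt = tr$N[k], D0 = tr$D[1], R0 = tr$R[1]))$value
  }, numeric(1))
  expect_equal(vals, rep(1e-14, 8), tolerance = 1e-3)
  expect_lt(max(vals) / min(vals) - 1, 1e-3)
})

test_that("SIM estimate inflates over time when gamma_T exceeds gamma_D", {
  tr <- ode_solve(det_params(1e-8), det_inoculum(), seq(0, 6, by = 1))
  vals <- vapply(2:7, function(k) {
    sim_estimate(assay_observation(
      t_tilde = tr$time[k], N0 = tr$N[1], Dt = tr$D[k], Rt = tr$R[k],
      Tt = tr$T[k], Nt = tr$N[k], D0 = tr$D[1], R0 = tr$R[1]))$value
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 1e-14))
})

test_that("SIM estimate handles degenerate observations with reason codes", {
  base <- list(t_tilde = 2, N0 = 200, D0 = 100, R0 = 100)
  zero_T <- sim_estimate(assay_observation(t_tilde = 2, N0 = 200,
                                           Dt = 500, Rt = 500, Tt = 0))
  expect_true(zero_T$valid)
  expect_identical(zero_T$value, 0)
  expect_match(zero_T$reason, "no transconjugants")
  no_growth <- sim_estimate(assay_observation(t_tilde = 2, N0 = 2000,
                                              Dt = 500, Rt = 500, Tt = 1))
  expect_false(no_growth$valid)
  expect_match(no_growth$reason, "no net growth")
})

test_that("parametric LDM inverts the analytic p0 exactly", {
  p <- baseline_params()
  init <- baseline_inoculum()
  est <- ldm_parametric(p0_analytic(p, init, 2), p, init, 2)
  expect_equal(est$value, 1e-6, tolerance = 1e-12)
  est10 <- ldm_parametric(p0_analytic(p, init, 2), p, init, 2, f = 10)
  expect_equal(est10$value, 1e-5, tolerance = 1e-12)
  # the inverse property holds across random settings; precision of
  # -log(p0) degrades as eps/hazard when p0 approaches 1, hence 1e-7
  for (inp in random_inputs(25, seed = 301)) {
    est <- ldm_parametric(p0_analytic(inp$params, inp$init, inp$t),
                          inp$params, inp$init, inp$t)
    expect_equal(est$value, inp$params$gamma_D, tolerance = 1e-7)
  }
})

test_that("parametric LDM maps boundary p0 to zero or invalid", {
  p <- baseline_params()
  init <- baseline_inoculum()
  allclear <- ldm_parametric(1, p, init, 2)
  expect_true(allclear$valid)
  expect_identical(allclear$value, 0)
  allturbid <- ldm_parametric(0, p, init, 2)
  expect_false(allturbid$valid)
  expect_match(allturbid$reason, "turbid")
  expect_error(ldm_parametric(1.2, p, init, 2), "0, 1")
})

test_that("end-point LDM equals the parametric form under realized rates", {
  for (inp in random_inputs(25, seed = 302)) {
    p <- inp$params
    Dt <- inp$init$D0 * exp(p$psi_D * inp$t)
    Rt <- inp$init$R0 * exp(p$psi_R * inp$t)
    obs <- assay_observation(t_tilde = inp$t, D0 = inp$init$D0,
                             R0 = inp$init$R0, Dt = Dt, Rt = Rt,
                             f = inp$f, p0_hat = inp$p0)
    a <- ldm_endpoint(obs)$value
    b <- ldm_parametric(inp$p0, p, inp$init, inp$t, f = inp$f)$value
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("end-point LDM recovers the generating rate from exact inputs", {
  p <- baseline_params()
  init <- baseline_inoculum()
  obs <- assay_observation(t_tilde = 2, D0 = init$D0, R0 = init$R0,
                           Dt = init$D0 * exp(2), Rt = init$R0 * exp(2),
                           p0_hat = p0_analytic(p, init, 2))
  expect_equal(ldm_endpoint(obs)$value, 1e-6, tolerance = 1e-12)
})

test_that("end-point LDM flags degenerate growth and boundary p0", {
  obs <- assay_observation(t_tilde = 2, D0 = 100, R0 = 100, Dt = 100,
                           Rt = 100, p0_hat = 0.5)
  bad <- ldm_endpoint(obs)
  expect_false(bad$valid)
  expect_match(bad$reason, "degenerate")
  obs1 <- assay_observation(t_tilde = 2, D0 = 100, R0 = 100, Dt = 500,
                            Rt = 500, p0_hat = 1)
  expect_identical(ldm_endpoint(obs1)$value, 0)
})

test_that("end-point LDM is monotone in its fluctuation signal", {
  mk <- function(p0, d0) {
    assay_observation(t_tilde = 2, D0 = d0, R0 = d0, Dt = d0 * exp(2),
                      Rt = d0 * exp(2), p0_hat = p0)
  }
  v <- vapply(c(0.8, 0.6, 0.4, 0.2), function(p0) ldm_endpoint(mk(p0, 100))$value,
              numeric(1))
  expect_true(all(diff(v) > 0))  # increasing in -log p0
  w <- vapply(c(50, 100, 200, 400), function(d0) ldm_endpoint(mk(0.5, d0))$value,
              numeric(1))
  expect_true(all(diff(w) < 0))  # decreasing in D0*R0
})

test_that("LDM estimators are homogeneous of degree 1 in the volume correction", {
  for (inp in random_inputs(10, seed = 303)) {
    p <- inp$params
    base <- ldm_parametric(inp$p0, p, inp$init, inp$t, f = 1)$value
    expect_equal(ldm_parametric(inp$p0, p, inp$init, inp$t, f = inp$f)$value,
                 inp$f * base, tolerance = 1e-12)
    obs <- function(f) {
      assay_observation(t_tilde = inp$t, D0 = inp$init$D0, R0 = inp$init$R0,
                        Dt = inp$init$D0 * exp(p$psi_D * inp$t),
                        Rt = inp$init$R0 * exp(p$psi_R * inp$t),
                        f = f, p0_hat = inp$p0)
    }
    expect_equal(ldm_endpoint(obs(inp$f))$value,
                 inp$f * ldm_endpoint(obs(1))$value, tolerance = 1e-12)
  }
})

test_that("the mutation-rate estimate matches its closed-form example", {
  est <- ld_mutation_rate(exp(-1), N0 = 1, psi_N = 1, t_tilde = log(2))
  expect_equal(est$value, 1, tolerance = 1e-12)
  expect_identical(ld_mutation_rate(1, 10, 1, 1)$value, 0)
})

test_that("conjugation maps onto mutation with N0 = D0*R0 and psi_N = psi_D+psi_R", {
  for (inp in random_inputs(25, seed = 304)) {
    p <- inp$params
    a <- ld_mutation_rate(inp$p0, N0 = inp$init$D0 * inp$init$R0,
                          psi_N = p$psi_D + p$psi_R, t_tilde = inp$t)$value
    b <- ldm_parametric(inp$p0, p, inp$init, inp$t, f = 1)$value
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("estimate objects print, coerce and tabulate", {
  est <- ldm_parametric(0.5, baseline_params(), baseline_inoculum(), 2)
  expect_output(print(est), "LDM-parametric")
  expect_equal(unname(coef(est)), est$value)
  tab <- estimates_table(list(est, ldm_parametric(1, baseline_params(),
                                                  baseline_inoculum(), 2)))
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$valid))
})
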