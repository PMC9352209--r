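test_that("batch designs enforce divisibility", {
  expect_error(batch_design(1050, 100), "divisible")
  expect_s3_class(batch_design(1000, 100), "batch_design")
})

test_that("batching yields one estimate per block of populations", {
  cfg <- sim_config(baseline_params(), baseline_inoculum(), t_max = 3,
                    engine = "hybrid")
  ens <- run_ensemble(cfg, 400, 17)
  des <- batch_design(400, 100, master_seed = 17)
  est <- ldm_batch_estimates(ens, 2.4, des)
  expect_length(est, 4)
  expect_length(sim_batch_estimates(ens, 2.4, des), 4)
})

test_that("an assay scored before any conjugation yields valid zero estimates", {
  cfg <- sim_config(rate_params(1, 1, 1, 1e-12, 1e-12), baseline_inoculum(),
                    t_max = 1, engine = "hybrid")
  ens <- run_ensemble(cfg, 200, 5)
  est <- ldm_batch_estimates(ens, 1, batch_design(200, 100, 5))
  expect_true(all(vapply(est, `[[`, logical(1), "valid")))
  expect_true(all(vapply(est, `[[`, numeric(1), "value") == 0))
})

test_that("batched LDM estimates recover the generating conjugation rate", {
  cfg <- sim_config(baseline_params(), baseline_inoculum(), t_max = 4,
                    engine = "hybrid")
  ens <- run_ensemble(cfg, 2000, 29)
  des <- batch_design(2000, 100, master_seed = 29)
  t_ldm <- as.numeric(choose_t_ldm(ens))
  est <- ldm_batch_estimates(ens, t_ldm, des)
  v <- vapply(est, `[[`, numeric(1), "value")
  v <- v[vapply(est, `[[`, logical(1), "valid") & v > 0]
  gm <- exp(mean(log(v)))
  expect_gt(gm, 1e-6 / 1.5)
  expect_lt(gm, 1e-6 * 1.5)
})

test_that("batch estimates are reproducible from the master seed", {
  cfg <- sim_config(baseline_params(), baseline_inoculum(), t_max = 3,
                    engine = "hybrid")
  des <- batch_design(300, 100, master_seed = 41)
  e1 <- sim_batch_estimates(run_ensemble(cfg, 300, 41), 2.4, des)
  e2 <- sim_batch_estimates(run_ensemble(cfg, 300, 41), 2.4, des)
  expect_identical(e1, e2)
})

test_that("LDM incubation time is the mean observed first-event time", {
  times <- c(0, 1, 2, 3)
  ens <- fake_ensemble(c(1, 2, 3), times,
                       list(c(0, 1, 1, 1), c(0, 0, 1, 1), c(0, 0, 0, 1)))
  expect_equal(as.numeric(choose_t_ldm(ens)), 2)
  single <- fake_ensemble(0.7, times, list(c(0, 1, 1, 1)))
  expect_equal(as.numeric(choose_t_ldm(single)), 0.7)
  excl <- fake_ensemble(c(1, NA, 3), times,
                        list(c(0, 1, 1, 1), c(0, 0, 0, 0), c(0, 0, 0, 1)))
  expect_equal(as.numeric(choose_t_ldm(excl)), 2)
  expect_equal(attr(choose_t_ldm(excl), "n_excluded"), 1)
  none <- fake_ensemble(c(NA, NA), times,
                        list(c(0, 0, 0, 0), c(0, 0, 0, 0)))
  expect_error(choose_t_ldm(none), "no run")
})

test_that("SIM incubation time interpolates the mean-count crossing", {
  ens <- fake_ensemble(c(1, 1), c(1, 2, 3),
                       list(c(0, 30, 60), c(0, 30, 60)))
  # mean count crosses 50 two thirds of the way from t=2 (30) to t=3 (60)
  expect_equal(choose_t_sim(ens), 2 + 20 / 30)
  low <- fake_ensemble(c(1, 1), c(1, 2, 3), list(c(0, 1, 2), c(0, 1, 2)))
  expect_error(choose_t_sim(low), "t_max")
})

test_that("incubation sweeps flag intervals by the 90% finite-nonzero rule", {
  cfg <- sim_config(baseline_params(), baseline_inoculum(), t_max = 5,
                    engine = "hybrid")
  des <- batch_design(600, 100, master_seed = 61)
  expect_error(incubation_sweep(cfg, c(1, 1.7), des), "0.5 hr")
  sw <- incubation_sweep(cfg, seq(1, 4.5, by = 0.5), des)
  expect_s3_class(sw, "sweep_result")
  ldm_in <- vapply(sw$cells, `[[`, logical(1), "ldm_included")
  sim_in <- vapply(sw$cells, `[[`, logical(1), "sim_included")
  # the LDM window flanks the mean first-event time and closes before the
  # (later) SIM window: every included LDM time precedes every included SIM
  # time that is not also LDM-included
  expect_true(any(ldm_in))
  expect_true(any(sim_in))
  expect_lt(min(sw$axis[ldm_in]), min(sw$axis[sim_in]))
  # flags follow the 90% rule applied to the estimate lists themselves
  for (cell in sw$cells) {
    frac <- mean(vapply(cell$ldm, function(e) {
      e$valid && is.finite(e$value) && e$value != 0
    }, logical(1)))
    expect_identical(cell$ldm_included, frac >= 0.9)
  }
  # bitwise reproducible
  sw2 <- incubation_sweep(cfg, seq(1, 4.5, by = 0.5), des)
  expect_identical(sw, sw2)
})

test_that("conjugation-rate heterogeneity biases SIM but not LDM", {
  cfg <- sim_config(baseline_params(), baseline_inoculum(), t_max = 5,
                    engine = "hybrid")
  des <- batch_design(500, 100, master_seed = 71)
  sw <- parameter_sweep(cfg, axis = "conjugation", values = c(1e-8, 1e-4),
                        design = des)
  for (cell in sw$cells) {
    expect_gt(cell$ldm_summary$median, 1e-6 / 2.5)
    expect_lt(cell$ldm_summary$median, 1e-6 * 2.5)
  }
  # at gamma_T = 100 * gamma_D the SIM median overshoots the truth
  expect_gt(sw$cells[[2]]$sim_summary$median, sw$cells[[2]]$ldm_summary$median)
})

test_that("distribution summaries follow the boxplot conventions", {
  mk <- function(v) new_est_list(v)
  s <- summarize_distribution(mk(rep(2, 5)))
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 2)
  expect_equal(s$whisker_low, 2)
  s2 <- summarize_distribution(mk(1:100))
  expect_equal(s2$median, 50.5)
  expect_equal(s2$q1, 25.75)
  expect_equal(s2$q3, 75.25)
  s3 <- summarize_distribution(mk(c(0, 0, 1, 2, 3)))
  expect_equal(s3$n_zero, 2)
  expect_equal(s3$n_valid, 5)
  # whiskers clip to the data range
  s4 <- summarize_distribution(mk(c(1, 2, 3, 4, 100)))
  expect_equal(s4$whisker_low, 1)
  expect_lte(s4$whisker_high, 100)
})

test_that("group comparisons use a log-scale Welch test with a permutation check", {
  g1 <- new_est_list(rep(c(1e-6, 2e-6, 3e-6), 4))
  expect_equal(compare_estimates(g1, g1)$p_value, 1)
  g2 <- new_est_list(rep(c(1, 2, 3), 4))  # six logs apart, tiny variance
  expect_lt(compare_estimates(g1, g2)$p_value, 1e-4)
  # zeros are excluded but counted
  g3 <- new_est_list(c(0, 1e-6, 2e-6, 3e-6))
  cmp <- compare_estimates(g3, g1)
  expect_equal(cmp$excluded_a, 1)
  # permutation oracle on moderately separated groups
  set.seed(5150)
  a <- new_est_list(10^rnorm(15, -6.0, 0.3))
  b <- new_est_list(10^rnorm(15, -6.4, 0.3))
  welch_p <- compare_estimates(a, b)$p_value
  xa <- log10(vapply(a, `[[`, numeric(1), "value"))
  xb <- log10(vapply(b, `[[`, numeric(1), "value"))
  pool <- c(xa, xb)
  obs_d <- abs(mean(xa) - mean(xb))
  perm_d <- replicate(4000, {
    idx <- sample.int(30, 15)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  perm_p <- mean(perm_d >= obs_d)
  expect_lt(abs(welch_p - perm_p), 0.1)
})

test_that("sweep results export tidily", {
  cfg <- sim_config(baseline_params(), baseline_inoculum(), t_max = 3.5,
                    engine = "hybrid")
  des <- batch_design(200, 100, master_seed = 83)
  sw <- incubation_sweep(cfg, c(2, 2.5), des)
  f <- tempfile(fileext = ".csv")
  write_sweep_csv(sw, f)
  rows <- read.csv(f)
  expect_equal(nrow(rows), 2 * 2 * 2)  # 2 times x 2 methods x 2 estimates
  expect_true(all(c("axis", "method", "value", "valid") %in% names(rows)))
})
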