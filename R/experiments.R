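#' Batching design for simulation studies
#'
#' How an ensemble of simulated mating assays is partitioned into estimates:
#' disjoint blocks of `populations_per_ldm` runs each contribute one LDM
#' estimate (the block's transconjugant-free fraction plus densities from
#' one randomly designated run in the block) and one SIM estimate (from the
#' same designated run). The default 10,000 populations in blocks of 100
#' yield 100 estimates of each kind.
#'
#' @param n_populations Total number of runs; must be divisible by
#'   `populations_per_ldm`.
#' @param populations_per_ldm Runs per LDM estimate (wells per plate
#'   analogue), default 100.
#' @param master_seed Integer seed governing the designation of density
#'   runs, so a whole sweep is replayable.
#' @return An object of class `batch_design`.
#' @export
batch_design <- function(n_populations = 10000, populations_per_ldm = 100,
                         master_seed = 1) {
  stopifnot(n_populations >= 1, populations_per_ldm >= 1)
  if (n_populations %% populations_per_ldm != 0) {
    stop("n_populations must be divisible by populations_per_ldm",
         call. = FALSE)
  }
  structure(list(n_populations = n_populations,
                 populations_per_ldm = populations_per_ldm,
                 master_seed = master_seed),
            class = "batch_design")
}

# deterministic designation of the density-measurement run in each block
block_representatives <- function(design) {
  n_blocks <- design$n_populations / design$populations_per_ldm
  set.seed(design$master_seed)
  within_block <- sample.int(design$populations_per_ldm, n_blocks,
                             replace = TRUE)
  (seq_len(n_blocks) - 1L) * design$populations_per_ldm + within_block
}

#' LDM estimates from a batched ensemble
#'
#' Partitions the ensemble into disjoint blocks of
#' `design$populations_per_ldm` runs. Each block yields one LDM end-point
#' estimate: `p0_hat` is the fraction of the block's runs whose first
#' conjugation event falls after `t_tilde`, and the initial/final donor and
#' recipient densities come from one seeded-randomly designated run in the
#' block, with `f` = 1/volume. Blocks with `p0_hat = 0` are recorded as
#' invalid estimates, not dropped.
#'
#' @param ensemble A `mating_ensemble` from [run_ensemble()] with at least
#'   `design$n_populations` runs.
#' @param t_tilde Incubation time (hr) at which wells are scored.
#' @param design A [batch_design()].
#' @return List of `conj_estimate` objects (one per block).
#' @export
ldm_batch_estimates <- function(ensemble, t_tilde, design) {
  stopifnot(inherits(ensemble, "mating_ensemble"),
            inherits(design, "batch_design"))
  if (length(ensemble$runs) < design$n_populations) {
    stop("ensemble is smaller than the design's n_populations", call. = FALSE)
  }
  V <- ensemble$config$volume
  per <- design$populations_per_ldm
  reps <- block_representatives(design)
  n_blocks <- design$n_populations / per
  lapply(seq_len(n_blocks), function(b) {
    idx <- ((b - 1L) * per + 1L):(b * per)
    ts <- vapply(ensemble$runs[idx], function(r) r$t_star, numeric(1))
    p0_hat <- mean(is.na(ts) | ts > t_tilde)
    run <- ensemble$runs[[reps[b]]]
    st <- state_at(run, t_tilde)
    obs <- assay_observation(
      t_tilde = t_tilde,
      D0 = run$init$D0, R0 = run$init$R0,
      Dt = st[["D"]] / V, Rt = st[["R"]] / V,
      f = 1 / V, p0_hat = p0_hat, n_wells = per)
    ldm_endpoint(obs)
  })
}

#' SIM estimates from a batched ensemble
#'
#' One SIM estimate per block, computed from the same designated run that
#' supplies the LDM densities (counts converted to densities via the
#' culture volume).
#'
#' @inheritParams ldm_batch_estimates
#' @return List of `conj_estimate` objects (one per block).
#' @export
sim_batch_estimates <- function(ensemble, t_tilde, design) {
  stopifnot(inherits(ensemble, "mating_ensemble"),
            inherits(design, "batch_design"))
  if (length(ensemble$runs) < design$n_populations) {
    stop("ensemble is smaller than the design's n_populations", call. = FALSE)
  }
  V <- ensemble$config$volume
  reps <- block_representatives(design)
  lapply(reps, function(i) {
    run <- ensemble$runs[[i]]
    st <- state_at(run, t_tilde)
    obs <- assay_observation(
      t_tilde = t_tilde,
      D0 = run$init$D0, R0 = run$init$R0,
      N0 = run$init$D0 + run$init$R0 + run$init$T0,
      Dt = st[["D"]] / V, Rt = st[["R"]] / V, Tt = st[["T"]] / V,
      f = 1 / V)
    sim_estimate(obs)
  })
}

#' Incubation time for the LDM estimate
#'
#' The average observed first-conjugation time t* across the ensemble; runs
#' without an event are excluded and their count attached as attribute
#' `n_excluded`.
#'
#' @param ensemble A `mating_ensemble`.
#' @return Mean t* (hr).
#' @export
choose_t_ldm <- function(ensemble) {
  ts <- tstar_values(ensemble)
  if (length(ts) == 0) {
    stop("no run experienced a first conjugation event", call. = FALSE)
  }
  structure(mean(ts),
            n_excluded = length(ensemble$runs) - length(ts))
}

#' Incubation time for the SIM estimate
#'
#' The earliest time at which the ensemble's mean transconjugant count
#' reaches 50, linearly interpolated between sample times.
#'
#' @param ensemble A `mating_ensemble`.
#' @param target Mean transconjugant count to reach (default 50).
#' @return Time (hr).
#' @export
choose_t_sim <- function(ensemble, target = 50) {
  mc <- ensemble_mean_counts(ensemble)
  if (max(mc$T) < target) {
    stop("mean transconjugant count never reaches the target; ",
         "increase t_max", call. = FALSE)
  }
  i <- which(mc$T >= target)[1]
  if (i == 1L) return(mc$time[1])
  t0 <- mc$time[i - 1]; t1 <- mc$time[i]
  y0 <- mc$T[i - 1]; y1 <- mc$T[i]
  t0 + (target - y0) / (y1 - y0) * (t1 - t0)
}

valid_nonzero_fraction <- function(estimates) {
  vals <- vapply(estimates, `[[`, numeric(1), "value")
  ok <- vapply(estimates, `[[`, logical(1), "valid")
  mean(ok & is.finite(vals) & vals != 0)
}

#' Incubation-time sweep of both estimators
#'
#' Runs one ensemble and computes the LDM and SIM estimate distributions at
#' each time of a 30-minute grid. A grid time is flagged as included for a
#' method only if at least 90% of that method's estimates are finite and
#' nonzero (applied per method, since the valid windows of the two
#' estimators differ).
#'
#' @param config A [sim_config()]; its sample grid is replaced by `t_grid`.
#' @param t_grid Strictly increasing times (hr) in 0.5-hr steps.
#' @param design A [batch_design()].
#' @return An object of class `sweep_result` with one cell per grid time:
#'   the LDM and SIM estimate lists, their summaries
#'   ([summarize_distribution()]), and inclusion flags.
#' @export
incubation_sweep <- function(config, t_grid, design) {
  stopifnot(inherits(config, "sim_config"), inherits(design, "batch_design"))
  if (any(abs(diff(t_grid) - 0.5) > 1e-9)) {
    stop("t_grid must advance in 30-minute (0.5 hr) steps", call. = FALSE)
  }
  st <- sort(unique(c(0, t_grid)))
  cfg <- sim_config(config$params, config$init, volume = config$volume,
                    t_max = max(t_grid), population_cap = config$population_cap,
                    engine = config$engine, sample_times = st)
  ens <- run_ensemble(cfg, design$n_populations, design$master_seed)
  cells <- lapply(t_grid, function(tt) {
    ldm <- ldm_batch_estimates(ens, tt, design)
    sim <- sim_batch_estimates(ens, tt, design)
    list(t_tilde = tt, ldm = ldm, sim = sim,
         ldm_summary = summarize_distribution(ldm),
         sim_summary = summarize_distribution(sim),
         ldm_included = valid_nonzero_fraction(ldm) >= 0.9,
         sim_included = valid_nonzero_fraction(sim) >= 0.9)
  })
  structure(list(axis = t_grid, axis_name = "t_tilde", cells = cells,
                 design = design, config = cfg),
            class = "sweep_result")
}

#' Parametric-heterogeneity sweep
#'
#' Re-runs the simulation study along one parameter axis: `"growth"` sets
#' the plasmid-bearing growth rates `psi_D = psi_T` to each value (modelling
#' plasmid cost/benefit), `"conjugation"` sets the transconjugant
#' conjugation rate `gamma_T`. For each value a fresh ensemble is generated
#' and each estimator gets its own incubation time ([choose_t_ldm()] /
#' [choose_t_sim()]).
#'
#' @param base_config A [sim_config()] holding the baseline parameters.
#' @param axis `"growth"` or `"conjugation"`.
#' @param values Positive parameter values to sweep.
#' @param design A [batch_design()].
#' @return A `sweep_result`; cells additionally record the chosen
#'   incubation times.
#' @export
parameter_sweep <- function(base_config,
                            axis = c("growth", "conjugation"),
                            values, design) {
  stopifnot(inherits(base_config, "sim_config"),
            inherits(design, "batch_design"), all(values > 0))
  axis <- match.arg(axis)
  cells <- lapply(seq_along(values), function(k) {
    v <- values[k]
    p <- base_config$params
    p2 <- if (axis == "growth") {
      rate_params(v, p$psi_R, v, p$gamma_D, p$gamma_T)
    } else {
      rate_params(p$psi_D, p$psi_R, p$psi_T, p$gamma_D, v)
    }
    cfg <- sim_config(p2, base_config$init, volume = base_config$volume,
                      t_max = base_config$t_max,
                      population_cap = base_config$population_cap,
                      engine = base_config$engine,
                      sample_times = base_config$sample_times)
    # independent but reproducible substream per cell
    ens <- run_ensemble(cfg, design$n_populations,
                        (design$master_seed + 7919L * k) %% 2147483647L)
    t_ldm <- as.numeric(choose_t_ldm(ens))
    t_sim <- tryCatch(choose_t_sim(ens), error = function(e) NA_real_)
    ldm <- ldm_batch_estimates(ens, t_ldm, design)
    sim <- if (is.na(t_sim)) list() else sim_batch_estimates(ens, t_sim, design)
    list(value = v, t_ldm = t_ldm, t_sim = t_sim, ldm = ldm, sim = sim,
         ldm_summary = summarize_distribution(ldm),
         sim_summary = if (length(sim)) summarize_distribution(sim) else NULL)
  })
  structure(list(axis = values, axis_name = axis, cells = cells,
                 design = design, config = base_config),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep over %s (%d cells, %d populations per cell)\n",
              x$axis_name, length(x$cells), x$design$n_populations))
  for (cell in x$cells) {
    lab <- if (x$axis_name == "t_tilde") cell$t_tilde else cell$value
    ldm_med <- cell$ldm_summary$median
    sim_med <- if (!is.null(cell$sim_summary)) cell$sim_summary$median else NA
    cat(sprintf("  %-10g LDM median %.3g | SIM median %.3g\n",
                lab, ldm_med, sim_med))
  }
  invisible(x)
}

#' Boxplot-style summary of an estimate distribution
#'
#' Quartiles (linear-interpolation, type-7 quantiles), median, mean, and
#' whiskers at 1.5 times the interquartile range clipped to the data range.
#' Zero estimates are retained in the distribution and counted; invalid
#' estimates are excluded from the numbers but counted.
#'
#' @param estimates List of `conj_estimate` objects (at least one).
#' @return List with `n`, `n_valid`, `n_zero`, `n_invalid`, `mean`,
#'   `median`, `q1`, `q3`, `whisker_low`, `whisker_high`.
#' @export
summarize_distribution <- function(estimates) {
  stopifnot(length(estimates) >= 1)
  vals <- vapply(estimates, `[[`, numeric(1), "value")
  ok <- vapply(estimates, `[[`, logical(1), "valid") & is.finite(vals)
  x <- vals[ok]
  if (length(x) == 0) {
    return(list(n = length(estimates), n_valid = 0, n_zero = 0,
                n_invalid = length(estimates), mean = NA_real_,
                median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                whisker_low = NA_real_, whisker_high = NA_real_))
  }
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  list(n = length(estimates), n_valid = length(x), n_zero = sum(x == 0),
       n_invalid = sum(!ok), mean = mean(x), median = q[2],
       q1 = q[1], q3 = q[3],
       whisker_low = max(min(x), q[1] - 1.5 * iqr),
       whisker_high = min(max(x), q[3] + 1.5 * iqr))
}

#' Compare two groups of conjugation-rate estimates
#'
#' Welch's two-sided t-test on log10 estimates, the scale on which
#' conjugation rates are compared. Zero and invalid estimates cannot be
#' log-transformed; they are excluded and their counts reported. A
#' permutation test on the same statistic is available as a cross-check.
#'
#' @param group_a,group_b Lists of `conj_estimate` objects with at least two
#'   valid nonzero members each.
#' @return List with `t`, `df`, `p_value`, the group means on the log10
#'   scale and the excluded counts; class `conj_comparison`.
#' @export
compare_estimates <- function(group_a, group_b) {
  pick <- function(g) {
    vals <- vapply(g, `[[`, numeric(1), "value")
    ok <- vapply(g, `[[`, logical(1), "valid") & is.finite(vals) & vals > 0
    list(x = log10(vals[ok]), excluded = sum(!ok))
  }
  a <- pick(group_a); b <- pick(group_b)
  if (length(a$x) < 2 || length(b$x) < 2) {
    stop("need at least 2 valid nonzero estimates per group", call. = FALSE)
  }
  if (sd(a$x) == 0 && sd(b$x) == 0 && mean(a$x) == mean(b$x)) {
    res <- list(statistic = 0, parameter = length(a$x) + length(b$x) - 2,
                p.value = 1)  # t.test errors on identical constant data
  } else {
    ht <- t.test(a$x, b$x)
    res <- list(statistic = unname(ht$statistic),
                parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  structure(list(t = res$statistic, df = res$parameter,
                 p_value = res$p.value,
                 mean_log10_a = mean(a$x), mean_log10_b = mean(b$x),
                 n_a = length(a$x), n_b = length(b$x),
                 excluded_a = a$excluded, excluded_b = b$excluded),
            class = "conj_comparison")
}

#' @export
print.conj_comparison <- function(x, ...) {
  cat(sprintf(
    "Welch t-test on log10 estimates: t = %.3g, df = %.3g, p = %.3g\n",
    x$t, x$df, x$p_value))
  cat(sprintf("  group means (log10): %.3g vs %.3g (n = %d, %d; excluded %d, %d)\n",
              x$mean_log10_a, x$mean_log10_b, x$n_a, x$n_b,
              x$excluded_a, x$excluded_b))
  invisible(x)
}

#' Tidy CSV export of a sweep
#'
#' One row per estimate: axis value, method, estimate value, validity and
#' reason.
#'
#' @param sweep A `sweep_result`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_sweep_csv <- function(sweep, file) {
  stopifnot(inherits(sweep, "sweep_result"))
  rows <- do.call(rbind, lapply(sweep$cells, function(cell) {
    lab <- if (sweep$axis_name == "t_tilde") cell$t_tilde else cell$value
    rbind(
      cbind(axis = lab, estimates_table(cell$ldm)),
      if (length(cell$sim)) cbind(axis = lab, estimates_table(cell$sim)))
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}
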