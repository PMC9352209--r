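#' Configuration for stochastic mating-assay simulations
#'
#' @param params A [rate_params()] object.
#' @param init An [inoculum()] object.
#' @param volume Culture volume in ml (default 1, where counts equal
#'   densities in cfu/ml).
#' @param t_max Simulation horizon (hr).
#' @param population_cap Stop condition on the total count; default 1e9,
#'   the usual end point of a batch mating assay.
#' @param engine `"gillespie"` (exact SSA over the five reactions) or
#'   `"hybrid"` (deterministic donors/recipients, stochastic transconjugant
#'   path; see [hybrid_run()]).
#' @param sample_times Times (hr) at which counts are recorded; defaults to
#'   a 0.1-hr grid over `[0, t_max]`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(params, init, volume = 1, t_max,
                       population_cap = 1e9,
                       engine = c("hybrid", "gillespie"),
                       sample_times = NULL) {
  stopifnot(inherits(params, "rate_params"), inherits(init, "inoculum"),
            volume > 0, t_max > 0, population_cap > 0)
  engine <- match.arg(engine)
  if (is.null(sample_times)) {
    sample_times <- seq(0, t_max, by = 0.1)
    if (sample_times[length(sample_times)] < t_max) {
      sample_times <- c(sample_times, t_max)
    }
  }
  stopifnot(all(diff(sample_times) > 0), all(sample_times >= 0),
            all(sample_times <= t_max))
  structure(list(params = params, init = init, volume = volume,
                 t_max = t_max, population_cap = population_cap,
                 engine = engine, sample_times = sample_times),
            class = "sim_config")
}

# densities -> integer counts in the simulated volume, guarding fractional
# inocula (a warning; an error if no sensible integer is nearby)
initial_counts <- function(init, volume) {
  x <- c(D = init$D0, R = init$R0, T = init$T0) * volume
  r <- round(x)
  if (any(abs(x - r) > 0.4999)) {
    stop("initial densities times volume are not close to integer counts",
         call. = FALSE)
  }
  if (any(abs(x - r) > 1e-6)) {
    warning("fractional initial counts rounded to integers", call. = FALSE)
  }
  r
}

new_stochastic_run <- function(config, D, R, T, t_star, end_time,
                               final, stop_reason, seed,
                               t_jumps = NULL, engine = config$engine) {
  structure(list(sample_times = config$sample_times,
                 D = D, R = R, T = T,
                 t_star = t_star, end_time = end_time, final = final,
                 stop_reason = stop_reason, seed = seed, engine = engine,
                 t_jumps = t_jumps,
                 params = config$params, init = config$init,
                 volume = config$volume),
            class = "stochastic_run")
}

#' @export
print.stochastic_run <- function(x, ...) {
  cat(sprintf("Stochastic mating-assay run (%s engine, volume %g ml)\n",
              x$engine, x$volume))
  cat(sprintf("  t* = %s hr; final counts D=%g R=%g T=%g (%s at t=%g)\n",
              if (is.na(x$t_star)) "none" else format(x$t_star),
              x$final[1], x$final[2], x$final[3], x$stop_reason, x$end_time))
  invisible(x)
}

#' Exact Gillespie realization of the mating assay
#'
#' Simulates the five reactions of the stochastic mating model exactly:
#' divisions of donors, recipients and transconjugants at `psi_D`, `psi_R`,
#' `psi_T`, donor-to-recipient conjugation at `gamma_D * D * R / V`
#' (converting one recipient into a transconjugant, and setting `t_star` on
#' its first firing), and transconjugant-to-recipient conjugation at
#' `gamma_T * T * R / V`.
#'
#' The exact SSA walks every event, so it refuses configurations whose
#' expected event count exceeds 1e8; use the hybrid engine for those.
#' Seed the R RNG (`set.seed`) before calling for reproducibility.
#'
#' @param config A [sim_config()].
#' @return An object of class `stochastic_run` with counts at
#'   `config$sample_times`, the first-conjugation time `t_star` (`NA` if no
#'   donor-to-recipient event occurred before the run ended), the final
#'   state, and the stop reason (`"t_max"`, `"population_cap"` or
#'   `"absorbed"`).
#' @export
gillespie_run <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cnt <- initial_counts(config$init, config$volume)
  psi_max <- max(config$params$psi_D, config$params$psi_R,
                 config$params$psi_T)
  expected_events <- min(sum(cnt) * exp(psi_max * config$t_max),
                         config$population_cap)
  if (expected_events > 1e8) {
    stop("expected event count exceeds 1e8; use engine = \"hybrid\"",
         call. = FALSE)
  }
  res <- .ssa_mating(cnt[1], cnt[2], cnt[3],
                     config$params$psi_D, config$params$psi_R,
                     config$params$psi_T,
                     config$params$gamma_D, config$params$gamma_T,
                     config$volume, config$t_max, config$population_cap,
                     config$sample_times)
  new_stochastic_run(config, res$D, res$R, res$T, res$t_star, res$end_time,
                     res$final, res$stop_reason, seed = NA_integer_,
                     engine = "gillespie")
}

#' Sample the first-conjugation time by inverse transform
#'
#' Draws t*, the time of the first donor-to-recipient conjugation event,
#' by inverting the analytic survival function [p0_analytic()]: with
#' \eqn{s = \psi_D + \psi_R} and whole-culture hazard scale
#' \eqn{\lambda = V \gamma_D D_0 R_0},
#' \deqn{t^* = \log(1 + s(-\log u)/\lambda)/s,}
#' falling back to the exponential \eqn{(-\log u)/\lambda} when `s = 0`.
#'
#' @param params A [rate_params()] object.
#' @param init An [inoculum()] with `T0 = 0`.
#' @param volume Culture volume (ml).
#' @param u Uniform(0,1) variates; vectorized.
#' @return Times (hr) whose survival function is `p0_analytic`.
#' @export
hybrid_tstar_sample <- function(params, init, volume = 1, u) {
  stopifnot(inherits(params, "rate_params"), inherits(init, "inoculum"))
  if (init$T0 != 0) stop("t* sampling assumes T0 = 0", call. = FALSE)
  stopifnot(all(u > 0), all(u < 1))
  lam <- volume * params$gamma_D * init$D0 * init$R0
  if (lam <= 0) {
    stop("zero conjugation hazard (gamma_D * D0 * R0 = 0): no event to sample",
         call. = FALSE)
  }
  s <- params$psi_D + params$psi_R
  if (s > 0) log1p(s * (-log(u)) / lam) / s else -log(u) / lam
}

#' Hybrid realization: deterministic hosts, stochastic transconjugants
#'
#' A fast simulator consistent with the LDM model assumptions: donors and
#' recipients follow their exponential closed forms while the transconjugant
#' count is an explicit stochastic pure-birth path, simulated by thinning an
#' inhomogeneous Poisson process with immigration rate
#' \eqn{V \gamma_D D_t R_t} (new transconjugants founded by donors) and
#' per-capita birth rate \eqn{\psi_T + \gamma_T R_t} (division plus
#' transconjugant-mediated conversion; both channels add one transconjugant
#' since hosts are not decremented in this engine). The thinning majorant is
#' piecewise constant, refreshed at each event or every 0.1 hr, whichever
#' comes first, because the recipient density grows exponentially.
#'
#' This engine is an addition of this package, validated against the exact
#' SSA on overlapping scales; t* is distributed exactly per [p0_analytic()].
#'
#' @inheritParams gillespie_run
#' @return A `stochastic_run`; additionally carries `t_jumps`, the ordered
#'   times of every transconjugant increment, so the T path is known exactly
#'   at any time.
#' @export
hybrid_run <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$init$T0 != 0) {
    stop("hybrid engine assumes T0 = 0", call. = FALSE)
  }
  initial_counts(config$init, config$volume)  # validate inoculum only
  p <- config$params
  V <- config$volume
  D0 <- config$init$D0
  R0 <- config$init$R0
  s <- p$psi_D + p$psi_R
  imm_rate <- function(t) V * p$gamma_D * D0 * R0 * exp(s * t)
  percap_rate <- function(t) p$psi_T + p$gamma_T * R0 * exp(p$psi_R * t)
  host_count <- function(t) V * (D0 * exp(p$psi_D * t) + R0 * exp(p$psi_R * t))

  u <- runif(1)
  t_star <- hybrid_tstar_sample(p, config$init, V, u)
  t_jumps <- numeric(0)
  stop_reason <- "t_max"
  end_time <- config$t_max
  if (t_star <= config$t_max) {
    t_jumps <- t_star
    t <- t_star
    T_n <- 1
    window <- 0.1
    repeat {
      t_hi <- min(t + window, config$t_max)
      bound <- imm_rate(t_hi) + T_n * percap_rate(t_hi)
      if (!is.finite(bound)) {
        stop(sprintf("propensity overflow at T count %g", T_n), call. = FALSE)
      }
      dt <- stats::rexp(1, bound)
      if (t + dt > t_hi) {
        t <- t_hi
        if (t >= config$t_max) break
        next
      }
      t <- t + dt
      if (runif(1) * bound <= imm_rate(t) + T_n * percap_rate(t)) {
        T_n <- T_n + 1
        t_jumps <- c(t_jumps, t)
        if (host_count(t) + T_n >= config$population_cap) {
          stop_reason <- "population_cap"
          end_time <- t
          break
        }
      }
    }
  }
  T_path <- vapply(config$sample_times,
                   function(tt) sum(t_jumps <= tt), numeric(1))
  D_path <- V * D0 * exp(p$psi_D * pmin(config$sample_times, end_time))
  R_path <- V * R0 * exp(p$psi_R * pmin(config$sample_times, end_time))
  new_stochastic_run(config, D_path, R_path, T_path,
                     t_star = if (t_star <= config$t_max) t_star else NA_real_,
                     end_time = end_time,
                     final = c(D_path[length(D_path)], R_path[length(R_path)],
                               length(t_jumps)),
                     stop_reason = stop_reason, seed = NA_integer_,
                     t_jumps = t_jumps, engine = "hybrid")
}

#' Counts of a stochastic run at an arbitrary time
#'
#' Hybrid runs are exact at any time (closed-form hosts, stored jump times).
#' Gillespie runs are exact at their sample times; between samples, donor
#' and recipient counts are interpolated geometrically (exact in expectation
#' for exponential growth) and the transconjugant count linearly.
#'
#' @param run A `stochastic_run`.
#' @param t Time in `[0, t_max]` (hr).
#' @return Named numeric vector `c(D, R, T)` of counts in the run's volume.
#' @export
state_at <- function(run, t) {
  stopifnot(inherits(run, "stochastic_run"), length(t) == 1L, t >= 0)
  st <- run$sample_times
  if (t > st[length(st)]) {
    stop("time is beyond the run's sampled horizon", call. = FALSE)
  }
  if (run$engine == "hybrid") {
    tt <- min(t, run$end_time)
    return(c(D = run$volume * run$init$D0 * exp(run$params$psi_D * tt),
             R = run$volume * run$init$R0 * exp(run$params$psi_R * tt),
             T = sum(run$t_jumps <= t)))
  }
  hit <- which(st == t)
  if (length(hit) == 1L) {
    return(c(D = run$D[hit], R = run$R[hit], T = run$T[hit]))
  }
  i <- findInterval(t, st)
  th <- (t - st[i]) / (st[i + 1] - st[i])
  interp <- function(a, b, geometric) {
    if (geometric && a > 0 && b > 0) a * (b / a)^th else a + th * (b - a)
  }
  c(D = interp(run$D[i], run$D[i + 1], TRUE),
    R = interp(run$R[i], run$R[i + 1], TRUE),
    T = interp(run$T[i], run$T[i + 1], FALSE))
}

#' Ensemble of independent stochastic runs
#'
#' Runs `n` independent realizations of one [sim_config()], with per-run
#' seeds drawn reproducibly from `master_seed`, so the whole ensemble is
#' bitwise reproducible from `(config, master_seed)`.
#'
#' @param config A [sim_config()].
#' @param n Number of runs.
#' @param master_seed Integer master seed.
#' @return An object of class `mating_ensemble`: the runs, the config, the
#'   master seed and the derived per-run seeds.
#' @export
run_ensemble <- function(config, n, master_seed) {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, n)
  engine_fun <- switch(config$engine,
                       gillespie = gillespie_run, hybrid = hybrid_run)
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    runs[[i]] <- engine_fun(config)
    runs[[i]]$seed <- seeds[i]
  }
  structure(list(runs = runs, config = config,
                 master_seed = master_seed, seeds = seeds),
            class = "mating_ensemble")
}

#' @rdname mating_model
#' @param nsim Number of stochastic runs.
#' @param seed Master seed for the ensemble.
#' @param t_max,volume,engine Passed to [sim_config()].
#' @export
simulate.mating_model <- function(object, nsim = 1, seed = 1, t_max,
                                  volume = 1, engine = "hybrid", ...) {
  cfg <- sim_config(object$params, object$init, volume = volume,
                    t_max = t_max, engine = engine, ...)
  run_ensemble(cfg, nsim, seed)
}

#' @export
print.mating_ensemble <- function(x, ...) {
  n <- length(x$runs)
  ts <- tstar_values(x)
  cat(sprintf(
    "Ensemble of %d %s runs (master seed %d)\n", n, x$config$engine,
    x$master_seed))
  cat(sprintf("  t* observed in %d/%d runs%s\n", length(ts), n,
              if (length(ts)) sprintf(", mean %.3g hr", mean(ts)) else ""))
  invisible(x)
}

#' First-conjugation times observed in an ensemble
#'
#' @param ensemble A `mating_ensemble`.
#' @return Numeric vector of the observed (finite) t* values; runs without a
#'   first conjugation event are omitted.
#' @export
tstar_values <- function(ensemble) {
  stopifnot(inherits(ensemble, "mating_ensemble"))
  ts <- vapply(ensemble$runs, function(r) r$t_star, numeric(1))
  ts[!is.na(ts)]
}

#' Fraction of runs still transconjugant-free at a time
#'
#' The empirical analogue of [p0_analytic()]: the share of runs whose first
#' conjugation event falls strictly after `t` (runs with no event at all
#' count as transconjugant-free).
#'
#' @param ensemble A `mating_ensemble`.
#' @param t Time (hr); vectorized.
#' @return Fractions in `[0, 1]`, nonincreasing in `t`.
#' @export
fraction_tfree <- function(ensemble, t) {
  stopifnot(inherits(ensemble, "mating_ensemble"))
  ts <- vapply(ensemble$runs, function(r) r$t_star, numeric(1))
  vapply(t, function(tt) mean(is.na(ts) | ts > tt), numeric(1))
}

#' Mean counts of an ensemble on its sample grid
#'
#' @param ensemble A `mating_ensemble`.
#' @return Data frame with columns `time`, `D`, `R`, `T`: mean counts across
#'   runs at each sample time.
#' @export
ensemble_mean_counts <- function(ensemble) {
  stopifnot(inherits(ensemble, "mating_ensemble"))
  st <- ensemble$config$sample_times
  data.frame(
    time = st,
    D = rowMeans(vapply(ensemble$runs, `[[`, numeric(length(st)), "D")),
    R = rowMeans(vapply(ensemble$runs, `[[`, numeric(length(st)), "R")),
    T = rowMeans(vapply(ensemble$runs, `[[`, numeric(length(st)), "T")))
}

#' Serialize an ensemble
#'
#' `write_ensemble_csv` writes one row per sampled time per run (tidy long
#' form); `write_ensemble_summary_json` writes a compact summary (t* list,
#' seeds, config echo).
#'
#' @param ensemble A `mating_ensemble`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_ensemble_csv <- function(ensemble, file) {
  stopifnot(inherits(ensemble, "mating_ensemble"))
  st <- ensemble$config$sample_times
  rows <- do.call(rbind, lapply(seq_along(ensemble$runs), function(i) {
    r <- ensemble$runs[[i]]
    data.frame(run = i, seed = r$seed, time = st, D = r$D, R = r$R, T = r$T)
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_ensemble_csv
#' @export
write_ensemble_summary_json <- function(ensemble, file) {
  stopifnot(inherits(ensemble, "mating_ensemble"))
  cfg <- ensemble$config
  jsonlite::write_json(
    list(engine = cfg$engine, volume = cfg$volume, t_max = cfg$t_max,
         population_cap = cfg$population_cap,
         params = unclass(cfg$params), init = unclass(cfg$init),
         master_seed = ensemble$master_seed, seeds = ensemble$seeds,
         t_star = vapply(ensemble$runs, function(r) r$t_star, numeric(1))),
    file, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(file)
}
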