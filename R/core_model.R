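#' Deterministic mating-assay dynamics
#'
#' Integrates the mass-action mating model
#' \deqn{dD/dt = \psi_D D}
#' \deqn{dR/dt = \psi_R R - \gamma_D D R - \gamma_T T R}
#' \deqn{dT/dt = \psi_T T + \gamma_D D R + \gamma_T T R}
#' over a time grid. The recipient loss terms are retained even though the
#' LDM derivation neglects them; their effect is negligible whenever
#' \eqn{\gamma D \ll \psi_R}, which is itself a testable property.
#'
#' Integration uses a stiff-capable adaptive solver (rtol 1e-10, atol 1e-10
#' cfu/ml) because transconjugant densities span many orders of magnitude.
#'
#' @param params A [rate_params()] object.
#' @param init An [inoculum()] object.
#' @param times Strictly increasing time grid (hr) with `times[1] == 0`.
#' @return A `mating_trajectory`: a data frame with columns `time`, `D`, `R`,
#'   `T`, `N` (`N = D + R + T`), densities in cfu/ml.
#' @examples
#' tr <- ode_solve(rate_params(1, 1, 1, 1e-14, 1e-14),
#'                 inoculum(1e5, 1e5), seq(0, 6, by = 1))
#' all.equal(tr$D, 1e5 * exp(tr$time), tolerance = 1e-8)
#' @export
ode_solve <- function(params, init, times) {
  stopifnot(inherits(params, "rate_params"), inherits(init, "inoculum"))
  if (length(times) < 2L || any(diff(times) <= 0) || times[1] != 0) {
    stop("`times` must be strictly increasing and start at 0", call. = FALSE)
  }
  deriv <- function(t, y, p) {
    conj_D <- p$gamma_D * y[1] * y[2]
    conj_T <- p$gamma_T * y[3] * y[2]
    list(c(p$psi_D * y[1],
           p$psi_R * y[2] - conj_D - conj_T,
           p$psi_T * y[3] + conj_D + conj_T))
  }
  y0 <- c(D = init$D0, R = init$R0, T = init$T0)
  sol <- deSolve::lsoda(y0, times, deriv, params,
                        rtol = 1e-10, atol = 1e-10)
  sol <- as.data.frame(sol)
  if (any(!is.finite(as.matrix(sol)))) {
    t_bad <- sol$time[which(!stats::complete.cases(sol) |
                              apply(!is.finite(as.matrix(sol)), 1, any))[1]]
    stop(sprintf("integration failed: nonfinite state at time %g hr", t_bad),
         call. = FALSE)
  }
  names(sol) <- c("time", "D", "R", "T")
  sol$N <- sol$D + sol$R + sol$T
  structure(sol, class = c("mating_trajectory", "data.frame"),
            params = params, init = init)
}

#' Closed-form exponential growth
#'
#' Density of a population growing exponentially at per-capita rate `psi`
#' from initial density `x0`: `x0 * exp(psi * t)`. This is the closed form
#' used for donors and recipients in the LDM derivation.
#'
#' @param x0 Initial density (cfu/ml), nonnegative.
#' @param psi Per-capita growth rate (1/hr).
#' @param t Time (hr), nonnegative. Vectorized over `t`.
#' @return Density at time `t` (cfu/ml). Overflow returns `Inf` with a
#'   warning.
#' @export
exponential_density <- function(x0, psi, t) {
  stopifnot(is.numeric(x0), x0 >= 0, is.numeric(t), all(t >= 0))
  out <- x0 * exp(psi * t)
  if (any(is.infinite(out))) {
    warning("exponential_density overflowed to Inf", call. = FALSE)
  }
  out
}

#' Probability that a coculture is still transconjugant-free
#'
#' Analytic probability that no transconjugant exists at time `t` in a
#' culture inoculated with donors and recipients only:
#' \deqn{p_0(t) = \exp\{-V \gamma_D D_0 R_0
#'   (e^{(\psi_D+\psi_R)t} - 1) / (\psi_D+\psi_R)\}}
#' for culture volume `V` in ml (the classic form assumes 1 ml, where counts
#' equal densities). The limit \eqn{\psi_D+\psi_R = 0} is handled
#' analytically, giving \eqn{\exp(-V\gamma_D D_0 R_0 t)}.
#'
#' @param params A [rate_params()] object (`psi_D`, `psi_R`, `gamma_D` used).
#' @param init An [inoculum()] object with `T0 = 0`.
#' @param t Time (hr); vectorized.
#' @param volume Culture volume in ml (default 1).
#' @return Probability in (0, 1].
#' @seealso [cumulative_hazard()], [ldm_parametric()]
#' @export
p0_analytic <- function(params, init, t, volume = 1) {
  exp(-cumulative_hazard(params, init, t, volume))
}

#' Expected number of first-transconjugant-founding events
#'
#' Cumulative hazard of the first donor-to-recipient conjugation event, i.e.
#' the integral of \eqn{V \gamma_D D_t R_t} with exponentially growing donors
#' and recipients; equals `-log(p0_analytic(...))`.
#'
#' @inheritParams p0_analytic
#' @return Nonnegative expected event count, nondecreasing in `t`.
#' @export
cumulative_hazard <- function(params, init, t, volume = 1) {
  stopifnot(inherits(params, "rate_params"), inherits(init, "inoculum"))
  if (init$T0 > 0) {
    stop("cumulative hazard of the first transconjugant assumes T0 = 0",
         call. = FALSE)
  }
  stopifnot(is.numeric(t), all(t >= 0), volume > 0)
  s <- params$psi_D + params$psi_R
  volume * params$gamma_D * init$D0 * init$R0 * growth_phi(s, t)
}

#' Mean time of the first conjugation event
#'
#' Expected value of t*, the random time at which the first transconjugant
#' appears, computed as the integral of the survival function
#' [p0_analytic()] by adaptive quadrature (truncated where p0 drops below
#' 1e-12). This is the natural incubation time for the LDM assay, which
#' needs a mix of transconjugant-free and transconjugant-positive cultures.
#'
#' @inheritParams p0_analytic
#' @return Positive finite expected time (hr).
#' @export
mean_tstar_analytic <- function(params, init, volume = 1) {
  stopifnot(inherits(params, "rate_params"), inherits(init, "inoculum"))
  lam <- volume * params$gamma_D * init$D0 * init$R0
  if (lam <= 0) {
    stop("zero conjugation hazard (gamma_D * D0 * R0 = 0): t* never occurs",
         call. = FALSE)
  }
  s <- params$psi_D + params$psi_R
  target <- -log(1e-12)
  t_up <- if (s > 0) log1p(s * target / lam) / s else target / lam
  stats::integrate(function(t) p0_analytic(params, init, t, volume),
                   0, t_up, rel.tol = 1e-10)$value
}

#' Write a deterministic trajectory as tidy CSV
#'
#' @param trajectory A `mating_trajectory` from [ode_solve()].
#' @param file Output path; columns `time`, `D`, `R`, `T`, `N`.
#' @return Invisibly, `file`.
#' @export
write_trajectory_csv <- function(trajectory, file) {
  stopifnot(inherits(trajectory, "mating_trajectory"))
  utils::write.csv(as.data.frame(trajectory)[c("time", "D", "R", "T", "N")],
                   file, row.names = FALSE)
  invisible(file)
}
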