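#' Assay observation for end-point estimators
#'
#' One mating assay's measured quantities: incubation time, initial and
#' final densities, the reciprocal culture volume `f` (1/ml), and optionally
#' the fraction of transconjugant-free parallel cocultures `p0_hat` with the
#' number of wells scored.
#'
#' @param t_tilde Incubation time (hr), positive.
#' @param D0,R0,N0 Initial densities (cfu/ml); `N0` may be omitted, in which
#'   case it defaults to `D0 + R0` when both are present.
#' @param Dt,Rt,Tt,Nt Final densities (cfu/ml); `Nt` defaults to
#'   `Dt + Rt + Tt` when those are present.
#' @param f Reciprocal culture volume (1/ml); `f = 1` for a 1-ml assay,
#'   `f = 10` for 100 ul.
#' @param p0_hat Fraction of transconjugant-free cocultures, in `[0, 1]`.
#' @param n_wells Number of cocultures scored for `p0_hat`.
#' @return An object of class `assay_observation`.
#' @export
assay_observation <- function(t_tilde, D0 = NA, R0 = NA, N0 = NA,
                              Dt = NA, Rt = NA, Tt = NA, Nt = NA,
                              f = 1, p0_hat = NA, n_wells = NA) {
  stopifnot(t_tilde > 0, f > 0)
  if (is.na(N0) && !is.na(D0) && !is.na(R0)) N0 <- D0 + R0
  if (is.na(Nt) && !is.na(Dt) && !is.na(Rt) && !is.na(Tt)) Nt <- Dt + Rt + Tt
  dens <- c(D0, R0, N0, Dt, Rt, Tt, Nt)
  if (any(dens < 0, na.rm = TRUE)) {
    stop("densities must be nonnegative", call. = FALSE)
  }
  if (!is.na(p0_hat) && (p0_hat < 0 || p0_hat > 1)) {
    stop("p0_hat must lie in [0, 1]", call. = FALSE)
  }
  if (!is.na(Nt) && !is.na(Dt) && !is.na(Rt) && !is.na(Tt)) {
    if (abs(Nt - (Dt + Rt + Tt)) > 0.01 * Nt) {
      stop("Nt is not within 1% of Dt + Rt + Tt", call. = FALSE)
    }
  }
  structure(list(t_tilde = t_tilde, D0 = D0, R0 = R0, N0 = N0,
                 Dt = Dt, Rt = Rt, Tt = Tt, Nt = Nt,
                 f = f, p0_hat = p0_hat, n_wells = n_wells),
            class = "assay_observation")
}

new_conj_estimate <- function(method, value, valid, reason = NA_character_,
                              inputs = NULL) {
  structure(list(method = method, value = value, valid = valid,
                 reason = reason, inputs = inputs),
            class = "conj_estimate")
}

#' @export
print.conj_estimate <- function(x, ...) {
  unit <- if (x$method == "LD-mutation") "per cell division-ish (1/hr scale)"
          else "ml cell^-1 hr^-1"
  if (x$valid) {
    cat(sprintf("%s estimate: %.6g %s%s\n", x$method, x$value, unit,
                if (!is.na(x$reason)) sprintf(" (%s)", x$reason) else ""))
  } else {
    cat(sprintf("%s estimate: invalid (%s)\n", x$method, x$reason))
  }
  invisible(x)
}

#' @export
coef.conj_estimate <- function(object, ...) {
  setNames(object$value, object$method)
}

#' Realized exponential growth rate
#'
#' `log(xt/x0)/t`, the per-capita rate a population must have grown at to
#' move from density `x0` to `xt` in time `t` under exponential growth.
#'
#' @param x0,xt Initial and final densities, positive.
#' @param t Elapsed time (hr), positive.
#' @return Growth rate (1/hr).
#' @export
growth_rate_realized <- function(x0, xt, t) {
  if (any(x0 <= 0) || any(xt <= 0)) {
    stop("densities must be positive to compute a realized growth rate",
         call. = FALSE)
  }
  stopifnot(all(t > 0))
  log(xt / x0) / t
}

#' Maximum-likelihood estimate of the transconjugant-free probability
#'
#' The fraction of parallel cocultures scored transconjugant-free
#' (nonturbid under transconjugant selection): `n_negative / n_total`.
#'
#' @param n_negative Number of transconjugant-free cocultures.
#' @param n_total Number of cocultures scored, at least 1.
#' @return Probability in `[0, 1]`.
#' @export
p0_mle <- function(n_negative, n_total) {
  if (length(n_total) != 1L || n_total < 1) {
    stop("n_total must be a single count >= 1", call. = FALSE)
  }
  stopifnot(n_negative >= 0, n_negative <= n_total)
  n_negative / n_total
}

#' Simonsen end-point (SIM) estimate of the donor conjugation rate
#'
#' The classic end-point estimate assuming identical growth and conjugation
#' rates across the three populations:
#' \deqn{\hat\gamma_D = \psi \log(1 + (T_t/R_t)(N_t/D_t)) / (N_t - N_0),}
#' with \eqn{\psi} the realized growth rate of the total population,
#' `log(Nt/N0)/t_tilde`.
#'
#' @param obs An [assay_observation()] with `N0`, `Nt`, `Dt`, `Rt`, `Tt` and
#'   `t_tilde`.
#' @param psi Optional override for the growth rate used; default is the
#'   realized total-population rate.
#' @return A `conj_estimate`. `Tt = 0` yields a valid zero estimate with
#'   reason `"no transconjugants"`; `Nt <= N0` or a zero `Dt`/`Rt` yields an
#'   invalid result with a reason code.
#' @export
sim_estimate <- function(obs, psi = NULL) {
  stopifnot(inherits(obs, "assay_observation"))
  need <- c("N0", "Nt", "Dt", "Rt", "Tt")
  if (any(is.na(unlist(obs[need])))) {
    stop("SIM estimate needs N0, Nt, Dt, Rt, Tt", call. = FALSE)
  }
  if (obs$Nt <= obs$N0) {
    return(new_conj_estimate("SIM", NA_real_, FALSE, "no net growth", obs))
  }
  if (obs$Dt <= 0 || obs$Rt <= 0) {
    return(new_conj_estimate("SIM", NA_real_, FALSE,
                             "zero donor or recipient density", obs))
  }
  if (is.null(psi)) psi <- growth_rate_realized(obs$N0, obs$Nt, obs$t_tilde)
  if (obs$Tt == 0) {
    return(new_conj_estimate("SIM", 0, TRUE, "no transconjugants", obs))
  }
  value <- psi * log1p((obs$Tt / obs$Rt) * (obs$Nt / obs$Dt)) /
    (obs$Nt - obs$N0)
  new_conj_estimate("SIM", value, TRUE, NA_character_, obs)
}

#' Parametric LDM estimate of the donor conjugation rate
#'
#' Inverts the analytic transconjugant-free probability for \eqn{\gamma_D}:
#' \deqn{\hat\gamma_D = f\,(-\log \hat p_0)\,
#'   \frac{\psi_D+\psi_R}{D_0 R_0 (e^{(\psi_D+\psi_R)\tilde t} - 1)},}
#' using known (or separately measured) growth rates. `f` scales the 1-ml
#' formula to the actual culture volume (`f` = 1/volume in ml). The
#' \eqn{\psi_D+\psi_R = 0} limit is handled analytically.
#'
#' @param p0_hat Estimated transconjugant-free fraction, in `(0, 1]`.
#' @param params A [rate_params()] (`psi_D`, `psi_R` used).
#' @param init An [inoculum()] with `D0 * R0 > 0`.
#' @param t_tilde Incubation time (hr), positive.
#' @param f Reciprocal culture volume (1/ml).
#' @return A `conj_estimate`. `p0_hat = 1` yields a valid zero with reason
#'   `"no wells turbid"`; `p0_hat = 0` an invalid result (`-log 0`
#'   undefined).
#' @export
ldm_parametric <- function(p0_hat, params, init, t_tilde, f = 1) {
  stopifnot(inherits(params, "rate_params"), inherits(init, "inoculum"),
            t_tilde > 0, f > 0)
  if (is.na(p0_hat) || p0_hat < 0 || p0_hat > 1) {
    stop("p0_hat must lie in [0, 1]", call. = FALSE)
  }
  if (init$D0 * init$R0 <= 0) {
    stop("LDM estimate requires D0 > 0 and R0 > 0", call. = FALSE)
  }
  if (p0_hat == 0) {
    return(new_conj_estimate("LDM-parametric", NA_real_, FALSE,
                             "all wells turbid; -log 0 undefined"))
  }
  if (p0_hat == 1) {
    return(new_conj_estimate("LDM-parametric", 0, TRUE, "no wells turbid"))
  }
  s <- params$psi_D + params$psi_R
  value <- f * (-log(p0_hat)) /
    (init$D0 * init$R0 * growth_phi(s, t_tilde))
  new_conj_estimate("LDM-parametric", value, TRUE)
}

#' End-point LDM estimate of the donor conjugation rate
#'
#' The laboratory form of the LDM estimate, needing only measured initial
#' and final donor/recipient densities (no growth-rate inputs):
#' \deqn{\hat\gamma_D = \frac{f\,[-\log \hat p_0]\,
#'   (\log D_{\tilde t} R_{\tilde t} - \log D_0 R_0)}
#'   {\tilde t\,(D_{\tilde t} R_{\tilde t} - D_0 R_0)}.}
#' It is algebraically identical to [ldm_parametric()] with the growth rates
#' replaced by their realized values `log(Dt/D0)/t` and `log(Rt/R0)/t`.
#'
#' @param obs An [assay_observation()] with `p0_hat`, `D0`, `R0`, `Dt`,
#'   `Rt`, `t_tilde` and `f`; all densities positive.
#' @return A `conj_estimate`; degenerate growth (`Dt*Rt == D0*R0`) and
#'   `p0_hat = 0` give invalid results with reason codes.
#' @export
ldm_endpoint <- function(obs) {
  stopifnot(inherits(obs, "assay_observation"))
  need <- c("p0_hat", "D0", "R0", "Dt", "Rt")
  if (any(is.na(unlist(obs[need])))) {
    stop("LDM end-point estimate needs p0_hat, D0, R0, Dt, Rt", call. = FALSE)
  }
  if (any(unlist(obs[c("D0", "R0", "Dt", "Rt")]) <= 0)) {
    return(new_conj_estimate("LDM", NA_real_, FALSE,
                             "nonpositive density", obs))
  }
  if (obs$p0_hat == 0) {
    return(new_conj_estimate("LDM", NA_real_, FALSE,
                             "all wells turbid; -log 0 undefined", obs))
  }
  if (obs$p0_hat == 1) {
    return(new_conj_estimate("LDM", 0, TRUE, "no wells turbid", obs))
  }
  prod0 <- obs$D0 * obs$R0
  prodt <- obs$Dt * obs$Rt
  if (prodt == prod0) {
    return(new_conj_estimate("LDM", NA_real_, FALSE,
                             "degenerate growth: Dt*Rt equals D0*R0", obs))
  }
  value <- obs$f * (-log(obs$p0_hat)) * (log(prodt) - log(prod0)) /
    (obs$t_tilde * (prodt - prod0))
  new_conj_estimate("LDM", value, TRUE, NA_character_, obs)
}

#' Luria-Delbruck mutation rate from the zero-mutant fraction
#'
#' The classic fluctuation-test estimate:
#' \deqn{\hat\mu = (-\log \hat p_0)\,\psi_N / (N_0 (e^{\psi_N \tilde t}-1)),}
#' for a wild-type population of initial size `N0` growing at rate `psi_N`.
#' The conjugation analogue is recovered by the mapping `N0 -> D0*R0`,
#' `psi_N -> psi_D + psi_R`.
#'
#' @param p0_hat Fraction of mutant-free cultures, in `(0, 1]`.
#' @param N0 Initial wild-type population size, positive.
#' @param psi_N Wild-type growth rate (1/hr).
#' @param t_tilde Incubation time (hr), positive.
#' @return A `conj_estimate` with method `"LD-mutation"`.
#' @export
ld_mutation_rate <- function(p0_hat, N0, psi_N, t_tilde) {
  stopifnot(N0 > 0, t_tilde > 0)
  if (is.na(p0_hat) || p0_hat < 0 || p0_hat > 1) {
    stop("p0_hat must lie in [0, 1]", call. = FALSE)
  }
  if (p0_hat == 0) {
    return(new_conj_estimate("LD-mutation", NA_real_, FALSE,
                             "all cultures contain mutants; -log 0 undefined"))
  }
  if (p0_hat == 1) {
    return(new_conj_estimate("LD-mutation", 0, TRUE, "no mutants observed"))
  }
  value <- (-log(p0_hat)) / (N0 * growth_phi(psi_N, t_tilde))
  new_conj_estimate("LD-mutation", value, TRUE)
}

#' Collect estimate results into a tidy data frame
#'
#' @param estimates A list of `conj_estimate` objects.
#' @return Data frame with columns `method`, `value`, `valid`, `reason`.
#' @export
estimates_table <- function(estimates) {
  if (inherits(estimates, "conj_estimate")) estimates <- list(estimates)
  data.frame(
    method = vapply(estimates, `[[`, character(1), "method"),
    value = vapply(estimates, `[[`, numeric(1), "value"),
    valid = vapply(estimates, `[[`, logical(1), "valid"),
    reason = vapply(estimates, `[[`, character(1), "reason"))
}
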