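#' Rate parameters of the mating model
#'
#' Bundles the five rates of the donor/recipient/transconjugant mating model:
#' per-capita growth rates of donors, recipients and transconjugants
#' (`psi_D`, `psi_R`, `psi_T`, in 1/hr) and the two conjugation rate
#' parameters (`gamma_D`: donor to recipient; `gamma_T`: transconjugant to
#' recipient; in ml/(cell hr) under mass action).
#'
#' @param psi_D,psi_R,psi_T Per-capita growth rates (1/hr), nonnegative.
#' @param gamma_D,gamma_T Conjugation rate parameters (ml cell^-1 hr^-1),
#'   nonnegative.
#' @return An object of class `rate_params`.
#' @examples
#' rate_params(psi_D = 1, psi_R = 1, psi_T = 1, gamma_D = 1e-6, gamma_T = 1e-6)
#' @export
rate_params <- function(psi_D, psi_R, psi_T, gamma_D, gamma_T) {
  x <- c(psi_D = psi_D, psi_R = psi_R, psi_T = psi_T,
         gamma_D = gamma_D, gamma_T = gamma_T)
  if (!is.numeric(x) || length(x) != 5L) {
    stop("all five rates must be single numeric values", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("rate parameters must be finite", call. = FALSE)
  if (any(x < 0)) stop("rate parameters must be nonnegative", call. = FALSE)
  structure(as.list(x), class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Mating-model rates (1/hr; conjugation in ml cell^-1 hr^-1):\n")
  cat(sprintf("  psi_D = %g  psi_R = %g  psi_T = %g\n",
              x$psi_D, x$psi_R, x$psi_T))
  cat(sprintf("  gamma_D = %g  gamma_T = %g\n", x$gamma_D, x$gamma_T))
  invisible(x)
}

#' Inoculum densities
#'
#' Initial densities (cfu/ml) of donors, recipients and transconjugants. An
#' assay suitable for the LDM estimate starts with donors and recipients but
#' no transconjugants (`D0 > 0`, `R0 > 0`, `T0 = 0`).
#'
#' @param D0,R0,T0 Initial densities in cfu/ml; `T0` defaults to 0.
#' @return An object of class `inoculum`.
#' @export
inoculum <- function(D0, R0, T0 = 0) {
  x <- c(D0 = D0, R0 = R0, T0 = T0)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("initial densities must be finite and nonnegative", call. = FALSE)
  }
  structure(as.list(x), class = "inoculum")
}

#' @export
print.inoculum <- function(x, ...) {
  cat(sprintf("Inoculum (cfu/ml): D0 = %g, R0 = %g, T0 = %g\n",
              x$D0, x$R0, x$T0))
  invisible(x)
}

#' Mating model object
#'
#' Couples a [rate_params()] set with an [inoculum()], giving a model of a
#' well-mixed mating assay whose deterministic dynamics are available through
#' [predict()] (numerical integration of the mass-action equations) and whose
#' stochastic realizations are available through [simulate()].
#'
#' @param params A [rate_params()] object.
#' @param init An [inoculum()] object.
#' @return An object of class `mating_model`.
#' @seealso [predict.mating_model()], [simulate.mating_model()],
#'   [p0_analytic()]
#' @examples
#' m <- mating_model(rate_params(1, 1, 1, 1e-6, 1e-6), inoculum(1e2, 1e2))
#' predict(m, times = seq(0, 2, by = 0.5))
#' @export
mating_model <- function(params, init) {
  stopifnot(inherits(params, "rate_params"), inherits(init, "inoculum"))
  structure(list(params = params, init = init), class = "mating_model")
}

#' @export
print.mating_model <- function(x, ...) {
  cat("Donor/recipient/transconjugant mating model\n")
  print(x$params)
  print(x$init)
  invisible(x)
}

#' @rdname mating_model
#' @param object A `mating_model`.
#' @param times Strictly increasing time grid starting at 0 (hr).
#' @param ... Unused.
#' @export
predict.mating_model <- function(object, times, ...) {
  ode_solve(object$params, object$init, times)
}

# (exp(s*t) - 1)/s, with a 2nd-order series near s*t = 0 to avoid
# cancellation; the s -> 0 limit is t.
growth_phi <- function(s, t) {
  st <- s * t
  out <- numeric(length(st))
  small <- abs(st) < 1e-8
  out[small] <- t[small] * (1 + st[small] / 2 + st[small]^2 / 6)
  if (any(!small)) out[!small] <- expm1(st[!small]) / s
  out
}

read_params_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  list(params = rate_params(x$params$psi_D, x$params$psi_R, x$params$psi_T,
                            x$params$gamma_D, x$params$gamma_T),
       init = inoculum(x$init$D0, x$init$R0,
                       if (is.null(x$init$T0)) 0 else x$init$T0))
}

#' Read and write model configurations as JSON
#'
#' Parameter sets and inocula are serialized with explicit unit annotations
#' so that configurations are self-describing. Time is in hours, densities in
#' cfu/ml and conjugation rates in ml cell^-1 hr^-1 throughout the package.
#'
#' @param params A [rate_params()] object.
#' @param init An [inoculum()] object.
#' @param file Path to a JSON file.
#' @return `write_model_json` invisibly returns `file`; `read_model_json`
#'   returns a list with elements `params` and `init`.
#' @export
write_model_json <- function(params, init, file) {
  stopifnot(inherits(params, "rate_params"), inherits(init, "inoculum"))
  jsonlite::write_json(
    list(units = list(time = "hr", density = "cfu/ml",
                      conjugation_rate = "ml cell^-1 hr^-1"),
         params = unclass(params), init = unclass(init)),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(file) read_params_json(file)
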