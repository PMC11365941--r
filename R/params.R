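#' Construct model parameters
#'
#' All rates and amounts are non-negative; `lam`, `phi`, `nu` are strictly
#' positive and `g_eff` strictly negative. See
#' [ModelParameters-class] for the meaning and units of each constant.
#'
#' @param C_s,C_d,lam,g_eff,alpha1,alpha2,beta1,beta2,gamma,rho,phi,nu,zeta1,zeta2
#'   numeric scalars; defaults are the package reference set (see
#'   [referenceParameters()]).
#' @return A [ModelParameters-class].
#' @export
modelParameters <- function(C_s = 0.003, C_d = 1.0, lam = 3,
                            g_eff = -4 * log(2), alpha1 = 0.2, alpha2 = 0.25,
                            beta1 = 0.1, beta2 = 6, gamma = 0.30,
                            rho = 1.35, phi = 2, nu = 1.42,
                            zeta1 = 0.177, zeta2 = 0.45) {
  v <- c(C_s = C_s, C_d = C_d, lam = lam, g_eff = g_eff, alpha1 = alpha1,
         alpha2 = alpha2, beta1 = beta1, beta2 = beta2, gamma = gamma,
         rho = rho, phi = phi, nu = nu, zeta1 = zeta1, zeta2 = zeta2)
  new("ModelParameters", values = v)
}

#' Reference parameter set
#'
#' A fixed parameter set chosen to place the model in the empirically
#' reported qualitative regime: an isolated spine potentiates rapidly and
#' decays towards a sustained size well above baseline; clustered spines
#' potentiate less at +2 min but hold their size longer; edge spines of
#' large clusters out-potentiate middle spines at late times. These are
#' reference values for simulation studies and synthetic data, not
#' experimentally fitted constants.
#'
#' @return A [ModelParameters-class].
#' @export
referenceParameters <- function() modelParameters()

#' @describeIn modelParameters named numeric vector of the 14 constants.
#' @param object a `ModelParameters`.
#' @export
paramValues <- function(object) object@values

#' Replace a subset of parameter values
#'
#' @param object a [ModelParameters-class].
#' @param ... named scalar replacements, e.g. `updateParameters(p, nu = 1.2)`.
#' @return A [ModelParameters-class].
#' @export
updateParameters <- function(object, ...) {
  repl <- unlist(list(...))
  bad <- setdiff(names(repl), PARAM_NAMES)
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  v <- object@values
  v[names(repl)] <- repl
  new("ModelParameters", values = v)
}

setMethod("show", "ModelParameters", function(object) {
  cat("ModelParameters:\n")
  print(round(object@values, 5))
})
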