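#' Sigmoidal concentration-response families
#'
#' Three two- and three-parameter sigmoid families commonly used to describe
#' quantal mortality data from acute aquatic bioassays, all expressed on the
#' decadic-log concentration scale:
#'
#' \describe{
#'   \item{Weibull}{\eqn{f(x) = 1 - \exp(-\exp(\alpha + \beta \log_{10} x))}}
#'   \item{BCW (Box-Cox-Weibull)}{\eqn{f(x) = 1 - \exp(-\exp(\alpha + \beta
#'     (x^\gamma - 1)/\gamma))}; the concentration enters through a Box-Cox
#'     transform with exponent \eqn{\gamma \ne 0}.}
#'   \item{GL (generalised logit)}{\eqn{f(x) = (1 + \exp(-\alpha - \beta
#'     \log_{10} x))^{-\gamma}} with shape exponent \eqn{\gamma > 0}.}
#' }
#'
#' `crc_evaluate()` computes the effect (mortality) fraction at concentration
#' `x`; `crc_invert()` applies the closed-form inverse, returning the
#' concentration producing effect fraction `Y`.
#'
#' The BCW family with \eqn{\gamma = 0} is rejected rather than silently
#' replaced by its natural-log limit: that limit is a Weibull in \eqn{\ln x},
#' which is a reparameterisation of (not identical to) the decadic-log Weibull
#' family above, so the caller must pick a family explicitly.
#'
#' @param family One of `"Weibull"`, `"BCW"`, `"GL"` (case-insensitive).
#' @param alpha,beta Location and slope parameters; `beta` must be non-zero.
#' @param gamma Shape parameter; required for BCW (non-zero) and GL
#'   (positive), must be omitted/`NULL`/`NA` for Weibull.
#' @param x Concentration(s), mg/L, strictly positive.
#' @param Y Target effect fraction(s), strictly inside (0, 1).
#'
#' @return `crc_evaluate()`: effect fractions in \[0, 1\]; `crc_invert()`:
#'   concentrations in mg/L. Both are vectorised over `x` / `Y`.
#'
#' @examples
#' crc_evaluate("Weibull", -0.4, 1.21, x = 1.07)   # ~0.50
#' crc_invert("GL", -9.44, 8.94, gamma = 0.2, Y = 0.5)  # ~4.7 mg/L
#' @export
crc_evaluate <- function(family, alpha, beta, gamma = NULL, x) {
  family <- match_family(family)
  check_params(family, alpha, beta, gamma)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("concentrations must be finite and > 0", call. = FALSE)
  }
  switch(family,
    Weibull = 1 - exp(-exp(alpha + beta * log10(x))),
    BCW     = 1 - exp(-exp(alpha + beta * (x^gamma - 1) / gamma)),
    GL      = (1 + exp(-alpha - beta * log10(x)))^(-gamma)
  )
}

#' @rdname crc_evaluate
#' @export
crc_invert <- function(family, alpha, beta, gamma = NULL, Y) {
  family <- match_family(family)
  check_params(family, alpha, beta, gamma)
  if (any(!is.finite(Y)) || any(Y <= 0) || any(Y >= 1)) {
    stop("effect fraction Y must lie strictly inside (0, 1)", call. = FALSE)
  }
  switch(family,
    Weibull = 10^((log(-log(1 - Y)) - alpha) / beta),
    BCW = {
      u <- (log(-log(1 - Y)) - alpha) / beta
      arg <- 1 + gamma * u
      if (any(arg <= 0)) {
        stop("BCW inverse has no solution: 1 + gamma * u <= 0", call. = FALSE)
      }
      arg^(1 / gamma)
    },
    GL = 10^((-alpha - log(Y^(-1 / gamma) - 1)) / beta)
  )
}

#' Gradient of a CRC with respect to its parameters
#'
#' Analytic partial derivatives of the effect fraction with respect to
#' (alpha, beta\[, gamma\]), evaluated at concentrations `x`. Used for the
#' Gauss-Newton parameter covariance and the observation confidence band.
#'
#' @inheritParams crc_evaluate
#' @return A matrix with one row per `x` and one column per parameter.
#' @keywords internal
crc_gradient <- function(family, alpha, beta, gamma = NULL, x) {
  family <- match_family(family)
  check_params(family, alpha, beta, gamma)
  stopifnot(all(x > 0))
  if (family == "Weibull") {
    t <- log10(x)
    u <- alpha + beta * t
    e <- exp(-exp(u)) * exp(u)           # d f / d u
    cbind(alpha = e, beta = t * e)
  } else if (family == "BCW") {
    g <- (x^gamma - 1) / gamma
    u <- alpha + beta * g
    e <- exp(-exp(u)) * exp(u)
    dg_dgamma <- (gamma * x^gamma * log(x) - (x^gamma - 1)) / gamma^2
    cbind(alpha = e, beta = g * e, gamma = beta * dg_dgamma * e)
  } else {
    t <- log10(x)
    u <- alpha + beta * t
    q <- 1 + exp(-u)
    base <- gamma * q^(-gamma - 1) * exp(-u) # d f / d u
    cbind(alpha = base, beta = t * base, gamma = -q^(-gamma) * log(q))
  }
}

#' Names of the supported CRC families
#' @return Character vector `c("Weibull", "BCW", "GL")`.
#' @export
crc_families <- function() c("Weibull", "BCW", "GL")

n_params_family <- function(family) if (family == "Weibull") 2L else 3L

match_family <- function(family) {
  if (length(family) != 1L || !is.character(family)) {
    stop("`family` must be a single string", call. = FALSE)
  }
  hit <- match(tolower(family), tolower(crc_families()))
  if (is.na(hit)) {
    stop("unknown CRC family '", family,
         "'; choose one of ", paste(crc_families(), collapse = ", "),
         call. = FALSE)
  }
  crc_families()[hit]
}

check_params <- function(family, alpha, beta, gamma) {
  stopifnot(is.numeric(alpha), is.numeric(beta), length(alpha) == 1L,
            length(beta) == 1L, is.finite(alpha), is.finite(beta))
  if (beta == 0) stop("beta must be non-zero", call. = FALSE)
  has_gamma <- !is.null(gamma) && length(gamma) == 1L && is.finite(gamma)
  if (family == "Weibull") {
    if (has_gamma) stop("Weibull takes no gamma parameter", call. = FALSE)
  } else if (!has_gamma) {
    stop(family, " requires a finite gamma parameter", call. = FALSE)
  } else if (family == "BCW" && gamma == 0) {
    stop("BCW with gamma = 0 is rejected; use the Weibull family explicitly",
         call. = FALSE)
  } else if (family == "GL" && gamma <= 0) {
    stop("GL requires gamma > 0", call. = FALSE)
  }
  invisible(TRUE)
}
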