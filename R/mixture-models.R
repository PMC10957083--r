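#' Concentration-addition (Loewe) mixture effect concentration
#'
#' Under concentration addition the components act as dilutions of one
#' another, so a mixture with mass fractions \eqn{\pi_i} reaches effect
#' fraction p at the total concentration
#' \deqn{LC_p^{mix} = \left(\sum_i \pi_i / LC_{p,i}\right)^{-1},}
#' the fraction-weighted harmonic mean of the component effect
#' concentrations. It always lies between the smallest and largest component
#' LCp.
#'
#' @param fractions Mass fractions summing to 1.
#' @param component_lcps Component effect concentrations (mg/L) at the same
#'   effect level, all > 0.
#' @return Mixture effect concentration, mg/L.
#' @examples
#' ca_effect_concentration(c(0.53, 0.47), c(1.07, 4.7))  # 1.68 mg/L
#' @export
ca_effect_concentration <- function(fractions, component_lcps) {
  stopifnot(length(fractions) == length(component_lcps))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  if (any(component_lcps <= 0)) stop("LCp values must be > 0", call. = FALSE)
  1 / sum(fractions / component_lcps)
}

#' Concentration-addition effect at a given total concentration
#'
#' Solves the Loewe toxic-unit equation
#' \eqn{\sum_i c_i / LC_{Y,i} = 1} for the common effect fraction Y, where
#' \eqn{c_i} are the component concentrations. Requires every component CRC
#' to be invertible (increasing in concentration).
#'
#' @param fits List of `crc_fit` objects, one per component.
#' @param concs Component concentrations (mg/L), same order as `fits`.
#' @return Effect fraction in (0, 1); 0 if all concentrations are 0.
#' @export
ca_effect <- function(fits, concs) {
  stopifnot(length(fits) == length(concs), all(concs >= 0))
  if (all(concs == 0)) return(0)
  tu <- function(Y) {
    sum(vapply(seq_along(fits), function(i) {
      if (concs[i] == 0) return(0)
      f <- fits[[i]]
      concs[i] / crc_invert(f$family, f$alpha, f$beta, f$gamma, Y)
    }, numeric(1))) - 1
  }
  eps <- 1e-9
  # toxic units decrease in Y; no root inside (eps, 1-eps) means the effect
  # is pinned at (numerically) 0 or 1
  if (tu(eps) < 0) return(0)
  if (tu(1 - eps) > 0) return(1)
  stats::uniroot(tu, c(eps, 1 - eps), tol = 1e-12)$root
}

#' Independent-action mixture effect
#'
#' Response addition: components act through unrelated mechanisms, so the
#' probability of surviving the mixture is the product of the single-agent
#' survival probabilities, \eqn{E = 1 - \prod_i (1 - f_i(c_i))}.
#'
#' @param fits List of `crc_fit` objects, one per component.
#' @param concs Component concentrations (mg/L), >= 0; a zero concentration
#'   contributes zero effect.
#' @return Effect fraction; at least the maximum single-component effect and
#'   at most 1.
#' @export
ia_effect <- function(fits, concs) {
  if (length(fits) != length(concs)) {
    stop("fits and concs must have the same length", call. = FALSE)
  }
  if (any(concs < 0)) stop("concentrations must be >= 0", call. = FALSE)
  fi <- vapply(seq_along(fits), function(i) {
    if (concs[i] == 0) return(0)
    f <- fits[[i]]
    crc_evaluate(f$family, f$alpha, f$beta, f$gamma, concs[i])
  }, numeric(1))
  1 - prod(1 - fi)
}

#' Independent-action mixture effect concentration
#'
#' Total concentration along a ray at which the independent-action effect
#' reaches `p`, found by root search on the log-concentration scale (unique
#' when every component CRC is increasing).
#'
#' @param ray A [mixture_ray()] (only its fractions are used).
#' @param fits List of `crc_fit` objects matching the ray's components.
#' @param p Target effect fraction in (0, 1).
#' @param interval Search interval for the total concentration, mg/L.
#' @return Mixture LCp, mg/L.
#' @export
ia_effect_concentration <- function(ray, fits, p,
                                    interval = c(1e-8, 1e6)) {
  stopifnot(inherits(ray, "mixture_ray"))
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)", call. = FALSE)
  g <- function(logT) {
    ia_effect(fits, exp(logT) * ray$fractions) - p
  }
  lo <- log(interval[1]); hi <- log(interval[2])
  if (g(lo) > 0 || g(hi) < 0) {
    stop("independent-action effect does not cross p = ", p,
         " inside the search interval", call. = FALSE)
  }
  exp(stats::uniroot(g, c(lo, hi), tol = 1e-12)$root)
}

#' Synergistic-ratio interaction classification
#'
#' The synergistic ratio SR compares a component's single-agent LC50
#' (\eqn{C_i}) with the mixture LC50 (\eqn{E_i}): \eqn{SR = C_i / E_i}. An
#' SR above 1 means the mixture kills at lower total concentration than the
#' component alone (synergism); below 1, antagonism; equal to 1, simple
#' additivity. `epsilon` sets the half-width of the additive band around 1
#' (`epsilon = 0` reproduces the strict equal-to-1 rule).
#'
#' @param single_lc50 Single-agent LC50, mg/L.
#' @param mixture_lc50 Mixture LC50, mg/L.
#' @param component_id Optional component name carried into the result.
#' @param epsilon Additivity tolerance on SR (default 0.05).
#' @return Object of class `interaction_result`: list with `component_id`,
#'   `single_lc50`, `mixture_lc50`, `sr`, `label`.
#' @examples
#' synergistic_ratio(1.07, 0.74)$sr   # 1.45 -> synergistic
#' synergistic_ratio(1.07, 1.48)$sr   # 0.72 -> antagonistic
#' @export
synergistic_ratio <- function(single_lc50, mixture_lc50,
                              component_id = NA_character_, epsilon = 0.05) {
  if (single_lc50 <= 0 || mixture_lc50 <= 0) {
    stop("LC50 values must be > 0", call. = FALSE)
  }
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  sr <- single_lc50 / mixture_lc50
  label <- if (abs(sr - 1) <= epsilon) "additive"
           else if (sr > 1) "synergistic" else "antagonistic"
  structure(
    list(component_id = component_id, single_lc50 = single_lc50,
         mixture_lc50 = mixture_lc50, sr = sr, label = label),
    class = "interaction_result"
  )
}

#' @exportS3Method print interaction_result
print.interaction_result <- function(x, ...) {
  id <- if (is.na(x$component_id)) "" else paste0("(", x$component_id, ") ")
  cat(sprintf("SR %s= %.3f (%s): single LC50 %.4g, mixture LC50 %.4g mg/L\n",
              id, x$sr, x$label, x$single_lc50, x$mixture_lc50))
  invisible(x)
}

#' Compare mixture-model predictions against observed effects
#'
#' Scores each candidate model's predicted effect fractions against the
#' observed ones with [fit_metrics()] and ranks models by R-squared.
#'
#' @param observed Numeric vector of observed effect fractions (>= 3).
#' @param predictions Named list of numeric vectors, one per model, each the
#'   same length as `observed`.
#' @return data.frame with one row per model: `model`, `r2`, `mse`, `mae`,
#'   ordered by decreasing `r2`.
#' @export
compare_models <- function(observed, predictions) {
  if (length(observed) < 3) stop("need >= 3 observation points", call. = FALSE)
  stopifnot(is.list(predictions), length(predictions) >= 1,
            !is.null(names(predictions)))
  rows <- lapply(names(predictions), function(nm) {
    q <- fit_metrics(observed, predictions[[nm]])
    data.frame(model = nm, r2 = q$r2, mse = q$mse, mae = q$mae)
  })
  out <- do.call(rbind, rows)
  out[order(-out$r2), , drop = FALSE]
}
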