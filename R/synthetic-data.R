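#' Specify a true concentration-response curve
#'
#' Lightweight curve specification used as simulation truth (and accepted
#' anywhere a fitted `crc_fit` is, by [ca_effect()], [ia_effect()] and the
#' simulators).
#'
#' @inheritParams crc_evaluate
#' @return List with elements `family`, `alpha`, `beta`, `gamma`.
#' @examples
#' cr96 <- crc_params("Weibull", -0.4, 1.21)
#' crc_evaluate(cr96$family, cr96$alpha, cr96$beta, x = 1.07)
#' @export
crc_params <- function(family, alpha, beta, gamma = NULL) {
  family <- match_family(family)
  check_params(family, alpha, beta, gamma)
  list(family = family, alpha = alpha, beta = beta, gamma = gamma)
}

curve_effect <- function(curve, x) {
  if (x == 0) return(0)
  crc_evaluate(curve$family, curve$alpha, curve$beta, curve$gamma, x)
}

#' Simulate a single-toxicant mortality experiment
#'
#' Draws binomial deaths per concentration and replicate from a known true
#' CRC, reproducing the structure of a static acute bioassay: groups of
#' `n_exposed` animals, `replicates` independent replicate groups per
#' concentration, deaths counted at one census time. Defaults (10 animals,
#' 3 replicates, 5 concentration levels in the shipped designs) match common
#' acute-toxicity practice for small crustaceans.
#'
#' @param curve True CRC from [crc_params()] (or a fitted `crc_fit`).
#' @param concentrations Exposure concentrations, mg/L, all > 0.
#' @param time_h Census time in hours (recorded, not modelled).
#' @param n_exposed Animals per group.
#' @param replicates Replicate groups per concentration.
#' @param seed Integer seed; the same (arguments, seed) pair always yields
#'   identical records.
#' @param component Component name recorded in the output.
#' @return Flat mortality records: data.frame with columns `component_a`,
#'   `component_b` (NA), `conc_a_mg_L`, `conc_b_mg_L` (NA), `time_h`,
#'   `n_exposed`, `n_dead`, `replicate`.
#' @examples
#' simulate_single(crc_params("Weibull", -0.4, 1.21),
#'                 c(0.2, 0.59, 1.73, 5.1, 15), seed = 1)
#' @export
simulate_single <- function(curve, concentrations, time_h = 96,
                            n_exposed = 10, replicates = 3, seed = 1,
                            component = "A") {
  stopifnot(n_exposed >= 1, replicates >= 1)
  if (any(concentrations <= 0)) {
    stop("concentrations must be > 0", call. = FALSE)
  }
  p <- vapply(concentrations, function(x) curve_effect(curve, x), numeric(1))
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates),
                      level = seq_along(concentrations))
  data.frame(
    component_a = component, component_b = NA_character_,
    conc_a_mg_L = concentrations[grid$level], conc_b_mg_L = NA_real_,
    time_h = time_h, n_exposed = as.integer(n_exposed),
    n_dead = stats::rbinom(nrow(grid), n_exposed, p[grid$level]),
    replicate = grid$replicate
  )
}

#' Simulate a binary-mixture mortality experiment along a ray
#'
#' For every dilution level of a fixed-ratio ray, computes the true mixture
#' effect under the chosen null model — concentration addition
#' ([ca_effect()]) or independent action ([ia_effect()]) — from the two
#' components' true CRCs, then draws binomial deaths per replicate.
#'
#' @param ray A [mixture_ray()] with a filled dilution series
#'   (see [frrd_series()]).
#' @param curves List of two true CRCs ([crc_params()] or `crc_fit`),
#'   matching the ray's components.
#' @param truth_model `"CA"` or `"IA"`.
#' @inheritParams simulate_single
#' @return Flat mortality records with both concentration columns filled.
#' @export
simulate_mixture <- function(ray, curves, truth_model = c("CA", "IA"),
                             time_h = 96, n_exposed = 10, replicates = 3,
                             seed = 1) {
  stopifnot(inherits(ray, "mixture_ray"), length(curves) == 2L,
            n_exposed >= 1, replicates >= 1)
  truth_model <- match.arg(truth_model)
  if (!length(ray$series)) {
    stop("ray has no dilution series; apply frrd_series()", call. = FALSE)
  }
  p <- vapply(ray$series, function(total) {
    concs <- total * ray$fractions
    if (truth_model == "CA") ca_effect(curves, concs)
    else ia_effect(curves, concs)
  }, numeric(1))
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates),
                      level = seq_along(ray$series))
  total <- ray$series[grid$level]
  data.frame(
    component_a = ray$component_ids[1], component_b = ray$component_ids[2],
    conc_a_mg_L = total * ray$fractions[1],
    conc_b_mg_L = total * ray$fractions[2],
    time_h = time_h, n_exposed = as.integer(n_exposed),
    n_dead = stats::rbinom(nrow(grid), n_exposed, p[grid$level]),
    replicate = grid$replicate
  )
}
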