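#' Binary mixture rays
#'
#' A mixture ray is a fixed mass-fraction ratio of two components together
#' with (optionally) a dilution series of total concentrations. Rays are the
#' unit of the fixed-ratio ray design (FRRD): every exposure level on a ray
#' shares the same component ratio.
#'
#' @param component_ids Character vector of two component names.
#' @param amounts Component amounts (mg/L) defining the ratio; the ray's
#'   fractions are `amounts / sum(amounts)` and its defining top
#'   concentration is `sum(amounts)`.
#' @param design Label, e.g. `"EECR 50"` or `"EquRay 3"`.
#' @return An object of class `mixture_ray`: list with `component_ids`,
#'   `fractions`, `design`, `top` and `series` (empty until
#'   [frrd_series()] is applied).
#' @export
mixture_ray <- function(component_ids, amounts, design = "ray") {
  stopifnot(length(component_ids) == 2L, length(amounts) == 2L)
  if (any(!is.finite(amounts)) || any(amounts <= 0)) {
    stop("component amounts must be finite and > 0", call. = FALSE)
  }
  structure(
    list(component_ids = as.character(component_ids),
         fractions = amounts / sum(amounts),
         design = design,
         top = sum(amounts),
         series = numeric(0)),
    class = "mixture_ray"
  )
}

#' @exportS3Method print mixture_ray
print.mixture_ray <- function(x, ...) {
  cat(sprintf("%s: %s %.3f : %s %.3f (top %.4g mg/L, %d levels)\n",
              x$design, x$component_ids[1], x$fractions[1],
              x$component_ids[2], x$fractions[2], x$top, length(x$series)))
  invisible(x)
}

#' Equi-effect concentration ratio (EECR) ray
#'
#' Mixes two components in proportion to a common effect concentration: for
#' the "EECR 50" ray each component contributes its own LC50, so the mass
#' fractions are `lcp / (lcp_a + lcp_b)` and the defining top concentration
#' of the dilution series is the sum of the two LCp values.
#'
#' @param lcp_a,lcp_b Effect concentrations (mg/L) of the two components at
#'   the common effect level (e.g. both LC50s).
#' @param label Design label, default `"EECR 50"`.
#' @param component_ids Component names.
#' @return A [mixture_ray()].
#' @examples
#' eecr_ray(0.03, 0.59, "EECR 10")$fractions  # 0.048, 0.952
#' @export
eecr_ray <- function(lcp_a, lcp_b, label = "EECR 50",
                     component_ids = c("A", "B")) {
  mixture_ray(component_ids, c(lcp_a, lcp_b), design = label)
}

#' Direct equipartition (EquRay) rays
#'
#' Places `n_rays` equidistant points on the segment joining the two
#' components' LC50 intercepts on the concentration axes. Ray `i` (1-based)
#' combines `(n_rays + 1 - i)/(n_rays + 1)` of component a's LC50 with
#' `i/(n_rays + 1)` of component b's LC50, so successive rays shift mass from
#' component a to component b. With `index_from_text = TRUE` the indexing is
#' reversed (ray i takes `i/(n+1)` of component a), the alternative
#' convention sometimes used when rays are numbered from the a-axis.
#'
#' @param lc50_a,lc50_b Component LC50s in mg/L.
#' @param n_rays Number of rays (default 5).
#' @param component_ids Component names.
#' @param index_from_text Reverse the ray indexing (see Details).
#' @return List of [mixture_ray()] objects labelled `"EquRay 1"`, ...
#' @examples
#' rays <- equray_rays(1.07, 4.7, component_ids = c("Cr", "Ni"))
#' sapply(rays, function(r) round(r$fractions[1], 2))  # 0.53 0.31 0.19 0.10 0.04
#' @export
equray_rays <- function(lc50_a, lc50_b, n_rays = 5,
                        component_ids = c("A", "B"),
                        index_from_text = FALSE) {
  if (lc50_a <= 0 || lc50_b <= 0) stop("LC50s must be > 0", call. = FALSE)
  if (n_rays < 1) stop("n_rays must be >= 1", call. = FALSE)
  lapply(seq_len(n_rays), function(i) {
    k <- if (index_from_text) n_rays + 1 - i else i
    wa <- (n_rays + 1 - k) / (n_rays + 1)
    wb <- k / (n_rays + 1)
    mixture_ray(component_ids, c(wa * lc50_a, wb * lc50_b),
                design = paste("EquRay", i))
  })
}

#' Fill a ray's fixed-ratio dilution series
#'
#' Serial dilution from the ray's top total concentration, keeping the
#' component ratio constant: level `k` (0-based) has total concentration
#' `top / dilution_factor^k`.
#'
#' @param ray A [mixture_ray()].
#' @param n_levels Number of dilution levels (default 12).
#' @param dilution_factor Factor between successive levels, > 1 (default 2).
#' @param top Override for the top total concentration; defaults to the
#'   ray's defining sum.
#' @return The ray with `series` filled (strictly decreasing totals).
#' @examples
#' r <- frrd_series(eecr_ray(1.07, 4.7), n_levels = 12)
#' range(r$series)
#' @export
frrd_series <- function(ray, n_levels = 12, dilution_factor = 2, top = NULL) {
  stopifnot(inherits(ray, "mixture_ray"))
  if (n_levels < 2) stop("n_levels must be >= 2", call. = FALSE)
  if (!is.finite(dilution_factor) || dilution_factor <= 1) {
    stop("dilution_factor must be > 1", call. = FALSE)
  }
  if (!is.null(top)) ray$top <- top
  ray$series <- ray$top / dilution_factor^(seq_len(n_levels) - 1)
  ray
}

#' Per-level component concentrations of a ray
#'
#' @param ray A [mixture_ray()] with a filled series.
#' @return data.frame with columns `level`, `total`, and one column per
#'   component (named by `component_ids`), in mg/L.
#' @export
ray_concentrations <- function(ray) {
  stopifnot(inherits(ray, "mixture_ray"))
  if (!length(ray$series)) stop("ray has no dilution series; apply frrd_series()",
                                call. = FALSE)
  out <- data.frame(level = seq_along(ray$series), total = ray$series,
                    a = ray$series * ray$fractions[1],
                    b = ray$series * ray$fractions[2])
  names(out)[3:4] <- ray$component_ids
  out
}
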