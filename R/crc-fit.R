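#' Goodness-of-fit metrics for effect fractions
#'
#' Coefficient of determination, mean squared error and mean absolute error
#' between observed and predicted effect fractions:
#' \deqn{R^2 = 1 - \sum (y_i - \hat y_i)^2 / \sum (y_i - \bar y)^2, \quad
#'       MSE = \frac{1}{n}\sum (y_i - \hat y_i)^2, \quad
#'       MAE = \frac{1}{n}\sum |y_i - \hat y_i|.}
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return An object of class `fit_quality`: a list with elements `r2`,
#'   `mse`, `mae`.
#' @examples
#' fit_metrics(c(0.2, 0.5, 0.9), c(0.25, 0.45, 0.9))
#' @export
fit_metrics <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted))
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have the same length", call. = FALSE)
  }
  if (length(observed) < 2L) stop("need at least 2 points", call. = FALSE)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    stop("R-squared undefined: observed values are all identical",
         call. = FALSE)
  }
  sse <- sum((observed - predicted)^2)
  structure(
    list(r2 = 1 - sse / sst,
         mse = sse / length(observed),
         mae = mean(abs(observed - predicted))),
    class = "fit_quality"
  )
}

#' @exportS3Method print fit_quality
print.fit_quality <- function(x, ...) {
  cat(sprintf("R2 = %.4f, MSE = %.5f, MAE = %.4f\n", x$r2, x$mse, x$mae))
  invisible(x)
}

# Pool mortality records to one (conc, mortality) row per concentration.
# Accepts either the flat record schema (see read_mortality_csv) or a
# ready-made data.frame with columns conc and mortality. Replicates are
# pooled by the mean of their mortality proportions.
pool_mortality <- function(records) {
  stopifnot(is.data.frame(records))
  if (all(c("conc", "mortality") %in% names(records))) {
    d <- records[, c("conc", "mortality")]
  } else if (all(c("conc_a_mg_L", "n_exposed", "n_dead") %in% names(records))) {
    cb <- if ("conc_b_mg_L" %in% names(records)) {
      ifelse(is.na(records$conc_b_mg_L), 0, records$conc_b_mg_L)
    } else 0
    d <- data.frame(conc = records$conc_a_mg_L + cb,
                    mortality = records$n_dead / records$n_exposed)
  } else {
    stop("records must have columns (conc, mortality) or the flat schema ",
         "(conc_a_mg_L[, conc_b_mg_L], n_exposed, n_dead)", call. = FALSE)
  }
  out <- stats::aggregate(mortality ~ conc, data = d, FUN = mean)
  out[order(out$conc), , drop = FALSE]
}

# Box-Cox transform robust near gamma = 0 (used only inside the optimiser;
# the BCW family itself requires gamma != 0).
boxcox_tr <- function(x, gamma) {
  if (abs(gamma) < 1e-10) log(x) else expm1(gamma * log(x)) / gamma
}

crc_predict_raw <- function(family, par, x) {
  # par on the optimiser scale: GL gamma is log-parameterised to stay > 0
  if (family == "Weibull") {
    1 - exp(-exp(par[1] + par[2] * log10(x)))
  } else if (family == "BCW") {
    1 - exp(-exp(par[1] + par[2] * boxcox_tr(x, par[3])))
  } else {
    (1 + exp(-par[1] - par[2] * log10(x)))^(-exp(par[3]))
  }
}

# Plausible parameter box (optimiser scale; GL gamma is log-parameterised).
# Mortality profiles observable on a 5-12 level design cannot support slopes
# steeper than beta ~ 12 on the log10 scale; without the box the
# three-parameter families drift to near-step curves that win on raw R2 but
# are biologically meaningless.
crc_bounds <- function(family) {
  if (family == "Weibull") {
    list(lower = c(-12, 0.5), upper = c(2, 12))
  } else if (family == "BCW") {
    list(lower = c(-12, 0.5, -0.5), upper = c(2, 12, 0.5))
  } else {
    list(lower = c(-12, 0.5, log(0.05)), upper = c(2, 12, log(2)))
  }
}

crc_starts <- function(family, x, y) {
  # coarse multi-start grid; BCW and GL respond badly to single starts
  alphas <- seq(-12, 2, length.out = 8)
  betas <- seq(0.5, 12, length.out = 8)
  grid <- expand.grid(alpha = alphas, beta = betas)
  # linearised starts from the complementary log-log / logit transform
  yc <- pmin(pmax(y, 0.005), 0.995)
  t10 <- log10(x)
  cll <- stats::coef(stats::lm(log(-log(1 - yc)) ~ t10))
  lgt <- stats::coef(stats::lm(log(yc / (1 - yc)) ~ t10))
  if (family == "Weibull") {
    starts <- rbind(as.matrix(grid), unname(cll))
  } else if (family == "BCW") {
    gammas <- c(-0.5, -0.25, -0.05, 0.05, 0.25, 0.5)
    starts <- as.matrix(merge(grid, data.frame(gamma = gammas)))
    starts <- rbind(starts, c(unname(cll), 0.05), c(unname(cll), -0.05))
  } else {
    log_gammas <- log(c(0.05, 0.2, 0.5, 1, 2))
    starts <- as.matrix(merge(grid, data.frame(lgamma = log_gammas)))
    starts <- rbind(starts, c(unname(lgt), 0))
  }
  starts
}

#' Fit a sigmoidal concentration-response curve
#'
#' Least-squares fit of one CRC family to mortality records. Replicates are
#' pooled to a mean mortality proportion per concentration and the sum of
#' squared residuals between pooled proportions and the curve is minimised by
#' Levenberg-Marquardt iterations started from a coarse parameter grid (the
#' BCW and GL families are ill-conditioned, so the best of many starts is
#' kept). Parameters are constrained to a plausible box
#' (\eqn{\alpha \in [-12, 2]}, \eqn{\beta \in [0.5, 12]},
#' \eqn{\gamma \in [-0.5, 0.5]} for BCW and \eqn{[0.05, 2]} for GL); an
#' optimum pinned to the box edge is flagged `on_boundary`, since such
#' solutions are near-step curves with no biological interpretation. The
#' parameter covariance is the Gauss-Newton approximation
#' \eqn{s^2 (J^T J)^{-1}} with \eqn{s^2 = SSR/(n - m)}, where `n` is the
#' number of distinct concentrations and `m` the number of parameters.
#'
#' @param records Mortality records: either the flat schema produced by
#'   [read_mortality_csv()] / [simulate_single()], or a data.frame with
#'   columns `conc` (mg/L) and `mortality` (fraction).
#' @param family CRC family name; see [crc_families()].
#' @return An object of class `crc_fit` with components `family`, `alpha`,
#'   `beta`, `gamma` (`NULL` for Weibull), `param_cov`, `resid_var`,
#'   `n_points`, `n_params`, `data`, `fitted` and `quality`
#'   (a [fit_metrics()] result).
#' @examples
#' d <- data.frame(conc = c(0.2, 0.59, 1.73, 5.1, 15),
#'                 mortality = c(0.23, 0.47, 0.53, 0.77, 1.00))
#' fit <- fit_crc(d, "Weibull")
#' fit$quality$r2
#' @seealso [select_best_family()], [effect_concentration()],
#'   [observation_band()]
#' @export
fit_crc <- function(records, family) {
  family <- match_family(family)
  d <- pool_mortality(records)
  x <- d$conc
  y <- d$mortality
  if (any(x <= 0)) stop("all concentrations must be > 0", call. = FALSE)
  m <- n_params_family(family)
  n <- length(x)
  if (n < m + 1L) {
    stop("need at least ", m + 1L, " distinct concentrations to fit ",
         family, call. = FALSE)
  }
  if (all(y == 0) || all(y == 1)) {
    stop("degenerate data: mortality is identically ",
         if (all(y == 0)) "0" else "1", call. = FALSE)
  }

  starts <- crc_starts(family, x, y)
  bounds <- crc_bounds(family)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(as.numeric(starts[i, ]), bounds$lower), bounds$upper)
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, lower = bounds$lower, upper = bounds$upper,
        fn = function(p) y - crc_predict_raw(family, p, x),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    ssr <- sum(res$fvec^2)
    if (!is.finite(ssr)) next
    if (is.null(best) || ssr < best$ssr) best <- list(ssr = ssr, par = res$par)
  }
  if (is.null(best)) {
    stop("CRC fit failed for family ", family,
         ": no start converged", call. = FALSE)
  }

  par <- best$par
  on_boundary <- any(par - bounds$lower < 1e-4) ||
    any(bounds$upper - par < 1e-4)
  alpha <- par[1]; beta <- par[2]
  gamma <- if (family == "Weibull") NULL
           else if (family == "BCW") par[3] else exp(par[3])
  if (family == "BCW" && abs(gamma) < 1e-10) {
    stop("BCW fit collapsed to gamma = 0; refit with the Weibull family",
         call. = FALSE)
  }
  fitted <- crc_evaluate(family, alpha, beta, gamma, x)
  ssr <- sum((y - fitted)^2)
  s2 <- ssr / (n - m)
  J <- crc_gradient(family, alpha, beta, gamma, x)
  JtJ <- crossprod(J)
  Cmat <- tryCatch(s2 * solve(JtJ), error = function(e) s2 * MASS::ginv(JtJ))
  Cmat <- (Cmat + t(Cmat)) / 2
  dimnames(Cmat) <- list(colnames(J), colnames(J))

  structure(
    list(family = family, alpha = alpha, beta = beta, gamma = gamma,
         param_cov = Cmat, resid_var = s2, n_points = n, n_params = m,
         data = d, fitted = fitted, on_boundary = on_boundary,
         quality = fit_metrics(y, fitted)),
    class = "crc_fit"
  )
}

#' @exportS3Method print crc_fit
print.crc_fit <- function(x, ...) {
  g <- if (is.null(x$gamma)) "" else sprintf(", gamma = %.4g", x$gamma)
  cat(sprintf("%s CRC fit: alpha = %.4g, beta = %.4g%s\n",
              x$family, x$alpha, x$beta, g))
  cat(sprintf("  n = %d concentrations, ", x$n_points))
  print(x$quality)
  invisible(x)
}

#' @export
predict.crc_fit <- function(object, newdata, ...) {
  conc <- if (is.data.frame(newdata)) newdata$conc else newdata
  crc_evaluate(object$family, object$alpha, object$beta, object$gamma, conc)
}

#' Fit all CRC families and keep the best
#'
#' Fits every requested family with [fit_crc()] and returns the fit with the
#' highest R-squared. Fits whose optimum sits on the plausible-parameter box
#' (see [fit_crc()]) are excluded whenever at least one family converged to
#' an interior optimum. Fits whose R-squared values are within `tie_tol` of
#' the best are treated as ties, resolved in favour of fewer parameters and
#' then lower MSE, so a two-parameter Weibull is preferred over a
#' three-parameter family that matches it only by using its extra degree of
#' freedom.
#'
#' @inheritParams fit_crc
#' @param families Character vector of families to try.
#' @param tie_tol R-squared difference below which two fits count as tied.
#' @return The winning `crc_fit`; the full set is attached as
#'   `attr(, "candidates")`.
#' @export
select_best_family <- function(records, families = crc_families(),
                               tie_tol = 1e-4) {
  fits <- list(); errs <- character()
  for (fam in families) {
    f <- tryCatch(fit_crc(records, fam), error = function(e) e)
    if (inherits(f, "error")) errs[fam] <- conditionMessage(f)
    else fits[[fam]] <- f
  }
  if (!length(fits)) {
    stop("all CRC families failed to fit: ",
         paste(sprintf("%s (%s)", names(errs), errs), collapse = "; "),
         call. = FALSE)
  }
  # prefer fits whose optimum is interior to the plausible parameter box;
  # boundary-pinned optima are degenerate near-step curves
  interior <- !vapply(fits, function(f) isTRUE(f$on_boundary), logical(1))
  candidates <- fits
  if (any(interior)) fits <- fits[interior]
  r2 <- vapply(fits, function(f) f$quality$r2, numeric(1))
  tied <- which(r2 >= max(r2) - tie_tol)
  ord <- order(vapply(fits[tied], function(f) f$n_params, integer(1)),
               vapply(fits[tied], function(f) f$quality$mse, numeric(1)))
  best <- fits[[tied[ord[1]]]]
  attr(best, "candidates") <- candidates
  best
}

#' Observation confidence band around a fitted CRC
#'
#' Pointwise band combining residual variance with parameter-estimation
#' uncertainty:
#' \deqn{\hat y \pm t_{n-m,\,(1-\mathrm{level})/2} \sqrt{s^2 + v C v^T},}
#' where \eqn{v} is the gradient of the curve with respect to its parameters
#' at each concentration and \eqn{C} the parameter covariance. Because the
#' residual term \eqn{s^2} is included, this is a band for a new observed
#' mortality proportion, not just for the mean curve.
#'
#' @param fit A `crc_fit`.
#' @param xs Concentrations (mg/L) at which to evaluate the band.
#' @param level Confidence level, default 0.95.
#' @return data.frame with columns `conc`, `fit`, `lower`, `upper`.
#' @export
observation_band <- function(fit, xs, level = 0.95) {
  stopifnot(inherits(fit, "crc_fit"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  if (any(xs <= 0)) stop("concentrations must be > 0", call. = FALSE)
  df <- fit$n_points - fit$n_params
  if (df <= 0) stop("no residual degrees of freedom (n <= m)", call. = FALSE)
  yhat <- predict(fit, xs)
  v <- crc_gradient(fit$family, fit$alpha, fit$beta, fit$gamma, xs)
  half <- stats::qt(1 - (1 - level) / 2, df) *
    sqrt(fit$resid_var + rowSums((v %*% fit$param_cov) * v))
  data.frame(conc = xs, fit = yhat, lower = yhat - half, upper = yhat + half)
}
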