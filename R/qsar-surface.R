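#' Feature table for mixture-mortality regression
#'
#' Builds the composition feature matrix used by the regression surrogate:
#' per exposure group the two component concentrations, their total, and the
#' mass fraction of the first component, with the mortality proportion as
#' response. These are the only descriptors a composition-only mixture
#' dataset contains.
#'
#' @param records Mixture mortality records in the flat schema (both
#'   `conc_a_mg_L` and `conc_b_mg_L` present and non-missing).
#' @return data.frame with columns `conc_a`, `conc_b`, `total`,
#'   `fraction_a`, `mortality`, in the input row order.
#' @export
build_feature_table <- function(records) {
  need <- c("conc_a_mg_L", "conc_b_mg_L", "n_exposed", "n_dead")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(records$conc_a_mg_L)) || any(is.na(records$conc_b_mg_L))) {
    stop("mixture records must have both component concentrations",
         call. = FALSE)
  }
  total <- records$conc_a_mg_L + records$conc_b_mg_L
  if (any(total <= 0)) stop("total concentration must be > 0", call. = FALSE)
  data.frame(conc_a = records$conc_a_mg_L,
             conc_b = records$conc_b_mg_L,
             total = total,
             fraction_a = records$conc_a_mg_L / total,
             mortality = records$n_dead / records$n_exposed)
}

surface_families <- function() c("ridge", "xgboost", "mlp", "mlr")

fit_one_surface <- function(family, xtr, ytr, seed) {
  set.seed(seed)
  if (family == "ridge") {
    nf <- max(3L, min(10L, nrow(xtr)))
    cv <- glmnet::cv.glmnet(xtr, ytr, alpha = 0, nfolds = nf, grouped = FALSE)
    list(predict = function(x) as.numeric(stats::predict(cv, x, s = "lambda.min")))
  } else if (family == "xgboost") {
    bst <- xgboost::xgboost(xtr, ytr, nrounds = 200, max_depth = 3,
                            learning_rate = 0.1, nthreads = 1, verbosity = 0)
    list(predict = function(x) as.numeric(stats::predict(bst, x)))
  } else if (family == "mlp") {
    xm <- colMeans(xtr); xs <- pmax(apply(xtr, 2, stats::sd), 1e-8)
    scl <- function(x) sweep(sweep(x, 2, xm), 2, xs, "/")
    net <- nnet::nnet(scl(xtr), ytr, size = 32, linout = TRUE, decay = 1e-3,
                      maxit = 1000, trace = FALSE, MaxNWts = 5000)
    list(predict = function(x) as.numeric(stats::predict(net, scl(x))))
  } else if (family == "mlr") {
    d <- as.data.frame(xtr); d$.y <- ytr
    fm <- stats::lm(.y ~ ., data = d)
    list(predict = function(x) as.numeric(stats::predict(fm, as.data.frame(x))))
  } else {
    stop("unknown surface family '", family, "'", call. = FALSE)
  }
}

#' Fit regression surrogates of the mixture mortality surface
#'
#' Fits up to four model families — ridge regression (penalty by internal
#' cross-validation), gradient-boosted trees (200 rounds, depth 3, learning
#' rate 0.1), a single-hidden-layer perceptron (32 units, standardised
#' inputs) and ordinary multilinear regression — on a seeded random
#' train/test split of the feature table, scores each on the held-out rows,
#' and marks the family with the highest test R-squared as selected. A family
#' that fails to converge is reported as failed and the others proceed.
#'
#' @param features data.frame of numeric predictors (e.g. from
#'   [build_feature_table()], without the `mortality` column).
#' @param response Numeric response vector (mortality fractions).
#' @param families Subset of `c("ridge", "xgboost", "mlp", "mlr")`.
#' @param split_ratio Fraction of rows used for training (default 0.8).
#' @param seed Integer seed controlling the split and every stochastic
#'   fitter.
#' @return Object of class `surface_fit`: list with `report` (data.frame of
#'   per-family train/test R-squared and MSE plus a `selected` flag),
#'   `models` (named list of prediction closures), `selected` (name of the
#'   winning family), `train_index`, `feature_names` and `feature_ranges`.
#' @export
fit_surface <- function(features, response,
                        families = surface_families(),
                        split_ratio = 0.8, seed = 1) {
  features <- as.data.frame(features)
  if ("mortality" %in% names(features) && missing(response)) {
    response <- features$mortality
    features$mortality <- NULL
  }
  x <- as.matrix(features)
  stopifnot(is.numeric(x), nrow(x) == length(response))
  if (nrow(x) < 10) stop("need at least 10 rows", call. = FALSE)
  if (stats::sd(response) == 0) {
    stop("degenerate response: all values identical", call. = FALSE)
  }
  families <- match.arg(families, surface_families(), several.ok = TRUE)
  n <- nrow(x)
  n_train <- round(split_ratio * n)
  if (n - n_train < 2) stop("split leaves fewer than 2 test rows", call. = FALSE)
  set.seed(seed)
  train_index <- sort(sample.int(n, n_train))
  xtr <- x[train_index, , drop = FALSE]; ytr <- response[train_index]
  xte <- x[-train_index, , drop = FALSE]; yte <- response[-train_index]
  if (stats::sd(yte) == 0 || stats::sd(ytr) == 0) {
    stop("degenerate split: constant response in train or test set",
         call. = FALSE)
  }

  models <- list(); rows <- list()
  for (fam in families) {
    fit <- tryCatch(fit_one_surface(fam, xtr, ytr, seed),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[fam]] <- data.frame(family = fam, failed = TRUE,
                                train_r2 = NA, train_mse = NA,
                                test_r2 = NA, test_mse = NA)
      next
    }
    qtr <- fit_metrics(ytr, fit$predict(xtr))
    qte <- fit_metrics(yte, fit$predict(xte))
    models[[fam]] <- fit
    rows[[fam]] <- data.frame(family = fam, failed = FALSE,
                              train_r2 = qtr$r2, train_mse = qtr$mse,
                              test_r2 = qte$r2, test_mse = qte$mse)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!length(models)) stop("every surface family failed", call. = FALSE)
  ok <- !report$failed
  selected <- report$family[ok][which.max(report$test_r2[ok])]
  report$selected <- report$family == selected

  structure(
    list(report = report, models = models, selected = selected,
         split_ratio = split_ratio, seed = seed, train_index = train_index,
         feature_names = colnames(x),
         feature_ranges = apply(x, 2, range)),
    class = "surface_fit"
  )
}

#' @exportS3Method print surface_fit
print.surface_fit <- function(x, ...) {
  cat("Mixture-mortality regression surrogate (seed", x$seed, ")\n")
  print(x$report, digits = 4)
  invisible(x)
}

#' Predict mortality from a fitted surrogate
#'
#' @param object A `surface_fit`.
#' @param newdata data.frame/matrix with the training feature columns.
#' @param family Model family to use; defaults to the selected one.
#' @param ... Unused.
#' @export
predict.surface_fit <- function(object, newdata, family = object$selected,
                                ...) {
  if (!family %in% names(object$models)) {
    stop("family '", family, "' was not fitted successfully", call. = FALSE)
  }
  x <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  object$models[[family]]$predict(x)
}

#' Effect concentration from the regression surrogate
#'
#' Predicts mortality along a fixed-ratio ray over a log-spaced grid of
#' total concentrations, monotonises the prediction by a running maximum
#' (tree ensembles produce stepwise, occasionally non-monotone curves), and
#' interpolates the first crossing of the target effect fraction.
#'
#' @param object A `surface_fit`.
#' @param fractions Two mass fractions of the ray (sum to 1).
#' @param p Target effect fraction in (0, 1).
#' @param t_range Total-concentration search range, mg/L; defaults to the
#'   range of `total` seen in training.
#' @param n_grid Grid resolution (default 400).
#' @param family Model family; defaults to the selected one.
#' @return Mixture LCp in mg/L.
#' @export
surrogate_effect_concentration <- function(object, fractions, p,
                                           t_range = NULL, n_grid = 400,
                                           family = object$selected) {
  stopifnot(inherits(object, "surface_fit"))
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  if (is.null(t_range)) {
    t_range <- object$feature_ranges[, "total"]
  }
  total <- exp(seq(log(t_range[1]), log(t_range[2]), length.out = n_grid))
  nd <- data.frame(conc_a = total * fractions[1],
                   conc_b = total * fractions[2],
                   total = total,
                   fraction_a = fractions[1])
  pred <- cummax(predict(object, nd, family = family))
  if (p < pred[1] || p > pred[length(pred)]) {
    stop("predicted effect never crosses p = ", p,
         " inside the search range", call. = FALSE)
  }
  i <- which(pred >= p)[1]
  if (i == 1L) return(total[1])
  # linear interpolation on log-concentration between bracketing grid points
  w <- if (pred[i] > pred[i - 1]) (p - pred[i - 1]) / (pred[i] - pred[i - 1]) else 0
  exp((1 - w) * log(total[i - 1]) + w * log(total[i]))
}
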