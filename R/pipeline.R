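#' Configuration for the end-to-end mixture-toxicity pipeline
#'
#' Collects and validates every pipeline setting. Only the single-toxicant
#' input is mandatory; when no mixture records are supplied the pipeline
#' simulates them along the designed rays under the chosen null model, so
#' the whole analysis can run from single-toxicant data alone.
#'
#' @param single_input Single-toxicant mortality data: a path to a flat
#'   records CSV ([read_mortality_csv()]), a data.frame in the flat schema,
#'   or a data.frame with columns `element`, `time_h`, `conc`, `mortality`
#'   (as returned by [crni_single_mortality()]).
#' @param mixture_input Optional mixture mortality records (path or flat
#'   data.frame). If `NULL`, mixtures are simulated.
#' @param elements Two component names for the mixture stages; defaults to
#'   the first two elements found in the single-toxicant data.
#' @param times Census times to fit; defaults to all present in the data.
#' @param mixture_time Census time (h) whose fits drive the mixture stages.
#' @param families CRC families to try, see [crc_families()].
#' @param confidence Confidence level for LCx intervals.
#' @param effect_levels Effect fractions reported as LCx (default LC10,
#'   LC30, LC50; LC50 must be included).
#' @param n_rays Number of EquRay rays.
#' @param n_levels,dilution_factor Fixed-ratio dilution series settings.
#' @param sr_epsilon Additivity tolerance for [synergistic_ratio()].
#' @param truth_model Null model used to simulate mixture data (`"CA"` or
#'   `"IA"`).
#' @param n_exposed,replicates Group size and replication for simulated
#'   mixtures.
#' @param qsar_families Regression surrogate families, see [fit_surface()].
#' @param split_ratio Train fraction for the surrogate.
#' @param seed Integer seed funnelling all pipeline randomness.
#' @param out_dir Optional directory for CSV outputs and the run log.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(single_input,
                            mixture_input = NULL,
                            elements = NULL,
                            times = NULL,
                            mixture_time = 96,
                            families = crc_families(),
                            confidence = 0.95,
                            effect_levels = c(0.1, 0.3, 0.5),
                            n_rays = 5,
                            n_levels = 12,
                            dilution_factor = 2,
                            sr_epsilon = 0.05,
                            truth_model = c("CA", "IA"),
                            n_exposed = 10,
                            replicates = 3,
                            qsar_families = surface_families(),
                            split_ratio = 0.8,
                            seed = 1,
                            out_dir = NULL) {
  families <- vapply(families, match_family, character(1), USE.NAMES = FALSE)
  qsar_families <- match.arg(qsar_families, surface_families(),
                             several.ok = TRUE)
  truth_model <- match.arg(truth_model)
  stopifnot(confidence > 0, confidence < 1,
            all(effect_levels > 0), all(effect_levels < 1),
            n_rays >= 1, n_levels >= 2, dilution_factor > 1,
            sr_epsilon >= 0, n_exposed >= 1, replicates >= 1)
  if (!any(abs(effect_levels - 0.5) < 1e-12)) {
    stop("effect_levels must include 0.5 (the LC50 drives the design)",
         call. = FALSE)
  }
  if (is.character(single_input) && !file.exists(single_input)) {
    stop("single_input file not found: ", single_input, call. = FALSE)
  }
  if (is.character(mixture_input) && !file.exists(mixture_input)) {
    stop("mixture_input file not found: ", mixture_input, call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

# normalise single-toxicant input to (element, time_h, conc, mortality)
normalise_singles <- function(single_input) {
  d <- if (is.character(single_input)) read_mortality_csv(single_input)
       else single_input
  stopifnot(is.data.frame(d))
  if (all(c("element", "time_h", "conc", "mortality") %in% names(d))) {
    return(d[, c("element", "time_h", "conc", "mortality")])
  }
  if (all(record_schema %in% names(d))) {
    singles <- d[is.na(d$component_b) | is.na(d$conc_b_mg_L), ]
    if (!nrow(singles)) stop("no single-toxicant rows found", call. = FALSE)
    return(data.frame(element = singles$component_a,
                      time_h = singles$time_h,
                      conc = singles$conc_a_mg_L,
                      mortality = singles$n_dead / singles$n_exposed))
  }
  stop("unrecognised single-toxicant input format", call. = FALSE)
}

#' Run the mixture-toxicity analysis pipeline
#'
#' Executes the full analysis: single-toxicant CRC fitting and LCx
#' estimation per element and census time; EECR/EquRay mixture design from
#' the LCx values; mixture exposure (simulated under the configured null
#' model unless measured records are supplied); mixture CRC fitting along
#' each ray; concentration-addition, independent-action and
#' regression-surrogate predictions with model comparison; and
#' synergistic-ratio interaction classing. Stage failures are logged and
#' stages that depend on a failed stage are skipped.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of class `pipeline_result` with elements
#'   `single_fits` (fit-table data.frame), `fits` (nested list of `crc_fit`
#'   objects), `design`, `mixture_records`, `mixture_fits`,
#'   `model_comparison`, `surface`, `interactions`, `log` (character), and
#'   `status` (named stage status vector). If `config$out_dir` is set, CSV
#'   tables and `run_log.txt` are written there.
#' @examples
#' cfg <- pipeline_config(crni_single_mortality(), times = 96,
#'                        n_levels = 8, seed = 7)
#' res <- run_pipeline(cfg)
#' head(res$single_fits)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  status <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
  }
  stage <- function(name, expr, needs = character()) {
    if (length(needs) && any(status[needs] != "ok")) {
      status[name] <<- "skipped"
      say("stage ", name, ": skipped (upstream failure)")
      return(NULL)
    }
    out <- tryCatch(expr, error = function(e) e)
    if (inherits(out, "error")) {
      status[name] <<- "failed"
      say("stage ", name, ": FAILED - ", conditionMessage(out))
      NULL
    } else {
      status[name] <<- "ok"
      say("stage ", name, ": ok")
      out
    }
  }
  say("raytox ", as.character(utils::packageVersion("raytox")),
      " pipeline, seed ", config$seed)

  ## stage 1: single-toxicant fits + LCx table -----------------------------
  singles <- stage("read_singles", normalise_singles(config$single_input))
  fit_bundle <- stage("fit_singles", needs = "read_singles", {
    elements <- unique(singles$element)
    times <- if (is.null(config$times)) sort(unique(singles$time_h))
             else config$times
    fits <- list(); rows <- list()
    for (el in elements) for (tt in times) {
      d <- singles[singles$element == el & singles$time_h == tt, ]
      if (!nrow(d)) next
      f <- select_best_family(d, config$families)
      fits[[el]][[as.character(tt)]] <- f
      row <- data.frame(element = el, time_h = tt, family = f$family,
                        alpha = f$alpha, beta = f$beta,
                        gamma = if (is.null(f$gamma)) NA_real_ else f$gamma,
                        r2 = f$quality$r2, mae = f$quality$mae)
      for (p in sort(config$effect_levels)) {
        ec <- suppressWarnings(
          effect_concentration(f, p, level = config$confidence))
        lab <- sprintf("lc%g", round(100 * p))
        row[[lab]] <- ec$value
        row[[paste0(lab, "_low")]] <- ec$ci_low
        row[[paste0(lab, "_high")]] <- ec$ci_high
      }
      rows[[paste(el, tt)]] <- row
    }
    list(fits = fits, table = do.call(rbind, c(rows, make.row.names = FALSE)))
  })

  ## stage 2: mixture design -----------------------------------------------
  design <- stage("design", needs = "fit_singles", {
    elements <- config$elements
    if (is.null(elements)) elements <- names(fit_bundle$fits)[1:2]
    if (length(elements) != 2 || anyNA(elements)) {
      stop("mixture design needs exactly two elements", call. = FALSE)
    }
    tkey <- as.character(config$mixture_time)
    fa <- fit_bundle$fits[[elements[1]]][[tkey]]
    fb <- fit_bundle$fits[[elements[2]]][[tkey]]
    if (is.null(fa) || is.null(fb)) {
      stop("no ", config$mixture_time, " h fit for both elements",
           call. = FALSE)
    }
    rays <- list()
    for (p in sort(config$effect_levels)) {
      lab <- sprintf("EECR %g", round(100 * p))
      rays[[lab]] <- eecr_ray(
        crc_invert(fa$family, fa$alpha, fa$beta, fa$gamma, p),
        crc_invert(fb$family, fb$alpha, fb$beta, fb$gamma, p),
        label = lab, component_ids = elements)
    }
    lc50a <- crc_invert(fa$family, fa$alpha, fa$beta, fa$gamma, 0.5)
    lc50b <- crc_invert(fb$family, fb$alpha, fb$beta, fb$gamma, 0.5)
    for (r in equray_rays(lc50a, lc50b, config$n_rays, elements)) {
      rays[[r$design]] <- r
    }
    rays <- lapply(rays, frrd_series, n_levels = config$n_levels,
                   dilution_factor = config$dilution_factor)
    sheet <- do.call(rbind, lapply(rays, function(r) {
      cbind(design = r$design, ray_concentrations(r))
    }))
    names(sheet)[4:5] <- c("conc_a_mg_L", "conc_b_mg_L")
    rownames(sheet) <- NULL
    list(rays = rays, sheet = sheet,
         elements = elements, single_fits = list(a = fa, b = fb))
  })

  ## stage 3: mixture records (measured or simulated) ----------------------
  mixture_records <- stage("mixture_data", needs = "design", {
    if (!is.null(config$mixture_input)) {
      d <- if (is.character(config$mixture_input)) {
        read_mortality_csv(config$mixture_input)
      } else config$mixture_input
      d <- d[!is.na(d$conc_b_mg_L), ]
      if (!nrow(d)) stop("no mixture rows in mixture_input", call. = FALSE)
      d$design <- if ("design" %in% names(d)) d$design else "measured"
      d
    } else {
      truth <- design$single_fits
      recs <- lapply(seq_along(design$rays), function(i) {
        r <- design$rays[[i]]
        out <- simulate_mixture(
          r, list(truth$a, truth$b), truth_model = config$truth_model,
          time_h = config$mixture_time, n_exposed = config$n_exposed,
          replicates = config$replicates, seed = config$seed + i)
        out$design <- r$design
        out
      })
      do.call(rbind, recs)
    }
  })

  ## stage 4: per-ray mixture CRC fits and LCx -----------------------------
  mixture_fits <- stage("fit_mixtures", needs = "mixture_data", {
    rows <- list(); fits <- list()
    for (lab in unique(mixture_records$design)) {
      d <- mixture_records[mixture_records$design == lab, ]
      f <- select_best_family(d, config$families)
      fits[[lab]] <- f
      row <- data.frame(combination = lab, family = f$family,
                        r2 = f$quality$r2)
      for (p in sort(config$effect_levels)) {
        ec <- suppressWarnings(
          effect_concentration(f, p, level = config$confidence))
        lab_p <- sprintf("lc%g", round(100 * p))
        row[[lab_p]] <- ec$value
        row[[paste0(lab_p, "_low")]] <- ec$ci_low
        row[[paste0(lab_p, "_high")]] <- ec$ci_high
      }
      rows[[lab]] <- row
    }
    list(fits = fits, table = do.call(rbind, c(rows, make.row.names = FALSE)))
  })

  ## stage 5: CA / IA predictions and model comparison ---------------------
  comparison <- stage("compare_models", needs = c("fit_mixtures", "design"), {
    truth <- design$single_fits
    pooled <- pool_by_design(mixture_records)
    ca <- mapply(function(a, b) ca_effect(list(truth$a, truth$b), c(a, b)),
                 pooled$conc_a, pooled$conc_b)
    ia <- mapply(function(a, b) ia_effect(list(truth$a, truth$b), c(a, b)),
                 pooled$conc_a, pooled$conc_b)
    compare_models(pooled$mortality, list(CA = ca, IA = ia))
  })

  ## stage 6: regression surrogate -----------------------------------------
  surface <- stage("qsar", needs = "mixture_data", {
    ft <- build_feature_table(mixture_records)
    fit_surface(ft[, c("conc_a", "conc_b", "total", "fraction_a")],
                ft$mortality, families = config$qsar_families,
                split_ratio = config$split_ratio, seed = config$seed)
  })
  qsar_table <- stage("qsar_lcx", needs = c("qsar", "fit_mixtures"), {
    rows <- lapply(names(mixture_fits$fits), function(lab) {
      r <- design$rays[[lab]]
      row <- data.frame(combination = lab)
      for (p in sort(config$effect_levels)) {
        v <- tryCatch(
          surrogate_effect_concentration(surface, r$fractions, p),
          error = function(e) NA_real_)
        row[[sprintf("qsar_lc%g", round(100 * p))]] <- v
      }
      row
    })
    do.call(rbind, c(rows, make.row.names = FALSE))
  })

  ## stage 7: synergistic-ratio classification -----------------------------
  interactions <- stage("interactions", needs = c("fit_mixtures", "design"), {
    truth <- design$single_fits
    lc50 <- c(
      crc_invert(truth$a$family, truth$a$alpha, truth$a$beta,
                 truth$a$gamma, 0.5),
      crc_invert(truth$b$family, truth$b$alpha, truth$b$beta,
                 truth$b$gamma, 0.5))
    rows <- lapply(seq_len(nrow(mixture_fits$table)), function(i) {
      mix <- mixture_fits$table$lc50[i]
      sa <- synergistic_ratio(lc50[1], mix, design$elements[1],
                              epsilon = config$sr_epsilon)
      sb <- synergistic_ratio(lc50[2], mix, design$elements[2],
                              epsilon = config$sr_epsilon)
      data.frame(combination = mixture_fits$table$combination[i],
                 mixture_lc50 = mix,
                 sr_a = sa$sr, label_a = sa$label,
                 sr_b = sb$sr, label_b = sb$label)
    })
    do.call(rbind, c(rows, make.row.names = FALSE))
  })

  result <- structure(
    list(single_fits = fit_bundle$table,
         fits = fit_bundle$fits,
         design = if (is.null(design)) NULL else design$sheet,
         rays = if (is.null(design)) NULL else design$rays,
         mixture_records = mixture_records,
         mixture_fits = if (is.null(mixture_fits)) NULL else mixture_fits$table,
         model_comparison = comparison,
         surface = surface,
         qsar_lcx = qsar_table,
         interactions = interactions,
         log = log_lines, status = status, config = config),
    class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(obj, file) {
      if (!is.null(obj)) {
        utils::write.csv(obj, file.path(config$out_dir, file),
                         row.names = FALSE, na = "")
      }
    }
    wr(result$single_fits, "single_fits.csv")
    wr(result$design, "design.csv")
    wr(result$mixture_records, "mixture_records.csv")
    wr(result$mixture_fits, "mixture_fits.csv")
    wr(result$model_comparison, "model_comparison.csv")
    wr(if (is.null(surface)) NULL else surface$report, "qsar_report.csv")
    wr(result$qsar_lcx, "qsar_lcx.csv")
    wr(result$interactions, "interactions.csv")
    writeLines(c(log_lines,
                 paste0("status: ",
                        paste(names(status), status, sep = "=",
                              collapse = ", "))),
               file.path(config$out_dir, "run_log.txt"))
  }
  if (any(status == "failed")) {
    warning("pipeline finished with failed stage(s): ",
            paste(names(status)[status == "failed"], collapse = ", "),
            call. = FALSE)
  }
  invisible(result)
}

# pooled mortality per (design, level): mean across replicates
pool_by_design <- function(records) {
  key <- paste(records$design, records$conc_a_mg_L, records$conc_b_mg_L)
  agg <- stats::aggregate(
    cbind(mortality = records$n_dead / records$n_exposed),
    by = list(key = key, design = records$design,
              conc_a = records$conc_a_mg_L, conc_b = records$conc_b_mg_L),
    FUN = mean)
  agg[order(agg$design, -agg$conc_a - agg$conc_b),
      c("design", "conc_a", "conc_b", "mortality")]
}

#' @exportS3Method print pipeline_result
print.pipeline_result <- function(x, ...) {
  cat("mixture-toxicity pipeline result\n")
  cat("  stages:", paste(names(x$status), x$status, sep = "=",
                         collapse = ", "), "\n")
  if (!is.null(x$single_fits)) {
    cat("  single fits:", nrow(x$single_fits), "element-time rows\n")
  }
  if (!is.null(x$interactions)) {
    cat("  interactions:\n")
    print(x$interactions, digits = 3)
  }
  invisible(x)
}
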