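record_schema <- c("component_a", "component_b", "conc_a_mg_L",
                   "conc_b_mg_L", "time_h", "n_exposed", "n_dead",
                   "replicate")

#' Read and write flat mortality records
#'
#' One CSV schema covers single-toxicant and binary-mixture experiments:
#' columns `component_a`, `component_b`, `conc_a_mg_L`, `conc_b_mg_L`,
#' `time_h`, `n_exposed`, `n_dead`, `replicate`, with the `*_b` columns
#' empty for single-toxicant rows. `read_mortality_csv()` validates every
#' row (non-negative concentrations, `0 <= n_dead <= n_exposed`, positive
#' time) and reports offending line numbers; `write_mortality_csv()` writes
#' records back so that a write-then-read round trip is the identity.
#'
#' @param path File path.
#' @param records data.frame in the flat schema.
#' @return `read_mortality_csv()`: validated data.frame in the flat schema.
#' @export
read_mortality_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("empty input: ", path, call. = FALSE)
  miss <- setdiff(record_schema, names(d))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- d[, record_schema]
  for (col in c("conc_a_mg_L", "conc_b_mg_L", "time_h")) {
    d[[col]] <- as.numeric(d[[col]])
  }
  for (col in c("n_exposed", "n_dead", "replicate")) {
    d[[col]] <- as.integer(d[[col]])
  }
  d$component_a <- as.character(d$component_a)
  d$component_b <- as.character(d$component_b)
  d$component_b[!is.na(d$component_b) & d$component_b == ""] <- NA_character_
  # CSV line numbers: header is line 1
  line <- seq_len(nrow(d)) + 1L
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      stop("invalid records (", what, ") at line(s) ",
           paste(line[which(cond)], collapse = ", "), call. = FALSE)
    }
  }
  bad(!is.finite(d$conc_a_mg_L) | d$conc_a_mg_L < 0, "conc_a_mg_L")
  bad(!is.na(d$conc_b_mg_L) & d$conc_b_mg_L < 0, "conc_b_mg_L")
  bad(!is.finite(d$time_h) | d$time_h <= 0, "time_h")
  bad(!is.finite(d$n_exposed) | d$n_exposed < 1, "n_exposed")
  bad(!is.finite(d$n_dead) | d$n_dead < 0 | d$n_dead > d$n_exposed,
      "n_dead outside [0, n_exposed]")
  d
}

#' @rdname read_mortality_csv
#' @export
write_mortality_csv <- function(records, path) {
  miss <- setdiff(record_schema, names(records))
  if (length(miss)) {
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(records[, record_schema], path, row.names = FALSE,
                   na = "")
  invisible(path)
}
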