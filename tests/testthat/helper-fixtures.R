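# Shared fixtures: published single-toxicity data and CRC parameters.

cr96_data <- function() {
  data.frame(conc = c(0.2, 0.59, 1.73, 5.1, 15),
             mortality = c(0.23, 0.47, 0.53, 0.77, 1.00))
}

ni96_data <- function() {
  data.frame(conc = c(3, 5.87, 11.49, 22.48, 44),
             mortality = c(0.37, 0.57, 0.90, 0.93, 1.00))
}

# printed 96-h curve parameters (chromium Weibull, nickel generalised logit)
cr96_curve <- function() crc_params("Weibull", -0.4, 1.21)
ni96_curve <- function() crc_params("GL", -9.44, 8.94, 0.2)

# the study's eight design rays (EECR 10/30/50 + EquRay 1-5) built from the
# printed 96-h LCx values, each with the default 12-level halving series
study_rays <- function(n_levels = 12) {
  cr <- cr96_curve(); ni <- ni96_curve()
  lcx <- function(f, p) crc_invert(f$family, f$alpha, f$beta, f$gamma, p)
  rays <- c(
    lapply(c(0.1, 0.3, 0.5), function(p) {
      eecr_ray(lcx(cr, p), lcx(ni, p), sprintf("EECR %g", 100 * p),
               c("Cr", "Ni"))
    }),
    equray_rays(lcx(cr, 0.5), lcx(ni, 0.5), 5, c("Cr", "Ni"))
  )
  lapply(rays, frrd_series, n_levels = n_levels)
}

# deterministic pseudo-random parameter draws inside the plausible box
random_curves <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    fam <- sample(c("Weibull", "GL"), 1)
    alpha <- runif(1, -8, 1)
    beta <- runif(1, 0.8, 8)
    if (fam == "Weibull") crc_params(fam, alpha, beta)
    else crc_params(fam, alpha, beta, runif(1, 0.1, 1.8))
  })
}
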