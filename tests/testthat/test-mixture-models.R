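test_that("concentration addition is the weighted harmonic mean", {
  expect_equal(ca_effect_concentration(c(0.53, 0.47), c(1.07, 4.7)), 1.68,
               tolerance = 0.005)
  # a one-component 'mixture' is just that component
  expect_equal(ca_effect_concentration(1, 5), 5)
  expect_error(ca_effect_concentration(c(0.6, 0.6), c(1, 2)), "sum to 1")
  expect_error(ca_effect_concentration(c(0.5, 0.5), c(1, 0)), "> 0")
})

test_that("CA mixture LCp lies between the component LCps (property)", {
  set.seed(5)
  for (i in 1:50) {
    w <- runif(1, 0.01, 0.99)
    lcp <- runif(2, 0.1, 50)
    mix <- ca_effect_concentration(c(w, 1 - w), lcp)
    expect_gte(mix, min(lcp) - 1e-12)
    expect_lte(mix, max(lcp) + 1e-12)
  }
})

test_that("CA effect inverts the toxic-unit sum consistently", {
  cr <- cr96_curve(); ni <- ni96_curve()
  # at the CA LC50 of a ray, the effect must be 0.5
  fr <- c(0.53, 0.47)
  lc50s <- c(crc_invert("Weibull", -0.4, 1.21, Y = 0.5),
             crc_invert("GL", -9.44, 8.94, 0.2, Y = 0.5))
  mix <- ca_effect_concentration(fr, lc50s)
  expect_equal(ca_effect(list(cr, ni), mix * fr), 0.5, tolerance = 1e-6)
  expect_equal(ca_effect(list(cr, ni), c(0, 0)), 0)
})

test_that("independent action multiplies survival probabilities", {
  cr <- cr96_curve()
  lc50 <- crc_invert("Weibull", -0.4, 1.21, Y = 0.5)
  # two half-effects combine to 0.75
  expect_equal(ia_effect(list(cr, cr), c(lc50, lc50)), 0.75,
               tolerance = 1e-9)
  # zero concentration is the neutral element
  ni <- ni96_curve()
  expect_equal(ia_effect(list(cr, ni), c(lc50, 0)),
               crc_evaluate("Weibull", -0.4, 1.21, x = lc50))
  # cross-check against direct evaluation of both printed curves
  f1 <- crc_evaluate("Weibull", -0.4, 1.21, x = 0.535)
  f2 <- crc_evaluate("GL", -9.44, 8.94, 0.2, x = 2.35)
  expect_equal(ia_effect(list(cr, ni), c(0.535, 2.35)),
               1 - (1 - f1) * (1 - f2))
  expect_error(ia_effect(list(cr), c(1, 2)), "same length")
})

test_that("IA effect is monotone and bounded by the strongest component", {
  cr <- cr96_curve(); ni <- ni96_curve()
  set.seed(9)
  for (i in 1:30) {
    c1 <- runif(1, 0.01, 10); c2 <- runif(1, 0.01, 10)
    e <- ia_effect(list(cr, ni), c(c1, c2))
    expect_gte(e, max(crc_evaluate("Weibull", -0.4, 1.21, x = c1),
                      crc_evaluate("GL", -9.44, 8.94, 0.2, x = c2)) - 1e-12)
    expect_lte(e, 1)
    # monotone nondecreasing in each component
    expect_gte(ia_effect(list(cr, ni), c(c1 * 1.5, c2)), e - 1e-12)
    expect_gte(ia_effect(list(cr, ni), c(c1, c2 * 1.5)), e - 1e-12)
  }
})

test_that("IA effect concentration solves the product form", {
  cr <- cr96_curve()
  ray <- frrd_series(mixture_ray(c("A", "B"), c(1, 1)), n_levels = 6)
  # identical components at equal fractions: 1-(1-f)^2 = p  =>
  # f = 1 - sqrt(1-p) at concentration T/2
  lcp <- ia_effect_concentration(ray, list(cr, cr), 0.5)
  f_half <- 1 - sqrt(0.5)
  expect_equal(lcp, 2 * crc_invert("Weibull", -0.4, 1.21, Y = f_half),
               tolerance = 1e-6)
  # a solved LCp evaluates back to p
  ni <- ni96_curve()
  ray2 <- study_rays()[[4]]
  lcp2 <- ia_effect_concentration(ray2, list(cr, ni), 0.5)
  expect_gt(lcp2, 0)
  expect_equal(ia_effect(list(cr, ni), lcp2 * ray2$fractions), 0.5,
               tolerance = 1e-8)
  expect_error(ia_effect_concentration(ray, list(cr, cr), 1.5), "in \\(0, 1\\)")
})

test_that("synergistic ratios reproduce the published classification", {
  sr3 <- synergistic_ratio(1.07, 1.03, "Cr", epsilon = 0)
  expect_equal(round(sr3$sr, 2), 1.04)
  expect_identical(sr3$label, "synergistic")
  sr1 <- synergistic_ratio(1.07, 1.48, "Cr", epsilon = 0)
  expect_equal(sr1$sr, 0.72, tolerance = 0.005)
  expect_identical(sr1$label, "antagonistic")
  eq <- synergistic_ratio(2.5, 2.5)
  expect_equal(eq$sr, 1)
  expect_identical(eq$label, "additive")
  # tolerance band widens the additive class
  expect_identical(synergistic_ratio(1.04, 1, epsilon = 0.05)$label,
                   "additive")
  expect_identical(synergistic_ratio(1.04, 1, epsilon = 0)$label,
                   "synergistic")
  expect_error(synergistic_ratio(0, 1), "> 0")
})

test_that("published mixture LC50s give the published SR(Cr) to 0.02", {
  mix <- crni_mixture_results()
  sr <- vapply(mix$lc50, function(e) synergistic_ratio(1.07, e)$sr,
               numeric(1))
  expect_true(all(abs(sr - mix$sr_cr) <= 0.02))
})

test_that("model comparison identifies the generating model", {
  cr <- cr96_curve(); ni <- ni96_curve()
  ray <- study_rays()[[5]]
  concs <- lapply(ray$series, function(T) T * ray$fractions)
  ca <- vapply(concs, function(cc) ca_effect(list(cr, ni), cc), numeric(1))
  ia <- vapply(concs, function(cc) ia_effect(list(cr, ni), cc), numeric(1))
  # noise-free CA truth: CA scores perfectly, IA cannot
  cmp <- compare_models(ca, list(CA = ca, IA = ia))
  expect_identical(cmp$model[1], "CA")
  expect_equal(cmp$r2[cmp$model == "CA"], 1)
  expect_lt(cmp$r2[cmp$model == "IA"], 1)
  # deterministic pure function
  expect_identical(cmp, compare_models(ca, list(CA = ca, IA = ia)))
  expect_error(compare_models(c(0.5, 0.5), list(m = c(0.4, 0.6))), ">= 3")
})
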