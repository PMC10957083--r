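# noise-free mixture mortality surface under CA truth on the 8 study rays
surface_fixture <- function() {
  cr <- cr96_curve(); ni <- ni96_curve()
  rows <- do.call(rbind, lapply(study_rays(), function(r) {
    data.frame(conc_a = r$series * r$fractions[1],
               conc_b = r$series * r$fractions[2],
               total = r$series,
               fraction_a = r$fractions[1],
               mortality = vapply(r$series, function(T) {
                 ca_effect(list(cr, ni), T * r$fractions)
               }, numeric(1)))
  }))
  rownames(rows) <- NULL
  rows
}

test_that("feature table has the composition columns and row order", {
  rec <- simulate_mixture(study_rays()[[4]], list(cr96_curve(), ni96_curve()),
                          "CA", seed = 2)
  ft <- build_feature_table(rec)
  expect_equal(nrow(ft), nrow(rec))
  expect_named(ft, c("conc_a", "conc_b", "total", "fraction_a", "mortality"))
  expect_equal(ft$total, ft$conc_a + ft$conc_b)
  # fraction is constant along a ray
  expect_equal(length(unique(round(ft$fraction_a, 12))), 1L)
  # CSV round trip preserves the table
  tmp <- tempfile(fileext = ".csv")
  write.csv(ft, tmp, row.names = FALSE)
  expect_equal(read.csv(tmp), ft, tolerance = 1e-12)
  unlink(tmp)
  expect_error(build_feature_table(data.frame(conc_a_mg_L = 1)),
               "missing column")
  rec$conc_b_mg_L[1] <- NA
  expect_error(build_feature_table(rec), "both component concentrations")
})

test_that("surrogate families fit a noise-free surface faithfully", {
  sfx <- surface_fixture()
  sf <- fit_surface(sfx[, 1:4], sfx$mortality, seed = 1)
  expect_s3_class(sf, "surface_fit")
  # the selected family is the argmax of test R2 among non-failed families
  ok <- !sf$report$failed
  expect_identical(sf$selected,
                   sf$report$family[ok][which.max(sf$report$test_r2[ok])])
  expect_true(sf$report$selected[sf$report$family == sf$selected])
  expect_gte(sf$report$test_r2[sf$report$family == sf$selected], 0.95)
  # with ample signal no family overfits wildly
  expect_true(all(sf$report$train_r2[ok] > sf$report$test_r2[ok] - 0.2))
})

test_that("surface fitting is deterministic under a fixed seed", {
  sfx <- surface_fixture()
  a <- fit_surface(sfx[, 1:4], sfx$mortality, seed = 31)
  b <- fit_surface(sfx[, 1:4], sfx$mortality, seed = 31)
  expect_identical(a$report, b$report)
  expect_identical(a$train_index, b$train_index)
  nd <- sfx[seq(1, 96, by = 7), 1:4]
  expect_identical(predict(a, nd), predict(b, nd))
  # a different seed changes the split
  c <- fit_surface(sfx[, 1:4], sfx$mortality, seed = 32)
  expect_false(identical(a$train_index, c$train_index))
})

test_that("degenerate inputs are rejected", {
  sfx <- surface_fixture()
  expect_error(fit_surface(sfx[1:6, 1:4], sfx$mortality[1:6]), "at least 10")
  expect_error(fit_surface(sfx[, 1:4], rep(0.5, nrow(sfx))), "degenerate")
})

test_that("surrogate inversion recovers the generating mixture LC50", {
  sfx <- surface_fixture()
  sf <- fit_surface(sfx[, 1:4], sfx$mortality, seed = 1)
  cr <- cr96_curve(); ni <- ni96_curve()
  lc50s <- c(crc_invert("Weibull", -0.4, 1.21, Y = 0.5),
             crc_invert("GL", -9.44, 8.94, 0.2, Y = 0.5))
  for (ray in study_rays()[c(3, 4, 6)]) {
    truth <- ca_effect_concentration(ray$fractions, lc50s)
    est <- surrogate_effect_concentration(sf, ray$fractions, 0.5)
    expect_equal(est, truth, tolerance = 0.1)
  }
  # unreachable effect level errors out
  expect_error(
    surrogate_effect_concentration(sf, c(0.5, 0.5), 0.999999,
                                   t_range = c(1e-4, 1e-3)),
    "never crosses")
  expect_error(surrogate_effect_concentration(sf, c(0.7, 0.7), 0.5),
               "sum to 1")
})
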