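test_that("inhibition rate follows the four-absorbance formula", {
  expect_equal(inhibition_rate(0.5, 0.1, 0.9, 0.1), 50)
  expect_equal(inhibition_rate(0.4, 0.1, 0.4, 0.1), 0)    # A1-A2 = A3-A4
  expect_equal(inhibition_rate(0.2, 0.2, 0.9, 0.1), 100)  # A1 = A2
  expect_error(inhibition_rate(0.5, 0.1, 0.3, 0.3), "A3 - A4")
})

test_that("cell viability follows the three-absorbance formula", {
  expect_equal(cell_viability(0.6, 1.1, 0.1), 50)
  expect_equal(cell_viability(1.1, 1.1, 0.1), 100)  # As = Ac
  expect_equal(cell_viability(0.1, 1.1, 0.1), 0)    # As = Ab
  expect_error(cell_viability(0.5, 0.2, 0.2), "Ac - Ab")
})

test_that("inhibition rate is affine in the sample absorbance", {
  a <- inhibition_rate(0.3, 0.1, 0.9, 0.1)
  b <- inhibition_rate(0.5, 0.1, 0.9, 0.1)
  c <- inhibition_rate(0.7, 0.1, 0.9, 0.1)
  expect_equal(c - b, b - a, tolerance = 1e-12)
})

test_that("linear interpolation finds the 50% crossing", {
  s <- dose_response_series(c(1, 5, 20, 50), c(5, 20, 80, 95))
  expect_equal(estimate_ic50(s)$ic50, 12.5)  # between (5,20%) and (20,80%)
  exact <- dose_response_series(c(1, 5, 10, 20), c(10, 30, 50, 70))
  expect_equal(estimate_ic50(exact)$ic50, 10)
  low <- dose_response_series(c(1, 2, 4, 8), c(5, 10, 15, 20))
  expect_error(estimate_ic50(low), "not bracketed")
})

test_that("4PL recovers the generating IC50 on noiseless data", {
  s <- gen_dose_response(13.03, 1.2,
                         conc_grid = c(1, 2, 5, 10, 13.03, 20, 50, 100))
  fit <- estimate_ic50(s, "four_parameter_logistic")
  expect_lt(rel_err(fit$ic50, 13.03), 1e-6)
  expect_gt(fit$fit_quality, 0.999999)
})

test_that("4PL is robust to replicate noise across many seeds", {
  # 9 doses spanning 256-fold around IC50 (pins both asymptotes),
  # triplicate wells averaged as in plate practice, 2% intensity noise
  grid <- 20 * 2^seq(-4, 4, length.out = 9)
  errs <- vapply(1:200, function(sd) {
    set.seed(sd)
    y <- rowMeans(vapply(1:3, function(r)
      100 / (1 + (20 / grid)^1.1) + rnorm(length(grid), 0, 2),
      numeric(length(grid))))
    s <- dose_response_series(grid, y)
    tryCatch(rel_err(estimate_ic50(s, "four_parameter_logistic")$ic50, 20),
             error = function(e) NA_real_)
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.05)
})

test_that("reversibility verdict checks origin and slope monotonicity", {
  E <- c(100, 200, 300, 400)
  mk <- function(conc, slope, intercept = 0)
    reversibility_series(conc, E, intercept + slope * E)
  good <- list(mk(0, 2e-4), mk(5, 1.5e-4), mk(10, 1e-4))
  v <- reversibility_verdict(good)
  expect_true(v$reversible)

  shifted <- list(mk(0, 2e-4, intercept = 0.5 * 2e-4 * 400), mk(5, 1.5e-4))
  expect_false(reversibility_verdict(shifted)$reversible)
  expect_true("not_through_origin" %in% reversibility_verdict(shifted)$flags)

  wobble <- list(mk(0, 1.0e-4), mk(5, 1.4e-4), mk(10, 0.9e-4))
  expect_true("slopes_not_decreasing" %in% reversibility_verdict(wobble)$flags)

  expect_error(reversibility_verdict(list(
    reversibility_series(0, c(100, 100, 100), c(1, 1, 1)),
    mk(5, 1e-4))), "rank-deficient")
})

test_that("reversibility verdict ignores point order within lines", {
  E <- c(100, 200, 300, 400)
  v1 <- reversibility_verdict(list(
    reversibility_series(0, E, 2e-4 * E),
    reversibility_series(5, E, 1e-4 * E)))
  v2 <- reversibility_verdict(list(
    reversibility_series(0, rev(E), rev(2e-4 * E)),
    reversibility_series(5, rev(E), rev(1e-4 * E))))
  expect_equal(v1$reversible, v2$reversible)
  expect_equal(v1$table$slope, v2$table$slope, tolerance = 1e-12)
})

test_that("stability profile summarizes condition grids", {
  flat <- list(a = c(A1 = .4, A2 = .1, A3 = .9, A4 = .1),
               b = c(A1 = .4, A2 = .1, A3 = .9, A4 = .1))
  expect_equal(stability_profile(flat)$range, 0)

  grid <- list(ph6 = c(A1 = .5, A2 = .1, A3 = .9, A4 = .1),
               ph7 = c(A1 = .5, A2 = .1, A3 = .9, A4 = .1),
               ph9 = c(A1 = .3, A2 = .1, A3 = .9, A4 = .1))
  sp <- stability_profile(grid)
  expect_equal(sp$max_condition, "ph9")  # alkaline condition inhibits most
  expect_gt(sp$rates["ph9"], sp$rates["ph7"])
})
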