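test_that("amide-I window extraction removes a straight baseline exactly", {
  w <- seq(1550, 1750, 1)
  flat <- ftir_spectrum(w, rep(0.3, length(w)))
  expect_true(all(extract_amide_I(flat)$absorbance == 0))
  ramp <- ftir_spectrum(w, 0.1 + 0.002 * (w - 1550))
  expect_lt(max(abs(extract_amide_I(ramp)$absorbance)), 1e-12)
})

test_that("Gaussian-plus-line input returns the Gaussian area", {
  sp <- gen_ftir_spectrum(c(alpha_helix = 2.5), sigma = 5,
                          baseline_slope = 0.001, baseline_offset = 0.05)
  win <- extract_amide_I(sp)
  h <- diff(win$wavenumber)
  area <- sum((win$absorbance[-1] + win$absorbance[-length(win$absorbance)]) /
                2 * h)
  expect_lt(abs(area - 2.5) / 2.5, 0.005)
})

test_that("a single sub-band is recovered with center and area fidelity", {
  sp <- gen_ftir_spectrum(c(alpha_helix = 1),
                          centers = c(alpha_helix = 1655), sigma = 6)
  pk <- deconvolve(extract_amide_I(sp), seeding = "second_derivative")$peaks
  main <- pk[which.max(pk$area), ]
  expect_lt(abs(main$center - 1655), 0.5)
  expect_lt(abs(sum(pk$area) - 1), 0.01)
  expect_equal(main$klass, "alpha_helix")
})

test_that("five-class mixtures are deconvoluted to within 3% per class", {
  for (fr in list(amy_fractions,
                  c(alpha_helix = 24.74, beta_sheet = 32.91,
                    beta_turn = 14.72, random_coil = 19.42,
                    beta_antiparallel = 8.21))) {
    sp <- gen_ftir_spectrum(fr)
    st <- assign_structure(deconvolve(extract_amide_I(sp),
                                      seeding = "fixed_classes"))
    expect_lt(max(abs(st$fractions[names(fr)] - fr)), 3)
    expect_lt(abs(sum(st$fractions) - 100), 0.1)
  }
})

test_that("overlapped bands conserve total area", {
  sp <- gen_ftir_spectrum(c(alpha_helix = 1, beta_turn = 1.5),
                          centers = c(alpha_helix = 1655, beta_turn = 1665),
                          sigma = 5)
  dv <- deconvolve(extract_amide_I(sp), seeding = "second_derivative")
  expect_lt(abs(sum(dv$peaks$area) - 2.5) / 2.5, 0.01)
  expect_gte(nrow(dv$peaks), 2)
})

test_that("deconvolution total area matches the windowed integral", {
  sp <- gen_ftir_spectrum(amy_fractions)
  win <- extract_amide_I(sp)
  dv <- deconvolve(win, seeding = "fixed_classes")
  h <- diff(win$wavenumber)
  integral <- sum((win$absorbance[-1] +
                     win$absorbance[-length(win$absorbance)]) / 2 * h)
  expect_lt(abs(sum(dv$peaks$area) - integral) / integral, 0.01)
})

test_that("class assignment applies the wavenumber range table", {
  pk <- data.frame(center = c(1620, 1670), area = c(2, 3))
  fr <- assign_structure(pk)$fractions
  expect_equal(unname(fr["beta_sheet"]), 40)
  expect_equal(unname(fr["beta_turn"]), 60)
  one <- assign_structure(data.frame(center = 1655, area = 7))$fractions
  expect_equal(unname(one["alpha_helix"]), 100)
})

test_that("range-gap boundaries resolve to the lower class (closed-left)", {
  expect_equal(unname(
    assign_structure(data.frame(center = 1637, area = 1))$fractions["beta_sheet"]),
    100)
  expect_equal(unname(
    assign_structure(data.frame(center = 1637.5, area = 1))$fractions["beta_sheet"]),
    100)
  expect_equal(unname(
    assign_structure(data.frame(center = 1638, area = 1))$fractions["beta_antiparallel"]),
    100)
})

test_that("assignment ignores sub-peak order and uniform area rescaling", {
  pk <- data.frame(center = c(1626, 1643, 1655, 1670, 1686),
                   area = c(5, 2, 4, 3, 1))
  f1 <- assign_structure(pk)$fractions
  f2 <- assign_structure(pk[sample(5), ])$fractions
  f3 <- assign_structure(transform(pk, area = area * 42))$fractions
  expect_equal(f1, f2)
  expect_equal(f1, f3)
  expect_lt(abs(sum(f1) - 100), 0.1)
})

test_that("out-of-range centers are excluded with a warning", {
  pk <- data.frame(center = c(1605, 1655), area = c(1, 3))
  expect_warning(st <- assign_structure(pk), "excluded")
  expect_equal(unname(st$fractions["alpha_helix"]), 100)
  expect_equal(st$unassigned_area, 1)
})

test_that("spectrum constructor enforces window coverage and monotonicity", {
  expect_error(ftir_spectrum(seq(1650, 1700, 1), rep(1, 51)), "window")
  expect_error(ftir_spectrum(c(1600, 1600, 1700), c(1, 1, 1)), "monotone")
  down <- ftir_spectrum(seq(1750, 1550, -1), rep(0.2, 201))
  expect_true(all(diff(down$wavenumber) > 0))
})
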