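test_that("both fitting modes recover Michaelis-Menten truth exactly", {
  s <- gen_kinetics(mixed_truth$km, mixed_truth$vmax, "mixed",
                    ki = mixed_truth$ki, kis = mixed_truth$kis,
                    substrate_grid = c(2.5, 5, 7.5, 10),
                    inhibitor_grid = 0)[[1]]
  lb <- fit_kinetics(s, "lineweaver_burk")
  nl <- fit_kinetics(s, "nonlinear")
  expect_lt(rel_err(lb$Km, mixed_truth$km), 1e-9)
  expect_lt(rel_err(lb$Vmax, mixed_truth$vmax), 1e-9)
  expect_lt(rel_err(nl$Km, lb$Km), 1e-6)
  expect_lt(rel_err(nl$Vmax, lb$Vmax), 1e-6)
  expect_equal(lb$lb_slope, lb$Km / lb$Vmax, tolerance = 1e-12)
})

test_that("saturating data pins Vmax to the plateau", {
  S <- c(50, 100, 200, 400)  # S >> Km = 1
  s <- kinetic_series(0, S, 0.2 * S / (1 + S))
  expect_equal(fit_kinetics(s)$Vmax, 0.2, tolerance = 0.02)
})

test_that("classification recovers every generating inhibition type", {
  S <- c(2.5, 5, 7.5, 10)
  I <- c(0, 2, 4, 6, 8, 10)
  types <- c("mixed", "competitive", "noncompetitive", "uncompetitive")
  for (type in types) {
    fits <- lapply(gen_kinetics(3.9, 0.18, type, ki = 8.7, kis = 21.3,
                                substrate_grid = S, inhibitor_grid = I),
                   fit_kinetics)
    expect_equal(classify_inhibition(fits, tol = 0.05)$type, type,
                 info = type)
  }
})

test_that("mixed-type Lineweaver-Burk lines meet in the second quadrant", {
  fits <- gen_mixed_fits()
  cl <- classify_inhibition(fits)
  expect_lt(cl$intersection$x, 0)
  expect_gt(cl$intersection$y, 0)
  expect_equal(cl$intersection$quadrant, "second_quadrant")
  # exact geometry: x* = -Ki/(Km Kis), y* = (1 - Ki/Kis)/Vmax
  expect_equal(cl$intersection$x,
               -mixed_truth$ki / (mixed_truth$km * mixed_truth$kis),
               tolerance = 1e-6)
  expect_equal(cl$intersection$y,
               (1 - mixed_truth$ki / mixed_truth$kis) / mixed_truth$vmax,
               tolerance = 1e-6)
})

test_that("noncompetitive lines meet on the negative x-axis", {
  fits <- lapply(gen_kinetics(3.6, 0.18, "noncompetitive", ki = 158,
                              substrate_grid = c(2.5, 5, 7.5, 10),
                              inhibitor_grid = c(0, 40, 80, 120)),
                 fit_kinetics)
  cl <- classify_inhibition(fits)
  expect_equal(cl$intersection$quadrant, "negative_x_axis")
  expect_equal(cl$intersection$x, -1 / 3.6, tolerance = 1e-6)
})

test_that("secondary plots invert the generator exactly at zero noise", {
  fits <- gen_mixed_fits()
  expect_lt(rel_err(estimate_ki(fits)$Ki, mixed_truth$ki), 1e-9)
  expect_lt(rel_err(estimate_kis(fits)$Kis, mixed_truth$kis), 1e-9)
})

test_that("Ki ordering is preserved for mixed data and Ki < Kis iff generated so", {
  S <- c(2.5, 5, 7.5, 10); I <- c(0, 5, 10, 15)
  for (pair in list(c(5, 20), c(20, 5))) {
    fits <- lapply(gen_kinetics(3, 0.2, "mixed", ki = pair[1], kis = pair[2],
                                substrate_grid = S, inhibitor_grid = I),
                   fit_kinetics)
    ki <- estimate_ki(fits)$Ki
    kis <- estimate_kis(fits)$Kis
    expect_equal(ki < kis, pair[1] < pair[2])
  }
})

test_that("Ki is invariant to rescaling all velocities", {
  fits <- gen_mixed_fits()
  # rescaling every velocity by a common factor = scaling Vmax in the model
  fits2 <- lapply(gen_kinetics(mixed_truth$km, 3.7 * mixed_truth$vmax,
                               "mixed", ki = mixed_truth$ki,
                               kis = mixed_truth$kis,
                               substrate_grid = c(2.5, 5, 7.5, 10),
                               inhibitor_grid = c(0, 2, 4, 6, 8, 10)),
                  fit_kinetics)
  expect_equal(estimate_ki(fits2)$Ki, estimate_ki(fits)$Ki,
               tolerance = 1e-9)
})

test_that("Kis is refused for inhibition types that do not define it", {
  fits <- lapply(gen_kinetics(3.6, 0.18, "noncompetitive", ki = 50,
                              substrate_grid = c(2.5, 5, 7.5, 10),
                              inhibitor_grid = c(0, 10, 20, 30)),
                 fit_kinetics)
  type <- classify_inhibition(fits)$type
  expect_equal(type, "noncompetitive")
  expect_error(estimate_kis(fits, type = type), "not applicable")
  # without data: 1/Vmax still rises with [I], slope from Ki alone
  expect_silent(estimate_kis(fits))
})

test_that("fit preconditions are enforced", {
  expect_error(kinetic_series(0, c(1, 2), c(0.1, 0.2)), "3 distinct")
  expect_error(kinetic_series(0, c(1, 2, 3), c(0.1, -0.2, 0.3)),
               "non-positive velocity at row 2")
  fits <- gen_mixed_fits(inhibitor_grid = c(0, 5))
  expect_error(classify_inhibition(fits), ">= 3")
  expect_error(estimate_ki(fits), ">= 3")
  noI0 <- gen_mixed_fits(inhibitor_grid = c(2, 4, 6))
  expect_error(classify_inhibition(noI0), "\\[I\\] = 0")
})
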