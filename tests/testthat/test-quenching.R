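test_that("inner-filter correction matches its closed form and identity case", {
  t0 <- quench_titration(298, c(0, 1e-6), c(100, 90),
                         Aex = c(0, 0), Aem = c(0, 0))
  expect_equal(inner_filter_correct(t0)$Fobs, c(100, 90))
  t1 <- quench_titration(298, c(0, 1e-6), c(100, 100),
                         Aex = c(0.25, 0.25), Aem = c(0.15, 0.15))
  expect_equal(inner_filter_correct(t1)$Fobs[1], 100 * exp(0.2),
               tolerance = 1e-12)
  expect_warning(inner_filter_correct(quench_titration(298, c(0, 1e-6),
                                                       c(100, 90))),
                 "uncorrected")
  expect_error(quench_titration(298, c(0, 1e-6), c(100, 90),
                                Aex = c(-0.1, 0), Aem = c(0, 0)),
               "non-negative")
})

test_that("Stern-Volmer fit identifies exact linear data", {
  Q <- c(0, 2, 4, 6, 8, 10) * 1e-6
  t <- quench_titration(298, Q, 100 / (1 + 2e4 * Q))
  fit <- stern_volmer_fit(t)
  expect_equal(fit$Ksv, 2e4, tolerance = 1e-9)
  expect_equal(fit$model, "linear")
  expect_lt(abs(fit$curvature_score), 0.05)
  expect_equal(fit$Kq, fit$Ksv / 1e-8, tolerance = 1e-12)
})

test_that("constant intensity yields zero quenching constant", {
  t <- quench_titration(298, c(0, 1e-6, 2e-6, 3e-6), rep(100, 4))
  expect_equal(stern_volmer_fit(t)$Ksv, 0)
})

test_that("upward-curved titrations select the exponential model", {
  Q <- seq(0, 8e-6, length.out = 6)
  ksv <- 1e5  # Ksv Qmax = 0.8
  t <- quench_titration(298, Q, 100 / exp(ksv * Q))
  fit <- stern_volmer_fit(t)
  expect_equal(fit$model, "exponential")
  expect_equal(fit$Ksv, ksv, tolerance = 1e-9)
  expect_gt(fit$curvature_score, 0.5)
})

test_that("fluorescence enhancement is rejected as a data-quality error", {
  t <- quench_titration(298, c(0, 1e-6, 2e-6, 3e-6), c(100, 110, 90, 80))
  expect_error(stern_volmer_fit(t), "enhancement")
})

test_that("mechanism classification follows the temperature and Kq rules", {
  static_df <- data.frame(temperature = c(298, 304, 310),
                          Ksv = c(4.07, 3.37, 3.07) * 1e4)
  expect_equal(classify_mechanism(static_df)$mechanism, "static")

  mixed_df <- data.frame(temperature = c(298, 304, 310),
                         Ksv = c(4.32, 3.36, 3.29) * 1e4,
                         model = c("exponential", "linear", "linear"))
  expect_equal(classify_mechanism(mixed_df)$mechanism,
               "mixed_static_dominant")

  dyn_df <- data.frame(temperature = c(298, 304, 310),
                       Ksv = c(1, 1.2, 1.4) * 1e4)
  expect_equal(classify_mechanism(dyn_df)$mechanism, "dynamic")
  low_kq <- data.frame(temperature = c(298, 310), Ksv = c(20, 10))
  expect_equal(classify_mechanism(low_kq)$mechanism, "dynamic")
  expect_error(classify_mechanism(data.frame(temperature = c(298, 298),
                                             Ksv = c(1, 2))), "distinct")
})

test_that("static call is threshold-independent below min(Kq)", {
  fits <- lapply(c(298, 304, 310), function(Tk) {
    ksv <- 5e4 * (1 - (Tk - 298) / 100)
    Q <- c(0, 2, 4, 6, 8) * 1e-6
    stern_volmer_fit(quench_titration(Tk, Q, 100 / (1 + ksv * Q)))
  })
  min_kq <- min(vapply(fits, function(f) f$Kq, numeric(1)))
  for (thr in c(1e9, 1e10, 0.99 * min_kq))
    expect_equal(classify_mechanism(fits, threshold = thr)$mechanism,
                 "static")
})

test_that("double-log fit reads Ka and n off constructed linear data", {
  Q <- c(0, 1, 2, 4, 8) * 1e-6
  Fq <- 100 / (1 + 1e4 * Q)  # (F0-F)/F = 1e4 [Q]
  fit <- double_log_fit(quench_titration(298, Q, Fq))
  expect_equal(fit$n, 1, tolerance = 1e-9)
  expect_equal(fit$Ka, 1e4, tolerance = 1e-9)
})

test_that("double-log fit inverts the generator over a (Ka, n) grid", {
  for (ka in c(1e3, 1e5, 1e7)) for (n in c(0.5, 1, 1.16, 2)) {
    # titrate across the binding transition, as a real design would
    Q <- c(0, 0.2, 0.5, 1, 2, 5) * ka^(-1 / n)
    t <- gen_quench_titration(200, Q, ka = ka, n = n)
    fit <- double_log_fit(t)
    expect_lt(rel_err(fit$Ka, ka), 1e-9)
    expect_lt(rel_err(fit$n, n), 1e-9)
  }
  # single-site data give back n ~ 1, the single-binding-site signature
  Q1 <- c(0, 0.2, 0.5, 1, 2, 5) * 1e-5
  t <- gen_quench_titration(200, Q1, ka = 1e5, n = 1)
  expect_equal(double_log_fit(t)$n, 1, tolerance = 1e-9)
})

test_that("unquenched points are named in the log-domain error", {
  t <- quench_titration(298, c(0, 1e-6, 2e-6), c(100, 100, 90))
  expect_error(double_log_fit(t), "rows 2")
})

test_that("binding constants fall with temperature for exothermic binding", {
  tg <- c(298, 304, 310)
  ka_t <- gen_vant_hoff(-5e4, -100, tg)$ka_l_per_mol
  Q <- c(0, 1, 2, 4, 8) * 1e-6
  rec <- vapply(seq_along(tg), function(i) {
    double_log_fit(gen_quench_titration(100, Q, temperature = tg[i],
                                        ka = ka_t[i], n = 1))$Ka
  }, numeric(1))
  expect_true(all(diff(rec) < 0))
})
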