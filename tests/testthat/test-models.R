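test_that("derived rates obey detailed balance and convert units once", {
  wm <- wm_mt_fixture()
  r <- derived_rates(wm, unit = "s")
  expect_equal(r$kb, 4.3 * 0.883 / 0.117, tolerance = 1e-12)
  expect_equal(r$ka * r$M0a, r$kb * r$M0b, tolerance = 1e-12)

  my <- myelin_fixture()
  expect_equal(derived_rates(my, unit = "s")$kb, 8)

  sym <- epgx_bm_model(1000, 1000, 100, 100, ka = 2, f = 0.5)
  expect_equal(derived_rates(sym, unit = "s")$kb, 2)

  # ms is the internal base: rates are 1e-3 times the s^-1 values
  expect_equal(derived_rates(wm, unit = "ms")$kb,
               derived_rates(wm, unit = "s")$kb * 1e-3)
})

test_that("invalid pool parameters are rejected", {
  expect_error(epgx_bm_model(1000, 500, 100, 20, ka = 2, f = 0),
               "f = 0 with ka > 0")
  expect_error(epgx_bm_model(-1, 500, 100, 20, ka = 0, f = 0), "positive")
  expect_error(epgx_bm_model(1000, 500, 100, 20, ka = 2, f = 1.2), "0 <= f < 1")
  expect_error(epgx_mt_model(779, 779, 45, -2, 4.3, 0.117), "positive")
  expect_silent(epgx_bm_model(1000, 500, 100, 20, ka = 0, f = 0))
})

test_that("observed T1 closed form matches the printed reference values", {
  expect_equal(t1_observed(wm_mt_fixture()), 779, tolerance = 1e-3)
  bsa <- epgx_mt_model(t1a = 1763, t1b = 363, t2a = 92, t2b_us = 12,
                       ka = 6.2, f = 0.100)
  expect_equal(t1_observed(bsa), 1283, tolerance = 0.002)
})

test_that("observed T1 reduces to max(T1a, T1b) without exchange", {
  m <- epgx_bm_model(1200, 400, 100, 20, ka = 0, f = 0.2)
  expect_equal(t1_observed(m), 1200, tolerance = 1e-12)
})

test_that("closed-form observed T1 equals the eigenvalue of the coupled
           longitudinal matrix for random models", {
  withr::with_seed(42, {
    for (i in 1:1000) {
      m <- random_bm_model()
      r <- derived_rates(m, unit = "ms")
      lam <- matrix(c(-r$R1a - r$ka, r$kb, r$ka, -r$R1b - r$kb), 2, 2,
                    byrow = TRUE)
      ev <- eigen(lam, only.values = TRUE)$values
      expect_equal(t1_observed(m), -1 / max(ev), tolerance = 1e-10)
    }
  })
})

test_that("both residence-time conventions are exposed", {
  my <- myelin_fixture()
  rt <- residence_time(my)
  expect_equal(rt$tau_b_ratio, 100)           # f / ka
  expect_equal(rt$tau_b_balance, 125)         # f / (ka (1 - f)) = 1 / kb
})
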