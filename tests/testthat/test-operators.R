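test_that("RF transition matrix reproduces limiting pulses and a rotation oracle", {
  expect_equal(rf_transition(0, 0.7), diag(3) + 0i, tolerance = 1e-14)
  expect_equal(rf_transition(pi, 0),
               matrix(c(0, 1, 0, 1, 0, 0, 0, 0, -1), 3, 3, byrow = TRUE) + 0i,
               tolerance = 1e-14)
  for (ap in list(c(pi / 2, pi / 2), c(0.3, 1.1), c(2.1, -0.4))) {
    expect_equal(rf_transition(ap[1], ap[2]),
                 rf_rotation_cartesian(ap[1], ap[2]), tolerance = 1e-12)
  }
})

test_that("RF transition blocks act per pool and per order", {
  # MT with no saturation and no flip: identity on all states
  expect_equal(rf_transition_block(0, 0, "mt", 0), diag(4) + 0i,
               tolerance = 1e-14)
  # MT saturation only: free pool untouched, bound Z scaled
  B <- rf_transition_block(0, 0, "mt", wsat_exponent = 0.8)
  expect_equal(B[1:3, 1:3], diag(3) + 0i)
  expect_equal(B[4, 4], exp(-0.8) + 0i)
  expect_error(rf_transition_block(0.1, 0, "mt", wsat_exponent = -1), ">= 0")

  # BM excitation from equilibrium splits order-0 transverse (1-f):f
  my <- myelin_fixture()
  st <- epgx_state(my, 4)
  st2 <- epgx:::state_rf(st, pi / 2, 0)
  expect_equal(st2$fplus_a[1], -1i * 0.8, tolerance = 1e-14)
  expect_equal(st2$fplus_b[1], -1i * 0.2, tolerance = 1e-14)
  expect_equal(st2$fminus_a[1], Conj(st2$fplus_a[1]), tolerance = 1e-14)
})

test_that("shift operator does integer bookkeeping only", {
  my <- myelin_fixture()
  st <- epgx_state(my, 5)
  st$fplus_a[1] <- 0.3 + 0.1i
  st$fminus_a[1] <- Conj(st$fplus_a[1])
  st2 <- epgx_shift(st)
  expect_equal(st2$fplus_a[2], 0.3 + 0.1i)
  expect_equal(st2$fplus_a[1], 0 + 0i)   # refilled from empty F-1 ladder
  expect_equal(st2$z_a, st$z_a)          # longitudinal untouched
  expect_equal(st2$fminus_a[1], Conj(st2$fplus_a[1]))
})

test_that("shift matches pointwise phase multiplication of the profile", {
  # FFT oracle: shifting states multiplies the reconstructed M+(psi) by
  # exp(i psi)
  my <- myelin_fixture()
  st <- epgx_state(my, 8)
  withr::with_seed(7, {
    st$fplus_a[2:4] <- complex(real = rnorm(3), imaginary = rnorm(3))
    st$fminus_a[2:4] <- complex(real = rnorm(3), imaginary = rnorm(3))
    st$fminus_a[1] <- Conj(st$fplus_a[1])
  })
  p1 <- states_to_profile(st, 33)
  st2 <- epgx_shift(st)
  p2 <- states_to_profile(st2, 33)
  expect_equal(p2$m_plus_a, p1$m_plus_a * exp(1i * p1$psi), tolerance = 1e-12)
})

test_that("relaxation-exchange propagators match a Taylor-series exponential", {
  my <- myelin_fixture(delta_b = 17)
  r <- derived_rates(my, unit = "ms")
  dt <- 5
  prop <- relaxation_exchange(my, dt)
  dw <- 2i * pi * 17e-3
  lam_t <- matrix(0 + 0i, 4, 4)
  lam_t[1, 1] <- lam_t[2, 2] <- -r$R2a - r$ka
  lam_t[3, 3] <- -r$R2b - r$kb - dw
  lam_t[4, 4] <- -r$R2b - r$kb + dw
  lam_t[1, 3] <- lam_t[2, 4] <- r$kb
  lam_t[3, 1] <- lam_t[4, 2] <- r$ka
  expect_equal(prop$xi_t, expm_taylor(lam_t * dt), tolerance = 1e-12)
  lam_l <- matrix(c(-r$R1a - r$ka, r$kb, r$ka, -r$R1b - r$kb), 2, 2,
                  byrow = TRUE)
  expect_equal(prop$xi_l, expm_taylor(lam_l * dt), tolerance = 1e-12)
})

test_that("decoupled and degenerate limits of the propagators", {
  m <- epgx_bm_model(1000, 500, 100, 20, ka = 0, f = 0.2)
  prop <- relaxation_exchange(m, 3)
  expect_equal(diag(prop$xi_p), c(exp(-3 / 100), exp(-3 / 20)) + 0i,
               tolerance = 1e-14)
  expect_equal(prop$xi_p[1, 2], 0 + 0i)
  expect_equal(prop$xi_p[2, 1], 0 + 0i)
  p0 <- relaxation_exchange(m, 0)
  expect_equal(p0$xi_l, diag(2), tolerance = 1e-14)
  expect_equal(p0$recovery, c(0, 0), tolerance = 1e-14)

  # f -> 0 with ka = 0 reproduces single-pool operators exactly
  sp <- single_pool_model(1000, 100)
  f0 <- epgx_bm_model(1000, 500, 100, 20, ka = 0, f = 0)
  pf <- relaxation_exchange(f0, 7)
  ps <- relaxation_exchange(sp, 7)
  expect_equal(Re(pf$xi_p[1, 1]), ps$xi_t, tolerance = 1e-14)
  expect_equal(pf$xi_l[1, 1], ps$xi_l, tolerance = 1e-14)
  expect_equal(pf$recovery[1], ps$recovery, tolerance = 1e-12)
})

test_that("exchange couples only states of the same type and order", {
  my <- myelin_fixture(delta_b = 10)
  prop <- relaxation_exchange(my, 4)
  # + and -* blocks never mix: entries (1,2),(1,4),(2,1),(2,3),... are zero
  zero_idx <- rbind(c(1, 2), c(1, 4), c(2, 1), c(2, 3),
                    c(3, 2), c(3, 4), c(4, 1), c(4, 3))
  expect_true(all(Mod(prop$xi_t[zero_idx]) == 0))
})

test_that("transverse propagator commutes with the dephasing operator", {
  withr::with_seed(11, {
    for (i in 1:20) {
      m <- random_bm_model()
      dt <- runif(1, 0.5, 20)
      psi <- runif(1, -pi, pi)
      r <- derived_rates(m, unit = "ms")
      dw <- 2i * pi * m$delta_b * 1e-3
      lam_p <- matrix(c(-r$R2a - r$ka, r$kb, r$ka, -r$R2b - r$kb - dw),
                      2, 2, byrow = TRUE)
      om <- diag(c(-1i * psi / dt, -1i * psi / dt))
      lhs <- relaxation_exchange(m, dt)$xi_p * exp(-1i * psi)
      rhs <- expm_taylor((lam_p + om) * dt)
      expect_equal(lhs, rhs, tolerance = 1e-10)
    }
  })
})

test_that("equilibrium is a fixed point of the longitudinal update", {
  withr::with_seed(3, {
    for (i in 1:20) {
      m <- random_bm_model()
      dt <- runif(1, 0.1, 50)
      prop <- relaxation_exchange(m, dt)
      z_eq <- c((1 - m$f) * m$m0, m$f * m$m0)
      expect_equal(as.numeric(prop$xi_l %*% z_eq + prop$recovery), z_eq,
                   tolerance = 1e-12)
    }
  })
})

test_that("super-Lorentzian lineshape hits the reference zero-offset value", {
  expect_equal(lineshape_value(0, 12), 15.1, tolerance = 0.01)
})

test_that("lineshape is symmetric and matches direct quadrature off-resonance", {
  offs <- c(1800, 2780, 5000, 20000)
  expect_equal(lineshape_value(offs, 12), lineshape_value(-offs, 12),
               tolerance = 1e-12)
  # outside the interpolation band the value is the quadrature integral
  t2 <- 12e-6
  direct <- vapply(offs, function(d) {
    1e6 * integrate(function(u) {
      den <- abs(3 * u^2 - 1)
      sqrt(2 / pi) * t2 / den * exp(-2 * (2 * pi * d * t2 / den)^2)
    }, 0, 1, rel.tol = 1e-10, subdivisions = 800L)$value
  }, numeric(1))
  expect_equal(lineshape_value(offs, 12), direct, tolerance = 1e-6)
  # gaussian closed form
  expect_equal(lineshape_value(0, 12, kind = "gaussian"),
               12 / sqrt(2 * pi), tolerance = 1e-12)
})

test_that("saturation exponent depends on pulse energy only", {
  expect_equal(saturation_exponent(0, 15.1), 0)
  expect_error(saturation_exponent(-1, 15.1), ">= 0")
  # hand unit analysis: pi * gamma^2 [rad^2 ms^-2 uT^-2] * E [ms uT^2]
  #                     * G [ms] -> dimensionless
  g <- 0.2675221
  e <- 54.3 * (10 * pi / 180)^2
  expect_equal(saturation_exponent(e, 15.1), pi * g^2 * e * 15.1e-3,
               tolerance = 1e-14)
  # hard pulse at fixed B1: energy (hence exponent) scales linearly in alpha
  a <- c(0.1, 0.2, 0.4)
  en <- vapply(a, function(x) as.numeric(hard_pulse_energy(x, 13.5)),
               numeric(1))
  expect_equal(en, 13.5 * a / g, tolerance = 1e-12)
  w <- saturation_exponent(en, 15.1)
  expect_equal(w[2] / w[1], 2, tolerance = 1e-12)
})
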