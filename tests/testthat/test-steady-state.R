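test_that("ideally spoiled steady state reproduces the Ernst formula", {
  sp <- single_pool_model(779, 45)
  tr <- 5
  alpha <- 10 * pi / 180
  e1 <- exp(-tr / 779)
  ernst <- sin(alpha) * (1 - e1) / (1 - e1 * cos(alpha))
  expect_equal(spgr_steady_state(sp, tr, alpha)$signal, ernst,
               tolerance = 1e-14)
})

test_that("non-exchanging BM steady state is a weighted sum of Ernst formulas", {
  m <- epgx_bm_model(1000, 500, 100, 20, ka = 0, f = 0.2)
  tr <- 5
  alpha <- 10 * pi / 180
  ernst <- function(t1, w) {
    e1 <- exp(-tr / t1)
    w * sin(alpha) * (1 - e1) / (1 - e1 * cos(alpha))
  }
  expect_equal(spgr_steady_state(m, tr, alpha)$signal,
               ernst(1000, 0.8) + ernst(500, 0.2), tolerance = 1e-12)
})

test_that("perfect-spoiling transients converge to the direct SPGR solution", {
  tr <- 5
  alpha <- 10 * pi / 180
  en <- as.numeric(hard_pulse_energy(alpha))
  for (nm in c("single_wm", "wm_mt", "myelin_bm")) {
    m <- tissue_preset(nm)
    n <- ceiling(5 * t1_observed(m) / tr)
    s <- simulate_train(m, spgr_sequence(tr = tr, alpha = alpha, n_pulses = n),
                        perfect_spoil = TRUE)
    ss <- spgr_steady_state(m, tr, alpha, energy = en)
    expect_equal(Mod(s$signal[n]), ss$signal, tolerance = 1e-3)
  }
})

test_that("well-spoiled RF increments approach the ideal value, spikes do not", {
  wm <- wm_mt_fixture()
  tr <- 5
  alpha <- 10 * pi / 180
  n <- ceiling(5 * 779 / tr)
  ideal <- spgr_steady_state(wm, tr, alpha,
                             energy = as.numeric(hard_pulse_energy(alpha)))$signal
  dev_of <- function(phi0) {
    s <- simulate_train(wm, spgr_sequence(tr = tr, alpha = alpha, phi0 = phi0,
                                          n_pulses = n))
    abs(Mod(s$signal[n]) - ideal) / ideal
  }
  expect_lt(dev_of(117 * pi / 180), 0.02)
  expect_gt(dev_of(0), dev_of(117 * pi / 180))
})

test_that("single-pool bSSFP matches the classical closed form on resonance", {
  sp <- single_pool_model(779, 45)
  tr <- 5
  alpha <- 10 * pi / 180
  e1 <- exp(-tr / 779)
  e2 <- exp(-tr / 45)
  cf <- sin(alpha) * (1 - e1) / (1 - (e1 - e2) * cos(alpha) - e1 * e2) *
    exp(-(tr / 2) / 45)
  expect_equal(bssfp_steady_state(sp, tr, alpha, psi = 0)$signal, cf,
               tolerance = 1e-12)
})

test_that("MT bSSFP solver agrees with the reduced on-resonance closed form", {
  tr <- 5
  alpha <- 10 * pi / 180
  for (nm in c("wm_mt", "cn_mt")) {
    m <- tissue_preset(nm)
    expect_equal(bssfp_steady_state(m, tr, alpha, psi = 0)$signal,
                 mt_bssfp_analytic(m, tr, alpha), tolerance = 1e-12)
  }
})

test_that("bSSFP profile asymmetry appears iff the pool-b offset is nonzero", {
  tr <- 5
  alpha <- 10 * pi / 180
  psi <- seq(-3, 3, length.out = 13)
  prof <- function(m) {
    vapply(psi, function(p) bssfp_steady_state(m, tr, alpha, psi = p)$signal,
           numeric(1))
  }
  sym <- prof(tissue_preset("myelin_bm"))
  asym <- prof(tissue_preset("myelin_bm", delta_b = 12.8))
  expect_equal(sym, rev(sym), tolerance = 1e-12)
  expect_gt(max(abs(asym - rev(asym))), 0.01)
})

test_that("converged bSSFP profiles match the direct solver on a psi grid", {
  tr <- 5
  alpha <- 10 * pi / 180
  for (nm in c("single_wm", "wm_mt")) {
    m <- tissue_preset(nm)
    pr <- bssfp_profile(m, tr, alpha, n_psi = 16)
    ss <- vapply(pr$psi, function(p) {
      bssfp_steady_state(m, tr, alpha, psi = p)$signal
    }, numeric(1))
    expect_lt(max(abs(Mod(pr$signal) - ss) / ss), 1e-3)
  }
})
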