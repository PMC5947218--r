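test_that("EPG-X reduces to the textbook single-pool EPG", {
  sp <- single_pool_model(779, 45)
  train <- spgr_sequence(tr = 5, alpha = 10 * pi / 180, phi0 = 117 * pi / 180,
                         n_pulses = 150)
  sig <- simulate_train(sp, train)$signal
  ref <- epg_single_reference(779, 45, 1, train$flips, train$phases, 5)
  expect_lt(max(Mod(sig - ref)), 1e-12)
})

test_that("non-exchanging BM pools equal the weighted sum of two single-pool EPGs", {
  m <- epgx_bm_model(1000, 500, 100, 20, ka = 0, f = 0.2)
  train <- spgr_sequence(n_pulses = 120)
  sig <- simulate_train(m, train)$signal
  ra <- epg_single_reference(1000, 100, 0.8, train$flips, train$phases, 5)
  rb <- epg_single_reference(500, 20, 0.2, train$flips, train$phases, 5)
  expect_lt(max(Mod(sig - (ra + rb))), 1e-10)
})

test_that("quadratic spoiling phases follow phi0 j (j + 1) / 2", {
  tr <- spgr_sequence(phi0 = 117 * pi / 180, n_pulses = 3)
  expect_equal(tr$phases * 180 / pi, c(0, 117, 351))
  expect_equal(spgr_sequence(phi0 = 0, n_pulses = 5)$phases, rep(0, 5))
})

test_that("different spoiling increments give visibly different transients", {
  bsa <- epgx_mt_model(1763, 363, 92, 12, ka = 6.2, f = 0.1, g0 = 29.4)
  s150 <- simulate_train(bsa, mrf_train(phi0 = 150 * pi / 180))$signal
  s117 <- simulate_train(bsa, mrf_train(phi0 = 117 * pi / 180))$signal
  expect_gt(max(abs(Mod(s150) - Mod(s117))) / max(Mod(s150)), 0.05)
})

test_that("bSSFP trains alternate phase and do not dephase", {
  tr <- bssfp_sequence(n_pulses = 6)
  expect_equal(tr$phases, rep(c(0, pi), 3))
  expect_equal(tr$dephasing_cycles, 0L)
})

test_that("ideal CPMG of a single pool is a pure T2 decay", {
  e <- simulate_cpmg(single_pool_model(1000, 100), n_echoes = 20, esp = 5)
  expect_equal(e$echoes, exp(-e$echo_times / 100), tolerance = 1e-12)
})

test_that("non-exchanging CPMG echoes are bi-exponential", {
  m <- epgx_bm_model(1000, 500, 100, 20, ka = 0, f = 0.2)
  e <- simulate_cpmg(m, n_echoes = 50, esp = 5)
  th <- 0.8 * exp(-e$echo_times / 100) + 0.2 * exp(-e$echo_times / 20)
  expect_equal(e$echoes, th, tolerance = 1e-12)
})

test_that("fingerprinting train has the stated structure", {
  tr <- mrf_train()
  expect_length(tr$flips, 257)                    # inversion + 256
  expect_equal(tr$flips[1], pi)
  expect_equal(tr$energies[1], 433)
  lv <- sort(unique(round(tr$flips[-1], 10)))
  expect_equal(length(lv), 16)                    # 16 levels including zero
  expect_equal(lv[1], 0)
  expect_equal(tr$energies[-1], 54.3 * tr$flips[-1]^2, tolerance = 1e-12)
})

test_that("zero-flip intervals still relax and shift the states", {
  wm <- wm_mt_fixture()
  tr <- pulse_train(flips = c(pi / 2, 0, 0), tr = 12, dephasing_cycles = 1)
  s <- simulate_train(wm, tr)
  # longitudinal keeps recovering through the zero-flip TRs
  expect_gt(Re(s$z0_a[3]), Re(s$z0_a[2]))
  # transverse created by the excitation has moved to higher orders
  expect_equal(Mod(s$signal[2]), 0, tolerance = 1e-14)
})

test_that("MT and observed-T1 single-pool transients diverge most after inversion", {
  wm <- wm_mt_fixture()
  sp <- single_pool_model(t1_observed(wm), wm$t2a)
  tr <- mrf_train()
  s_mt <- Mod(simulate_train(wm, tr)$signal) / (1 - wm$f)
  s_sp <- Mod(simulate_train(sp, tr)$signal)
  rel <- abs(s_mt - s_sp) / max(s_sp)
  expect_lt(which.max(rel[-1]), length(rel) / 4)
})

test_that("signal never exceeds equilibrium and energy decays without recovery", {
  my <- myelin_fixture()
  tr <- spgr_sequence(n_pulses = 300)
  s <- simulate_train(my, tr)
  expect_true(all(Mod(s$signal) <= my$m0 + 1e-12))
  # with the recovery term zeroed the total state norm is non-increasing
  st <- epgx_state(my, 50)
  st <- epgx:::state_rf(st, pi / 3, 0.2)
  prop <- relaxation_exchange(my, 5)
  prop$recovery <- c(0, 0)
  norms <- numeric(40)
  for (i in 1:40) {
    st <- epgx:::shift_once(epgx:::state_relax(st, prop))
    norms[i] <- sum(Mod(st$fplus_a)^2 + Mod(st$fminus_a)^2 + Mod(st$z_a)^2 +
                    Mod(st$fplus_b)^2 + Mod(st$fminus_b)^2 + Mod(st$z_b)^2)
  }
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("transient signals converge to a steady state by 5 T1", {
  for (nm in c("single_wm", "wm_mt", "myelin_bm")) {
    m <- tissue_preset(nm)
    n <- ceiling(5 * t1_observed(m) / 5)
    s <- Mod(simulate_train(m, spgr_sequence(n_pulses = n))$signal)
    expect_lt(abs(s[n] - s[n - 1]) / s[n], 1e-8)
  }
})

test_that("order-0 conjugate symmetry holds throughout a simulation", {
  my <- myelin_fixture(delta_b = 12.8)
  tr <- spgr_sequence(n_pulses = 60)
  st <- epgx_state(my, 70)
  prop <- relaxation_exchange(my, tr$tr)
  for (j in 1:60) {
    st <- epgx:::state_rf(st, tr$flips[j], tr$phases[j])
    expect_lt(Mod(st$fminus_a[1] - Conj(st$fplus_a[1])), 1e-12)
    expect_lt(Mod(st$fminus_b[1] - Conj(st$fplus_b[1])), 1e-12)
    st <- epgx:::shift_once(epgx:::state_relax(st, prop))
  }
})

test_that("diffusion attenuation has the constant-gradient order dependence", {
  my <- myelin_fixture()
  st <- epgx_state(my, 6)
  st$fplus_a[1:5] <- 1 + 0i
  st$z_a[1:5] <- 0.5 + 0i
  sp <- diffusion_spec(0)
  expect_equal(apply_diffusion(st, sp, 5), st)     # D = 0 is the identity
  sp <- diffusion_spec(2.35e-3)
  st2 <- apply_diffusion(st, sp, 5)
  expect_equal(st2$z_a[1], st$z_a[1])              # n = 0 longitudinal intact
  att_f <- Mod(st2$fplus_a[1:5]) / Mod(st$fplus_a[1:5])
  att_z <- Mod(st2$z_a[2:5]) / Mod(st$z_a[2:5])
  expect_true(all(diff(att_f) < 0))                # higher orders decay more
  expect_true(all(diff(att_z) < 0))
  # b-factor oracle: attenuation is exp(-D k^2 dt ((n + 1/2)^2 + 1/12))
  n <- 0:4
  b <- 2.35e-3 * 1e-3 * (2 * pi / 1.5)^2 * 5 * ((n + 0.5)^2 + 1 / 12)
  expect_equal(att_f, exp(-b), tolerance = 1e-12)
})

test_that("multislice TSE reduces to plain TSE for one slice and spares CSF", {
  wm <- wm_mt_fixture()
  one <- multislice_tse(wm, n_slices = 1)
  expect_length(one$echoes, 25)
  csf <- tissue_preset("csf")
  expect_equal(multislice_tse(csf, n_slices = 15)$mean_echo,
               multislice_tse(csf, n_slices = 1)$mean_echo, tolerance = 1e-12)
  expect_error(multislice_tse(wm, n_slices = 4), "odd")
})
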