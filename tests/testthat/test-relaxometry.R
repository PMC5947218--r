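test_that("NNLS spectrum recovers mono- and bi-exponential inputs", {
  t <- 5 * (1:50)
  sp1 <- nnls_t2_spectrum(exp(-t / 100), t)
  expect_equal(sp1$f_hat, 0)
  expect_equal(sp1$t2b_hat, 100, tolerance = 0.05)
  sp2 <- nnls_t2_spectrum(0.8 * exp(-t / 100) + 0.2 * exp(-t / 20), t)
  expect_equal(sp2$f_hat, 0.2, tolerance = 0.005)
  expect_equal(sp2$t2b_hat, 20, tolerance = 0.5)
})

test_that("NNLS solution satisfies the KKT conditions", {
  my <- myelin_fixture()
  ec <- simulate_cpmg(my, 50, 5, 1.1)
  sp <- nnls_t2_spectrum(ec$echoes, ec$echo_times)
  A <- exp(-outer(ec$echo_times, sp$t2_grid, "/"))
  grad <- t(A) %*% (ec$echoes - A %*% sp$amplitudes)
  expect_lt(max(abs(grad[sp$amplitudes > 0])), 1e-8)   # active set
  expect_lt(max(grad), 1e-8)                           # dual feasibility
  expect_true(all(sp$amplitudes >= 0))
  expect_error(nnls_t2_spectrum(rep(0, 50), t), "empty spectrum")
})

test_that("estimates are insensitive to the T2 grid density", {
  my <- myelin_fixture()
  ec <- simulate_cpmg(my, 50, 5, 1.1)
  f80 <- nnls_t2_spectrum(ec$echoes, ec$echo_times,
                          t2_grid = epgx:::logseq(5, 2000, 80))$f_hat
  f200 <- nnls_t2_spectrum(ec$echoes, ec$echo_times,
                           t2_grid = epgx:::logseq(5, 2000, 200))$f_hat
  expect_lt(abs(f80 - f200), 0.01)
})

test_that("bias surface: exchange depresses f_hat, B1 drives t2b_hat", {
  my <- myelin_fixture()
  grid <- bias_surface(my, ka_values = c(0, 1, 2),
                       b1_values = c(0.75, 1, 1.25))
  b1_1 <- grid[grid$b1 == 1, ]
  expect_equal(b1_1$f_hat[b1_1$ka == 0], 0.2, tolerance = 0.01)
  expect_true(all(diff(b1_1$f_hat[order(b1_1$ka)]) < 0))   # monotone in ka
  # across the transmit-field range, t2b_hat moves more with B1 than with ka
  # (0.75 vs 1.0: the 0.75/1.25 pair gives identical refocusing by symmetry)
  d_b1 <- abs(mean(grid$t2b_hat[grid$b1 == 0.75]) -
                mean(grid$t2b_hat[grid$b1 == 1]))
  d_ka <- abs(mean(grid$t2b_hat[grid$ka == 2]) -
                mean(grid$t2b_hat[grid$ka == 0]))
  expect_gt(d_b1, d_ka)
})

test_that("f_hat responds to the pool-b frequency offset", {
  my <- myelin_fixture()
  grid <- bias_surface(my, ka_values = 2, b1_values = 1,
                       deltab_values = c(-128, 0, 128))
  expect_gt(diff(range(grid$f_hat)), 0.002)
})

test_that("synthetic signals are exact at infinite SNR and seeded otherwise", {
  wm <- wm_mt_fixture()
  tr <- mrf_train(n_pulses = 64)
  clean <- simulate_train(wm, tr)$signal
  s_inf <- synth_signal(wm, tr, snr = Inf)
  expect_identical(s_inf$signal, clean)
  s1 <- synth_signal(wm, tr, snr = 50, seed = 1)
  s2 <- synth_signal(wm, tr, snr = 50, seed = 1)
  s3 <- synth_signal(wm, tr, snr = 50, seed = 2)
  expect_identical(s1$signal, s2$signal)
  expect_gt(max(Mod(s1$signal - s3$signal)), 0)
  # CLT check: the mean of many seeded realizations stays within 3 standard
  # errors of the noiseless signal
  reps <- vapply(1:200, function(sd) {
    Re(synth_signal(wm, tr, snr = 20, seed = sd)$signal[10])
  }, numeric(1))
  sigma <- mean(Mod(clean)) / 20
  expect_lt(abs(mean(reps) - Re(clean[10])), 3 * sigma / sqrt(200))
})

test_that("noiseless self-consistency fit recovers the generating parameters", {
  truth <- epgx_mt_model(t1a = 1763, t1b = 363, t2a = 92, t2b_us = 12,
                         ka = 6.2, f = 0.100, g0 = 29.4)
  tr150 <- mrf_train(n_pulses = 128, phi0 = 150 * pi / 180)
  tr117 <- mrf_train(n_pulses = 128, phi0 = 117 * pi / 180)
  te <- 2.9
  s1 <- Mod(simulate_train(truth, tr150, te = te)$signal)
  s2 <- Mod(simulate_train(truth, tr117, te = te)$signal)
  fit <- fit_epgx_mt(list(s1, s2), list(tr150, tr117),
                     fixed = list(t2a = 92, scale = 1),
                     t1obs_measured = t1_observed(truth),
                     n_starts = 1, te = te)
  tv <- c(ka = 6.2, t1a = 1763, t1b = 363, f = 0.1, g0 = 29.4)
  expect_lt(max(abs(fit$par - tv) / tv), 0.02)
  expect_lt(fit$rmsd, 0.1)
  expect_equal(fit$t1obs_implied, t1_observed(truth), tolerance = 1e-10)
})

test_that("t1a elimination inverts the observed-T1 relation", {
  truth <- epgx_mt_model(1763, 363, 92, 12, ka = 6.2, f = 0.1)
  expect_equal(t1a_from_observed(6.2, 363, 0.1, t1_observed(truth)), 1763,
               tolerance = 1e-9)
  expect_true(is.na(t1a_from_observed(6.2, 363, 0.1, 1e6)))
})
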