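test_that("kinetic trace generator evaluates the exponential exactly and is seed-deterministic", {
  tr <- gen_kinetic_trace("dissociation", times = c(0, 10), k_off = 0.1,
                          amplitude = 100, baseline = 0, noise_sd = 0)
  expect_equal(tr$signal[1], 100)              # baseline + amplitude at t = 0
  expect_equal(tr$signal[2], 100 * exp(-1), tolerance = 1e-12)

  a <- gen_kinetic_trace("dissociation", times = 0:50, k_off = 0.1,
                         noise_sd = 2, seed = 7L)
  b <- gen_kinetic_trace("dissociation", times = 0:50, k_off = 0.1,
                         noise_sd = 2, seed = 7L)
  expect_identical(a$signal, b$signal)
  c <- gen_kinetic_trace("dissociation", times = 0:50, k_off = 0.1,
                         noise_sd = 2, seed = 8L)
  expect_false(identical(a$signal, c$signal))

  # association: initial slope equals v0
  v0 <- 2
  tr2 <- gen_kinetic_trace("association", times = seq(0, 1e-3, length.out = 5),
                           v0 = v0, plateau = 50, noise_sd = 0)
  slope <- diff(tr2$signal[1:2]) / diff(tr2$times[1:2])
  expect_equal(slope, v0, tolerance = 1e-5)

  expect_error(gen_kinetic_trace("dissociation", times = 0:10, k_off = -1),
               class = "mhc2x_invalid_parameter")
  expect_error(gen_kinetic_trace("dissociation", times = numeric(0), k_off = 1),
               class = "mhc2x_invalid_parameter")
})

test_that("melt curve generator hits sigmoid hand values", {
  mc <- gen_melt_curve(c(50, 70, 72, 90), tm = 70, slope = 2, lower = 0,
                       upper = 1, noise_sd = 0)
  expect_equal(mc$fluorescence[2], 0.5)                    # midpoint at tm
  expect_equal(mc$fluorescence[3], 1 / (1 + exp(-1)), tolerance = 1e-12)
  flat <- gen_melt_curve(seq(25, 95, 5), tm = 70, slope = 2, lower = 0.4,
                         upper = 0.4, noise_sd = 0)
  expect_true(all(flat$fluorescence == 0.4))               # equal plateaus
  expect_error(gen_melt_curve(seq(25, 95, 5), tm = 70, slope = 0),
               class = "mhc2x_invalid_parameter")
})

test_that("isotherm generator solves the ligand-depletion quadratic", {
  iso <- gen_isotherm(c(100), kd = 100, probe_conc = 100, noise_sd = 0)
  expect_equal(iso$fraction_bound,
               ((300 - sqrt(300^2 - 4 * 100 * 100)) / 2) / 100,
               tolerance = 1e-12)
  # saturation and zero-receptor limits
  lim <- gen_isotherm(c(1e-9, 1e9), kd = 100, probe_conc = 100, noise_sd = 0)
  expect_equal(lim$fraction_bound[1], 0, tolerance = 1e-8)
  expect_equal(lim$fraction_bound[2], 1, tolerance = 1e-4)
})

test_that("CPMG generator matches the Luz-Meiboom closed form and limits", {
  cp <- gen_cpmg_profile(c(250), r2_0 = 10, phi = 1e4, kex = 1e3, noise_sd = 0)
  expect_equal(cp$r2eff, 10 + 10 * (1 - tanh(1)), tolerance = 1e-12)
  lims <- gen_cpmg_profile(c(1e-4, 1e7), r2_0 = 10, phi = 1e4, kex = 1e3,
                           noise_sd = 0)
  expect_equal(lims$r2eff[1], 10 + 1e4 / 1e3, tolerance = 1e-3)  # nu -> 0
  expect_equal(lims$r2eff[2], 10, tolerance = 1e-3)              # nu -> Inf
  # 0 Hz treated as reference, excluded
  cp0 <- gen_cpmg_profile(c(0, 100, 200), r2_0 = 10, phi = 1e4, kex = 1e3)
  expect_equal(cp0$freqs, c(100, 200))
  expect_error(gen_cpmg_profile(c(100), r2_0 = 10, phi = 1e4, kex = 0),
               class = "mhc2x_invalid_parameter")
})

test_that("Markov trajectory sampling converges to the stationary law", {
  T <- matrix(c(0.9, 0.1, 0.05, 0.95), 2, byrow = TRUE)
  # analytic stationary vector is (1/3, 2/3)
  dt <- gen_markov_trajectories(T, n_steps = 2e5, n_traj = 1L, seed = 11L)
  freq1 <- mean(dt$dtrajs[[1]] == 1L)
  expect_equal(freq1, 1 / 3, tolerance = 0.02)
  # empirical transition counts converge row-wise to n * T
  x <- dt$dtrajs[[1]]
  from1 <- x[-length(x)] == 1L
  p11 <- mean(x[-1][from1] == 1L)
  expect_equal(p11, 0.9, tolerance = 0.02)
  # identity chain stays put
  id <- gen_markov_trajectories(diag(2), n_steps = 100, seed = 1L, start = 1L)
  expect_true(all(id$dtrajs[[1]] == 1L))
  expect_identical(gen_markov_trajectories(T, 1000, seed = 3L)$dtrajs,
                   gen_markov_trajectories(T, 1000, seed = 3L)$dtrajs)
  expect_error(gen_markov_trajectories(matrix(c(1, 1, 0, 1), 2), 10),
               class = "mhc2x_invalid_parameter")
})

test_that("feature trajectory emits hidden states at the centers", {
  T <- metropolis_T(c(0.3, 0.7))
  centers <- matrix(c(0, 5), 2, 1)
  ft <- gen_feature_trajectory(T, centers, emission_sd = 0, fast_noise_dims = 0,
                               n_steps = 500, seed = 2L)
  expect_equal(ft$features[, 1], centers[ft$hidden, 1])
  expect_error(gen_feature_trajectory(matrix(1, 1, 1), matrix(0, 1, 1)),
               class = "mhc2x_invalid_parameter")
})

test_that("alignment generator reproduces column profiles", {
  point <- c(1, rep(0, 19))                       # all Ala
  even <- c(0.5, 0.5, rep(0, 18))                 # A/C 50:50
  aln <- gen_alignment(list(point, even), n_seqs = 1000, seed = 5L)
  m <- do.call(rbind, strsplit(aln$sequences, ""))
  expect_true(all(m[, 1] == "A"))
  expect_equal(mean(m[, 2] == "A"), 0.5, tolerance = 0.05)
  expect_identical(gen_alignment(list(even), 50, seed = 9L)$sequences,
                   gen_alignment(list(even), 50, seed = 9L)$sequences)
  expect_error(gen_alignment(list(rep(0.1, 20)), 10),
               class = "mhc2x_invalid_parameter")
})
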