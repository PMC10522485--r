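test_that("pair-distance featurization selects by radius and reproduces motion", {
  # 3 atoms on a line: res 1 at 0, res 2 at 5, res 3 at 30 (outside radius)
  ref <- rbind(c(0, 0, 0), c(5, 0, 0), c(30, 0, 0))
  frames <- 20
  coords <- array(NA_real_, c(frames, 3, 3))
  d_t <- 5 + sin(seq_len(frames) / 3)        # breathing distance
  for (f in seq_len(frames)) {
    coords[f, , ] <- rbind(c(0, 0, 0), c(d_t[f], 0, 0), c(30, 0, 0))
  }
  ft <- extract_pair_distances(coords, ref, residue_ids = 1:3,
                               anchor_residue = 1, radius = 15)
  expect_equal(ncol(ft$features), 1L)          # m = 2 atoms -> 1 pair
  expect_equal(ft$features[, 1], d_t)
  # two static atoms 5 A apart -> constant feature 5.0
  static <- array(rep(t(ref), frames), c(3, 3, frames))
  static <- aperm(static, c(3, 2, 1))   # frames x atoms x 3
  for (f in seq_len(frames)) static[f, , ] <- ref
  ft2 <- extract_pair_distances(static, ref, 1:3, anchor_residue = 1,
                                radius = 15)
  expect_true(all(ft2$features[, 1] == 5))
  expect_error(extract_pair_distances(coords, ref, 1:3, anchor_residue = 99),
               class = "mhc2x_invalid_parameter")
  # combinatorics: all 3 atoms -> 3 pairs
  ft3 <- extract_pair_distances(coords, ref, 1:3, 1, radius = 100)
  expect_equal(ncol(ft3$features), 3L)
})

test_that("TICA isolates the slow axis of a hidden two-state process", {
  T2 <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE)
  centers <- matrix(c(0, 4), 2, 1)
  ft <- gen_feature_trajectory(T2, centers, emission_sd = 0.2,
                               fast_noise_dims = 3L, n_steps = 20000,
                               seed = 21L)
  lag <- 2
  out <- tica(ft, lag = lag, n_components = 2)
  # slow axis is feature 1; first TIC should align with it
  v <- out$components[, 1]
  cosang <- abs(v[1]) / sqrt(sum(v^2))
  expect_gt(cosang, 0.99)
  # eigenvalue approximates the chain autocorrelation exp(-lag/t_relax)
  lambda2 <- 0.9                         # second eigenvalue of T2
  expect_equal(out$eigenvalues[1], lambda2^lag, tolerance = 0.05)
})

test_that("TICA on white noise gives near-zero eigenvalues; duplicated columns are harmless", {
  set.seed(31)
  X <- matrix(rnorm(20000 * 4), 20000, 4)
  out <- tica(X, lag = 1)
  expect_true(all(abs(out$eigenvalues) < 3 / sqrt(20000)))

  Xdup <- cbind(X, X[, 1])               # perfectly correlated extra column
  out2 <- tica(Xdup, lag = 1, n_components = 2)
  p1 <- tica(X, lag = 1, n_components = 2)$projections[[1]]
  p2 <- out2$projections[[1]]
  # projections agree up to sign
  for (j in 1:2) {
    expect_equal(abs(cor(p1[, j], p2[, j])), 1, tolerance = 1e-6)
  }
})

test_that("microstate clustering separates blobs and is seed-deterministic", {
  set.seed(12)
  blob1 <- matrix(rnorm(600, 0, 0.3), ncol = 2)
  blob2 <- matrix(rnorm(600, 0, 0.3), ncol = 2) + 10
  X <- rbind(blob1, blob2)
  dt <- cluster_microstates(X, k = 2, seed = 5L)
  lab <- dt$dtrajs[[1]]
  truth <- rep(1:2, each = 300)
  agree <- max(mean(lab == truth), mean(lab == 3 - truth))
  expect_gt(agree, 0.99)

  one <- cluster_microstates(X, k = 1, seed = 5L)
  expect_true(all(one$dtrajs[[1]] == 1L))
  expect_equal(as.numeric(one$centers), colMeans(X))

  expect_identical(cluster_microstates(X, 5, seed = 9L)$dtrajs,
                   cluster_microstates(X, 5, seed = 9L)$dtrajs)
  expect_error(cluster_microstates(X[1:3, ], k = 10),
               class = "mhc2x_invalid_parameter")
})

test_that("MSM estimation: alternating chain, analytic chain, connectivity", {
  alt <- list(rep(c(1L, 2L), 50))
  m <- estimate_msm(alt, lag = 1)
  expect_equal(m$T, matrix(c(0, 1, 1, 0), 2), tolerance = 1e-10)
  expect_equal(m$pi, c(0.5, 0.5), tolerance = 1e-10)

  T_true <- matrix(c(0.9, 0.1, 0.05, 0.95), 2, byrow = TRUE)
  dt <- gen_markov_trajectories(T_true, n_steps = 5e5, n_traj = 2, seed = 13L)
  m2 <- estimate_msm(dt, lag = 1)
  expect_true(all(abs(m2$T - T_true) < 0.005))
  expect_true(all(abs(m2$pi - c(1 / 3, 2 / 3)) < 0.01))

  # trajectory never leaving state 1 with 2 states declared
  stuck <- structure(list(dtrajs = list(rep(1L, 50)), n_states = 2L,
                          stride = 1), class = "dtraj_set")
  expect_warning(ms <- estimate_msm(stuck, lag = 1), "connected")
  expect_equal(ms$active, 1L)
})

test_that("estimated transition matrices satisfy the MSM invariants", {
  set.seed(17)
  for (rep_i in 1:5) {
    w <- runif(3); w <- w / sum(w)
    dt <- gen_markov_trajectories(block_T(w, eps = 0.05), n_steps = 20000,
                                  n_traj = 2, seed = 100L + rep_i)
    m <- suppressWarnings(estimate_msm(dt, lag = 1))
    expect_true(all(m$T >= 0))
    expect_true(all(abs(rowSums(m$T) - 1) < 1e-10))
    db <- outer(m$pi, rep(1, length(m$pi))) * m$T
    expect_true(max(abs(db - t(db))) < 1e-8)      # detailed balance
    expect_equal(sum(m$pi), 1, tolerance = 1e-12)
  }
})

test_that("implied timescales are approximately lag-independent on Markovian data", {
  T_true <- metropolis_T(c(0.2, 0.8), proposal = 0.3)
  # relaxation time of the 2-state chain
  lam2 <- sort(eigen(T_true, only.values = TRUE)$values)[1]
  t_mix <- -1 / log(abs(lam2))
  dt <- gen_markov_trajectories(T_true, n_steps = 4e5, n_traj = 2, seed = 23L)
  its <- vapply(c(1, 2, 3), function(l) {
    estimate_msm(dt, lag = l)$implied_timescales[1]
  }, 1)
  expect_true(all(abs(its - its[1]) / its[1] < 0.1))
})

test_that("PCCA+ resolves block structure, identity limit and tie rule", {
  # 2-block 4-microstate matrix with weak leakage
  T4 <- matrix(c(0.98, 0.0199, 1e-4, 0,
                 0.0199, 0.98, 0, 1e-4,
                 1e-4, 0, 0.98, 0.0199,
                 0, 1e-4, 0.0199, 0.98), 4, byrow = TRUE)
  T4 <- T4 / rowSums(T4)
  dt <- gen_markov_trajectories(T4, n_steps = 1e5, n_traj = 2, seed = 19L)
  m <- estimate_msm(dt, lag = 1)
  pc <- pcca(m, 2)
  expect_true(all(abs(rowSums(pc$memberships) - 1) < 1e-8))
  top <- apply(pc$memberships, 1, max)
  expect_true(all(top > 0.99))
  # the two blocks land in different metastable states
  asg <- pc$assignment[order(m$active)]
  expect_equal(length(unique(asg[1:2])), 1L)
  expect_equal(length(unique(asg[3:4])), 1L)
  expect_false(asg[1] == asg[3])

  # n_metastable = n microstates -> identity-like memberships
  pid <- pcca(m, length(m$active))
  expect_true(all(apply(pid$memberships, 1, max) > 0.95))

  # 50/50 membership is unassigned under the strict > cutoff rule
  fake <- structure(list(memberships = matrix(0.5, 1, 2),
                         assignment = NA_integer_, n_metastable = 2L,
                         crisp_cutoff = 0.5), class = "metastable_model")
  expect_true(is.na(fake$assignment))
  expect_error(pcca(m, 1), class = "mhc2x_invalid_parameter")
})

test_that("metastable thermodynamics reproduces -RT log population ratios", {
  # build a crisp metastable model by hand on 3 microstates
  msm <- structure(list(T = diag(3), pi = c(0.90, 0.08, 0.02),
                        active = 1:3, lag = 1, frame_time = 1),
                   class = "msm_result")
  meta <- structure(list(assignment = 1:3, n_metastable = 3L,
                         memberships = diag(3), crisp_cutoff = 0.5),
                    class = "metastable_model")
  th <- metastable_thermo(msm, meta, temperature = 300)
  expect_equal(th$reference, 1L)
  expect_equal(th$free_energies, c(0, 6.04, 9.49), tolerance = 1e-3)
  # ordering of G inverse to ordering of populations
  expect_equal(order(th$populations), rev(order(th$free_energies)))
  # equal populations -> all zero
  msm$pi <- rep(1 / 3, 3)
  th0 <- metastable_thermo(msm, meta, 300)
  expect_true(all(th0$free_energies == 0))
})

test_that("metastable rates equal inverse MFPTs with the analytic 2-state value", {
  T2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  msm <- structure(list(T = T2, pi = stationary_distribution(T2),
                        active = 1:2, lag = 1, frame_time = 1),
                   class = "msm_result")
  meta <- structure(list(assignment = 1:2, n_metastable = 2L,
                         memberships = diag(2), crisp_cutoff = 0.5),
                    class = "metastable_model")
  r <- metastable_rates(msm, meta)
  expect_equal(r[1, 2], 0.1, tolerance = 1e-12)    # MFPT = 1/T12 = 10
  expect_equal(r[2, 1], 0.2, tolerance = 1e-12)

  # symmetric chain: equal rates both ways
  Ts <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  msm$T <- Ts; msm$pi <- c(0.5, 0.5)
  rs <- metastable_rates(msm, meta)
  expect_equal(rs[1, 2], rs[2, 1])

  # coarse detailed balance pop(A) r(A->B) ~ pop(B) r(B->A)
  Tb <- metropolis_T(c(0.25, 0.75), proposal = 0.1)
  msm$T <- Tb; msm$pi <- stationary_distribution(Tb)
  rb <- metastable_rates(msm, meta)
  expect_equal(msm$pi[1] * rb[1, 2], msm$pi[2] * rb[2, 1], tolerance = 0.05)
})

test_that("end-to-end synthetic pipeline recovers hidden populations and energies", {
  pops_true <- c(0.08, 0.05, 0.87)
  Th <- metropolis_T(pops_true)
  centers <- matrix(c(0, 0, 4, 0, 2, 3.5), 3, 2, byrow = TRUE)
  fts <- lapply(1:6, function(k) {
    gen_feature_trajectory(Th, centers, emission_sd = 0.35,
                           fast_noise_dims = 3L, n_steps = 4000,
                           seed = 500L + k)
  })
  tic <- tica(fts, lag = 5, n_components = 2)
  dtr <- cluster_microstates(tic$projections, k = 40, seed = 7L)
  m <- suppressWarnings(estimate_msm(dtr, lag = 5))
  meta <- pcca(m, 3)
  th <- metastable_thermo(m, meta, temperature = 300)
  expect_equal(sort(th$populations), sort(pops_true), tolerance = 0.02)
  rt <- 8.314462618e-3 * 300
  g_true <- -rt * log(sort(pops_true, decreasing = TRUE) / max(pops_true))
  g_est <- sort(th$free_energies)
  expect_true(all(abs(g_est - g_true) < 0.3))
})

test_that("bootstrap CIs behave: degenerate resampling, determinism", {
  T_true <- block_T(c(0.15, 0.25, 0.6), eps = 0.05)
  one <- gen_markov_trajectories(T_true, n_steps = 5000, n_traj = 1,
                                 seed = 3L)$dtrajs[[1]]
  dup <- structure(list(dtrajs = rep(list(one), 10), n_states = 6L,
                        stride = 1), class = "dtraj_set")
  bs <- bootstrap_msm(dup, lag = 1, n_metastable = 3, n_boot = 15, seed = 2L)
  expect_true(all(bs$population_sd < 1e-12))    # identical replicates

  dt <- gen_markov_trajectories(T_true, n_steps = 3000, n_traj = 8, seed = 4L)
  b1 <- bootstrap_msm(dt, 1, 3, n_boot = 20, seed = 6L)
  b2 <- bootstrap_msm(dt, 1, 3, n_boot = 20, seed = 6L)
  expect_identical(b1$population_sd, b2$population_sd)
  expect_true(all(b1$population_sd > 0))
  expect_error(bootstrap_msm(dup$dtrajs[1], 1, 3),
               class = "mhc2x_insufficient_data")
})
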