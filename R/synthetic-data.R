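# Synthetic-data generators. Every downstream stage of the pipeline can be
# exercised on data from these functions, with ground-truth parameters known
# exactly. All generators draw from a private seeded RNG stream (see
# with_seed()) and are bit-reproducible.

#' Simulate a fluorescence-polarization kinetic trace
#'
#' Dissociation traces follow `baseline + amplitude * exp(-k_off * t)`;
#' association traces a saturating exponential rise
#' `baseline + plateau * (1 - exp(-(v0/plateau) * t))` whose initial slope is
#' exactly `v0`. Gaussian i.i.d. noise of standard deviation `noise_sd` is
#' added, emulating plate-reader replicate scatter.
#'
#' @param mode `"dissociation"` or `"association"`.
#' @param times time grid in minutes, strictly increasing and nonnegative.
#' @param k_off dissociation rate constant, per minute (dissociation mode).
#' @param v0 initial association velocity, polarization units per minute
#'   (association mode).
#' @param amplitude signal span above baseline (dissociation) in
#'   polarization units.
#' @param plateau final rise above baseline (association).
#' @param baseline signal offset.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer seed for the private RNG stream.
#' @param allotype,dm_conc,temperature assay metadata carried on the trace:
#'   allotype label, DM concentration in uM, temperature in degrees C.
#' @return A `kinetic_trace` object: list with `times`, `signal`, `mode`,
#'   `allotype`, `dm_conc`, `temperature`.
#' @examples
#' tr <- gen_kinetic_trace("dissociation", times = 0:60, k_off = 0.1, seed = 1)
#' @export
gen_kinetic_trace <- function(mode = c("dissociation", "association"),
                              times,
                              k_off = NULL, v0 = NULL,
                              amplitude = 100, plateau = 100, baseline = 0,
                              noise_sd = 0, seed = 1L,
                              allotype = NA_character_, dm_conc = 0,
                              temperature = 37) {
  mode <- match.arg(mode)
  if (length(times) < 1L || any(diff(times) <= 0) || any(times < 0)) {
    invalid_parameter("`times` must be a nonempty, nonnegative, strictly increasing grid")
  }
  if (noise_sd < 0) invalid_parameter("`noise_sd` must be nonnegative")
  if (mode == "dissociation") {
    stopifnot_positive(k_off, "k_off")
    stopifnot_positive(amplitude, "amplitude")
    mean_signal <- baseline + amplitude * exp(-k_off * times)
  } else {
    stopifnot_positive(v0, "v0")
    stopifnot_positive(plateau, "plateau")
    mean_signal <- baseline + plateau * (1 - exp(-(v0 / plateau) * times))
  }
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(times), sd = noise_sd))
  } else {
    numeric(length(times))
  }
  structure(
    list(times = as.numeric(times), signal = mean_signal + noise,
         mode = mode, allotype = allotype, dm_conc = dm_conc,
         temperature = temperature),
    class = "kinetic_trace"
  )
}

#' Simulate a thermal-shift melting curve
#'
#' Four-parameter Boltzmann sigmoid
#' `lower + (upper - lower) / (1 + exp((tm - T)/slope))` evaluated on the
#' temperature grid, plus Gaussian noise.
#'
#' @param temperatures temperature grid in degrees C, increasing.
#' @param tm midpoint (melting) temperature, degrees C.
#' @param slope transition width parameter, degrees C; must be positive.
#' @param lower,upper pre- and post-transition fluorescence plateaus.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer RNG seed.
#' @param allotype label carried on the curve.
#' @return A `melt_curve` object: list with `temperatures`, `fluorescence`,
#'   `allotype`.
#' @export
gen_melt_curve <- function(temperatures, tm, slope = 2, lower = 0, upper = 1,
                           noise_sd = 0, seed = 1L, allotype = NA_character_) {
  if (any(diff(temperatures) <= 0)) {
    invalid_parameter("`temperatures` must be strictly increasing")
  }
  stopifnot_positive(slope, "slope")
  mean_f <- lower + (upper - lower) / (1 + exp((tm - temperatures) / slope))
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(temperatures), sd = noise_sd))
  } else {
    numeric(length(temperatures))
  }
  structure(
    list(temperatures = as.numeric(temperatures),
         fluorescence = mean_f + noise, allotype = allotype),
    class = "melt_curve"
  )
}

# Exact ligand-depletion bound-probe concentration for receptor R, probe L,
# dissociation constant Kd (all same units): smaller root of the binding
# quadratic.
ligand_depletion_bound <- function(R, L, kd) {
  s <- R + L + kd
  (s - sqrt(s^2 - 4 * R * L)) / 2
}

#' Simulate an equilibrium binding isotherm with ligand depletion
#'
#' Fraction of fluorescent probe bound at each receptor concentration is
#' computed from the exact (quadratic) ligand-depletion solution, so probe
#' concentrations comparable to Kd are handled correctly.
#'
#' @param receptor_concs receptor (empty MHC-II) concentrations, nM.
#' @param kd true dissociation constant, nM.
#' @param probe_conc labeled-peptide concentration, nM (fixed).
#' @param noise_sd Gaussian noise sd on fraction bound.
#' @param seed integer RNG seed.
#' @param temperature temperature in K carried as metadata.
#' @return A `binding_isotherm` object: list with `receptor_concs`,
#'   `fraction_bound`, `probe_conc`, `temperature`.
#' @export
gen_isotherm <- function(receptor_concs, kd, probe_conc = 100,
                         noise_sd = 0, seed = 1L, temperature = 298.15) {
  stopifnot_positive(kd, "kd")
  stopifnot_positive(probe_conc, "probe_conc")
  if (any(receptor_concs < 0)) {
    invalid_parameter("`receptor_concs` must be nonnegative")
  }
  frac <- ligand_depletion_bound(receptor_concs, probe_conc, kd) / probe_conc
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(frac), sd = noise_sd))
  } else {
    numeric(length(frac))
  }
  structure(
    list(receptor_concs = as.numeric(receptor_concs),
         fraction_bound = frac + noise,
         probe_conc = probe_conc, temperature = temperature),
    class = "binding_isotherm"
  )
}

# Luz-Meiboom two-site fast-exchange dispersion model.
luz_meiboom <- function(nu, r2_0, phi, kex) {
  r2_0 + (phi / kex) * (1 - (4 * nu / kex) * tanh(kex / (4 * nu)))
}

#' Simulate a CPMG relaxation-dispersion profile
#'
#' Two-site fast-exchange (Luz-Meiboom) model
#' `R2eff(nu) = R2_0 + (phi/kex) * (1 - (4 nu / kex) * tanh(kex/(4 nu)))`.
#' Entries of 0 Hz in `freqs` are reference planes and are excluded from the
#' returned curve.
#'
#' @param freqs CPMG pulse frequencies, Hz. Zero entries are dropped.
#' @param r2_0 exchange-free transverse relaxation rate, 1/s.
#' @param phi exchange amplitude parameter (pa pb dw^2), 1/s^2.
#' @param kex exchange rate, 1/s; must be positive.
#' @param t_cpmg constant-time relaxation delay, s (metadata; default 40 ms).
#' @param noise_sd Gaussian noise sd on R2eff, 1/s.
#' @param seed integer RNG seed.
#' @param id methyl-group identifier carried on the curve.
#' @return A `dispersion_curve` object: list with `freqs`, `r2eff`,
#'   `t_cpmg`, `id`.
#' @export
gen_cpmg_profile <- function(freqs, r2_0, phi, kex, t_cpmg = 0.04,
                             noise_sd = 0, seed = 1L, id = NA_character_) {
  stopifnot_positive(kex, "kex")
  if (any(freqs < 0)) invalid_parameter("`freqs` must be nonnegative")
  nu <- as.numeric(freqs[freqs > 0])
  if (length(nu) == 0L) invalid_parameter("no nonzero CPMG frequencies")
  r2 <- luz_meiboom(nu, r2_0, phi, kex)
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(nu), sd = noise_sd))
  } else {
    numeric(length(nu))
  }
  structure(
    list(freqs = nu, r2eff = r2 + noise, t_cpmg = t_cpmg, id = id),
    class = "dispersion_curve"
  )
}

#' Sample discrete trajectories from a Markov chain
#'
#' @param T row-stochastic transition matrix.
#' @param n_steps trajectory length in frames (>= 2).
#' @param n_traj number of independent trajectories.
#' @param seed integer RNG seed.
#' @param start optional fixed start state (1-based); by default start states
#'   are drawn from the stationary distribution of `T`.
#' @return A `dtraj_set` object: list with `dtrajs` (list of integer vectors,
#'   states 1..n), `n_states`, `stride`.
#' @export
gen_markov_trajectories <- function(T, n_steps, n_traj = 1L, seed = 1L,
                                    start = NULL) {
  check_row_stochastic(T)
  if (n_steps < 2) invalid_parameter("`n_steps` must be >= 2")
  n <- nrow(T)
  pi0 <- stationary_distribution(T)
  dtrajs <- with_seed(seed, {
    lapply(seq_len(n_traj), function(i) {
      x <- integer(n_steps)
      x[1L] <- if (is.null(start)) {
        sample.int(n, 1L, prob = pi0)
      } else {
        as.integer(start)
      }
      for (t in 2:n_steps) {
        x[t] <- sample.int(n, 1L, prob = T[x[t - 1L], ])
      }
      x
    })
  })
  structure(list(dtrajs = dtrajs, n_states = n, stride = 1),
            class = "dtraj_set")
}

#' Emit a hidden metastable jump process into feature space
#'
#' A hidden Markov chain on `nrow(emission_centers)` metastable states is
#' sampled from `metastable_T`; each frame emits a Gaussian around its
#' state's center, and `fast_noise_dims` additional i.i.d. standard-normal
#' columns model fast, kinetically irrelevant coordinates. The hidden state
#' sequence is returned as ground truth, so slow-mode recovery by
#' TICA/clustering/MSM can be verified exactly.
#'
#' @param metastable_T row-stochastic hidden transition matrix (>= 2 states).
#' @param emission_centers matrix, one row per hidden state, columns = slow
#'   feature dimensions; rows must be distinct.
#' @param emission_sd Gaussian emission standard deviation (> 0 unless 0 for
#'   degenerate noise-free checks).
#' @param fast_noise_dims number of appended fast-noise columns.
#' @param n_steps frames to simulate.
#' @param seed integer RNG seed.
#' @return A `feature_trajectory` object: list with `features`
#'   (n_steps x d matrix), `hidden` (integer vector), `stride`.
#' @export
gen_feature_trajectory <- function(metastable_T, emission_centers,
                                   emission_sd = 0.1, fast_noise_dims = 0L,
                                   n_steps = 1000L, seed = 1L) {
  check_row_stochastic(metastable_T)
  if (nrow(metastable_T) < 2) {
    invalid_parameter("need at least 2 metastable states")
  }
  emission_centers <- as.matrix(emission_centers)
  if (nrow(emission_centers) != nrow(metastable_T)) {
    invalid_parameter("`emission_centers` must have one row per hidden state")
  }
  if (anyDuplicated(emission_centers)) {
    invalid_parameter("`emission_centers` rows must be distinct")
  }
  if (emission_sd < 0) invalid_parameter("`emission_sd` must be >= 0")
  d_slow <- ncol(emission_centers)
  out <- with_seed(seed, {
    hidden <- integer(n_steps)
    n <- nrow(metastable_T)
    hidden[1L] <- sample.int(n, 1L, prob = stationary_distribution(metastable_T))
    for (t in 2:n_steps) {
      hidden[t] <- sample.int(n, 1L, prob = metastable_T[hidden[t - 1L], ])
    }
    slow <- emission_centers[hidden, , drop = FALSE] +
      if (emission_sd > 0) {
        matrix(stats::rnorm(n_steps * d_slow, sd = emission_sd),
               n_steps, d_slow)
      } else 0
    feats <- if (fast_noise_dims > 0) {
      cbind(slow, matrix(stats::rnorm(n_steps * fast_noise_dims),
                         n_steps, fast_noise_dims))
    } else {
      slow
    }
    list(hidden = hidden, features = feats)
  })
  structure(list(features = out$features, hidden = out$hidden, stride = 1),
            class = "feature_trajectory")
}

# 20 standard amino acids, alphabetical one-letter order.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a multiple sequence alignment with controlled column profiles
#'
#' Each alignment column is sampled i.i.d. from its length-20 amino-acid
#' frequency profile, so empirical column frequencies converge to the
#' profiles as the number of sequences grows.
#'
#' @param column_profiles list (or 20-row matrix, one column per position) of
#'   length-20 frequency vectors over [AA20], each summing to 1 within 1e-9.
#' @param n_seqs number of sequences.
#' @param seed integer RNG seed.
#' @param ids optional sequence identifiers.
#' @return A `msa` object: list with `sequences` (character vector),
#'   `ids`.
#' @export
gen_alignment <- function(column_profiles, n_seqs, seed = 1L, ids = NULL) {
  if (is.matrix(column_profiles)) {
    column_profiles <- lapply(seq_len(ncol(column_profiles)),
                              function(j) column_profiles[, j])
  }
  for (p in column_profiles) {
    if (length(p) != 20L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      invalid_parameter("each column profile must be a length-20 frequency vector summing to 1")
    }
  }
  if (n_seqs < 1) invalid_parameter("`n_seqs` must be >= 1")
  cols <- with_seed(seed, {
    lapply(column_profiles, function(p) {
      sample(AA20, n_seqs, replace = TRUE, prob = p)
    })
  })
  seqs <- do.call(paste0, cols)
  if (is.null(ids)) ids <- sprintf("seq%04d", seq_len(n_seqs))
  structure(list(sequences = seqs, ids = ids), class = "msa")
}
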