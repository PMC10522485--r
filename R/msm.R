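# Markov state modelling: TICA featurization, k-means microstates,
# reversible maximum-likelihood MSM estimation, PCCA+ metastable
# decomposition, metastable thermodynamics and kinetics, and bootstrap
# uncertainty quantification.

#' Stationary distribution of a transition matrix
#'
#' Left Perron eigenvector of a row-stochastic matrix, normalized to sum 1.
#'
#' @param T row-stochastic transition matrix.
#' @return numeric stationary probability vector.
#' @export
stationary_distribution <- function(T) {
  check_row_stochastic(T)
  e <- eigen(t(T))
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Pairwise Calpha distance features around an anchor residue
#'
#' Selects all Calpha atoms within `radius` of the anchor residue's Calpha
#' in the reference structure and returns, per trajectory frame, all
#' pairwise distances among the selected atoms (fixed ordering: upper
#' triangle, row-major over the sorted selection).
#'
#' @param coords trajectory coordinates: array `frames x atoms x 3` (or a
#'   list of `atoms x 3` matrices, one per frame).
#' @param reference reference structure: `atoms x 3` coordinate matrix with
#'   the same atom ordering as the trajectory.
#' @param residue_ids residue identifiers, one per atom (shared between
#'   reference and trajectory).
#' @param anchor_residue residue id of the anchor.
#' @param radius selection radius in Angstrom (default 15).
#' @return a `feature_trajectory` whose `features` matrix has
#'   `m (m - 1) / 2` columns for a selection of m atoms; the selected
#'   residue ids and pair index are attached as attributes `"selection"` and
#'   `"pairs"`.
#' @export
extract_pair_distances <- function(coords, reference, residue_ids,
                                   anchor_residue, radius = 15) {
  if (is.list(coords)) {
    coords <- aperm(simplify2array(coords), c(3, 1, 2))
  }
  anchor_idx <- which(residue_ids == anchor_residue)
  if (length(anchor_idx) != 1L) {
    invalid_parameter("anchor residue absent (or ambiguous) in `residue_ids`")
  }
  d_ref <- sqrt(colSums((t(reference) - reference[anchor_idx, ])^2))
  sel <- which(d_ref <= radius)
  m <- length(sel)
  if (m < 2L) invalid_parameter("selection has fewer than 2 atoms")
  pairs <- utils::combn(sel, 2L)
  n_frames <- dim(coords)[1L]
  feats <- matrix(NA_real_, n_frames, ncol(pairs))
  for (f in seq_len(n_frames)) {
    xyz <- coords[f, , , drop = TRUE]
    d <- xyz[pairs[1L, ], , drop = FALSE] - xyz[pairs[2L, ], , drop = FALSE]
    feats[f, ] <- sqrt(rowSums(d^2))
  }
  structure(
    list(features = feats, hidden = NULL, stride = 1),
    class = "feature_trajectory",
    selection = residue_ids[sel],
    pairs = t(pairs)
  )
}

#' Time-lagged independent component analysis
#'
#' Solves the generalized eigenproblem `C_tau v = lambda C_0 v` with
#' mean-free instantaneous covariance `C_0` and symmetrized lagged
#' covariance `C_tau`, after ridge-regularized whitening
#' (`ridge = 1e-9 * trace(C_0)/dim`). Components are sorted by descending
#' eigenvalue; eigenvalues approximate autocorrelations at the lag, so the
#' leading components span the slowest linear coordinates.
#'
#' @param features a `feature_trajectory`, a numeric matrix, or a list of
#'   either (multiple trajectories share one model).
#' @param lag lag time in frames (>= 1).
#' @param n_components number of components to keep (default all).
#' @return list with `projections` (list of matrices), `eigenvalues`,
#'   `components` (columns = TICs in feature space), `mean`.
#' @export
tica <- function(features, lag, n_components = NULL) {
  if (lag < 1) invalid_parameter("`lag` must be >= 1")
  mats <- .as_feature_list(features)
  d <- ncol(mats[[1L]])
  total <- sum(vapply(mats, nrow, 1L))
  if (total <= d) invalid_parameter("need more frames than features")
  mu <- Reduce(`+`, lapply(mats, colSums)) / total
  c0 <- matrix(0, d, d); ct <- matrix(0, d, d); npairs <- 0
  for (x in mats) {
    xc <- sweep(x, 2L, mu)
    c0 <- c0 + crossprod(xc)
    n <- nrow(xc)
    if (n > lag) {
      a <- xc[1:(n - lag), , drop = FALSE]
      b <- xc[(1 + lag):n, , drop = FALSE]
      ct <- ct + (crossprod(a, b) + crossprod(b, a)) / 2
      npairs <- npairs + (n - lag)
    }
  }
  if (npairs == 0) invalid_parameter("no usable frame pairs at this lag")
  c0 <- c0 / total
  ct <- ct / npairs
  ridge <- 1e-9 * sum(diag(c0)) / d
  c0 <- c0 + diag(ridge, d)
  e0 <- eigen(c0, symmetric = TRUE)
  keep <- e0$values > 1e-12 * max(e0$values)
  if (!any(keep)) abort_mhc2x("instantaneous covariance is numerically zero",
                              "mhc2x_numerical_failure")
  W <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), sum(keep))
  M <- t(W) %*% ct %*% W
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  comps <- W %*% em$vectors
  vals <- em$values
  if (!is.null(n_components)) {
    n_components <- min(n_components, length(vals))
    comps <- comps[, seq_len(n_components), drop = FALSE]
    vals <- vals[seq_len(n_components)]
  }
  projections <- lapply(mats, function(x) sweep(x, 2L, mu) %*% comps)
  list(projections = projections, eigenvalues = vals,
       components = comps, mean = mu)
}

.as_feature_list <- function(features) {
  one <- function(f) {
    if (inherits(f, "feature_trajectory")) f$features else as.matrix(f)
  }
  if (inherits(features, "feature_trajectory") || is.matrix(features) ||
      is.data.frame(features)) {
    list(one(features))
  } else {
    lapply(features, one)
  }
}

#' Cluster projected trajectories into microstates
#'
#' k-means with greedy spread-out (k-means++ style) seeding followed by
#' Lloyd iterations; deterministic given `seed`. Every frame is assigned to
#' its nearest center.
#'
#' @param projections matrix or list of matrices (e.g. `$projections` from
#'   [tica()]).
#' @param k number of cluster centers.
#' @param seed integer RNG seed for the seeding step.
#' @param max_iter maximum Lloyd iterations.
#' @return a `dtraj_set` with `dtrajs` (1-based microstate sequences),
#'   `n_states = k`, and cluster `centers` attached.
#' @export
cluster_microstates <- function(projections, k, seed = 1L, max_iter = 100L) {
  mats <- .as_feature_list(projections)
  X <- do.call(rbind, mats)
  n <- nrow(X)
  if (k > n) invalid_parameter("`k` exceeds the number of frames")
  centers <- with_seed(seed, .kmeanspp_centers(X, k))
  km <- if (k == 1L) {
    list(centers = matrix(colMeans(X), 1L), cluster = rep(1L, n))
  } else {
    stats::kmeans(X, centers = centers, iter.max = max_iter,
                  algorithm = "Lloyd")
  }
  assign_all <- km$cluster
  lens <- vapply(mats, nrow, 1L)
  idx <- split(assign_all, rep(seq_along(mats), lens))
  structure(
    list(dtrajs = lapply(idx, as.integer), n_states = as.integer(k),
         stride = 1, centers = km$centers),
    class = "dtraj_set"
  )
}

# k-means++ greedy seeding (squared-distance weighted).
.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in 2:k) {
    pick <- if (all(d2 == 0)) sample.int(n, 1L) else {
      sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

#' Estimate a reversible Markov state model
#'
#' Sliding-window transition counts at the lag, restriction to the largest
#' strongly connected set of states, and reversible maximum-likelihood
#' estimation of the transition matrix by the standard detailed-balance
#' fixed-point iteration (converged when the maximum relative change of the
#' unnormalized flux matrix drops below 1e-10).
#'
#' @param dtrajs a `dtraj_set` or list of integer vectors (1-based states).
#' @param lag lag time in frames (>= 1).
#' @param n_states number of microstates (inferred if missing).
#' @param frame_time physical time per frame (default 1; used downstream).
#' @return an `msm_result`: list with `T` (transition matrix on the active
#'   set), `pi` (stationary distribution), `active` (original state labels
#'   of the active set), `counts` (full count matrix), `lag`, `frame_time`,
#'   `implied_timescales`.
#' @export
estimate_msm <- function(dtrajs, lag, n_states = NULL, frame_time = 1) {
  if (lag < 1) invalid_parameter("`lag` must be >= 1")
  trajs <- if (inherits(dtrajs, "dtraj_set")) dtrajs$dtrajs else dtrajs
  if (is.null(n_states)) {
    n_states <- if (inherits(dtrajs, "dtraj_set")) dtrajs$n_states else {
      max(unlist(trajs))
    }
  }
  C <- matrix(0, n_states, n_states)
  for (x in trajs) {
    n <- length(x)
    if (n > lag) {
      from <- x[1:(n - lag)]
      to <- x[(1 + lag):n]
      C <- C + matrix(tabulate(from + n_states * (to - 1L),
                               nbins = n_states^2), n_states, n_states)
    }
  }
  if (sum(C) == 0) {
    abort_mhc2x("no transition pairs at this lag", "mhc2x_disconnected")
  }
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  # largest SCC by total counts, restricted to states actually visited
  sizes <- vapply(seq_len(comp$no), function(m) {
    sum(C[comp$membership == m, comp$membership == m])
  }, 1)
  active <- which(comp$membership == which.max(sizes))
  if (length(active) < n_states) {
    warning(sprintf("restricting to largest connected set (%d of %d states)",
                    length(active), n_states))
  }
  Ca <- C[active, active, drop = FALSE]
  if (sum(Ca) == 0) abort_mhc2x("empty connected set", "mhc2x_disconnected")
  T <- .reversible_mle(Ca)
  pi_hat <- rowSums(.reversible_flux(Ca))
  pi_hat <- pi_hat / sum(pi_hat)
  ev <- sort(Re(eigen(T, only.values = TRUE)$values), decreasing = TRUE)
  its <- -lag / log(pmin(pmax(ev[-1L], .Machine$double.eps), 1 - 1e-15))
  structure(
    list(T = T, pi = pi_hat, active = active, counts = C, lag = lag,
         frame_time = frame_time, implied_timescales = its),
    class = "msm_result"
  )
}

# Reversible MLE flux matrix X (x_ij = x_ji, T = X / rowSums(X)) by the
# self-consistent iteration x_ij <- (c_ij + c_ji) / (c_i/x_i + c_j/x_j).
.reversible_flux <- function(C, tol = 1e-10, max_iter = 10000L) {
  Cs <- C + t(C)
  X <- Cs / sum(Cs)
  ci <- rowSums(C)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(X)
    denom <- outer(ci / xi, ci / xi, `+`)
    Xn <- ifelse(Cs > 0, Cs / denom, 0)
    Xn <- Xn / sum(Xn)
    delta <- max(abs(Xn - X) / pmax(X, 1e-300))
    X <- Xn
    if (delta < tol) break
  }
  X
}

.reversible_mle <- function(C) {
  X <- .reversible_flux(C)
  T <- X / rowSums(X)
  T / rowSums(T)   # renormalize against roundoff
}

#' PCCA+ metastable decomposition
#'
#' Fuzzy membership of microstates in `n_metastable` metastable sets from
#' the top right eigenvectors of a reversible transition matrix, using the
#' inner-simplex vertex initialization followed by feasibility projection
#' (memberships clipped to [0,1] and renormalized row-wise). A microstate
#' is crisply assigned to its maximal-membership metastable state iff that
#' membership exceeds `crisp_cutoff`; otherwise it stays unassigned.
#'
#' @param msm an `msm_result`.
#' @param n_metastable number of metastable states (2 <= m <= n active).
#' @param crisp_cutoff membership cutoff for crisp assignment (default 0.5).
#' @return a `metastable_model`: list with `memberships` (n x m, rows sum
#'   to 1), `assignment` (integer, NA = unassigned), `n_metastable`,
#'   `crisp_cutoff`.
#' @export
pcca <- function(msm, n_metastable, crisp_cutoff = 0.5) {
  T <- msm$T
  n <- nrow(T)
  m <- n_metastable
  if (m < 2 || m > n) {
    invalid_parameter("`n_metastable` must be between 2 and the active set size")
  }
  # Eigen via pi-symmetrization: S = D^{1/2} T D^{-1/2} is symmetric for a
  # reversible T, giving real spectra and stable vectors.
  pi_hat <- msm$pi
  sq <- sqrt(pi_hat)
  S <- (sq * T) %*% diag(1 / sq, n)   # rows scaled by sq, cols by 1/sq
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  ord <- order(es$values, decreasing = TRUE)
  vals <- es$values[ord][seq_len(m)]
  if (any(!is.finite(vals)) ||
      (m < n && abs(vals[m] - es$values[ord][m + 1L]) < 1e-12)) {
    abort_mhc2x("degenerate spectrum at the cut: requested metastable states exceed spectral support",
                "mhc2x_decomposition_error")
  }
  X <- es$vectors[, ord[seq_len(m)], drop = FALSE] / sq
  X[, 1L] <- 1
  # Inner simplex: pick m rows of X spanning the largest simplex.
  idx <- .inner_simplex_indices(X)
  A <- solve(X[idx, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  rs <- rowSums(chi)
  rs[rs == 0] <- 1
  chi <- chi / rs
  assign <- apply(chi, 1L, which.max)
  maxmem <- chi[cbind(seq_len(n), assign)]
  assign[maxmem <= crisp_cutoff] <- NA_integer_
  structure(
    list(memberships = chi, assignment = as.integer(assign),
         n_metastable = m, crisp_cutoff = crisp_cutoff,
         eigenvalues = vals),
    class = "metastable_model"
  )
}

# Successive furthest-row selection spanning the eigenvector simplex
# (standard PCCA+ initialization).
.inner_simplex_indices <- function(X) {
  m <- ncol(X)
  n <- nrow(X)
  idx <- integer(m)
  Y <- X
  idx[1L] <- which.max(rowSums(Y^2))
  Y <- sweep(Y, 2L, Y[idx[1L], ])
  for (j in 2:m) {
    nrm <- sqrt(rowSums(Y^2))
    idx[j] <- which.max(nrm)
    v <- Y[idx[j], ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-14) break
    v <- v / nv
    Y <- Y - (Y %*% v) %*% t(v)
  }
  idx
}

#' Metastable populations and relative free energies
#'
#' Population of each metastable state is the summed stationary probability
#' of its crisply assigned microstates. The most populated metastable state
#' is the reference (G = 0); others get
#' `G = -R T ln(pop / pop_ref)` in kJ/mol.
#'
#' @param msm an `msm_result`.
#' @param metastable a `metastable_model` from [pcca()].
#' @param temperature temperature in K (default 300).
#' @return list with `populations`, `free_energies` (kJ/mol), `reference`
#'   (index of the reference state), `unassigned` (stationary mass not
#'   crisply assigned), `temperature`.
#' @export
metastable_thermo <- function(msm, metastable, temperature = 300) {
  asg <- metastable$assignment
  m <- metastable$n_metastable
  if (sum(!is.na(unique(asg))) < 2L) {
    insufficient_data("need crisp assignments for >= 2 metastable states")
  }
  pops <- vapply(seq_len(m), function(j) sum(msm$pi[which(asg == j)]), 1)
  ref <- which.max(pops)
  rt <- .RGAS * temperature
  g <- ifelse(pops > 0, -rt * log(pops / pops[ref]), Inf)
  list(populations = pops, free_energies = g, reference = ref,
       unassigned = sum(msm$pi[is.na(asg)]), temperature = temperature)
}

#' Coarse transition rates between metastable states
#'
#' `rate(A -> B) = 1 / MFPT(A -> B)` where the mean first-passage time is
#' computed on the microstate transition matrix by solving the linear
#' system `(I - T_CC) h = lag * 1` (h = 0 on the target set B, C its
#' complement), then averaging over the source set A with weights
#' proportional to the stationary distribution restricted to A. Rates are
#' in inverse physical time (`frames * frame_time`).
#'
#' @param msm an `msm_result` (its `lag` and `frame_time` set the clock).
#' @param metastable a `metastable_model`.
#' @return matrix of rates, entry (A, B) = rate A -> B; diagonal NA.
#'   Unreachable targets give rate 0 with a warning.
#' @export
metastable_rates <- function(msm, metastable) {
  asg <- metastable$assignment
  m <- metastable$n_metastable
  present <- sort(unique(asg[!is.na(asg)]))
  if (length(present) < 2L) {
    insufficient_data("need >= 2 crisply assigned metastable states")
  }
  T <- msm$T
  n <- nrow(T)
  tau <- msm$lag * msm$frame_time
  rates <- matrix(NA_real_, m, m)
  for (b in present) {
    B <- which(asg == b)
    Cc <- setdiff(seq_len(n), B)
    h <- numeric(n)
    if (length(Cc) > 0) {
      A_mat <- diag(length(Cc)) - T[Cc, Cc, drop = FALSE]
      sol <- tryCatch(solve(A_mat, rep(tau, length(Cc))),
                      error = function(e) NULL)
      if (is.null(sol)) {
        warning("target metastable state unreachable; rate set to 0")
        h[Cc] <- Inf
      } else {
        h[Cc] <- sol
      }
    }
    for (a in setdiff(present, b)) {
      Aset <- which(asg == a)
      w <- msm$pi[Aset] / sum(msm$pi[Aset])
      mfpt <- sum(w * h[Aset])
      rates[a, b] <- if (is.finite(mfpt) && mfpt > 0) 1 / mfpt else 0
    }
  }
  rates
}

#' Bootstrap uncertainties for metastable populations, energies and rates
#'
#' Trajectories are resampled with replacement `n_boot` times; each
#' replicate re-estimates the MSM on the fixed microstate definitions and
#' re-runs PCCA+, with replicate metastable states matched to the full-data
#' model by maximal population overlap (greedy assignment). The reported
#' 1-sigma confidence interval is the standard deviation over replicates.
#'
#' @param dtrajs a `dtraj_set` or list of integer trajectories (>= 2
#'   trajectories; the trajectory is the resampling unit).
#' @param lag MSM lag in frames.
#' @param n_metastable number of metastable states.
#' @param n_boot number of bootstrap replicates (default 100).
#' @param seed integer RNG seed.
#' @param temperature temperature in K for free energies.
#' @param crisp_cutoff PCCA+ crisp assignment cutoff.
#' @param frame_time physical time per frame.
#' @return list with the full-data `msm`, `metastable`, `thermo`, `rates`,
#'   plus `population_sd`, `free_energy_sd`, `rate_sd`, and
#'   `n_dropped` (replicates discarded for connectivity failures).
#' @export
bootstrap_msm <- function(dtrajs, lag, n_metastable, n_boot = 100L,
                          seed = 1L, temperature = 300,
                          crisp_cutoff = 0.5, frame_time = 1) {
  trajs <- if (inherits(dtrajs, "dtraj_set")) dtrajs$dtrajs else dtrajs
  n_states <- if (inherits(dtrajs, "dtraj_set")) dtrajs$n_states else {
    max(unlist(trajs))
  }
  if (length(trajs) < 2L) {
    insufficient_data("bootstrap needs >= 2 trajectories")
  }
  full_msm <- estimate_msm(trajs, lag, n_states = n_states,
                           frame_time = frame_time)
  full_meta <- pcca(full_msm, n_metastable, crisp_cutoff)
  full_thermo <- metastable_thermo(full_msm, full_meta, temperature)
  full_rates <- metastable_rates(full_msm, full_meta)
  m <- n_metastable
  # Reference microstate -> metastable map in original state labels.
  ref_map <- rep(NA_integer_, n_states)
  ref_map[full_msm$active] <- full_meta$assignment
  pop_mat <- matrix(NA_real_, n_boot, m)
  g_mat <- matrix(NA_real_, n_boot, m)
  rate_arr <- array(NA_real_, c(n_boot, m, m))
  n_dropped <- 0L
  reps <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      sample.int(length(trajs), length(trajs), replace = TRUE)
    })
  })
  for (b in seq_len(n_boot)) {
    res <- tryCatch({
      bm <- suppressWarnings(
        estimate_msm(trajs[reps[[b]]], lag, n_states = n_states,
                     frame_time = frame_time)
      )
      bmeta <- pcca(bm, m, crisp_cutoff)
      # Match replicate metastable labels to the full-data model by
      # pi-weighted overlap of crisp assignments (greedy).
      boot_map <- rep(NA_integer_, n_states)
      boot_map[bm$active] <- bmeta$assignment
      overlap <- matrix(0, m, m)
      for (s in seq_len(n_states)) {
        i <- boot_map[s]; j <- ref_map[s]
        if (!is.na(i) && !is.na(j)) {
          k <- match(s, bm$active)
          overlap[i, j] <- overlap[i, j] + bm$pi[k]
        }
      }
      perm <- .greedy_match(overlap)
      bmeta$assignment <- perm[bmeta$assignment]
      bt <- metastable_thermo(bm, bmeta, temperature)
      br <- metastable_rates(bm, bmeta)
      list(pop = bt$populations, g = bt$free_energies, rates = br)
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_dropped <- n_dropped + 1L
    } else {
      pop_mat[b, ] <- res$pop
      g_mat[b, ] <- res$g
      rate_arr[b, , ] <- res$rates
    }
  }
  sd_ <- function(v) stats::sd(v[is.finite(v)])
  list(
    msm = full_msm, metastable = full_meta, thermo = full_thermo,
    rates = full_rates,
    population_sd = apply(pop_mat, 2L, sd_),
    free_energy_sd = apply(g_mat, 2L, sd_),
    rate_sd = apply(rate_arr, c(2L, 3L), sd_),
    population_boot = pop_mat, free_energy_boot = g_mat,
    n_dropped = n_dropped, n_boot = n_boot
  )
}

# Greedy one-to-one matching maximizing total overlap; returns perm such
# that replicate label i corresponds to reference label perm[i].
.greedy_match <- function(overlap) {
  m <- nrow(overlap)
  perm <- rep(NA_integer_, m)
  used <- logical(m)
  o <- overlap
  for (step in seq_len(m)) {
    best <- which(o == max(o), arr.ind = TRUE)[1L, ]
    if (o[best[1L], best[2L]] <= 0 && step > 1) break
    perm[best[1L]] <- best[2L]
    used[best[2L]] <- TRUE
    o[best[1L], ] <- -Inf
    o[, best[2L]] <- -Inf
  }
  # any unmatched replicate labels get the leftover reference labels
  if (anyNA(perm)) {
    perm[is.na(perm)] <- setdiff(seq_len(m), perm[!is.na(perm)])
  }
  perm
}
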