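# Shared fixtures, all generated in code.

# Reversible transition matrix with a prescribed stationary distribution
# (Metropolis acceptance on a uniform proposal).
metropolis_T <- function(pi_target, proposal = 0.05) {
  n <- length(pi_target)
  T <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) T[i, j] <- proposal * min(1, pi_target[j] / pi_target[i])
  }
  diag(T) <- 1 - rowSums(T)
  T
}

# 3-block 6-microstate metastable matrix: within-block mixing `p_in`,
# between-block leakage `eps`, block stationary weights `w`.
block_T <- function(w = c(0.08, 0.05, 0.87), eps = 0.01) {
  # two microstates per block; inter-block jumps via Metropolis on w
  Tm <- metropolis_T(w, proposal = eps)
  T <- matrix(0, 6, 6)
  for (a in 1:3) for (b in 1:3) {
    if (a == b) {
      T[2 * a - 1, 2 * a] <- 0.3
      T[2 * a, 2 * a - 1] <- 0.3
    } else {
      T[(2 * a - 1):(2 * a), (2 * b - 1):(2 * b)] <- Tm[a, b] / 2
    }
  }
  diag(T) <- 0
  diag(T) <- 1 - rowSums(T)
  T
}

# Helical two-chain Calpha structure (SYNTHETIC stand-in for a pMHCII
# heterodimer fold; real deposited coordinates are not bundled).
synthetic_heterodimer <- function(seed = 1L, n_a = 180L, n_b = 190L) {
  set.seed(seed)
  mkchain <- function(n, offset) {
    t <- seq_len(n)
    xyz <- cbind(cos(t / 3) * 5 + t * 0.8, sin(t / 3) * 5, t * 0.5)
    xyz <- sweep(xyz, 2L, offset, `+`)
    aa <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE)
    list(resno = seq_len(n), sequence = paste(aa, collapse = ""), xyz = xyz)
  }
  ca_structure(list(A = mkchain(n_a, c(0, 0, 0)),
                    B = mkchain(n_b, c(30, 5, 0))))
}

# Rigidly moved, noise-perturbed copy of a structure with optional outlier
# residues displaced by several Angstrom.
perturbed_copy <- function(s, seed = 2L, noise_sd = 0.3, n_outliers = 3L) {
  set.seed(seed)
  th <- runif(1, 0, pi)
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, byrow = TRUE)
  shift <- runif(3, -10, 10)
  for (ch in names(s)) {
    xyz <- s[[ch]]$xyz %*% t(R)
    xyz <- sweep(xyz, 2L, shift, `+`)
    xyz <- xyz + matrix(rnorm(length(xyz), sd = noise_sd), ncol = 3)
    if (n_outliers > 0) {
      out <- sample(nrow(xyz), n_outliers)
      xyz[out, ] <- xyz[out, ] + matrix(rnorm(3 * n_outliers, sd = 4),
                                        ncol = 3)
    }
    s[[ch]]$xyz <- xyz
  }
  s
}

# Minimal Calpha-only PDB writer for CLI round trips.
write_ca_pdb_file <- function(s, path) {
  lines <- character(0)
  i <- 0L
  aa1to3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
  for (chn in names(s)) {
    ch <- s[[chn]]
    aa <- strsplit(ch$sequence, "")[[1]]
    for (k in seq_along(ch$resno)) {
      i <- i + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, aa1to3[[aa[k]]], chn, ch$resno[k],
        ch$xyz[k, 1], ch$xyz[k, 2], ch$xyz[k, 3]))
    }
  }
  writeLines(lines, path)
  path
}
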