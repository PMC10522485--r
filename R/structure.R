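# Calpha structure comparison: PDB ATOM parsing, sequence-based residue
# pairing, Kabsch superposition with optional iterative outlier rejection.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

#' Read Calpha coordinates from a PDB file
#'
#' Parses ATOM records only (CA atoms, altloc blank or 'A', first model).
#'
#' @param path PDB file path.
#' @return a `ca_structure`: named list of chains, each a list with
#'   `resno` (integer), `sequence` (one-letter string), `xyz`
#'   (n x 3 matrix, Angstrom).
#' @export
read_ca_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]
  atoms <- lines[startsWith(lines, "ATOM")]
  name <- trimws(substr(atoms, 13, 16))
  altloc <- substr(atoms, 17, 17)
  keep <- name == "CA" & (altloc == " " | altloc == "A")
  atoms <- atoms[keep]
  if (length(atoms) == 0L) insufficient_data("no Calpha ATOM records found")
  chain <- substr(atoms, 22, 22)
  resno <- as.integer(substr(atoms, 23, 26))
  res3 <- trimws(substr(atoms, 18, 20))
  xyz <- cbind(as.numeric(substr(atoms, 31, 38)),
               as.numeric(substr(atoms, 39, 46)),
               as.numeric(substr(atoms, 47, 54)))
  out <- lapply(split(seq_along(atoms), chain), function(i) {
    o <- i[order(resno[i])]
    aa <- AA3TO1[res3[o]]
    aa[is.na(aa)] <- "X"
    list(resno = resno[o], sequence = paste(aa, collapse = ""),
         xyz = xyz[o, , drop = FALSE])
  })
  structure(out, class = "ca_structure")
}

#' Build a Calpha structure from coordinates
#'
#' Convenience constructor for synthetic or in-memory structures.
#'
#' @param chains named list; each element a list with `resno`, `sequence`,
#'   `xyz` (n x 3).
#' @return a `ca_structure`.
#' @export
ca_structure <- function(chains) {
  for (ch in chains) {
    if (nrow(ch$xyz) != length(ch$resno) ||
        nchar(ch$sequence) != length(ch$resno)) {
      invalid_parameter("chain fields must agree in length")
    }
    if (any(!is.finite(ch$xyz))) invalid_parameter("coordinates must be finite")
  }
  structure(chains, class = "ca_structure")
}

# Optimal proper rotation (Kabsch, SVD-based) mapping mobile onto target
# after centering. Returns list(R, t, rmsd).
.kabsch <- function(mobile, target) {
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(target, 2L, ct)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(R = R, t = ct - as.numeric(R %*% cm), rmsd = rmsd)
}

# Global pairwise alignment of two sequences (match +1, mismatch -1,
# gap -2) via Biostrings; returns index pairs.
.align_pairs <- function(seq1, seq2) {
  letters_all <- unique(c(strsplit(seq1, "")[[1]], strsplit(seq2, "")[[1]]))
  mat <- matrix(-1, length(letters_all), length(letters_all),
                dimnames = list(letters_all, letters_all))
  diag(mat) <- 1
  al <- Biostrings::pairwiseAlignment(
    Biostrings::BString(seq1), Biostrings::BString(seq2),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2
  )
  p <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  i1 <- Biostrings::start(Biostrings::pattern(al)) - 1L
  i2 <- Biostrings::start(Biostrings::subject(al)) - 1L
  out <- matrix(NA_integer_, 0L, 2L)
  for (k in seq_along(p)) {
    if (p[k] != "-") i1 <- i1 + 1L
    if (s[k] != "-") i2 <- i2 + 1L
    if (p[k] != "-" && s[k] != "-") out <- rbind(out, c(i1, i2))
  }
  out
}

#' Superpose two Calpha structures
#'
#' Chains are paired greedily by best alignment score, residues within
#' paired chains by global sequence alignment (match +1, mismatch -1,
#' gap -2). The optimal least-squares rotation is found by the Kabsch SVD
#' procedure (determinant +1 enforced). With `max_cycles > 0`, pairs whose
#' deviation exceeds `reject_factor` times the current RMSD are dropped and
#' the fit repeated, emulating the outlier-rejecting alignment used to
#' compare crystal structures; `max_cycles = 0` gives the plain Kabsch fit
#' on all pairs.
#'
#' @param mobile,target `ca_structure` objects.
#' @param max_cycles maximum outlier-rejection cycles (default 5).
#' @param reject_factor rejection threshold in multiples of the current
#'   RMSD (default 2).
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom, over retained pairs), `n_pairs` (retained),
#'   `n_pairs_initial`, `cycles`.
#' @export
superpose <- function(mobile, target, max_cycles = 5L, reject_factor = 2) {
  # Greedy chain pairing by alignment score.
  mob_chains <- names(mobile)
  tar_chains <- names(target)
  score <- matrix(-Inf, length(mob_chains), length(tar_chains),
                  dimnames = list(mob_chains, tar_chains))
  for (a in mob_chains) for (b in tar_chains) {
    pr <- .align_pairs(mobile[[a]]$sequence, target[[b]]$sequence)
    ident <- sum(substring(mobile[[a]]$sequence, pr[, 1L], pr[, 1L]) ==
                   substring(target[[b]]$sequence, pr[, 2L], pr[, 2L]))
    score[a, b] <- ident
  }
  P <- matrix(NA_real_, 0L, 3L)
  Q <- matrix(NA_real_, 0L, 3L)
  sc <- score
  repeat {
    if (all(!is.finite(sc)) || max(sc) <= 0) break
    best <- which(sc == max(sc), arr.ind = TRUE)[1L, ]
    a <- mob_chains[best[1L]]; b <- tar_chains[best[2L]]
    pr <- .align_pairs(mobile[[a]]$sequence, target[[b]]$sequence)
    P <- rbind(P, mobile[[a]]$xyz[pr[, 1L], , drop = FALSE])
    Q <- rbind(Q, target[[b]]$xyz[pr[, 2L], , drop = FALSE])
    sc[best[1L], ] <- -Inf
    sc[, best[2L]] <- -Inf
  }
  if (nrow(P) < 3L) insufficient_data("fewer than 3 residue pairs")
  keep <- seq_len(nrow(P))
  fit <- .kabsch(P, Q)
  cycles <- 0L
  if (max_cycles > 0) {
    for (cy in seq_len(max_cycles)) {
      moved <- sweep(P[keep, , drop = FALSE] %*% t(fit$R), 2L, fit$t, `+`)
      dev <- sqrt(rowSums((moved - Q[keep, , drop = FALSE])^2))
      drop_ <- dev > reject_factor * fit$rmsd
      if (!any(drop_) || sum(!drop_) < 3L) break
      keep <- keep[!drop_]
      fit <- .kabsch(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
      cycles <- cy
    }
  }
  list(rotation = fit$R, translation = fit$t, rmsd = fit$rmsd,
       n_pairs = length(keep), n_pairs_initial = nrow(P), cycles = cycles)
}
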