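# Sequence polymorphism: normalized Shannon entropy per alignment column.

#' Normalized entropy score of one alignment column
#'
#' `C = (-sum_a rho_a log2 rho_a) / log2(min(N, K))` where `rho_a = n_a / N`,
#' N is the number of residues observed at the position (gaps excluded) and
#' K the number of residue types (default 20). The min(N, K) normalization
#' keeps the score in [0, 1] even for shallow columns.
#'
#' @param counts per-residue-type counts at one column (numeric vector,
#'   zeros allowed).
#' @param k_types number of residue types K (default 20).
#' @return score in [0, 1].
#' @examples
#' position_entropy(c(1, 1))        # 1.0 (two types 50/50, N = 2)
#' position_entropy(c(2, 2))        # 0.5 (N = 4)
#' @export
position_entropy <- function(counts, k_types = 20L) {
  if (any(counts < 0)) invalid_parameter("counts must be nonnegative")
  n <- sum(counts)
  if (n < 2) {
    abort_mhc2x("entropy score undefined for N < 2 (denominator log2(min(N,K)) = 0)",
                "mhc2x_undefined_score")
  }
  p <- counts[counts > 0] / n
  h <- -sum(p * log2(p))
  h / log2(min(n, k_types))
}

#' Per-position entropy profile of a multiple alignment
#'
#' Applies [position_entropy()] to every column. Gaps (`-` or `.`) are
#' excluded from the per-column residue count N. Positions are reported both
#' as alignment columns and in the ungapped coordinates of the first
#' (reference) sequence, which allows mapping scores onto structure residue
#' numbers.
#'
#' @param alignment an `msa` (list with `sequences`), or a character vector
#'   of equal-length aligned sequences.
#' @param k_types number of residue types K (default 20).
#' @return data.frame with columns `column`, `ref_position` (NA where the
#'   reference has a gap), `n`, `score` (NA for all-gap or single-residue
#'   columns).
#' @export
profile_entropy <- function(alignment, k_types = 20L) {
  seqs <- if (is.list(alignment)) alignment$sequences else alignment
  if (length(seqs) < 2L) insufficient_data("need at least 2 sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    invalid_parameter("sequences must be aligned to equal length")
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  gap <- mat == "-" | mat == "."
  ref_gapless <- cumsum(!gap[1L, ])
  ncol_aln <- ncol(mat)
  score <- rep(NA_real_, ncol_aln)
  nres <- integer(ncol_aln)
  for (j in seq_len(ncol_aln)) {
    col <- mat[!gap[, j], j]
    nres[j] <- length(col)
    if (length(col) >= 2L) {
      score[j] <- position_entropy(table(col), k_types = k_types)
    }
  }
  data.frame(
    column = seq_len(ncol_aln),
    ref_position = ifelse(gap[1L, ], NA_integer_, ref_gapless),
    n = nres,
    score = score
  )
}

#' Write an alignment to FASTA
#'
#' @param alignment an `msa` object.
#' @param path output file path.
#' @export
write_msa_fasta <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", alignment$ids, "\n", alignment$sequences), con)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' @param path FASTA file path.
#' @return an `msa` object.
#' @export
read_msa_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  structure(list(sequences = unname(as.character(x)), ids = names(x)),
            class = "msa")
}
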