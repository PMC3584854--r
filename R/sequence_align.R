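# Global sequence alignment (Needleman-Wunsch / Gotoh, affine gaps).
# Scoring: BLOSUM62; a gap of length L costs gap_open + gap_ext * L
# (NCBI convention for "open 11 / extend 1"). Terminal gaps are penalized.
# Traceback ties are broken deterministically: substitution, then gap in
# the second sequence, then gap in the first.

nw_align <- function(seq_a, seq_b, gap_open = 11, gap_ext = 1) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) stop("empty sequence")
  bad <- unique(c(a, b)); bad <- bad[!bad %in% .BLOSUM62_LETTERS]
  if (length(bad)) stop("unknown amino-acid code(s): ", paste(bad, collapse = ", "))
  S <- .BLOSUM62[a, b, drop = FALSE]

  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends with a[i]~b[j]
  X <- matrix(NEG, n + 1, m + 1)   # ends with a[i]~gap
  Y <- matrix(NEG, n + 1, m + 1)   # ends with gap~b[j]
  pM <- matrix(0L, n + 1, m + 1)
  pX <- matrix(0L, n + 1, m + 1)
  pY <- matrix(0L, n + 1, m + 1)

  M[1, 1] <- 0
  if (n > 0) { X[2:(n + 1), 1] <- -(gap_open + gap_ext * (1:n)); pX[2:(n + 1), 1] <- 2L }
  if (m > 0) { Y[1, 2:(m + 1)] <- -(gap_open + gap_ext * (1:m)); pY[1, 2:(m + 1)] <- 3L }
  pX[2, 1] <- 1L; pY[1, 2] <- 1L

  for (i in 1:n) {
    for (j in 1:m) {
      ii <- i + 1L; jj <- j + 1L
      # M: from any state at (i-1, j-1)
      cand <- c(M[ii - 1L, jj - 1L], X[ii - 1L, jj - 1L], Y[ii - 1L, jj - 1L])
      k <- which.max(cand)
      M[ii, jj] <- cand[k] + S[i, j]; pM[ii, jj] <- k
      # X: consume a[i] against a gap
      cand <- c(M[ii - 1L, jj] - gap_open - gap_ext,
                X[ii - 1L, jj] - gap_ext,
                Y[ii - 1L, jj] - gap_open - gap_ext)
      k <- which.max(cand)
      X[ii, jj] <- cand[k]; pX[ii, jj] <- k
      # Y: consume b[j] against a gap
      cand <- c(M[ii, jj - 1L] - gap_open - gap_ext,
                X[ii, jj - 1L] - gap_open - gap_ext,
                Y[ii, jj - 1L] - gap_ext)
      k <- which.max(cand)
      Y[ii, jj] <- cand[k]; pY[ii, jj] <- k
    }
  }

  fin <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- which.max(fin)
  score <- fin[state]

  # traceback
  i <- n; j <- m
  ai <- integer(0); bj <- integer(0)   # 0 = gap
  while (i > 0 || j > 0) {
    if (state == 1L) {
      prev <- pM[i + 1L, j + 1L]
      ai <- c(i, ai); bj <- c(j, bj); i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      prev <- pX[i + 1L, j + 1L]
      ai <- c(i, ai); bj <- c(0L, bj); i <- i - 1L
    } else {
      prev <- pY[i + 1L, j + 1L]
      ai <- c(0L, ai); bj <- c(j, bj); j <- j - 1L
    }
    state <- prev
  }

  list(score = score,
       a_idx = ai, b_idx = bj,
       a_aligned = paste(ifelse(ai == 0, "-", a[pmax(ai, 1)]), collapse = ""),
       b_aligned = paste(ifelse(bj == 0, "-", b[pmax(bj, 1)]), collapse = ""))
}

#' Pairwise sequence identity from a global alignment
#'
#' Aligns two amino-acid sequences globally (BLOSUM62, affine gaps, open 11
#' / extend 1, end gaps penalized) and returns the fraction of alignment
#' columns with identical residues. Gap columns count in the denominator,
#' so the value depends on the full alignment length.
#'
#' @param seq_a,seq_b amino-acid strings (one-letter codes, `X` allowed)
#' @return fraction in `[0, 1]`; the alignment score and length are attached
#'   as attributes `score` and `alignment_length`
#' @examples
#' pairwise_identity("DKDKH", "DKDKH")  # 1
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  al <- nw_align(toupper(seq_a), toupper(seq_b))
  a <- strsplit(al$a_aligned, "")[[1]]
  b <- strsplit(al$b_aligned, "")[[1]]
  ident <- sum(a == b & a != "-")
  out <- ident / length(a)
  attr(out, "score") <- al$score
  attr(out, "alignment_length") <- length(a)
  out
}
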